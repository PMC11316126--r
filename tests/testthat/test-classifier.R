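# Topology classification: faces, descriptors, class lookup, overall topology.

test_that("the lookup table is well-formed and versioned", {
  tab <- zipper_class_table()
  expect_true(all(c(1:8) %in% tab$class_id))
  expect_equal(attr(tab, "lookup_version"), "1.0")
  op <- tab[tab$extra_symmetry_flag == "none", ]
  # descriptor combinations are unique and caption constraints hold
  expect_equal(anyDuplicated(op[, c("sheet_sense", "surface_parity",
                                    "sheet_direction")]), 0)
  expect_true(all(op$class_id[op$sheet_sense == "parallel"] %in% c(1:4)))
  expect_true(all(op$class_id[op$sheet_sense == "antiparallel"] %in% c(5:8)))
  expect_error(suppressWarnings(zipper_class_table(tempfile())))
})

test_that("face assignment follows the even/odd contact majority", {
  res <- fixture_class3_full()
  rep <- topology_report(res)
  odd <- grepl("LEU1", rep$residues_side_a)
  # odd-residue interface is back/back, even-residue interface face/face
  for (i in seq_along(res$interfaces)) {
    ifc <- res$interfaces[[i]]
    expected <- if (odd[i]) "back" else "face"
    expect_equal(ifc$face_a, expected)
    expect_equal(ifc$face_b, expected)
    # per-strand API agrees for a strand that carries contacts
    st <- ifc$sheet_a$strands[[unique(ifc$contact_pairs$strand_a)[1]]]
    expect_equal(assign_faces(st, ifc), expected)
  }
})

test_that("a parity tie falls back to the C-beta projection test", {
  res <- fixture_class3_full()
  ifc <- res$interfaces[[1]]
  cp <- ifc$contact_pairs
  side <- !(cp$name_a %in% c("N", "CA", "C", "O", "OXT"))
  one_even <- which(side & cp$resseq_a %% 2 == 0)[1]
  one_odd <- which(side & cp$resseq_a %% 2 == 1)[1]
  # class-3 interfaces are parity-pure on side a; build the tie by hand
  keep <- c(one_even, one_odd)
  keep <- keep[!is.na(keep)]
  if (length(keep) < 2) {
    # odd-odd interface: fabricate an even-residue contact row
    fake <- cp[one_odd, ]
    fake$resseq_a <- fake$resseq_a + 1
    ifc$contact_pairs <- rbind(cp[one_odd, ], fake)
  } else {
    ifc$contact_pairs <- cp[keep, ]
  }
  # both tie rows must sit on the same strand to exercise the fall-back
  ifc$contact_pairs$strand_a <- ifc$contact_pairs$strand_a[1]
  st <- ifc$sheet_a$strands[[ifc$contact_pairs$strand_a[1]]]
  # the fall-back resolves to the true (geometric) parity of the side
  expect_equal(assign_faces(st, ifc), res$interfaces[[1]]$face_a)
})

test_that("descriptors are symmetric under swapping the two sheets", {
  for (cl in c(2, 3, 7, 8)) {
    res <- fixture_classification(cl)
    ifc <- res$interfaces[[1]]
    d1 <- compute_descriptors(ifc)
    swapped <- ifc
    swapped$sheet_a <- ifc$sheet_b
    swapped$sheet_b <- ifc$sheet_a
    cp <- ifc$contact_pairs
    swapped$contact_pairs <- data.frame(
      strand_a = cp$strand_b, strand_b = cp$strand_a,
      name_a = cp$name_b, resname_a = cp$resname_b, resseq_a = cp$resseq_b,
      name_b = cp$name_a, resname_b = cp$resname_a, resseq_b = cp$resseq_a,
      xa = cp$xb, ya = cp$yb, za = cp$zb,
      xb = cp$xa, yb = cp$ya, zb = cp$za,
      dist = cp$dist, stringsAsFactors = FALSE)
    swapped$face_a <- ifc$face_b
    swapped$face_b <- ifc$face_a
    d2 <- compute_descriptors(swapped)
    expect_equal(d2, d1)
  }
})

test_that("antiparallel mirror pairs give opposite sheet direction", {
  # classes 7 (up-up) and 8 (up-down) differ only in direction
  d7 <- compute_descriptors(fixture_classification(7)$interfaces[[1]])
  d8 <- compute_descriptors(fixture_classification(8)$interfaces[[1]])
  expect_equal(d7$sheet_direction, "same")
  expect_equal(d8$sheet_direction, "opposite")
  expect_equal(d7$surface_parity, d8$surface_parity)
})

test_that("classification is a deterministic lookup with explicit misses", {
  combos <- expand.grid(sheet_sense = c("parallel", "antiparallel"),
                        surface_parity = c("same", "opposite"),
                        sheet_direction = c("same", "opposite"),
                        stringsAsFactors = FALSE)
  ids <- apply(combos, 1, function(r) {
    classify_interface(as.list(r))$class_id
  })
  expect_setequal(as.integer(ids), 1:8)
  # a truncated table yields "unclassified", never a coerced class
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# lookup_version: test",
               paste("sheet_sense", "surface_parity", "sheet_direction",
                     "extra_symmetry_flag", "class_id", sep = "\t"),
               paste("parallel", "same", "same", "none", "3", sep = "\t")), tf)
  small <- zipper_class_table(tf)
  miss <- classify_interface(list(sheet_sense = "antiparallel",
                                  surface_parity = "same",
                                  sheet_direction = "same"), small)
  expect_equal(miss$class_id, "unclassified")
  expect_equal(miss$basis$sheet_sense, "antiparallel")
  expect_equal(miss$lookup_version, "test")
})

test_that("the overall topology is the class of the largest interface", {
  mk <- function(id) structure(list(class_id = id, basis = list(),
                                    lookup_version = "1.0"),
                               class = "zipper_class")
  # three-interface map with a dominant extended interface
  t1 <- overall_topology(list(S1 = mk(1L), S2 = mk(4L), S3 = mk(4L)),
                         c(S1 = 250, S2 = 120, S3 = 100))
  expect_equal(t1$overall$class_id, 1L)
  # larger pair of one class dominating a smaller pair of another
  t2 <- overall_topology(
    list(S1 = mk(4L), S2 = mk(4L), S3 = mk(1L), S4 = mk(1L)),
    c(S1 = 200, S2 = 190, S3 = 80, S4 = 70))
  expect_equal(t2$overall$class_id, 4L)
  expect_equal(t2$dominant_label, "S1")
  t3 <- overall_topology(list(S1 = mk(8L)), c(S1 = 50))
  expect_equal(t3$overall$class_id, 8L)
  expect_error(overall_topology(list(), numeric()), "empty")
  expect_error(overall_topology(list(S1 = mk(1L)), c(S9 = 1)), "share keys")
})

test_that("synthetic analogues of the two LYIQNL forms classify as published", {
  rv <- zipper_analysis(synthetic_analogue("8QWV"), energies = FALSE,
                        geometry = FALSE)
  expect_equal(rv$topology$overall$class_id, 3L)
  rep <- topology_report(rv)
  main <- rep[rep$interface %in% c("S1", "S2"), ]
  expect_setequal(main$residues_side_a,
                  c("ASN5+ILE3+LEU1", "GLN4+LEU6+TYR2"))
  expect_equal(main$residues_side_a, main$residues_side_b)
  expect_true(all(main$class == "3"))
  ru <- zipper_analysis(synthetic_analogue("8QWU"), energies = FALSE,
                        geometry = FALSE)
  expect_equal(ru$topology$overall$class_id, 4L)
  repu <- topology_report(ru)
  expect_setequal(unlist(repu[repu$interface == "S1",
                              c("residues_side_a", "residues_side_b")]),
                  c("ASN5+ILE3+LEU1", "GLN4+LEU6+TYR2"))
})
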