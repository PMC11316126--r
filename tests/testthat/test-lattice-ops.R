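# Lattice expansion, sheet detection, interface enumeration, double layers.

test_that("the fibril axis is the unique ~4.8 A cell edge", {
  ax <- detect_fibril_axis(synthetic_analogue("8QWV"))
  expect_equal(ax$axis, "a")
  expect_equal(ax$length, 4.840)
  expect_equal(ax$repeat_len, 1L)
  ax2 <- detect_fibril_axis(synthetic_analogue("8QWU"))
  expect_equal(ax2$axis, "a")
  expect_equal(ax2$length, 4.848)
  # cubic toy cell: no candidate in either window -> ambiguous
  toy <- fixture_lattice(3)
  toy$cell <- unit_cell(10, 10, 10)
  expect_error(detect_fibril_axis(toy), "ambiguous-fibril-axis")
  ov <- detect_fibril_axis(toy, override = "b")
  expect_equal(ov$axis, "b")
  # antiparallel P 1 lattice: two-strand repeat window
  ax8 <- detect_fibril_axis(fixture_lattice(8))
  expect_equal(ax8$axis, "b")
  expect_equal(ax8$repeat_len, 2L)
})

test_that("pure-translation expansion yields exactly the in-radius copies", {
  strand <- build_ideal_strand("LYIQNL")
  strand$serial <- seq_len(nrow(strand))
  s <- crystal_structure(strand, unit_cell(40, 4.8, 40), "P 1",
                         source_id = "row")
  strands <- expand_lattice(s, radius = 1.5 * 4.8)
  expect_equal(length(strands), 3)
  shifts <- sort(vapply(strands, function(x) x$lattice_shift[2], integer(1)))
  expect_equal(shifts, c(-1L, 0L, 1L))
  # every copy is a rigid transform of the source
  d0 <- dist(strand[, c("x", "y", "z")])
  for (st in strands) {
    expect_lt(max(abs(dist(st$atoms[, c("x", "y", "z")]) - d0)), 1e-6)
  }
})

test_that("screw-operator copies appear in the monoclinic analogue", {
  s <- synthetic_analogue("8QWV")
  strands <- expand_lattice(s, 25)
  ops <- vapply(strands, function(x) x$op_index, integer(1))
  expect_true(any(ops != 1L))
  # rigid-transform preservation holds through the symmetry operator
  src <- split(s$atoms, s$atoms$chain)
  for (st in strands[ops != 1L][1:3]) {
    d0 <- dist(src[[st$source_chain]][, c("x", "y", "z")])
    expect_lt(max(abs(dist(st$atoms[, c("x", "y", "z")]) - d0)), 1e-6)
  }
})

test_that("sheets are grouped by backbone H-bond adjacency with correct sense", {
  r3 <- fixture_classification(3)
  expect_true(all(vapply(r3$sheets, function(sh) sh$sense, "") == "parallel"))
  expect_true(all(vapply(r3$sheets, function(sh) sh$repeat_len, 1L) == 1L))
  r8 <- fixture_classification(8)
  expect_true(all(vapply(r8$sheets, function(sh) sh$sense, "") == "antiparallel"))
  expect_true(all(vapply(r8$sheets, function(sh) sh$repeat_len, 1L) == 2L))
  # strands ordered along the axis
  sh <- r3$sheets[[1]]
  proj <- vapply(sh$strands, function(st) sum(colMeans(as.matrix(
    st$atoms[, c("x", "y", "z")])) * sh$fibril_axis), numeric(1))
  expect_false(is.unsorted(proj))
})

test_that("inputs without a hydrogen-bonded stack raise no-cross-beta", {
  strand <- build_ideal_strand("LYIQNL")
  strand$serial <- seq_len(nrow(strand))
  s <- crystal_structure(strand, unit_cell(60, 60, 60), "P 1",
                         source_id = "lonely")
  strands <- expand_lattice(s, 20) # only the identity copy fits
  expect_error(build_sheets(strands, c(0, 1, 0)), "no-cross-beta")
})

test_that("isolated sheets yield no interfaces, with a warning", {
  s <- build_lattice(lattice_spec(2, "LYIQNL", sheet_spacing = 24))
  axis <- detect_fibril_axis(s)
  strands <- expand_lattice(s, 20)
  sheets <- build_sheets(strands, axis)
  expect_warning(ifaces <- enumerate_interfaces(sheets, rank_areas = FALSE),
                 "no sheet-sheet contacts")
  expect_equal(length(ifaces), 0)
})

test_that("interface labels are deterministic and ordered by buried area", {
  res <- fixture_class3_full()
  labels <- vapply(res$interfaces, function(i) i$label, "")
  expect_equal(labels, paste0("S", seq_along(labels)))
  areas <- vapply(res$interfaces, function(i) i$buried_area_per_strand, 1)
  expect_false(is.unsorted(rev(areas)))
  # identical rerun gives identical labels and residue compositions
  res2 <- zipper_analysis(fixture_lattice(3))
  expect_identical(topology_report(res), topology_report(res2))
})

test_that("double layers hold 2x3 parallel or 2x6 antiparallel strands", {
  r3 <- fixture_classification(3)
  dl3 <- build_double_layer(r3$interfaces[[1]])
  expect_equal(dl3$n_per_sheet, 3L)
  expect_equal(length(dl3$sheets[[1]]$strands) + length(dl3$sheets[[2]]$strands), 6)
  expect_equal(length(dl3$central[[1]]), 1)
  expect_equal(length(dl3$central[[2]]), 1)
  r8 <- fixture_classification(8)
  dl8 <- build_double_layer(r8$interfaces[[1]])
  expect_equal(dl8$n_per_sheet, 6L)
  expect_equal(length(dl8$sheets[[1]]$strands) + length(dl8$sheets[[2]]$strands), 12)
  expect_equal(length(dl8$central[[1]]), 2)
  expect_equal(length(dl8$central[[2]]), 2)
  # the central strands of an antiparallel sheet are one translational repeat
  cs <- dl8$sheets[[1]]$strands[dl8$central[[1]]]
  expect_lt(sum(cs[[1]]$direction * cs[[2]]$direction), -0.9)
  # mixed-sense input errors
  bad <- r3$interfaces[[1]]
  bad$sheet_b <- r8$interfaces[[1]]$sheet_b
  expect_error(build_double_layer(bad), "inconsistent-sense")
  # parity of the stack size is enforced
  expect_error(build_double_layer(r3$interfaces[[1]], n_per_sheet = 4),
               "odd strand count")
  expect_error(build_double_layer(r8$interfaces[[1]], n_per_sheet = 5),
               "even strand count")
})

test_that("sheet membership is invariant under translations of the motif", {
  s <- fixture_lattice(4)
  r1 <- zipper_analysis(s, energies = FALSE, geometry = FALSE,
                        rank_areas = FALSE)
  # arbitrary translation plus one full lattice vector
  s2 <- s
  shift <- c(1.3, -0.4, 2.2) + c(0, s$cell$b, 0)
  s2$atoms$x <- s2$atoms$x + shift[1]
  s2$atoms$y <- s2$atoms$y + shift[2]
  s2$atoms$z <- s2$atoms$z + shift[3]
  r2 <- zipper_analysis(s2, energies = FALSE, geometry = FALSE,
                        rank_areas = FALSE)
  n1 <- sort(vapply(r1$sheets, function(sh) length(sh$strands), 1L))
  n2 <- sort(vapply(r2$sheets, function(sh) length(sh$strands), 1L))
  expect_equal(n1, n2)
  expect_equal(r2$topology$overall$class_id, r1$topology$overall$class_id)
  expect_equal(length(r2$interfaces), length(r1$interfaces))
})

test_that("classification is invariant under rotation of the expanded lattice", {
  s <- fixture_lattice(4)
  axis <- detect_fibril_axis(s)
  strands <- expand_lattice(s, 30)
  th <- 0.9; u <- c(1, 2, 2) / 3
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  rot <- lapply(strands, function(st) {
    xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% t(R)
    st$atoms$x <- xyz[, 1]; st$atoms$y <- xyz[, 2]; st$atoms$z <- xyz[, 3]
    st$xyz <- xyz; st$centroid <- colMeans(xyz)
    st$direction <- as.numeric(R %*% st$direction)
    st
  })
  cls <- function(strands, ax) {
    sheets <- build_sheets(strands, ax)
    ifaces <- enumerate_interfaces(sheets, rank_areas = FALSE)
    sort(vapply(ifaces, function(i) {
      as.character(classify_interface(compute_descriptors(i))$class_id)
    }, ""))
  }
  expect_equal(cls(rot, as.numeric(R %*% axis$vector)), cls(strands, axis$vector))
})
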