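# Space-group operator tables.
#
# Only the groups occurring in amyloid-like peptide crystals handled here are
# embedded (P 1, P 2\(_1\), P 2\(_1\) 2\(_1\) 2\(_1\), C 2 and the explicit
# P 1 2\(_1\) 1 setting). Any other symbol raises an "unsupported-spacegroup"
# error rather than silently falling back to P 1.

#' Symmetry operator
#'
#' A crystallographic symmetry operator in the fractional basis: a 3 x 3
#' rotation matrix over \{-1, 0, 1\} plus a translation vector of small
#' fractions.
#'
#' @param rotation 3 x 3 integer matrix, det = +/-1.
#' @param translation Numeric length-3 translation in fractional units.
#' @return An object of class `sym_op`.
#' @export
sym_op <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (abs(abs(det(rotation)) - 1) > 1e-9) stop("sym_op: rotation must have det +/-1")
  structure(list(R = rotation, t = as.numeric(translation)), class = "sym_op")
}

#' @export
print.sym_op <- function(x, ...) {
  cat("sym_op:", sym_op_string(x), "\n")
  invisible(x)
}

# human-readable xyz triplet, e.g. "-x,y+1/2,-z"
sym_op_string <- function(op) {
  axes <- c("x", "y", "z")
  paste(vapply(1:3, function(i) {
    terms <- ""
    for (j in 1:3) {
      r <- op$R[i, j]
      if (r == 1) terms <- paste0(terms, if (nzchar(terms)) "+" else "", axes[j])
      if (r == -1) terms <- paste0(terms, "-", axes[j])
    }
    tr <- op$t[i] %% 1
    if (abs(tr) > 1e-9) {
      fr <- .as_fraction(tr)
      terms <- paste0(terms, "+", fr)
    }
    terms
  }, character(1)), collapse = ",")
}

.as_fraction <- function(x) {
  for (den in c(2, 3, 4, 6, 12)) {
    num <- round(x * den)
    if (abs(x - num / den) < 1e-9) return(paste0(num, "/", den))
  }
  format(x)
}

# Apply op to fractional coordinates (n x 3 matrix or length-3 vector).
apply_sym_op <- function(op, xf, shift = c(0, 0, 0)) {
  if (!is.matrix(xf)) xf <- matrix(xf, 1, 3)
  sweep(xf %*% t(op$R), 2, op$t + shift, "+")
}

# Compose two operators: op1 followed by op2 (i.e. op2 %after% op1).
compose_sym_ops <- function(op2, op1) {
  sym_op(op2$R %*% op1$R, as.numeric(op2$R %*% op1$t) + op2$t)
}

.normalize_sg_symbol <- function(symbol) {
  s <- toupper(gsub("[ _()]", "", symbol))
  # strip explicit sub-script markers such as "21" already joined; map known
  # aliases to a canonical key
  map <- c(
    "P1" = "P1",
    "P21" = "P21", "P121" = "P21", "P1211" = "P21",
    "P212121" = "P212121",
    "C2" = "C2", "C121" = "C2", "C121" = "C2"
  )
  if (!s %in% names(map)) return(NA_character_)
  unname(map[s])
}

#' Space-group symmetry operators
#'
#' Look up the symmetry operators of a space group from its Hermann-Mauguin
#' symbol. Supported symbols: `"P 1"`, `"P 21"` (also written `"P 1 21 1"` or
#' `"P2_1"`), `"P 21 21 21"` (`"P2_1_2_1_2_1"`), and `"C 2"` (`"C 1 2 1"`);
#' spaces, underscores and case are ignored.
#'
#' @param symbol Hermann-Mauguin space-group symbol.
#' @return List of [sym_op()] objects; the first is always the identity.
#' @examples
#' length(space_group_ops("P 21 21 21")) # 4
#' @export
space_group_ops <- function(symbol) {
  key <- .normalize_sg_symbol(symbol)
  if (is.na(key)) {
    stop(sprintf(
      "unsupported-spacegroup: '%s' (supported: P 1, P 21, P 21 21 21, C 2)",
      symbol
    ))
  }
  id <- sym_op(diag(3))
  switch(key,
    P1 = list(id),
    # unique axis b
    P21 = list(
      id,
      sym_op(diag(c(-1, 1, -1)), c(0, 1 / 2, 0))
    ),
    P212121 = list(
      id,
      sym_op(diag(c(1, -1, -1)), c(1 / 2, 1 / 2, 0)),
      sym_op(diag(c(-1, 1, -1)), c(0, 1 / 2, 1 / 2)),
      sym_op(diag(c(-1, -1, 1)), c(1 / 2, 0, 1 / 2))
    ),
    C2 = list(
      id,
      sym_op(diag(c(-1, 1, -1)), c(0, 0, 0)),
      sym_op(diag(3), c(1 / 2, 1 / 2, 0)),
      sym_op(diag(c(-1, 1, -1)), c(1 / 2, 1 / 2, 0))
    )
  )
}

# canonical display form of a supported symbol
canonical_sg_symbol <- function(symbol) {
  key <- .normalize_sg_symbol(symbol)
  c(P1 = "P 1", P21 = "P 21", P212121 = "P 21 21 21", C2 = "C 2")[[key]]
}
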