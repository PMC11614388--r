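# Natural-abundance correction matrices and MID deconvolution.
#
# The observed isotopologue pattern of a fragment is the convolution of
# (i) tracer label on the tracer-eligible carbons and (ii) natural heavy
# isotopes on every remaining atom (including Si from TBDMS and O, N, S,
# H). Column j of the correction matrix is the theoretical observed pattern
# when exactly j tracer carbons carry label; solving A x ~ raw recovers the
# tracer-only mass isotopomer distribution x.

#' Build a per-fragment natural-abundance correction matrix
#'
#' Column `j` (for `j = 0..n_tracer`) is the theoretical observed pattern of
#' the fragment when exactly `j` tracer carbons are labeled: the natural
#' pattern of the fragment minus its `n_tracer` tracer carbons, convolved
#' with the natural pattern of the `n_tracer - j` unlabeled tracer carbons
#' and the tracer-purity binomial of the `j` labeled ones. With purity 1 the
#' tracer term is a delta at shift `j` and the matrix is lower-triangular
#' with positive diagonal.
#'
#' @param fragment `elemental_formula` of the measured fragment (after
#'   derivatization/fragmentation, e.g. from [tbdms_m57_fragment()]).
#' @param n_tracer Number of tracer-eligible carbons (<= fragment carbons).
#' @param purity Isotopic purity of the tracer substrate, in (0, 1]; each
#'   nominally labeled carbon is 13C with this probability. Default 1.
#' @param K Maximum retained mass shift; default `n_tracer + 4` to capture
#'   the Si/S heavy tails of TBDMS fragments.
#' @param table Isotope abundance table.
#' @return A `correction_matrix`: numeric `(K+1) x (n_tracer+1)` matrix with
#'   attributes `fragment`, `n_tracer`, `purity`.
#' @examples
#' A <- build_correction_matrix(parse_formula("C2"), n_tracer = 2, K = 2)
#' round(A, 6)
#' @export
build_correction_matrix <- function(fragment, n_tracer,
                                    purity = 1,
                                    K = n_tracer + 4L,
                                    table = default_isotope_table()) {
  stopifnot(inherits(fragment, "elemental_formula"))
  n_tracer <- as.integer(n_tracer)
  n_c <- if ("C" %in% names(fragment)) fragment[["C"]] else 0L
  if (n_tracer < 0) stop("n_tracer must be >= 0")
  if (n_tracer > n_c)
    stop("n_tracer (", n_tracer, ") exceeds fragment carbon count (", n_c, ")")
  if (purity <= 0 || purity > 1) stop("tracer purity must be in (0, 1]")
  K <- as.integer(K)
  stopifnot(K >= n_tracer)

  backbone <- if (n_tracer > 0) {
    formula_subtract(fragment, elemental_formula(c(C = n_tracer)))
  } else fragment
  base <- natural_pattern(backbone, K, table)
  c_nat <- single_atom_pattern("C", table, K)
  lab <- c(1 - purity, purity, numeric(K - 1))[seq_len(K + 1)]

  A <- matrix(0, nrow = K + 1, ncol = n_tracer + 1)
  for (j in 0:n_tracer) {
    col <- convolve_patterns(base, pattern_power(c_nat, n_tracer - j, K), K)
    col <- convolve_patterns(col, pattern_power(lab, j, K), K)
    A[, j + 1] <- col
  }
  structure(A,
            class = c("correction_matrix", "matrix", "array"),
            fragment = fragment, n_tracer = n_tracer, purity = purity)
}

#' @export
print.correction_matrix <- function(x, ...) {
  cat("<correction_matrix> fragment ", format(attr(x, "fragment")),
      ", n_tracer ", attr(x, "n_tracer"),
      ", purity ", attr(x, "purity"), "\n", sep = "")
  y <- unclass(x)
  attributes(y) <- attributes(y)["dim"]
  dimnames(y) <- list(paste0("m+", 0:(nrow(y) - 1)), paste0("x", 0:(ncol(y) - 1)))
  print(round(y, 6), ...)
  invisible(x)
}

#' Correct a raw isotopologue vector to a mass isotopomer distribution
#'
#' Solves `A x ~ raw` under `x >= 0` by non-negative least squares and
#' renormalizes `x` to sum 1. Non-negativity matters because measurement
#' noise makes naive matrix inversion return small negative fractions.
#' Raw vectors shorter than the matrix are zero-padded; longer ones are
#' truncated with a warning.
#'
#' @param raw Non-negative numeric vector of raw peak areas m+0, m+1, ...
#' @param A `correction_matrix` from [build_correction_matrix()].
#' @param residual_warn Relative 2-norm residual above which the result is
#'   flagged (default 0.05).
#' @return A `mid` object: list with `fractions` (sums to 1), `pool` (total
#'   corrected area, for abundance use), `residual` (relative 2-norm),
#'   `flagged` (logical).
#' @export
correct_mid <- function(raw, A, residual_warn = 0.05) {
  stopifnot(inherits(A, "correction_matrix"))
  if (any(is.na(raw)) || any(raw < 0)) stop("raw areas must be non-negative")
  Kp1 <- nrow(A)
  if (length(raw) > Kp1) {
    warning("raw vector longer than correction matrix (", length(raw), " > ",
            Kp1, "); truncating")
    raw <- raw[seq_len(Kp1)]
  } else if (length(raw) < Kp1) {
    raw <- c(raw, numeric(Kp1 - length(raw)))
  }
  if (sum(raw) == 0) stop("all-zero raw isotopologue vector: MID undefined")

  # scale-invariant solve keeps lsqnonneg's internal tolerance honest for
  # raw areas spanning ~1e9
  sc <- max(raw)
  x <- pracma::lsqnonneg(unclass(A), raw / sc)$x * sc
  resid <- sqrt(sum((as.vector(unclass(A) %*% x) - raw)^2)) / sqrt(sum(raw^2))
  pool <- sum(x)
  if (pool == 0) stop("corrected pool is zero: MID undefined")
  structure(list(fractions = x / pool, pool = pool, residual = resid,
                 flagged = resid > residual_warn),
            class = "mid")
}

#' @export
print.mid <- function(x, ...) {
  cat("<mid> ", paste0("m+", seq_along(x$fractions) - 1, "=",
                       signif(x$fractions, 4), collapse = " "),
      "\n  pool ", signif(x$pool, 6), ", rel. residual ", signif(x$residual, 3),
      if (x$flagged) " [FLAGGED]" else "", "\n", sep = "")
  invisible(x)
}

#' Fractional enrichment of a MID
#'
#' Mean labeled-carbon fraction, `sum(j * mid_j) / n_tracer`, in [0, 1].
#'
#' @param mid A `mid` object or plain MID fraction vector (m+0 first).
#' @param n_tracer Number of tracer-eligible carbons.
#' @return Scalar fraction.
#' @export
fractional_enrichment <- function(mid, n_tracer) {
  fr <- if (inherits(mid, "mid")) mid$fractions else mid
  stopifnot(n_tracer >= 1, all(fr >= -1e-12))
  sum((seq_along(fr) - 1) * fr) / n_tracer
}

#' Normalize a peak area to the internal standard and cell number
#'
#' Area divided by the internal-standard area (D-myristic acid, spiked at
#' 750 ng/sample) and by cell count, reported per 1e6 cells.
#'
#' @param area Peak area (>= 0).
#' @param internal_standard_area Internal-standard peak area (> 0).
#' @param cell_count Number of cells in the sample (> 0).
#' @return Normalized abundance, ratio per 1e6 cells.
#' @examples
#' normalize_abundance(100, 50, 1e6)  # 2 per 1e6 cells
#' @export
normalize_abundance <- function(area, internal_standard_area, cell_count) {
  if (any(internal_standard_area <= 0)) stop("internal standard area must be > 0")
  if (any(cell_count <= 0)) stop("cell count must be > 0")
  if (any(area < 0)) stop("area must be >= 0")
  area / internal_standard_area / cell_count * 1e6
}
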