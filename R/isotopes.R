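# Elemental formulas, TBDMS fragment arithmetic and theoretical
# natural-abundance isotope patterns.

#' Built-in natural isotope abundance table
#'
#' Relative abundances of stable isotopes, indexed by integer mass shift above
#' the lightest isotope. Values follow IUPAC representative isotopic
#' compositions. Sulfur's 36S sits at shift +4 (there is no stable shift +3
#' isotope); phosphorus and fluorine are monoisotopic.
#'
#' @return A named list; one element per chemical element, each a data frame
#'   with columns `shift` (integer, starting at 0, strictly increasing) and
#'   `abundance` (fractions summing to 1).
#' @examples
#' default_isotope_table()$C
#' @export
default_isotope_table <- function() {
  tab <- list(
    C  = list(shift = c(0L, 1L),          abundance = c(0.9893, 0.0107)),
    H  = list(shift = c(0L, 1L),          abundance = c(0.999885, 0.000115)),
    N  = list(shift = c(0L, 1L),          abundance = c(0.99636, 0.00364)),
    O  = list(shift = c(0L, 1L, 2L),      abundance = c(0.99757, 0.00038, 0.00205)),
    Si = list(shift = c(0L, 1L, 2L),      abundance = c(0.92223, 0.04685, 0.03092)),
    S  = list(shift = c(0L, 1L, 2L, 4L),  abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
    P  = list(shift = 0L,                 abundance = 1),
    F  = list(shift = 0L,                 abundance = 1)
  )
  lapply(tab, function(e) data.frame(shift = e$shift, abundance = e$abundance))
}

validate_isotope_table <- function(table) {
  stopifnot(is.list(table), length(table) > 0)
  for (el in names(table)) {
    e <- table[[el]]
    if (!all(c("shift", "abundance") %in% names(e)))
      stop("isotope table entry for ", el, " needs 'shift' and 'abundance'")
    if (e$shift[1] != 0 || any(diff(e$shift) <= 0))
      stop("isotope table shifts for ", el, " must start at 0 and increase")
    if (any(e$abundance < 0 | e$abundance > 1))
      stop("isotope table abundances for ", el, " must lie in [0,1]")
    if (abs(sum(e$abundance) - 1) > 1e-12)
      stop("isotope table abundances for ", el, " must sum to 1")
  }
  invisible(table)
}

#' Parse an elemental formula string
#'
#' Parses strings like `"C6H12O6"` or `"C11H25O3Si2"` into named integer atom
#' counts. An omitted count means 1. Element symbols must appear in the
#' isotope table, so typos are caught here rather than deep in a convolution.
#'
#' @param text Formula string, e.g. `"C3H6O3"`.
#' @param table Isotope table defining the known elements
#'   (default [default_isotope_table()]).
#' @return An `elemental_formula`: named integer vector of atom counts.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(text, table = default_isotope_table()) {
  stopifnot(is.character(text), length(text) == 1, !is.na(text))
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("malformed formula '", text, "': unparseable characters")
  counts <- integer(0)
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    if (!el %in% names(table))
      stop("unknown element '", el, "' in formula '", text, "'")
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  elemental_formula(counts)
}

#' Construct an elemental formula from atom counts
#'
#' @param counts Named integer vector (or coercible), element symbol -> count.
#' @return An `elemental_formula` with zero counts dropped.
#' @export
elemental_formula <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("atom counts must be named by element symbol")
  counts <- vapply(counts, function(x) {
    if (x < 0) stop("negative atom count in formula")
    as.integer(x)
  }, integer(1))
  # zero-atom formulas are allowed and convolve as the identity (delta at m+0)
  counts <- counts[counts > 0]
  counts <- counts[order(names(counts))]
  structure(counts, class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  ord <- c(intersect(c("C", "H"), names(x)), sort(setdiff(names(x), c("C", "H"))))
  paste0(ord, ifelse(unclass(x)[ord] == 1, "", unclass(x)[ord]), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Add or subtract elemental formulas
#'
#' Atom-count arithmetic. Subtraction that would drive any element below zero
#' raises an error, so infeasible derivatizations fail loudly.
#'
#' @param a,b `elemental_formula` objects.
#' @return An `elemental_formula`.
#' @export
formula_add <- function(a, b) {
  els <- union(names(a), names(b))
  out <- vapply(els, function(el) {
    (if (el %in% names(a)) a[[el]] else 0L) + (if (el %in% names(b)) b[[el]] else 0L)
  }, integer(1))
  elemental_formula(out)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  els <- union(names(a), names(b))
  out <- vapply(els, function(el) {
    (if (el %in% names(a)) a[[el]] else 0L) - (if (el %in% names(b)) b[[el]] else 0L)
  }, integer(1))
  if (any(out < 0))
    stop("formula subtraction yields negative count for ",
         paste(els[out < 0], collapse = ", "))
  elemental_formula(out)
}

#' TBDMS-derivatized M-57 fragment composition
#'
#' Each tert-butyldimethylsilyl (TBDMS) group replaces one active hydrogen
#' with C6H15Si; electron-impact ionization then cleaves a tert-butyl group
#' (C4H9, 57 Da) from one silicon, giving the characteristic M-57 fragment
#' whose composition (including silicon) governs the natural-abundance
#' correction.
#'
#' @param parent `elemental_formula` of the underivatized metabolite.
#' @param n_sites Number of TBDMS-derivatized active hydrogens (>= 1).
#' @return `elemental_formula` of the M-57 fragment.
#' @examples
#' tbdms_m57_fragment(parse_formula("C3H6O3"), 2)  # lactate -> C11H25O3Si2
#' @export
tbdms_m57_fragment <- function(parent, n_sites) {
  stopifnot(inherits(parent, "elemental_formula"))
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 1) stop("n_sites must be >= 1")
  tbdms <- elemental_formula(c(C = 6L, H = 15L, Si = 1L))
  out <- tryCatch({
    f <- formula_subtract(parent, elemental_formula(c(H = n_sites)))
    for (i in seq_len(n_sites)) f <- formula_add(f, tbdms)
    formula_subtract(f, elemental_formula(c(C = 4L, H = 9L)))
  }, error = function(e)
    stop("infeasible TBDMS derivatization of ", format(parent), " with ",
         n_sites, " site(s): ", conditionMessage(e)))
  out
}

#' Truncated discrete convolution of isotope patterns
#'
#' Convolves two mass-shift distributions and truncates at shift `K`.
#' Truncation only drops tail mass; retained entries are exact. The delta
#' pattern `c(1, 0, ...)` is the identity.
#'
#' @param a,b Numeric non-negative vectors indexed m+0, m+1, ...
#' @param K Maximum retained mass shift (result has `K + 1` entries).
#' @return Numeric vector of length `K + 1`.
#' @export
convolve_patterns <- function(a, b, K) {
  stopifnot(all(a >= 0), all(b >= 0), K >= 0)
  out <- numeric(K + 1)
  na <- min(length(a), K + 1)
  for (i in seq_len(na)) {
    if (a[i] == 0) next
    jmax <- min(length(b), K + 2 - i)
    if (jmax >= 1)
      out[i:(i + jmax - 1)] <- out[i:(i + jmax - 1)] + a[i] * b[seq_len(jmax)]
  }
  out
}

# pattern^n by exponentiation-by-squaring; identical contract to repeated
# convolution but O(log n) convolutions for e.g. H25 or C16 fragments.
pattern_power <- function(p, n, K) {
  out <- c(1, numeric(K))
  base <- p
  while (n > 0) {
    if (n %% 2 == 1) out <- convolve_patterns(out, base, K)
    n <- n %/% 2
    if (n > 0) base <- convolve_patterns(base, base, K)
  }
  out
}

single_atom_pattern <- function(element, table, K) {
  e <- table[[element]]
  if (is.null(e)) stop("element ", element, " missing from isotope table")
  p <- numeric(K + 1)
  keep <- e$shift <= K
  p[e$shift[keep] + 1] <- e$abundance[keep]
  p
}

#' Theoretical natural-abundance isotope pattern of a formula
#'
#' Convolution over all atoms of their single-atom mass-shift distributions,
#' truncated at m+`K`. The m+0 entry equals the product over elements of
#' (lightest-isotope abundance)^count.
#'
#' @param f `elemental_formula`.
#' @param K Maximum mass shift retained.
#' @param table Isotope table (default [default_isotope_table()]).
#' @return Numeric vector of length `K + 1` (fractions; sum <= 1, the deficit
#'   being truncated tail mass).
#' @examples
#' natural_pattern(parse_formula("C2"), K = 2)
#' @export
natural_pattern <- function(f, K, table = default_isotope_table()) {
  stopifnot(inherits(f, "elemental_formula"), K >= 0)
  validate_isotope_table(table)
  out <- c(1, numeric(K))
  for (el in names(f))
    out <- convolve_patterns(out, pattern_power(single_atom_pattern(el, table, K), f[[el]], K), K)
  out
}
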