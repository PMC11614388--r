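# Two-group differential metabolomics: fold change, Student's t, exact
# Wilcoxon rank-sum, BH FDR, pooled summaries, enrichment classification.

#' Fold change between group means
#'
#' `mean_treated / mean_control`. A zero mean is replaced by `pseudo` (the
#' caller's pseudo-abundance floor, typically half the smallest nonzero
#' value in the table); both means zero is undefined.
#'
#' @param mean_treated,mean_control Non-negative group means.
#' @param pseudo Pseudo-abundance substituted for a zero mean (default NA:
#'   zero means are an error).
#' @return Fold change (> 0).
#' @export
fold_change <- function(mean_treated, mean_control, pseudo = NA_real_) {
  if (mean_treated < 0 || mean_control < 0) stop("means must be >= 0")
  if (mean_treated == 0 && mean_control == 0)
    stop("fold change undefined: both group means are zero")
  if (mean_control == 0 || mean_treated == 0) {
    if (is.na(pseudo))
      stop("zero group mean and no pseudo-abundance configured")
    if (mean_control == 0) mean_control <- pseudo
    if (mean_treated == 0) mean_treated <- pseudo
  }
  mean_treated / mean_control
}

#' Base-2 log fold change
#'
#' @param fc Fold change (> 0).
#' @return `log2(fc)`. Rendered tables round to 2 decimals; machine output
#'   keeps full precision.
#' @export
log2fc <- function(fc) {
  if (any(fc <= 0)) stop("fold change must be > 0 for log2")
  log2(fc)
}

#' Two-tailed Student's t-test (pooled variance)
#'
#' Unpaired two-sample t with pooled variance, df = n1 + n2 - 2, two-tailed
#' p. Zero pooled variance with equal means gives t = 0, p = 1; with unequal
#' means p underflows to 0 and the result is flagged `degenerate`.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @examples
#' student_t_two_tailed(c(1, 2, 3), c(4, 5, 6))
#' @export
student_t_two_tailed <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  pooled_t_from_stats(mean(group_a), stats::sd(group_a), length(group_a),
                      mean(group_b), stats::sd(group_b), length(group_b))
}

#' Classify differential enrichment
#'
#' Volcano-style call: `label_treated` when `log2fc > lfc_threshold` and
#' `p < alpha`; `label_control` when `log2fc < -lfc_threshold` and
#' `p < alpha`; otherwise `"Not Sig"`.
#'
#' @param log2fc Log2 fold change (treated over control).
#' @param p Two-sided p-value.
#' @param lfc_threshold Absolute log2FC threshold (default 1, i.e. 2-fold).
#' @param alpha Significance threshold (default 0.05).
#' @param label_treated,label_control Labels for the two directions.
#' @return Character label.
#' @export
classify_enrichment <- function(log2fc, p, lfc_threshold = 1, alpha = 0.05,
                                label_treated = "treated",
                                label_control = "control") {
  dplyr::case_when(
    log2fc > lfc_threshold & p < alpha ~ label_treated,
    log2fc < -lfc_threshold & p < alpha ~ label_control,
    TRUE ~ "Not Sig")
}

#' Wilcoxon rank-sum p-value
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum p. `mode = "exact"` demands the
#' exact null distribution (full enumeration over rank assignments; refused
#' when ties make it invalid), `"normal-approx"` forces the normal
#' approximation with tie and continuity correction, and `"auto"` uses the
#' exact form whenever there are no ties and both groups have < 50
#' observations.
#'
#' @param group_a,group_b Numeric vectors (n >= 1 each).
#' @param mode `"auto"`, `"exact"` or `"normal-approx"`.
#' @return Two-sided p-value, capped at 1.
#' @examples
#' wilcoxon_rank_sum(1:6, 7:12)  # complete separation: 2/choose(12, 6)
#' @export
wilcoxon_rank_sum <- function(group_a, group_b,
                              mode = c("auto", "exact", "normal-approx")) {
  mode <- match.arg(mode)
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  if (mode == "exact" && ties)
    stop("ties present: the exact rank-sum null is invalid; use mode = \"auto\"")
  exact <- switch(mode, exact = TRUE, `normal-approx` = FALSE,
                  auto = !ties && length(group_a) < 50 && length(group_b) < 50)
  p <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE,
                       alternative = "two.sided")$p.value)
  min(p, 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values over the submitted family.
#'
#' @param p_values Vector of p-values in [0, 1].
#' @return q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Pool two group summaries into an overall mean and SD
#'
#' Exact pooling of per-group means and SDs: the overall mean is the
#' size-weighted mean and the overall variance combines within-group and
#' between-group terms,
#' `[(nA-1) sdA^2 + (nB-1) sdB^2 + nA (mA - M)^2 + nB (mB - M)^2] / (nA + nB - 1)`.
#' Composing this with per-group summaries of raw data reproduces the
#' summary of the concatenated raw data exactly.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries (n >= 2 each).
#' @return List with `mean` and `sd` of the pooled sample.
#' @export
pooled_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2)
  m <- (n_a * mean_a + n_b * mean_b) / (n_a + n_b)
  v <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2 +
          n_a * (mean_a - m)^2 + n_b * (mean_b - m)^2) / (n_a + n_b - 1)
  list(mean = m, sd = sqrt(v))
}

#' Two-group differential table
#'
#' One row per metabolite of a two-group abundance matrix: group means, fold
#' change (treated over control), log2FC, p (Student's t or Wilcoxon
#' rank-sum), -log10 p, optional BH q over all rows, and the enrichment
#' call. Zero group means use a pseudo-abundance of half the smallest
#' nonzero value in the table. Per-metabolite failures become flagged rows
#' (`note` column), never abort the table.
#'
#' @param abundances Numeric matrix or data frame, metabolites x samples,
#'   with metabolite names as rownames (or a `metabolite` first column).
#' @param groups Character/factor vector, one label per sample column.
#' @param treated Label of the treated group (numerator of FC); default the
#'   second level encountered.
#' @param test `"student_t"` or `"wilcoxon"`.
#' @param with_fdr Add BH q-values over all rows (default FALSE).
#' @param lfc_threshold,alpha Classification thresholds (defaults 1 and
#'   0.05).
#' @param sort `"lfc"` (|log2FC| descending) or `"p"` (ascending).
#' @return Tibble with columns `metabolite, mean_control, mean_treated, fc,
#'   log2fc, p, minus_log10_p, (q,) enrichment, note`.
#' @export
differential_table <- function(abundances, groups, treated = NULL,
                               test = c("student_t", "wilcoxon"),
                               with_fdr = FALSE, lfc_threshold = 1,
                               alpha = 0.05, sort = c("lfc", "p")) {
  test <- match.arg(test)
  sort <- match.arg(sort)
  if (is.data.frame(abundances)) {
    if (!is.numeric(abundances[[1]])) {
      mets <- as.character(abundances[[1]])
      abundances <- as.matrix(abundances[, -1, drop = FALSE])
      rownames(abundances) <- mets
    } else abundances <- as.matrix(abundances)
  }
  if (is.null(rownames(abundances)))
    rownames(abundances) <- paste0("metabolite_", seq_len(nrow(abundances)))
  groups <- as.character(groups)
  if (length(groups) != ncol(abundances))
    stop("groups length (", length(groups), ") != number of sample columns (",
         ncol(abundances), ")")
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required, got: ",
                            paste(lv, collapse = ", "))
  if (is.null(treated)) treated <- lv[2]
  if (!treated %in% lv) stop("treated label '", treated, "' not among groups")
  control <- setdiff(lv, treated)
  if (sum(groups == treated) < 2 || sum(groups == control) < 2)
    stop("each group needs >= 2 samples")
  if (any(abundances < 0, na.rm = TRUE)) stop("abundances must be >= 0")

  nz <- abundances[abundances > 0]
  pseudo <- if (length(nz) > 0) min(nz) / 2 else NA_real_

  rows <- lapply(rownames(abundances), function(met) {
    a <- abundances[met, groups == treated]
    b <- abundances[met, groups == control]
    res <- tryCatch({
      fc <- fold_change(mean(a), mean(b), pseudo = pseudo)
      p <- if (test == "student_t") student_t_two_tailed(a, b)$p
           else wilcoxon_rank_sum(a, b, mode = "auto")
      tibble::tibble(metabolite = met, mean_control = mean(b),
                     mean_treated = mean(a), fc = fc, log2fc = log2fc(fc),
                     p = p, note = NA_character_)
    }, error = function(e)
      tibble::tibble(metabolite = met, mean_control = mean(b),
                     mean_treated = mean(a), fc = NA_real_, log2fc = NA_real_,
                     p = NA_real_, note = conditionMessage(e)))
    res
  })
  out <- dplyr::bind_rows(rows)
  out$minus_log10_p <- -log10(out$p)
  if (with_fdr) out$q <- bh_fdr(out$p)
  out$enrichment <- classify_enrichment(out$log2fc, out$p,
                                        lfc_threshold = lfc_threshold,
                                        alpha = alpha,
                                        label_treated = treated,
                                        label_control = control)
  out$enrichment[is.na(out$p)] <- NA_character_
  if (sort == "lfc") out <- out[order(-abs(out$log2fc)), ]
  else out <- out[order(out$p), ]
  out
}

#' Volcano plot of a differential table
#'
#' log2 fold change against -log10 p, colored by enrichment call.
#'
#' @param diff Tibble from [differential_table()].
#' @param lfc_threshold,alpha Guide-line positions (defaults 1 and 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(diff, lfc_threshold = 1, alpha = 0.05) {
  d <- diff[!is.na(diff$p), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc, y = .data$minus_log10_p,
                                  color = .data$enrichment)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(-1, 1) * lfc_threshold, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p") +
    ggplot2::theme_minimal()
}
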