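# Experiment-level readouts: per-sample correction of a whole study table,
# per-condition labeling summaries, and media-transfer joins.

#' Correct every sample in a study table
#'
#' Applies [correct_mid()] to each metabolite of each sample of a wide area
#' table. Isotopologue columns are named `<metabolite>|m+<i>`; metadata comes
#' from the design sheet.
#'
#' @param areas Tibble with a `sample` column plus `<metabolite>|m+<i>` area
#'   columns.
#' @param design Tibble with columns `sample, group, compartment, cells,
#'   is_area`.
#' @param registry Metabolite registry tibble (default [default_registry()]).
#' @param purity Tracer purity passed to the correction matrices.
#' @param extra_shifts Heavy-tail channels beyond m+n (default 4).
#' @param residual_warn Residual flag threshold passed to [correct_mid()].
#' @return Long tibble: one row per sample x metabolite x isotopologue with
#'   `mid` (fraction), `pool` (total corrected area), `rel_abundance`
#'   (corrected isotopologue area normalized to internal standard and per
#'   1e6 cells), `enrichment` (fractional enrichment of the metabolite in
#'   that sample), `residual`, `flagged`.
#' @export
correct_samples <- function(areas, design, registry = default_registry(),
                            purity = 1, extra_shifts = 4L,
                            residual_warn = 0.05) {
  stopifnot("sample" %in% names(areas))
  need <- c("sample", "group", "compartment", "cells", "is_area")
  miss <- setdiff(need, names(design))
  if (length(miss) > 0)
    stop("design sheet missing column(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(areas$sample, design$sample)
  if (length(absent) > 0)
    stop("samples missing from design sheet: ", paste(absent, collapse = ", "))

  chan <- parse_channel_names(setdiff(names(areas), "sample"))
  mets <- unique(chan$metabolite)
  unknown <- setdiff(mets, registry$name)
  if (length(unknown) > 0)
    stop("metabolite(s) not in registry: ", paste(unknown, collapse = ", "))

  mats <- lapply(stats::setNames(mets, mets), function(m)
    registry_correction_matrix(registry, m, purity = purity,
                               extra_shifts = extra_shifts))

  out <- vector("list", nrow(areas) * length(mets))
  k <- 0
  for (i in seq_len(nrow(areas))) {
    smp <- areas$sample[i]
    meta <- design[design$sample == smp, ][1, ]
    for (m in mets) {
      cols <- chan$column[chan$metabolite == m][order(chan$shift[chan$metabolite == m])]
      raw <- as.numeric(unlist(areas[i, cols], use.names = FALSE))
      # metabolites not measured in this sample's compartment appear as
      # all-NA channel blocks and are skipped; partial NA is a data error
      if (all(is.na(raw))) next
      if (any(is.na(raw)))
        stop("sample ", smp, ", metabolite ", m,
             ": some but not all isotopologue channels are missing")
      fit <- correct_mid(raw, mats[[m]], residual_warn = residual_warn)
      n_tr <- length(fit$fractions) - 1
      k <- k + 1
      out[[k]] <- tibble::tibble(
        sample = smp, group = meta$group, compartment = meta$compartment,
        metabolite = m, isotopologue = 0:n_tr, mid = fit$fractions,
        pool = fit$pool,
        rel_abundance = normalize_abundance(fit$pool * fit$fractions,
                                            meta$is_area, meta$cells),
        enrichment = fractional_enrichment(fit, n_tr),
        residual = fit$residual, flagged = fit$flagged)
    }
  }
  dplyr::bind_rows(out)
}

parse_channel_names <- function(cols) {
  ok <- grepl("^.+\\|m\\+[0-9]+$", cols)
  if (any(!ok))
    stop("malformed isotopologue column name(s): ",
         paste(cols[!ok], collapse = ", "), " (expect '<metabolite>|m+<i>')")
  tibble::tibble(
    column = cols,
    metabolite = sub("\\|m\\+[0-9]+$", "", cols),
    shift = as.integer(sub("^.+\\|m\\+", "", cols)))
}

#' Summarize labeling of one isotopologue per condition
#'
#' Figure-style per-group summary (mean +/- SEM) of either the MID fraction
#' or the normalized labeled abundance of one `metabolite` isotopologue
#' `m+j`.
#'
#' @param corrected Long tibble from [correct_samples()].
#' @param metabolite Metabolite name.
#' @param j Isotopologue index (mass shift).
#' @param mode `"fraction"` (MID fraction) or `"relative_abundance"`
#'   (corrected isotopologue area per internal standard per 1e6 cells).
#' @param compartment Optional compartment filter (`"cell"`, `"media"`,
#'   `"recipient-cell"`).
#' @return A `label_readout` tibble: one row per group with `n`, `mean`,
#'   `sd`, `sem`, plus `metabolite`, `isotopologue`, `mode` columns.
#' @export
summarize_labeling <- function(corrected, metabolite, j,
                               mode = c("fraction", "relative_abundance"),
                               compartment = NULL) {
  mode <- match.arg(mode)
  d <- corrected
  if (!is.null(compartment)) d <- d[d$compartment == compartment, ]
  missing_samples <- unique(d$sample[!d$sample %in%
    d$sample[d$metabolite == metabolite]])
  d <- d[d$metabolite == metabolite & d$isotopologue == j, ]
  if (nrow(d) == 0)
    stop("no data for ", metabolite, " m+", j,
         if (!is.null(compartment)) paste0(" in compartment '", compartment, "'"))
  if (length(missing_samples) > 0)
    stop("metabolite '", metabolite, "' absent from sample(s): ",
         paste(missing_samples, collapse = ", "))
  d$value <- if (mode == "fraction") d$mid else d$rel_abundance
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$group),
    n = dplyr::n(),
    mean = mean(.data$value),
    sd = stats::sd(.data$value),
    sem = .data$sd / sqrt(.data$n),
    .groups = "drop")
  out$metabolite <- metabolite
  out$isotopologue <- as.integer(j)
  out$mode <- mode
  class(out) <- c("label_readout", class(out))
  out
}

# pooled-variance two-sample t from summary statistics; shared core for
# compare_conditions() and student_t_two_tailed()
pooled_t_from_stats <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 == 0) {
    if (m1 == m2)
      return(list(t = 0, p = 1, df = df, degenerate = FALSE))
    return(list(t = sign(m1 - m2) * Inf, p = 0, df = df, degenerate = TRUE))
  }
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df), df = df, degenerate = FALSE)
}

#' Compare the two conditions of a labeling readout
#'
#' Pooled-variance (Student's) two-sample t-test on the two groups of a
#' [summarize_labeling()] readout, two-tailed, df = n1 + n2 - 2. Welch's
#' unequal-variance form is available behind `welch = TRUE`.
#'
#' @param readout `label_readout` with exactly two groups.
#' @param welch Use Welch's t instead of the pooled form (default FALSE).
#' @return List with `t`, `p`, `df`, `degenerate` (TRUE when both groups
#'   have zero variance but different means, so p underflows to 0).
#' @export
compare_conditions <- function(readout, welch = FALSE) {
  stopifnot(nrow(readout) == 2)
  r <- readout
  if (!welch)
    return(pooled_t_from_stats(r$mean[1], r$sd[1], r$n[1],
                               r$mean[2], r$sd[2], r$n[2]))
  se2 <- r$sd^2 / r$n
  if (sum(se2) == 0) {
    if (r$mean[1] == r$mean[2]) return(list(t = 0, p = 1, df = NA, degenerate = FALSE))
    return(list(t = sign(r$mean[1] - r$mean[2]) * Inf, p = 0, df = NA, degenerate = TRUE))
  }
  tt <- (r$mean[1] - r$mean[2]) / sqrt(sum(se2))
  df <- sum(se2)^2 / sum(se2^2 / (r$n - 1))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df), df = df, degenerate = FALSE)
}

#' Join donor-media and recipient-cell labeling readouts
#'
#' For media-transfer experiments (conditioned media from a tracing
#' experiment incubated with recipient cells): joins donor-media labeled
#' abundance with recipient intracellular labeled abundance on shared
#' metabolite/isotopologue keys, per group. Recipient-only keys are dropped
#' with a message.
#'
#' @param donor_media,recipient_cells `label_readout` tibbles (stackable:
#'   several readouts row-bound together).
#' @return Tibble with one row per shared metabolite x isotopologue x group
#'   and columns `donor_mean, donor_sem, donor_n, recipient_mean,
#'   recipient_sem, recipient_n`.
#' @export
media_transfer_table <- function(donor_media, recipient_cells) {
  key <- c("metabolite", "isotopologue", "group")
  dropped <- dplyr::anti_join(recipient_cells, donor_media,
                              by = c("metabolite", "isotopologue"))
  if (nrow(dropped) > 0)
    message("dropping recipient-only metabolite/isotopologue key(s): ",
            paste(unique(paste0(dropped$metabolite, " m+", dropped$isotopologue)),
                  collapse = ", "))
  joined <- dplyr::inner_join(
    dplyr::select(donor_media, dplyr::all_of(key),
                  donor_mean = "mean", donor_sem = "sem", donor_n = "n"),
    dplyr::select(recipient_cells, dplyr::all_of(key),
                  recipient_mean = "mean", recipient_sem = "sem",
                  recipient_n = "n"),
    by = key)
  if (nrow(joined) == 0)
    stop("no shared metabolite/isotopologue keys between donor media and recipient cells")
  joined
}
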