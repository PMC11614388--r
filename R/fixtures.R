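# Bundled, fully synthetic study fixtures: self-contained input sets with
# documented ground truth for each experiment shape the pipeline handles.

#' Reference CSF differential-metabolomics table
#'
#' Bundled reference summary (34 metabolites) from a published targeted
#' metabolomics screen of cerebrospinal fluid, 3-day high-fat diet vs
#' control mice (n = 10 per group): printed fold changes and two-sided
#' p-values. Used as ground-truth effect sizes by the `csf_3dHFD` fixture
#' and as a worked reference input for the differential-statistics stage.
#'
#' @return Tibble with columns `metabolite`, `fc`, `p_value`.
#' @export
csf_reference <- function() {
  readr::read_csv(system.file("extdata", "csf_hfd3d_reference.csv",
                              package = "midtracer"),
                  comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Reference conditioned-media group statistics
#'
#' Bundled per-group summary statistics (mean, SD, n = 6 per group) from a
#' published conditioned-media metabolomics screen (control BSA vs
#' palmitate-treated cultures), ten rows. Input for [pooled_summary()]
#' reproduction and ground truth for the `media_24h` fixture.
#'
#' @return Tibble with columns `metabolite, n_bsa, mean_bsa, sd_bsa, n_pa,
#'   mean_pa, sd_pa, p_printed`.
#' @export
media_reference_stats <- function() {
  readr::read_csv(system.file("extdata", "media_conditioned_reference_stats.csv",
                              package = "midtracer"),
                  comment = "#", show_col_types = FALSE, progress = FALSE)
}

glucose_6h_scenario <- function() {
  dplyr::bind_rows(
    scenario_row("glucose",   "cell",  "BSA", mid_point_mass(6, 6, 0.55), 5e8),
    scenario_row("glucose",   "cell",  "PA",  mid_point_mass(6, 6, 0.70), 5e8),
    scenario_row("glutamate", "cell",  "BSA", mid_point_mass(5, 2, 0.10), 2e7),
    scenario_row("glutamate", "cell",  "PA",  mid_point_mass(5, 2, 0.20), 2e7),
    scenario_row("lactate",   "media", "BSA", mid_point_mass(3, 3, 0.30), 1e8),
    scenario_row("lactate",   "media", "PA",  mid_point_mass(3, 3, 0.45), 1.5e8),
    scenario_row("glutamate", "media", "BSA", mid_point_mass(5, 2, 0.05), 5e6),
    scenario_row("glutamate", "media", "PA",  mid_point_mass(5, 2, 0.12), 7e6),
    scenario_row("itaconate", "media", "BSA", mid_point_mass(5, 1, 0.04), 2e6),
    scenario_row("itaconate", "media", "PA",  mid_point_mass(5, 1, 0.10), 3e6),
    scenario_row("succinate", "media", "BSA", mid_point_mass(4, 2, 0.06), 3e6),
    scenario_row("succinate", "media", "PA",  mid_point_mass(4, 2, 0.14), 4e6),
    # media-transfer arm: recipient neurons take up ~30% of the donor media
    # pool at unchanged isotopologue composition
    scenario_row("lactate",   "recipient-cell", "BSA", mid_point_mass(3, 3, 0.30), 3e7),
    scenario_row("lactate",   "recipient-cell", "PA",  mid_point_mass(3, 3, 0.45), 4.5e7),
    scenario_row("itaconate", "recipient-cell", "BSA", mid_point_mass(5, 1, 0.04), 6e5),
    scenario_row("itaconate", "recipient-cell", "PA",  mid_point_mass(5, 1, 0.10), 9e5),
    scenario_row("succinate", "recipient-cell", "BSA", mid_point_mass(4, 2, 0.06), 9e5),
    scenario_row("succinate", "recipient-cell", "PA",  mid_point_mass(4, 2, 0.14), 1.2e6))
}

palmitate_4h_scenario <- function() {
  dplyr::bind_rows(
    scenario_row("palmitoylcarnitine", "cell", "BSA", mid_point_mass(16, 16, 0.35), 1e7),
    scenario_row("palmitoylcarnitine", "cell", "PA",  mid_point_mass(16, 16, 0.55), 1.5e7),
    scenario_row("acetylcarnitine",    "cell", "BSA", mid_point_mass(2, 2, 0.25), 2e7),
    scenario_row("acetylcarnitine",    "cell", "PA",  mid_point_mass(2, 2, 0.40), 2.5e7),
    scenario_row("glutamate",  "cell",  "BSA", mid_point_mass(5, 2, 0.12), 2e7),
    scenario_row("glutamate",  "cell",  "PA",  mid_point_mass(5, 2, 0.22), 2e7),
    scenario_row("succinate",  "cell",  "BSA", mid_point_mass(4, 2, 0.08), 8e6),
    scenario_row("succinate",  "cell",  "PA",  mid_point_mass(4, 2, 0.18), 8e6),
    scenario_row("itaconate",  "cell",  "BSA", mid_point_mass(5, 1, 0.05), 3e6),
    scenario_row("itaconate",  "cell",  "PA",  mid_point_mass(5, 1, 0.15), 4e6),
    scenario_row("glutamate",  "media", "BSA", mid_point_mass(5, 2, 0.04), 4e6),
    scenario_row("glutamate",  "media", "PA",  mid_point_mass(5, 2, 0.10), 6e6),
    scenario_row("itaconate",  "media", "BSA", mid_point_mass(5, 1, 0.03), 1.5e6),
    scenario_row("itaconate",  "media", "PA",  mid_point_mass(5, 1, 0.09), 2.5e6),
    scenario_row("succinate",  "media", "BSA", mid_point_mass(4, 2, 0.05), 2.5e6),
    scenario_row("succinate",  "media", "PA",  mid_point_mass(4, 2, 0.12), 3.5e6))
}

#' Generate a bundled study fixture
#'
#' Self-contained synthetic input sets mirroring the experiment shapes the
#' pipeline targets:
#' \describe{
#'   \item{`palmitate_4h`}{U-13C-palmitate tracing, 4 h, n = 3 per group
#'     (BSA vs PA), cell + media compartments; label mass at
#'     palmitoylcarnitine m+16, acetylcarnitine m+2, glutamate/succinate
#'     m+2, itaconate m+1. Channel CV 15% (cell) / 25% (media).}
#'   \item{`glucose_6h`}{U-13C-glucose tracing, 6 h, n = 3 per group, cell,
#'     media and recipient-cell (media transfer) compartments; glucose m+6,
#'     lactate m+3, glutamate/succinate m+2, itaconate m+1. Channel CV 10%.}
#'   \item{`csf_3dHFD`}{CSF-style two-group abundance table: 34 metabolites,
#'     n = 10 per group (CT vs HFD_3d), CV 20%, true fold changes taken from
#'     [csf_reference()] (the two fatty acids at 2.27 and 2.17).}
#'   \item{`media_24h`}{conditioned-media-style two-group abundance table,
#'     n = 6 per group (BSA vs PA), CV 25%, true fold changes implied by
#'     [media_reference_stats()] group means.}
#' }
#' Regenerating a fixture with the same seed writes byte-identical CSVs.
#'
#' @param name Fixture name (see above).
#' @param seed Integer seed (default 1234).
#' @param dir Optional directory; when given, writes the fixture files
#'   (`areas.csv`/`abundances.csv`, `design.csv`, `registry.csv`,
#'   `truth*.csv`) there.
#' @return For tracing fixtures, the [simulate_isotopologue_areas()] list
#'   plus `registry` and `truth_mids` (long ground-truth table); for
#'   two-group fixtures, the [simulate_two_group_table()] list plus
#'   `design_sheet`.
#' @export
bundled_fixture <- function(name, seed = 1234, dir = NULL) {
  known <- c("palmitate_4h", "glucose_6h", "csf_3dHFD", "media_24h")
  if (!name %in% known)
    stop("unknown fixture '", name, "'; options: ", paste(known, collapse = ", "))
  seed <- as.integer(seed)

  if (name %in% c("palmitate_4h", "glucose_6h")) {
    scen <- if (name == "glucose_6h") glucose_6h_scenario() else palmitate_4h_scenario()
    noise <- if (name == "glucose_6h") noise_model(cv = 0.10, baseline = 50)
             else noise_model(cv = c(cell = 0.15, media = 0.25), baseline = 50)
    des <- study_design(group_sizes = c(BSA = 3L, PA = 3L))
    sim <- simulate_isotopologue_areas(scen, noise, des, seed = seed)
    sim$registry <- default_registry()
    sim$truth_mids <- tidyr::unnest(
      dplyr::mutate(scen,
                    isotopologue = lapply(.data$mid, function(m) seq_along(m) - 1L),
                    true_mid = .data$mid, mid = NULL),
      c("isotopologue", "true_mid"))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      readr::write_csv(sim$areas, file.path(dir, "areas.csv"), progress = FALSE)
      readr::write_csv(sim$design, file.path(dir, "design.csv"), progress = FALSE)
      readr::write_csv(sim$registry, file.path(dir, "registry.csv"), progress = FALSE)
      readr::write_csv(sim$truth_mids, file.path(dir, "truth_mids.csv"), progress = FALSE)
    }
    return(sim)
  }

  if (name == "csf_3dHFD") {
    ref <- csf_reference()
    baseline <- stats::setNames(1e6 * (1 + (seq_len(nrow(ref)) - 1) %% 10),
                                ref$metabolite)
    des <- study_design(group_sizes = c(CT = 10L, HFD_3d = 10L),
                        baseline = baseline,
                        effects = stats::setNames(ref$fc, ref$metabolite),
                        treated = "HFD_3d")
    sim <- simulate_two_group_table(des, noise_model(cv = 0.20), seed = seed)
  } else {
    ref <- media_reference_stats()
    ref <- ref[ref$mean_bsa > 0 & ref$mean_pa > 0, ]
    des <- study_design(group_sizes = c(BSA = 6L, PA = 6L),
                        baseline = stats::setNames(ref$mean_bsa, ref$metabolite),
                        effects = stats::setNames(ref$mean_pa / ref$mean_bsa,
                                                  ref$metabolite),
                        treated = "PA")
    sim <- simulate_two_group_table(des, noise_model(cv = 0.25), seed = seed)
  }
  sim$design_sheet <- tibble::tibble(sample = colnames(sim$abundances),
                                     group = sim$groups)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ab <- tibble::as_tibble(sim$abundances, rownames = "metabolite")
    readr::write_csv(ab, file.path(dir, "abundances.csv"), progress = FALSE)
    readr::write_csv(sim$design_sheet, file.path(dir, "design.csv"), progress = FALSE)
    readr::write_csv(sim$truth, file.path(dir, "truth.csv"), progress = FALSE)
  }
  sim
}
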