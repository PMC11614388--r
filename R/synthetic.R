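# Synthetic-data generator: forward-simulates raw isotopologue area tables
# from declared labeling scenarios, and two-group abundance tables with
# declared fold changes, so every pipeline stage can be verified against
# known ground truth.

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Noise model for simulated peak areas
#'
#' Multiplicative lognormal noise per channel (mean-unbiased: the expected
#' simulated area equals the noise-free area), an additive baseline area,
#' and lognormal noise on the internal-standard channel. Peak areas are
#' positive and right-skewed, which the lognormal captures.
#'
#' @param cv Coefficient of variation of the multiplicative channel noise:
#'   a scalar, or a named vector keyed by compartment (e.g.
#'   `c(cell = 0.15, media = 0.25)` — media measurements are noisier).
#' @param baseline Additive baseline area per channel (default 0).
#' @param is_cv CV of the internal-standard area (default 0.05).
#' @return A `noise_model` list.
#' @export
noise_model <- function(cv = 0.15, baseline = 0, is_cv = 0.05) {
  stopifnot(all(cv >= 0), baseline >= 0, is_cv >= 0)
  structure(list(cv = cv, baseline = baseline, is_cv = is_cv),
            class = "noise_model")
}

cv_for_compartment <- function(noise, compartment) {
  if (is.null(names(noise$cv))) return(noise$cv[[1]])
  if (!compartment %in% names(noise$cv))
    stop("noise model has no CV for compartment '", compartment, "'")
  noise$cv[[compartment]]
}

# lognormal multiplier with E[x] = 1 and the given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Study design for simulations
#'
#' @param group_sizes Named integer vector, group label -> n (>= 2 each).
#' @param cells Cells per sample (default 2e6, a typical well).
#' @param is_area Nominal internal-standard peak area (default 5e6).
#' @param baseline Named numeric vector, metabolite -> control-group mean
#'   abundance (two-group tables only).
#' @param effects Named numeric vector, metabolite -> fold change in the
#'   treated group (two-group tables only; unlisted metabolites are null,
#'   FC = 1). All FCs must be > 0.
#' @param treated Label of the treated group (default: second group).
#' @return A `study_design` list.
#' @export
study_design <- function(group_sizes, cells = 2e6, is_area = 5e6,
                         baseline = NULL, effects = NULL,
                         treated = names(group_sizes)[2]) {
  stopifnot(length(group_sizes) >= 2, !is.null(names(group_sizes)),
            all(group_sizes >= 2))
  if (!is.null(effects) && any(effects <= 0)) stop("effect FCs must be > 0")
  structure(list(group_sizes = group_sizes, cells = cells, is_area = is_area,
                 baseline = baseline, effects = effects, treated = treated),
            class = "study_design")
}

#' Declare a labeling scenario
#'
#' A scenario row states, for one metabolite in one compartment and group,
#' the true tracer MID (over m+0..m+n tracer carbons, summing to 1) and the
#' true total pool in raw-area units.
#'
#' @param metabolite Registry metabolite name.
#' @param compartment `"cell"`, `"media"` or `"recipient-cell"`.
#' @param group Group label.
#' @param mid Numeric true MID (length n_tracer + 1, sums to 1).
#' @param pool True total pool (raw-area units, >= 0).
#' @return One-row scenario tibble; row-bind rows into a full scenario.
#' @export
scenario_row <- function(metabolite, compartment, group, mid, pool) {
  if (abs(sum(mid) - 1) > 1e-9) stop("true MID must sum to 1")
  if (any(mid < 0) || pool < 0) stop("MID fractions and pool must be >= 0")
  tibble::tibble(metabolite = metabolite, compartment = compartment,
                 group = group, mid = list(as.numeric(mid)), pool = pool)
}

# MID with fraction `frac` at m+j and the remainder at m+0
mid_point_mass <- function(n_tracer, j, frac) {
  m <- numeric(n_tracer + 1)
  m[1] <- 1 - frac
  m[j + 1] <- m[j + 1] + frac
  m
}

#' Simulate a raw isotopologue area table from a labeling scenario
#'
#' Forward model: per sample, the noise-free areas are
#' `pool * A %*% true_mid` (A the metabolite's natural-abundance correction
#' matrix, so natural isotopes are put back in), then each channel gets an
#' independent mean-unbiased lognormal multiplier and the additive baseline.
#' The internal-standard channel gets its own lognormal noise. The same seed
#' always reproduces the same table.
#'
#' @param scenario Scenario tibble ([scenario_row()] rows bound together).
#' @param noise A [noise_model()].
#' @param design A [study_design()].
#' @param seed Integer seed (required: simulated studies are reproducible).
#' @param registry Metabolite registry (default [default_registry()]).
#' @param purity Tracer purity used in the forward model (default 1).
#' @param extra_shifts Heavy-tail channels beyond m+n (default 4).
#' @return List with `areas` (wide tibble: `sample` + `<met>|m+<i>` columns),
#'   `design` (sample sheet: `sample, group, compartment, cells, is_area`),
#'   and `truth` (the scenario plus noise/design parameters).
#' @export
simulate_isotopologue_areas <- function(scenario, noise, design, seed,
                                        registry = default_registry(),
                                        purity = 1, extra_shifts = 4L) {
  stopifnot(inherits(noise, "noise_model"), inherits(design, "study_design"))
  unknown <- setdiff(unique(scenario$metabolite), registry$name)
  if (length(unknown) > 0)
    stop("scenario metabolite(s) not in registry: ",
         paste(unknown, collapse = ", "))
  mets_by_comp <- split(scenario$metabolite, scenario$compartment)
  mats <- lapply(stats::setNames(unique(scenario$metabolite),
                                 unique(scenario$metabolite)),
                 function(m) registry_correction_matrix(
                   registry, m, purity = purity, extra_shifts = extra_shifts))

  with_seed(seed, {
    design_rows <- list(); area_rows <- list(); k <- 0
    for (comp in names(mets_by_comp)) {
      mets <- unique(mets_by_comp[[comp]])
      for (g in names(design$group_sizes)) {
        for (i in seq_len(design$group_sizes[[g]])) {
          smp <- sprintf("%s_%s_%d", comp, g, i)
          k <- k + 1
          design_rows[[k]] <- tibble::tibble(
            sample = smp, group = g, compartment = comp,
            cells = design$cells,
            is_area = design$is_area * rlnorm_cv(1, noise$is_cv))
          chans <- list(sample = smp)
          for (m in mets) {
            row <- scenario[scenario$metabolite == m &
                              scenario$compartment == comp &
                              scenario$group == g, ]
            if (nrow(row) != 1)
              stop("scenario needs exactly one row for ", m, "/", comp, "/", g)
            A <- mats[[m]]
            expected <- row$pool * as.vector(unclass(A) %*% row$mid[[1]])
            obs <- expected * rlnorm_cv(length(expected),
                                        cv_for_compartment(noise, comp)) +
              noise$baseline
            names(obs) <- paste0(m, "|m+", seq_along(obs) - 1)
            chans <- c(chans, as.list(obs))
          }
          area_rows[[k]] <- tibble::as_tibble(chans)
        }
      }
    }
    list(areas = dplyr::bind_rows(area_rows),
         design = dplyr::bind_rows(design_rows),
         truth = list(scenario = scenario, noise = noise, design = design,
                      purity = purity, seed = seed))
  })
}

#' True sampling dispersion of corrected MID fractions under a scenario
#'
#' Monte-Carlo estimate of the per-sample standard deviation of each
#' corrected MID fraction implied by a scenario's noise model — the
#' scenario-truth dispersion that recovery tests compare against (truth
#' within 3 standard errors). Part of the generator's emitted ground truth;
#' tests need not reach into generator internals.
#'
#' @param scenario,noise Scenario and noise model as in
#'   [simulate_isotopologue_areas()].
#' @param seed Integer seed.
#' @param n_mc Monte-Carlo samples per scenario row (default 2000).
#' @param registry,purity,extra_shifts As in
#'   [simulate_isotopologue_areas()].
#' @return Long tibble: `metabolite, compartment, group, isotopologue,
#'   true_mid, true_sd` (per-sample SD of the corrected fraction).
#' @export
true_mid_dispersion <- function(scenario, noise, seed, n_mc = 2000,
                                registry = default_registry(), purity = 1,
                                extra_shifts = 4L) {
  mats <- lapply(stats::setNames(unique(scenario$metabolite),
                                 unique(scenario$metabolite)),
                 function(m) registry_correction_matrix(
                   registry, m, purity = purity, extra_shifts = extra_shifts))
  with_seed(seed, {
    out <- lapply(seq_len(nrow(scenario)), function(r) {
      row <- scenario[r, ]
      A <- mats[[row$metabolite]]
      expected <- row$pool * as.vector(unclass(A) %*% row$mid[[1]])
      cv <- cv_for_compartment(noise, row$compartment)
      fr <- matrix(NA_real_, nrow = n_mc, ncol = ncol(A))
      for (i in seq_len(n_mc)) {
        obs <- expected * rlnorm_cv(length(expected), cv) + noise$baseline
        fr[i, ] <- correct_mid(obs, A)$fractions
      }
      tibble::tibble(metabolite = row$metabolite,
                     compartment = row$compartment, group = row$group,
                     isotopologue = 0:(ncol(A) - 1),
                     true_mid = row$mid[[1]],
                     true_sd = apply(fr, 2, stats::sd))
    })
    dplyr::bind_rows(out)
  })
}

#' Simulate a two-group abundance table
#'
#' Lognormal abundances (mean-unbiased, CV from the noise model) around
#' per-group means: `baseline` for the control group and `baseline * FC`
#' for the treated group, FC taken from the design's effect map (1 for
#' unlisted metabolites).
#'
#' @param design A [study_design()] with `baseline` (and optionally
#'   `effects`) set.
#' @param noise A [noise_model()]; only `cv` is used.
#' @param seed Integer seed.
#' @return List with `abundances` (matrix, metabolites x samples), `groups`
#'   (label per column), `truth` (per-metabolite true FC and group means).
#' @export
simulate_two_group_table <- function(design, noise, seed) {
  stopifnot(inherits(design, "study_design"), inherits(noise, "noise_model"))
  if (is.null(design$baseline) || is.null(names(design$baseline)))
    stop("design$baseline must be a named metabolite -> mean vector")
  mets <- names(design$baseline)
  fc <- stats::setNames(rep(1, length(mets)), mets)
  if (!is.null(design$effects)) {
    bad <- setdiff(names(design$effects), mets)
    if (length(bad) > 0) stop("effect map names not in baseline: ",
                              paste(bad, collapse = ", "))
    fc[names(design$effects)] <- design$effects
  }
  groups <- rep(names(design$group_sizes), design$group_sizes)
  samples <- unlist(lapply(names(design$group_sizes), function(g)
    sprintf("%s_%d", g, seq_len(design$group_sizes[[g]]))))
  cv <- if (is.null(names(noise$cv))) noise$cv[[1]] else
    stop("two-group tables take a scalar (uncompartmented) noise CV")
  with_seed(seed, {
    ab <- matrix(NA_real_, nrow = length(mets), ncol = length(groups),
                 dimnames = list(mets, samples))
    for (m in mets) {
      mu <- ifelse(groups == design$treated,
                   design$baseline[[m]] * fc[[m]], design$baseline[[m]])
      ab[m, ] <- mu * rlnorm_cv(length(mu), cv)
    }
    list(abundances = ab, groups = groups,
         truth = tibble::tibble(metabolite = mets,
                                mean_control = unname(design$baseline),
                                true_fc = unname(fc)))
  })
}
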