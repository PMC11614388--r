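# Metabolite registry: which fragment is measured for each metabolite and
# how many carbons the tracer can reach.

#' Built-in metabolite registry
#'
#' Curated fragment definitions for the metabolites handled by the bundled
#' labeling scenarios: parent formula, derivatization (`"tbdms:<n_sites>"`
#' for GC-MS TBDMS esters measured as their M-57 fragment, `"none"` for
#' species quantified underivatized), optional explicit fragment formula
#' override, and the number of tracer-eligible carbons. TBDMS site counts
#' follow standard MTBSTFA chemistry (one site per carboxyl, hydroxyl and
#' primary/secondary amine hydrogen).
#'
#' @return A tibble with columns `name`, `parent_formula`, `derivatization`,
#'   `fragment_override_formula`, `n_tracer_carbons`.
#' @export
default_registry <- function() {
  tibble::tribble(
    ~name,                ~parent_formula, ~derivatization, ~fragment_override_formula, ~n_tracer_carbons,
    "lactate",            "C3H6O3",    "tbdms:2", NA_character_, 3L,
    "pyruvate",           "C3H4O3",    "tbdms:1", NA_character_, 3L,
    "alanine",            "C3H7NO2",   "tbdms:2", NA_character_, 3L,
    "glycine",            "C2H5NO2",   "tbdms:2", NA_character_, 2L,
    "serine",             "C3H7NO3",   "tbdms:3", NA_character_, 3L,
    "aspartate",          "C4H7NO4",   "tbdms:3", NA_character_, 4L,
    "glutamate",          "C5H9NO4",   "tbdms:3", NA_character_, 5L,
    "glutamine",          "C5H10N2O3", "tbdms:3", NA_character_, 5L,
    "succinate",          "C4H6O4",    "tbdms:2", NA_character_, 4L,
    "fumarate",           "C4H4O4",    "tbdms:2", NA_character_, 4L,
    "malate",             "C4H6O5",    "tbdms:3", NA_character_, 4L,
    "citrate",            "C6H8O7",    "tbdms:4", NA_character_, 6L,
    "alpha-ketoglutarate","C5H6O5",    "tbdms:2", NA_character_, 5L,
    "itaconate",          "C5H6O4",    "tbdms:2", NA_character_, 5L,
    "glucose",            "C6H12O6",   "none",    NA_character_, 6L,
    "palmitate",          "C16H32O2",  "tbdms:1", NA_character_, 16L,
    "palmitoylcarnitine", "C23H45NO4", "none",    NA_character_, 16L,
    "acetylcarnitine",    "C9H17NO4",  "none",    NA_character_, 2L,
    "acetylserine",       "C5H9NO4",   "none",    NA_character_, 2L
  )
}

#' Read a metabolite registry from CSV or YAML
#'
#' CSV needs columns `name, parent_formula, derivatization,
#' fragment_override_formula (optional), n_tracer_carbons`; YAML a list of
#' entries with the same fields.
#'
#' @param path File path (`.csv`, `.yml`/`.yaml`).
#' @return Registry tibble as in [default_registry()].
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  reg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    entries <- yaml::read_yaml(path)
    dplyr::bind_rows(lapply(entries, function(e) {
      tibble::tibble(
        name = e$name, parent_formula = e$parent_formula,
        derivatization = e$derivatization,
        fragment_override_formula = e$fragment_override_formula %||% NA_character_,
        n_tracer_carbons = as.integer(e$n_tracer_carbons))
    }))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  validate_registry(reg)
}

validate_registry <- function(reg) {
  need <- c("name", "parent_formula", "derivatization", "n_tracer_carbons")
  miss <- setdiff(need, names(reg))
  if (length(miss) > 0)
    stop("registry missing column(s): ", paste(miss, collapse = ", "))
  if (!"fragment_override_formula" %in% names(reg))
    reg$fragment_override_formula <- NA_character_
  if (anyDuplicated(reg$name))
    stop("duplicate metabolite names in registry")
  bad <- !grepl("^(none|tbdms:[0-9]+)$", reg$derivatization)
  if (any(bad))
    stop("bad derivatization spec for ", paste(reg$name[bad], collapse = ", "),
         " (expect 'none' or 'tbdms:<n_sites>')")
  reg$n_tracer_carbons <- as.integer(reg$n_tracer_carbons)
  if (any(is.na(reg$n_tracer_carbons) | reg$n_tracer_carbons < 1))
    stop("n_tracer_carbons must be a positive integer")
  tibble::as_tibble(reg)
}

#' Resolve the measured fragment formula for a registry entry
#'
#' Applies the derivatization rule (or the explicit override) to the parent
#' formula.
#'
#' @param entry One-row registry tibble (or list with the registry fields).
#' @param table Isotope table (defines known elements for parsing).
#' @return `elemental_formula` of the measured fragment.
#' @export
resolve_fragment <- function(entry, table = default_isotope_table()) {
  ov <- entry$fragment_override_formula
  if (length(ov) == 1 && !is.na(ov) && nzchar(ov))
    return(parse_formula(ov, table))
  parent <- parse_formula(entry$parent_formula, table)
  if (entry$derivatization == "none") return(parent)
  n_sites <- as.integer(sub("^tbdms:", "", entry$derivatization))
  tbdms_m57_fragment(parent, n_sites)
}

#' Correction matrix for a named registry metabolite
#'
#' Convenience wrapper: resolves the fragment and builds its correction
#' matrix with `K = n_tracer_carbons + extra_shifts`.
#'
#' @param registry Registry tibble.
#' @param name Metabolite name.
#' @param purity Tracer purity (default 1).
#' @param extra_shifts Heavy-tail channels beyond m+n (default 4).
#' @param table Isotope table.
#' @return A `correction_matrix`.
#' @export
registry_correction_matrix <- function(registry, name, purity = 1,
                                       extra_shifts = 4L,
                                       table = default_isotope_table()) {
  entry <- registry[registry$name == name, ]
  if (nrow(entry) != 1) stop("metabolite '", name, "' not found in registry")
  frag <- resolve_fragment(entry, table)
  n <- entry$n_tracer_carbons
  build_correction_matrix(frag, n, purity = purity, K = n + extra_shifts,
                          table = table)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
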