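# Table readers/writers and run configuration. All tables are UTF-8 CSV
# with a header; isotopologue columns are named `<metabolite>|m+<i>`.

#' Read a raw isotopologue area table
#'
#' @param path CSV with a `sample` column and `<metabolite>|m+<i>` area
#'   columns.
#' @return Tibble.
#' @export
read_areas_csv <- function(path) {
  if (!file.exists(path)) stop("areas file not found: ", path)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"sample" %in% names(x)) stop("areas CSV needs a 'sample' column: ", path)
  parse_channel_names(setdiff(names(x), "sample"))  # validates names
  # NA marks a metabolite not measured in a sample's compartment; negative
  # areas are always an error
  bad <- vapply(setdiff(names(x), "sample"),
                function(cl) any(x[[cl]] < 0, na.rm = TRUE), logical(1))
  if (any(bad))
    stop("negative areas in column(s): ", paste(names(bad)[bad], collapse = ", "))
  x
}

#' Read a sample design sheet
#'
#' @param path CSV with columns `sample, group, compartment, cells, is_area`
#'   (`compartment`, `cells`, `is_area` optional for two-group abundance
#'   designs).
#' @return Tibble.
#' @export
read_design_csv <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample", "group")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("design CSV missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$sample))
    stop("duplicate sample ids in design sheet: ",
         paste(unique(x$sample[duplicated(x$sample)]), collapse = ", "))
  x
}

#' Read a two-group abundance table
#'
#' @param path CSV whose first column is the metabolite name and remaining
#'   columns are samples.
#' @return List with `abundances` (matrix, metabolites x samples).
#' @export
read_abundance_csv <- function(path) {
  if (!file.exists(path)) stop("abundance file not found: ", path)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(x) < 3) stop("abundance CSV needs a metabolite column and >= 2 samples")
  m <- as.matrix(x[, -1])
  if (!is.numeric(m)) stop("non-numeric abundance values in ", path)
  rownames(m) <- as.character(x[[1]])
  list(abundances = m, samples = colnames(m))
}

#' Validated run configuration
#'
#' @param ... Named options. Recognized keys: `purity`, `extra_shifts`,
#'   `residual_warn`, `lfc_threshold`, `alpha`, `test`, `seed`,
#'   `round_digits`. Unknown keys are rejected.
#' @return A `run_config` list with defaults filled in.
#' @export
run_config <- function(...) {
  defaults <- list(purity = 1, extra_shifts = 4L, residual_warn = 0.05,
                   lfc_threshold = 1, alpha = 0.05, test = "student_t",
                   seed = 1234L, round_digits = NA_integer_)
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  stopifnot(cfg$purity > 0, cfg$purity <= 1, cfg$alpha > 0, cfg$alpha < 1,
            cfg$lfc_threshold >= 0,
            cfg$test %in% c("student_t", "wilcoxon"))
  structure(cfg, class = "run_config")
}

#' Read a YAML run configuration
#'
#' @param path YAML file of [run_config()] keys.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(run_config, yaml::read_yaml(path))
}

# reproducibility manifest written next to every CLI result set
write_manifest <- function(out_dir, config, inputs = character(0)) {
  manifest <- list(
    package = "midtracer",
    version = as.character(utils::packageVersion("midtracer")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    inputs = if (length(inputs) > 0)
      as.list(tools::md5sum(inputs)) else list())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
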