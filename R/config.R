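#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults are the values used throughout the analysis: MAG quality score
#' (completeness − 3 × contamination) at least 50, completeness at least 75%,
#' strain grouping at ANI ≥ 99%, detection at covered fraction ≥ 0.10,
#' seawater prevalence < 0.50 and per-seawater-sample relative abundance
#' < 0.1% for host specificity, collinearity pruning at |Pearson r| > 0.7,
#' environmental-vector selection at R² > 0.65, and KEGG-module reporting at
#' completeness > 75%.
#'
#' @param seed Integer seed controlling every permutation and simulation.
#' @param n_permutations Number of permutations for PERMANOVA, envfit and
#'   post-hoc tests (default 999).
#' @param fdr_method Multiple-testing method; fixed to Benjamini-Hochberg.
#' @param quality_min Minimum quality score (completeness − 3×contamination).
#' @param completeness_min Minimum completeness percent.
#' @param ani_threshold ANI percent at or above which two MAGs are strains.
#' @param covered_fraction_min Covered fraction at or above which a MAG
#'   counts as detected in a sample.
#' @param prevalence_max Strict upper bound on seawater prevalence for a
#'   host-specific call.
#' @param seawater_abund_max Strict upper bound (percent) on relative
#'   abundance in every seawater sample for a host-specific call.
#' @param collinearity_r Strict |Pearson r| threshold above which the later
#'   of two environmental variables is dropped.
#' @param envfit_r2_min Strict R² threshold for selecting fitted
#'   environmental vectors into the final constrained ordination.
#' @param module_report_min Strict completeness percent above which a KEGG
#'   module is flagged in reports.
#'
#' @return A list of class `magniche_config`.
#' @export
#' @examples
#' cfg <- run_config(seed = 1)
#' cfg$ani_threshold
run_config <- function(seed = 1L,
                       n_permutations = 999L,
                       fdr_method = "BH",
                       quality_min = 50,
                       completeness_min = 75,
                       ani_threshold = 99,
                       covered_fraction_min = 0.10,
                       prevalence_max = 0.50,
                       seawater_abund_max = 0.1,
                       collinearity_r = 0.7,
                       envfit_r2_min = 0.65,
                       module_report_min = 75) {
  fdr_method <- match.arg(fdr_method, "BH")
  cfg <- list(
    seed = as.integer(seed),
    n_permutations = as.integer(n_permutations),
    fdr_method = fdr_method,
    quality_min = quality_min,
    completeness_min = completeness_min,
    ani_threshold = ani_threshold,
    covered_fraction_min = covered_fraction_min,
    prevalence_max = prevalence_max,
    seawater_abund_max = seawater_abund_max,
    collinearity_r = collinearity_r,
    envfit_r2_min = envfit_r2_min,
    module_report_min = module_report_min
  )
  thresholds <- cfg[!names(cfg) %in% c("seed", "fdr_method")]
  if (!all(vapply(thresholds, function(x) is.numeric(x) && x > 0, logical(1)))) {
    abort("all thresholds in run_config() must be positive numbers")
  }
  if (cfg$n_permutations < 1L) abort("n_permutations must be >= 1")
  structure(cfg, class = "magniche_config")
}

#' Read a configuration file
#'
#' Accepts either a YAML mapping or a flat `key = value` file whose keys are
#' the arguments of [run_config()]. Unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return A `magniche_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (any(grepl("=", body, fixed = TRUE)) && !any(grepl(":", body, fixed = TRUE))) {
    kv <- strsplit(body, "=", fixed = TRUE)
    vals <- lapply(kv, function(x) {
      if (length(x) != 2) abort(paste0("malformed config line: ", paste(x, collapse = "=")))
      type.convert(trimws(x[2]), as.is = TRUE)
    })
    names(vals) <- vapply(kv, function(x) trimws(x[1]), character(1))
  } else {
    vals <- yaml::read_yaml(path)
  }
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' @export
print.magniche_config <- function(x, ...) {
  cat("<magniche_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
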