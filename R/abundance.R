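#' Apply the covered-fraction detection filter
#'
#' A MAG counts as detected in a sample only when its covered fraction is at
#' or above `min_covered_fraction` (default 0.10, the mapping tool's
#' default, applied inclusively). Sub-threshold entries have their mean
#' coverage set to zero and are marked undetected.
#'
#' @param coverage Long coverage tibble (see [read_coverage_table()]).
#' @param min_covered_fraction Detection threshold on covered fraction.
#' @return The coverage tibble with a logical `detected` column;
#'   `mean_coverage` is zero wherever `detected` is `FALSE`.
#' @export
apply_detection_filter <- function(coverage, min_covered_fraction = 0.10) {
  validate_coverage(coverage)
  dplyr::mutate(
    as_tibble(coverage),
    detected = .data$covered_fraction >= min_covered_fraction &
      .data$mean_coverage > 0,
    mean_coverage = ifelse(.data$detected, .data$mean_coverage, 0)
  )
}

#' Library-size normalization and relative abundance
#'
#' Scales each sample's mean coverages to the smallest library size
#' (`normalized_coverage = mean_coverage * min(library) / library(sample)`),
#' then converts to within-sample relative abundance in percent
#' (`100 * normalized_coverage / sum(normalized_coverage)`), summing over
#' the MAG set under analysis. Both layers are returned. Samples in which no
#' MAG is detected get `NA` relative abundance and are listed in the
#' `flagged_samples` attribute rather than being silently zeroed.
#'
#' @param coverage Detection-filtered coverage tibble
#'   (see [apply_detection_filter()]; a `detected` column is required).
#' @param samples Sample metadata tibble with `sample_id`,
#'   `library_size_gbp`.
#' @return Long tibble of class `magniche_abundance` with columns `mag_id`,
#'   `sample_id`, `detected`, `normalized_coverage`, `relative_abundance`.
#' @export
normalize_abundance <- function(coverage, samples) {
  validate_samples(samples)
  if (!"detected" %in% names(coverage)) {
    abort("coverage must be detection-filtered first; see apply_detection_filter()")
  }
  unknown <- setdiff(coverage$sample_id, samples$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("coverage references unknown sample(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  min_lib <- min(samples$library_size_gbp)
  lib <- setNames(samples$library_size_gbp, samples$sample_id)
  out <- coverage |>
    dplyr::mutate(
      normalized_coverage = .data$mean_coverage * min_lib /
        unname(lib[.data$sample_id])
    ) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      relative_abundance = if (sum(.data$normalized_coverage) > 0) {
        100 * .data$normalized_coverage / sum(.data$normalized_coverage)
      } else {
        NA_real_
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::select("mag_id", "sample_id", "detected",
                  "normalized_coverage", "relative_abundance")
  flagged <- unique(out$sample_id[is.na(out$relative_abundance)])
  if (length(flagged) > 0) {
    warn(paste0("no detected MAG in sample(s): ",
                paste(flagged, collapse = ", "),
                "; relative abundances set to NA"))
  }
  attr(out, "flagged_samples") <- flagged
  class(out) <- c("magniche_abundance", class(out))
  out
}

#' Per-sample-type prevalence
#'
#' Fraction of samples of each type (coral / seawater) in which a MAG is
#' detected.
#'
#' @param abund Abundance tibble from [normalize_abundance()] (or any long
#'   tibble with `mag_id`, `sample_id`, `detected`).
#' @param samples Sample metadata tibble.
#' @return Tibble with `mag_id`, `sample_type`, `n_detected`, `n_samples`,
#'   `prevalence`.
#' @export
mag_prevalence <- function(abund, samples) {
  validate_samples(samples)
  type_of <- setNames(samples$sample_type, samples$sample_id)
  n_type <- table(samples$sample_type)
  if (any(n_type == 0)) abort("a sample type has zero samples")
  abund |>
    as_tibble() |>
    dplyr::mutate(sample_type = unname(type_of[.data$sample_id])) |>
    dplyr::group_by(.data$mag_id, .data$sample_type) |>
    dplyr::summarise(n_detected = sum(.data$detected), .groups = "drop") |>
    tidyr::complete(.data$mag_id,
                    sample_type = names(n_type),
                    fill = list(n_detected = 0L)) |>
    dplyr::mutate(
      n_samples = as.integer(n_type[.data$sample_type]),
      prevalence = .data$n_detected / .data$n_samples
    )
}

# long abundance tibble -> samples x MAGs matrix of a chosen value column
abundance_matrix <- function(abund, value = "relative_abundance") {
  wide <- abund |>
    as_tibble() |>
    dplyr::select("mag_id", "sample_id", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "mag_id", values_from = dplyr::all_of(value),
                       values_fill = 0)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$sample_id
  m
}
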