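#' Three-criterion habitat-specificity classifier
#'
#' Assigns each MAG to `host_specific` or `seawater_specific` from its
#' normalized relative abundances. A MAG is host-specific iff it satisfies
#' all three criteria:
#'
#' 1. greater mean relative abundance in coral than in seawater samples
#'    (coral : seawater ratio strictly > 1, means taken over *all* samples
#'    of each type with undetected = 0);
#' 2. seawater prevalence strictly below 50%;
#' 3. relative abundance strictly below 0.1% in *every* seawater sample.
#'
#' A MAG absent from seawater entirely (seawater mean 0, coral mean > 0)
#' has ratio +Inf and satisfies criterion 1 — absence from the free-living
#' community is the strongest evidence of host association. MAGs undetected
#' in every sample are labelled `undetected` and excluded from downstream
#' enrichment. Failing any single criterion yields `seawater_specific`.
#'
#' @param abund Abundance tibble from [normalize_abundance()].
#' @param samples Sample metadata tibble with both sample types present.
#' @param config [run_config()] carrying `prevalence_max` (0.50) and
#'   `seawater_abund_max` (0.1%).
#' @return Tibble of class `magniche_specificity`, one row per MAG:
#'   mean abundances, ratio, seawater prevalence, maximum seawater
#'   abundance, the three criterion flags, and `label`.
#' @export
classify_specificity <- function(abund, samples, config = run_config()) {
  validate_samples(samples)
  if (length(unique(samples$sample_type)) < 2) {
    abort("both sample types (coral, seawater) must be present")
  }
  type_of <- setNames(samples$sample_type, samples$sample_id)

  # zero-fill: means are over ALL samples of a type, undetected included
  full <- abund |>
    as_tibble() |>
    dplyr::select("mag_id", "sample_id", "detected", "relative_abundance") |>
    tidyr::complete(.data$mag_id, sample_id = samples$sample_id,
                    fill = list(detected = FALSE, relative_abundance = 0)) |>
    dplyr::mutate(
      relative_abundance = tidyr::replace_na(.data$relative_abundance, 0),
      sample_type = unname(type_of[.data$sample_id])
    )

  res <- full |>
    dplyr::group_by(.data$mag_id) |>
    dplyr::summarise(
      mean_abund_coral = mean(.data$relative_abundance[.data$sample_type == "coral"]),
      mean_abund_seawater = mean(.data$relative_abundance[.data$sample_type == "seawater"]),
      seawater_prevalence = mean(.data$detected[.data$sample_type == "seawater"]),
      max_seawater_abund = max(c(0, .data$relative_abundance[.data$sample_type == "seawater"])),
      n_detected = sum(.data$detected),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ratio = dplyr::case_when(
        .data$mean_abund_seawater > 0 ~ .data$mean_abund_coral / .data$mean_abund_seawater,
        .data$mean_abund_coral > 0 ~ Inf,
        TRUE ~ NA_real_
      ),
      crit_ratio = !is.na(.data$ratio) & .data$ratio > 1,
      crit_prevalence = .data$seawater_prevalence < config$prevalence_max,
      crit_abundance = .data$max_seawater_abund < config$seawater_abund_max,
      label = dplyr::case_when(
        .data$n_detected == 0 ~ "undetected",
        .data$crit_ratio & .data$crit_prevalence & .data$crit_abundance ~ "host_specific",
        TRUE ~ "seawater_specific"
      )
    ) |>
    dplyr::select(-"n_detected")
  class(res) <- c("magniche_specificity", class(res))
  res
}

#' Summarize specificity calls
#'
#' Counts MAGs per label, and per phylum within label when a MAG table with
#' taxonomy strings is supplied (the phylum is the second semicolon-
#' delimited rank, `d__...;p__...`).
#'
#' @param spec Result of [classify_specificity()].
#' @param mags Optional MAG tibble with `mag_id` and `taxonomy`.
#' @return A list with tibbles `by_label` and (if `mags` given) `by_phylum`.
#' @export
summarize_specificity <- function(spec, mags = NULL) {
  if (nrow(spec) == 0) abort("empty specificity result")
  by_label <- spec |>
    dplyr::count(.data$label, name = "n") |>
    tidyr::complete(label = c("host_specific", "seawater_specific", "undetected"),
                    fill = list(n = 0L))
  out <- list(by_label = by_label)
  if (!is.null(mags)) {
    tax <- mags |>
      dplyr::mutate(phylum = extract_rank(.data$taxonomy, 2)) |>
      dplyr::select("mag_id", "phylum")
    out$by_phylum <- spec |>
      dplyr::inner_join(tax, by = "mag_id") |>
      dplyr::count(.data$label, .data$phylum, name = "n")
  }
  out
}

extract_rank <- function(taxonomy, rank) {
  vapply(strsplit(taxonomy, ";", fixed = TRUE), function(x) {
    if (length(x) >= rank) sub("^[a-z]__", "", trimws(x[rank])) else NA_character_
  }, character(1))
}
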