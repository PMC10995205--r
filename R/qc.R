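#' MAG quality score
#'
#' The standard genome-bin quality score, completeness − 3 × contamination,
#' both in percent. May be negative for heavily contaminated bins.
#'
#' @param completeness Completeness percent in \[0, 100\]; vectorized.
#' @param contamination Contamination percent, >= 0; vectorized.
#' @return Numeric vector of quality scores.
#' @export
#' @examples
#' quality_score(91.2, 2.03) # 85.11
quality_score <- function(completeness, contamination) {
  if (any(completeness < 0 | completeness > 100, na.rm = TRUE)) {
    abort("completeness must lie in [0, 100]")
  }
  if (any(contamination < 0, na.rm = TRUE)) {
    abort("contamination must be >= 0")
  }
  completeness - 3 * contamination
}

#' Assess and filter MAGs on quality
#'
#' A MAG is retained iff quality score >= `quality_min` (default 50) AND
#' completeness >= `completeness_min` (default 75); both thresholds are
#' inclusive. An assessment row is emitted for every input MAG, so the
#' operation is idempotent on the retained subset.
#'
#' @param mags MAG tibble (see [read_mag_table()]).
#' @param config A [run_config()] supplying the thresholds.
#' @return The input tibble with added columns `quality_score`,
#'   `passes_quality`, `passes_completeness`, `retained`.
#' @export
assess_mag_quality <- function(mags, config = run_config()) {
  validate_mags(mags)
  dplyr::mutate(
    as_tibble(mags),
    quality_score = quality_score(.data$completeness, .data$contamination),
    passes_quality = .data$quality_score >= config$quality_min,
    passes_completeness = .data$completeness >= config$completeness_min,
    retained = .data$passes_quality & .data$passes_completeness
  )
}

#' @rdname assess_mag_quality
#' @return `filter_mags()` returns only the retained rows.
#' @export
filter_mags <- function(mags, config = run_config()) {
  dplyr::filter(assess_mag_quality(mags, config), .data$retained)
}

#' Greedy centroid dereplication on ANI
#'
#' Groups strain-level duplicates (ANI at or above `threshold`, default 99)
#' and keeps one representative per group. MAGs are visited in descending
#' quality-score order (ties broken by lexicographic `mag_id`); each
#' unassigned MAG becomes a representative and absorbs all unassigned MAGs
#' whose ANI to it is at or above the threshold. Representatives are
#' therefore pairwise below the threshold, and every absorbed MAG is within
#' threshold of its representative — a guarantee single-linkage clustering
#' does not give. In `per_site` mode the procedure runs independently within
#' each site (removing redundancy between biological replicates); `overall`
#' mode runs across all sites (removing strains recovered independently from
#' different sites).
#'
#' The ANI matrix is max-symmetrized; asymmetries beyond 1 ANI point raise a
#' warning.
#'
#' @param mags MAG tibble; needs `mag_id`, `site`, `completeness`,
#'   `contamination`.
#' @param ani Square ANI matrix with mag ids as dimnames covering all MAGs.
#' @param threshold ANI percent; pairs at or above it are strains.
#' @param mode `"per_site"` or `"overall"`.
#' @return Tibble with columns `mag_id`, `site`, `cluster` (representative's
#'   id), `representative` (logical), carrying attribute `mode`.
#' @export
dereplicate_mags <- function(mags, ani, threshold = 99,
                             mode = c("per_site", "overall")) {
  mode <- match.arg(mode)
  ids <- mags$mag_id
  missing <- setdiff(ids, rownames(ani))
  if (length(missing) > 0) {
    abort(paste0("MAG(s) absent from ANI matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  a <- ani[ids, ids, drop = FALSE]
  asym <- max(abs(a - t(a)))
  if (asym > 1) {
    warn(sprintf("ANI matrix asymmetric (max |a_ij - a_ji| = %.3g); using max of the two directions", asym))
  }
  a <- pmax(a, t(a))
  if (anyNA(a)) abort("ANI matrix contains missing pairs")

  q <- quality_score(mags$completeness, mags$contamination)
  derep_block <- function(idx) {
    ord <- idx[order(-q[idx], ids[idx])]
    rep_of <- character(length(ord))
    names(rep_of) <- ids[ord]
    assigned <- setNames(rep(FALSE, length(ord)), ids[ord])
    for (i in ids[ord]) {
      if (assigned[[i]]) next
      members <- names(assigned)[!assigned & a[i, names(assigned)] >= threshold]
      members <- union(i, members)
      assigned[members] <- TRUE
      rep_of[members] <- i
    }
    rep_of
  }

  blocks <- if (mode == "per_site") {
    split(seq_along(ids), mags$site)
  } else {
    list(seq_along(ids))
  }
  rep_of <- unlist(unname(lapply(blocks, derep_block)))
  out <- tibble(
    mag_id = ids,
    site = mags$site,
    cluster = unname(rep_of[ids]),
    representative = ids == unname(rep_of[ids])
  )
  attr(out, "mode") <- mode
  out
}
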