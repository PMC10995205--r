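#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sort p-values ascending,
#' `adj_i = min_{j >= i} (m * p_j / j)` capped at 1, returned in input
#' order. Delegates to [stats::p.adjust()] after validating the input.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Compare genomic features between specificity groups
#'
#' Kruskal-Wallis (tie-corrected H, chi-square reference with k − 1 df) for
#' each genomic feature between host-specific and seawater-specific MAGs,
#' with BH adjustment across features and per-group medians.
#'
#' @param mags MAG tibble.
#' @param spec Result of [classify_specificity()] (or any tibble with
#'   `mag_id` and `label`); only `host_specific` / `seawater_specific` MAGs
#'   enter the test.
#' @param features Character vector of numeric MAG columns to compare.
#' @return Tibble with one row per feature: H `statistic`, `raw_p`,
#'   `adjusted_p`, group medians, and `direction` (label of the group with
#'   the higher median).
#' @export
compare_genomic_features <- function(mags, spec,
                                     features = c("genome_size", "gc",
                                                  "n_genes", "coding_density")) {
  dat <- dplyr::inner_join(as_tibble(mags),
                           dplyr::select(as_tibble(spec), "mag_id", "label"),
                           by = "mag_id") |>
    dplyr::filter(.data$label %in% c("host_specific", "seawater_specific"))
  if (dplyr::n_distinct(dat$label) < 2) {
    abort("both specificity groups must be non-empty")
  }
  res <- purrr::map_dfr(features, function(f) {
    if (sd(dat[[f]]) == 0) {
      # constant feature: no rank variation, H = 0 by convention
      kw <- list(statistic = c(H = 0), p.value = 1)
    } else {
      kw <- kruskal.test(dat[[f]], factor(dat$label))
    }
    med <- tapply(dat[[f]], dat$label, median)
    tibble(
      feature = f,
      statistic = unname(kw$statistic),
      raw_p = kw$p.value,
      median_host = unname(med[["host_specific"]]),
      median_seawater = unname(med[["seawater_specific"]]),
      direction = ifelse(med[["host_specific"]] >= med[["seawater_specific"]],
                         "host_specific", "seawater_specific")
    )
  })
  dplyr::mutate(res, adjusted_p = adjust_bh(.data$raw_p),
                .after = "raw_p")
}

#' Fisher's-exact functional enrichment
#'
#' Binarizes annotation counts to presence/absence (count >= 1), builds the
#' 2x2 presence-by-group table per feature, and computes the two-sided
#' Fisher exact p (sum of hypergeometric point probabilities not exceeding
#' the observed table's). BH adjustment is applied across all tested
#' features of the namespace; a feature present in no MAG (or in all MAGs
#' of both groups with identical proportions, i.e. degenerate margins) is
#' still reported, but all-absent features are skipped with a note.
#' Significance is conventionally called at adjusted p <= 0.05 (inclusive).
#'
#' @param annotations Wide annotation tibble (`mag_id` + one count column
#'   per feature; see [read_annotation_matrix()]).
#' @param spec Specificity result (or tibble with `mag_id`, `label`).
#' @param namespace Optional namespace tag; defaults to the matrix's
#'   `namespace` attribute.
#' @return Tibble of class `magniche_enrichment`: per feature the 2x2
#'   counts, presence proportions, odds ratio, `raw_p`, `adjusted_p`,
#'   `direction`.
#' @export
fisher_enrichment <- function(annotations, spec, namespace = NULL) {
  namespace <- namespace %||% attr(annotations, "namespace") %||% "feature"
  labs <- dplyr::filter(as_tibble(spec),
                        .data$label %in% c("host_specific", "seawater_specific"))
  ann <- dplyr::inner_join(as_tibble(annotations),
                           dplyr::select(labs, "mag_id", "label"),
                           by = "mag_id")
  grp <- factor(ann$label, levels = c("host_specific", "seawater_specific"))
  if (any(table(grp) < 2)) abort("need >= 2 MAGs per specificity group")
  feats <- setdiff(names(ann), c("mag_id", "label"))
  pres <- as.matrix(ann[feats]) >= 1
  n_host <- sum(grp == "host_specific")
  n_sea <- sum(grp == "seawater_specific")
  k_host <- colSums(pres[grp == "host_specific", , drop = FALSE])
  k_sea <- colSums(pres[grp == "seawater_specific", , drop = FALSE])

  empty <- (k_host + k_sea) == 0
  if (any(empty)) {
    inform(paste0(sum(empty), " ", namespace,
                  " feature(s) absent from all MAGs; skipped"))
  }
  keep <- which(!empty)
  res <- purrr::map_dfr(keep, function(i) {
    tab <- matrix(c(k_host[i], n_host - k_host[i],
                    k_sea[i], n_sea - k_sea[i]), nrow = 2)
    ft <- fisher.test(tab)
    tibble(
      feature = feats[i],
      present_host = unname(k_host[i]), absent_host = n_host - unname(k_host[i]),
      present_seawater = unname(k_sea[i]), absent_seawater = n_sea - unname(k_sea[i]),
      prop_host = unname(k_host[i]) / n_host,
      prop_seawater = unname(k_sea[i]) / n_sea,
      odds_ratio = unname(ft$estimate),
      raw_p = ft$p.value
    )
  })
  res <- res |>
    dplyr::mutate(
      adjusted_p = adjust_bh(.data$raw_p),
      direction = ifelse(.data$prop_host >= .data$prop_seawater,
                         "host_specific", "seawater_specific"),
      namespace = namespace
    )
  class(res) <- c("magniche_enrichment", class(res))
  res
}

#' Two-sided Mann-Whitney U test
#'
#' Exact two-sided p by complete enumeration of all group assignments when
#' `n1 * n2` does not exceed `exact_limit` (counting assignments whose U is
#' at least as far from the null mean `n1*n2/2` as the observed U; correct
#' under ties, where the permutation null is the right reference), and the
#' tie-corrected normal approximation otherwise.
#'
#' @param x,y Numeric vectors for the two groups.
#' @param exact_limit Enumerate exactly while `length(x)*length(y)` is at or
#'   below this (default 400).
#' @return List with `statistic` (U of the first group) and `p_value`.
#' @export
mann_whitney <- function(x, y, exact_limit = 400) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) abort("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 * n2 <= exact_limit) {
    idx <- combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    ties <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2) # continuity correction
      p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
    }
  }
  list(statistic = u_obs, p_value = p)
}

#' Abundance-weighted orthologous-cluster enrichment
#'
#' Weights each cluster's per-MAG copy counts by the relative abundance of
#' the MAGs encoding it: `W(c, s) = sum_m count(c, m) * abundance(m, s)`.
#' For each unordered pair of factor levels (default: water-quality
#' categories) and each cluster, a two-sided Mann-Whitney U test compares
#' the weights between the two categories. The raw p is the conventional
#' decision value (P < 0.05, unadjusted); BH-adjusted p-values within each
#' pair are additionally provided. Clusters encoded by no MAG give all-zero
#' weights and are skipped; level pairs with fewer than two samples per
#' level are skipped with a warning.
#'
#' @param clusters Wide cluster count tibble (`mag_id` + one column per
#'   cluster).
#' @param abund Abundance tibble from [normalize_abundance()].
#' @param samples Sample metadata tibble.
#' @param factor_col Column of `samples` holding the category factor.
#' @return Tibble: `cluster`, `group1`, `group2`, medians, U `statistic`,
#'   `raw_p`, `adjusted_p`.
#' @export
cluster_enrichment <- function(clusters, abund, samples,
                               factor_col = "wq_category") {
  validate_samples(samples)
  fac <- samples[[factor_col]]
  if (is.null(fac)) abort(paste0("no column '", factor_col, "' in samples"))
  keep <- !is.na(fac)
  samples <- samples[keep, ]
  fac <- fac[keep]

  cl_mat <- as.matrix(as_tibble(clusters)[-1])
  rownames(cl_mat) <- clusters$mag_id
  ab <- abundance_matrix(abund) # samples x mags
  common <- intersect(colnames(ab), rownames(cl_mat))
  if (length(common) == 0) abort("cluster matrix and abundance matrix share no MAGs")
  ab <- ab[intersect(rownames(ab), samples$sample_id), common, drop = FALSE]
  w <- ab %*% cl_mat[common, , drop = FALSE] # samples x clusters
  w <- w[, colSums(w) > 0, drop = FALSE]

  lev <- sort(unique(fac))
  pairs <- combn(lev, 2, simplify = FALSE)
  sample_fac <- setNames(fac, samples$sample_id)
  res <- purrr::map_dfr(pairs, function(pr) {
    s1 <- rownames(w)[sample_fac[rownames(w)] == pr[1]]
    s2 <- rownames(w)[sample_fac[rownames(w)] == pr[2]]
    if (length(s1) < 2 || length(s2) < 2) {
      warn(paste0("skipping pair ", pr[1], " vs ", pr[2],
                  ": fewer than 2 samples in a category"))
      return(tibble())
    }
    out <- purrr::map_dfr(colnames(w), function(cl) {
      mw <- mann_whitney(w[s1, cl], w[s2, cl])
      tibble(
        cluster = cl, group1 = pr[1], group2 = pr[2],
        median1 = median(w[s1, cl]), median2 = median(w[s2, cl]),
        statistic = mw$statistic, raw_p = mw$p_value
      )
    })
    dplyr::mutate(out, adjusted_p = adjust_bh(.data$raw_p))
  })
  res
}
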