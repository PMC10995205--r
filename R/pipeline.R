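#' Run the full genome-centric analysis pipeline
#'
#' Executes the stages in analysis order on an in-memory study (from
#' [simulate_study()] or [read_study()]): quality filtering, per-site
#' dereplication, detection filtering and library-size normalization,
#' habitat-specificity classification, Kruskal-Wallis genomic-feature
#' comparison, Fisher enrichment per annotation namespace, KEGG-module
#' completeness, overall (cross-site) dereplication, the ordination suite
#' (sample-type + site model on all samples; water-quality model,
#' environmental vector fitting and the reduced constrained model on
#' host-specific MAGs and coral samples only), and abundance-weighted
#' cluster enrichment. Every threshold comes from `config`; all
#' permutations derive from `config$seed`, so reruns are reproducible.
#'
#' Degenerate configurations (e.g. thresholds that retain zero MAGs)
#' short-circuit downstream stages to empty-but-valid outputs rather than
#' failing.
#'
#' @param study A `magniche_study` list.
#' @param config A [run_config()].
#' @param outdir Optional directory; when given, stage tables and a JSON
#'   run manifest are written there.
#' @return A list of class `magniche_report` with each stage's output and a
#'   `counts` summary.
#' @export
run_pipeline <- function(study, config = run_config(), outdir = NULL) {
  report <- list(config = config)

  # -- quality filtering ----------------------------------------------------
  qc <- assess_mag_quality(study$mags, config)
  retained <- dplyr::filter(qc, .data$retained)
  report$quality <- qc
  empty_from_qc <- nrow(retained) == 0

  # -- per-site dereplication ----------------------------------------------
  if (!empty_from_qc) {
    derep_site <- dereplicate_mags(retained, study$ani,
                                   threshold = config$ani_threshold,
                                   mode = "per_site")
    reps1 <- derep_site$mag_id[derep_site$representative]
  } else {
    derep_site <- tibble(mag_id = character(), site = character(),
                         cluster = character(), representative = logical())
    reps1 <- character()
  }
  report$dereplication_per_site <- derep_site

  # -- abundance + specificity ---------------------------------------------
  if (length(reps1) > 0) {
    cov1 <- dplyr::filter(study$coverage, .data$mag_id %in% reps1) |>
      apply_detection_filter(config$covered_fraction_min)
    abund1 <- normalize_abundance(cov1, study$samples)
    spec <- classify_specificity(abund1, study$samples, config)
    report$abundance <- abund1
    report$specificity <- spec
    report$prevalence <- mag_prevalence(abund1, study$samples)
  } else {
    spec <- tibble(mag_id = character(), label = character())
    report$specificity <- spec
  }

  two_groups <- all(c("host_specific", "seawater_specific") %in% spec$label) &&
    min(table(spec$label[spec$label != "undetected"])) >= 2

  # -- comparative statistics ----------------------------------------------
  if (two_groups) {
    report$genomic_features <- compare_genomic_features(study$mags, spec)
    report$enrichment <- lapply(study$annotations, function(ann) {
      sub <- dplyr::filter(ann, .data$mag_id %in% reps1)
      fisher_enrichment(sub, spec)
    })
  }

  # -- module completeness --------------------------------------------------
  if (!is.null(study$modules) && !is.null(study$annotations$KO) &&
      length(reps1) > 0) {
    ko1 <- dplyr::filter(study$annotations$KO, .data$mag_id %in% reps1)
    report$module_completeness <-
      completeness_report(study$modules, ko1,
                          threshold = config$module_report_min)
  }

  # -- overall dereplication + biogeography --------------------------------
  if (length(reps1) > 0) {
    mags1 <- dplyr::filter(study$mags, .data$mag_id %in% reps1)
    derep_all <- dereplicate_mags(mags1, study$ani,
                                  threshold = config$ani_threshold,
                                  mode = "overall")
    reps2 <- derep_all$mag_id[derep_all$representative]
    report$dereplication_overall <- derep_all

    cov2 <- dplyr::filter(study$coverage, .data$mag_id %in% reps2) |>
      apply_detection_filter(config$covered_fraction_min)
    abund2 <- normalize_abundance(cov2, study$samples)
    ok_samples <- setdiff(study$samples$sample_id,
                          attr(abund2, "flagged_samples"))
    samp2 <- dplyr::filter(study$samples, .data$sample_id %in% ok_samples)
    abund2 <- dplyr::filter(abund2, .data$sample_id %in% ok_samples)

    if (nrow(samp2) >= 3 && length(unique(samp2$sample_type)) == 2) {
      h <- hellinger_transform(abund2)
      d_all <- bray_curtis(h)
      ord_all <- dbrda(d_all, data.frame(
        sample_type = samp2$sample_type[match(rownames(h), samp2$sample_id)],
        site = samp2$site[match(rownames(h), samp2$sample_id)]
      ))
      pm_all <- permanova(d_all,
                          samp2$sample_type[match(rownames(h), samp2$sample_id)],
                          n_perm = config$n_permutations, seed = config$seed)
      report$ordination_all <- ord_all
      report$permanova_sample_type <- pm_all
    }

    # water-quality analyses: host-specific MAGs and coral samples only
    host_ids <- intersect(reps2,
                          spec$mag_id[spec$label == "host_specific"])
    coral <- dplyr::filter(samp2, .data$sample_type == "coral",
                           !is.na(.data$wq_category))
    if (length(host_ids) >= 2 && nrow(coral) >= 4 &&
        dplyr::n_distinct(coral$wq_category) >= 2) {
      cov3 <- study$coverage |>
        dplyr::filter(.data$mag_id %in% host_ids,
                      .data$sample_id %in% coral$sample_id) |>
        apply_detection_filter(config$covered_fraction_min)
      abund3 <- normalize_abundance(cov3, coral)
      h3 <- hellinger_transform(abund3)
      d_wq <- bray_curtis(h3)
      wq <- coral$wq_category[match(rownames(h3), coral$sample_id)]
      ord_wq <- dbrda(d_wq, wq)
      report$ordination_wq <- ord_wq
      report$permanova_wq <- permanova(d_wq, wq,
                                       n_perm = config$n_permutations,
                                       seed = config$seed)
      report$posthoc_wq <- pairwise_factor_fit(ord_wq, wq,
                                               n_perm = config$n_permutations,
                                               seed = config$seed)

      env_cols <- setdiff(names(coral), c(sample_required_cols))
      env_cols <- env_cols[vapply(coral[env_cols], is.numeric, logical(1))]
      if (length(env_cols) > 0) {
        env <- as.data.frame(coral[env_cols])
        rownames(env) <- coral$sample_id
        envp <- preprocess_env(env, r_threshold = config$collinearity_r)
        envp <- envp[rownames(h3), , drop = FALSE]
        ef <- fit_env_vectors(ord_wq, envp,
                              n_perm = config$n_permutations,
                              seed = config$seed)
        report$envfit <- ef
        report$env_removed <- attr(envp, "removal_log")
        sel <- ef$variable[ef$r_squared > config$envfit_r2_min &
                             ef$adjusted_p <= 0.05]
        if (length(sel) > 0) {
          report$ordination_env <- dbrda(d_wq,
                                         as.data.frame(envp[, sel, drop = FALSE]))
          report$selected_env <- sel
        }
      }

      if (!is.null(study$clusters)) {
        cl2 <- dplyr::filter(study$clusters, .data$mag_id %in% reps2)
        abund_cl <- study$coverage |>
          dplyr::filter(.data$mag_id %in% reps2,
                        .data$sample_id %in% coral$sample_id) |>
          apply_detection_filter(config$covered_fraction_min) |>
          normalize_abundance(coral)
        report$cluster_enrichment <-
          cluster_enrichment(cl2, abund_cl, coral, "wq_category")
      }
    }
  }

  report$counts <- report_counts(report)
  report <- structure(report, class = "magniche_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

report_counts <- function(report) {
  spec <- report$specificity
  n_enriched <- function(ns) {
    e <- report$enrichment[[ns]]
    if (is.null(e)) 0L else sum(e$adjusted_p <= 0.05)
  }
  list(
    mags_total = nrow(report$quality %||% tibble()),
    mags_retained = sum(report$quality$retained %||% logical()),
    mags_per_site_representatives =
      sum(report$dereplication_per_site$representative %||% logical()),
    mags_overall_representatives =
      sum(report$dereplication_overall$representative %||% logical()),
    host_specific = sum(spec$label == "host_specific"),
    seawater_specific = sum(spec$label == "seawater_specific"),
    undetected = sum(spec$label == "undetected"),
    enriched = vapply(names(report$enrichment %||% list()), n_enriched,
                      integer(1)),
    modules_flagged = if (is.null(report$module_completeness)) 0L else
      sum(report$module_completeness$flagged),
    significant_env = length(report$selected_env %||% character())
  )
}

#' @export
print.magniche_report <- function(x, ...) {
  ct <- x$counts
  cat("<magniche_report>\n")
  cat(sprintf("  MAGs: %d total, %d retained, %d per-site reps, %d overall reps\n",
              ct$mags_total, ct$mags_retained,
              ct$mags_per_site_representatives,
              ct$mags_overall_representatives))
  cat(sprintf("  specificity: %d host-specific, %d seawater-specific, %d undetected\n",
              ct$host_specific, ct$seawater_specific, ct$undetected))
  if (length(ct$enriched) > 0) {
    cat("  enriched features (adj. p <= 0.05): ",
        paste(names(ct$enriched), ct$enriched, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  cat(sprintf("  modules flagged >75%%: %d; selected env variables: %d\n",
              ct$modules_flagged, ct$significant_env))
  if (!is.null(x$permanova_sample_type)) {
    cat(sprintf("  PERMANOVA sample type: F = %.3g, p = %.4g\n",
                x$permanova_sample_type$statistic,
                x$permanova_sample_type$p_value))
  }
  invisible(x)
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_result_table(report$quality, p("quality.tsv"))
  write_result_table(report$dereplication_per_site, p("derep_per_site.tsv"))
  if (!is.null(report$abundance)) {
    write_result_table(report$abundance, p("abundance.tsv"))
  }
  write_result_table(report$specificity, p("specificity.tsv"))
  if (!is.null(report$genomic_features)) {
    write_result_table(report$genomic_features, p("genomic_features.tsv"))
  }
  for (ns in names(report$enrichment %||% list())) {
    write_result_table(report$enrichment[[ns]],
                       p(paste0("enrichment_", ns, ".tsv")))
  }
  if (!is.null(report$module_completeness)) {
    write_result_table(report$module_completeness, p("module_completeness.tsv"))
  }
  if (!is.null(report$envfit)) write_result_table(report$envfit, p("envfit.tsv"))
  if (!is.null(report$posthoc_wq)) {
    write_result_table(report$posthoc_wq, p("posthoc_wq.tsv"))
  }
  if (!is.null(report$cluster_enrichment)) {
    write_result_table(report$cluster_enrichment, p("cluster_enrichment.tsv"))
  }
  write_run_manifest(p("manifest.json"), report$config)
  invisible(outdir)
}

#' One-command synthetic demo
#'
#' Generates a synthetic study under the default design and runs the full
#' pipeline. With the same seed the report is identical across runs.
#'
#' @param seed Integer seed used for both the generator and the
#'   permutation tests.
#' @param design Optional [simulation_design()] override (its seed is set
#'   to `seed`).
#' @param n_permutations Permutations for all permutation tests.
#' @param outdir Optional output directory.
#' @return A `magniche_report`; the study is attached as attribute
#'   `"study"`.
#' @export
run_demo <- function(seed = 7L, design = NULL, n_permutations = 999L,
                     outdir = NULL) {
  if (is.null(design)) {
    design <- simulation_design(seed = seed)
  } else {
    design$seed <- as.integer(seed)
  }
  study <- simulate_study(design)
  config <- run_config(seed = seed, n_permutations = n_permutations)
  report <- run_pipeline(study, config, outdir = outdir)
  # classifier accuracy against planted truth, over classified MAGs
  truth <- study$ground_truth
  spec <- report$specificity
  m <- dplyr::inner_join(spec, truth, by = "mag_id") |>
    dplyr::filter(.data$label != "undetected")
  report$counts$specificity_accuracy <-
    if (nrow(m) > 0) mean(m$label == m$true_label) else NA_real_
  attr(report, "study") <- study
  report
}
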