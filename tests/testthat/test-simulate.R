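test_that("the generator is bit-reproducible under a fixed seed", {
  d <- simulation_design(n_host_specific = 8, n_seawater_specific = 6, seed = 4)
  s1 <- simulate_study(d)
  s2 <- simulate_study(d)
  expect_identical(s1$mags, s2$mags)
  expect_identical(s1$coverage, s2$coverage)
  expect_identical(s1$ani, s2$ani)
  expect_identical(s1$annotations$KO, s2$annotations$KO)
  expect_identical(s1$clusters, s2$clusters)
})

test_that("catalog bookkeeping matches the design counts", {
  d <- simulation_design(n_host_specific = 40, n_seawater_specific = 30, seed = 2)
  cat_ <- simulate_mag_catalog(d)
  expect_equal(nrow(cat_$mags), 70)
  expect_equal(sum(cat_$ground_truth$true_label == "host_specific"), 40)
  expect_equal(sum(cat_$ground_truth$true_label == "seawater_specific"), 30)
  expect_setequal(cat_$ground_truth$mag_id, cat_$mags$mag_id)
})

test_that("quality metrics match the stated distribution at Monte-Carlo scale", {
  d <- simulation_design(n_host_specific = 5000, n_seawater_specific = 5000,
                         seed = 8)
  cat_ <- simulate_mag_catalog(d)
  n <- nrow(cat_$mags)
  # generator draws completeness with mean 91.2, sd 7.12 on [75, 100]
  se_c <- 7.12 / sqrt(n)
  expect_lt(abs(mean(cat_$mags$completeness) - 91.2), 3 * se_c)
  expect_true(all(cat_$mags$completeness >= 75 & cat_$mags$completeness <= 100))
  se_k <- 2.16 / sqrt(n)
  expect_lt(abs(mean(cat_$mags$contamination) - 2.03), 3 * se_k)
  expect_true(all(cat_$mags$contamination >= 0))
  # host-specific regime: larger genomes, lower GC
  host <- cat_$ground_truth$true_label == "host_specific"
  expect_gt(mean(cat_$mags$genome_size[host]),
            mean(cat_$mags$genome_size[!host]))
  expect_lt(mean(cat_$mags$gc[host]), mean(cat_$mags$gc[!host]))
})

test_that("the ANI matrix is symmetric with unit diagonal and planted strains", {
  d <- simulation_design(n_host_specific = 10, n_seawater_specific = 8,
                         n_strain_groups = 3, seed = 5)
  cat_ <- simulate_mag_catalog(d)
  ani <- cat_$ani
  expect_equal(ani, t(ani))
  expect_equal(unname(diag(ani)), rep(100, nrow(ani)))
  gt <- cat_$ground_truth
  for (g in unique(stats::na.omit(gt$strain_group))) {
    pair <- gt$mag_id[!is.na(gt$strain_group) & gt$strain_group == g]
    expect_gte(ani[pair[1], pair[2]], 99)
    # members placed at different sites so only overall dereplication merges
    sites <- cat_$mags$site[match(pair, cat_$mags$mag_id)]
    expect_false(sites[1] == sites[2])
  }
  off <- ani
  diag(off) <- NA
  unplanted <- is.na(gt$strain_group)
  expect_true(all(off[unplanted, unplanted] < 99, na.rm = TRUE))
})

test_that("noise-free coverage guarantees exact specificity recovery", {
  d <- simulation_design(n_host_specific = 12, n_seawater_specific = 9,
                         noise_sd = 0, seed = 6)
  cat_ <- simulate_mag_catalog(d)
  cov_ <- simulate_coverage(cat_, d)
  ab <- apply_detection_filter(cov_$coverage) |>
    normalize_abundance(cov_$samples)
  spec <- classify_specificity(ab, cov_$samples)
  m <- dplyr::inner_join(spec, cat_$ground_truth, by = "mag_id")
  expect_true(all(m$label == m$true_label))
})

test_that("the planted driver correlates with the first compositional axis at the designed strength", {
  corr <- vapply(1:15, function(s) {
    d <- simulation_design(seed = s, env_gradient_strength = 0.8)
    cat_ <- simulate_mag_catalog(d)
    cov_ <- simulate_coverage(cat_, d)
    coral <- cov_$samples[cov_$samples$sample_type == "coral", ]
    host <- cat_$ground_truth$mag_id[cat_$ground_truth$true_label == "host_specific"]
    cov3 <- cov_$coverage[cov_$coverage$mag_id %in% host &
                            cov_$coverage$sample_id %in% coral$sample_id, ]
    ab <- apply_detection_filter(cov3) |> normalize_abundance(coral)
    pc <- pcoa(bray_curtis(hellinger_transform(ab)))
    temp <- coral$temperature[match(rownames(pc$scores), coral$sample_id)]
    abs(cor(temp, pc$scores[, 1]))
  }, numeric(1))
  # mean realized |correlation| close to the 0.8 target (Monte-Carlo margin)
  expect_lt(abs(mean(corr) - 0.8), 3 * sd(corr) / sqrt(length(corr)) + 0.03)
})

test_that("library sizes span the study's range and seawater wq is missing", {
  d <- simulation_design(seed = 9)
  cov_ <- simulate_coverage(simulate_mag_catalog(d), d)
  s <- cov_$samples
  expect_true(all(s$library_size_gbp >= 2 & s$library_size_gbp <= 100))
  expect_true(all(is.na(s$wq_category[s$sample_type == "seawater"])))
  expect_true(all(!is.na(s$wq_category[s$sample_type == "coral"])))
  expect_equal(sum(s$sample_type == "coral"), 22)
  expect_equal(sum(s$sample_type == "seawater"), 6)
})

test_that("degenerate designs are rejected", {
  expect_error(simulation_design(n_host_specific = 0), "counts")
  expect_error(simulation_design(env_gradient_strength = 1), "0, 1")
  expect_error(
    simulation_design(effect_enriched_features = list(
      KO = list(n_features = 10, n_enriched = 11, log_odds = 2)
    )),
    "more enriched"
  )
})

test_that("planted enrichment separates groups; null log-odds does not", {
  d <- simulation_design(seed = 10)
  cat_ <- simulate_mag_catalog(d)
  ann <- simulate_annotations(cat_, d)
  truth <- ann$truth_features[ann$truth_features$namespace == "KO", ]
  ko <- ann$annotations$KO
  host <- cat_$ground_truth$true_label == "host_specific"
  pres <- as.matrix(ko[-1]) >= 1
  gap <- colMeans(pres[host, , drop = FALSE]) -
    colMeans(pres[!host, , drop = FALSE])
  planted_host <- truth$feature[truth$direction == "host_specific"]
  expect_gt(mean(gap[planted_host]), mean(gap[setdiff(colnames(pres), truth$feature)]))
})
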