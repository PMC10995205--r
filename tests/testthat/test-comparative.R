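test_that("BH adjustment reproduces the step-up hand computation", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(adjust_bh(p), bh_brute(p))
  }
})

test_that("Kruskal-Wallis H matches the rank formula", {
  # closed form: groups [1,2,3] vs [4,5,6] -> H = 27/7
  res <- kruskal.test(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(unname(res$statistic), 27 / 7)
  # tie-corrected H against the explicit formula on random tied data
  set.seed(5)
  for (i in 1:10) {
    x <- sample(1:4, 8, replace = TRUE)
    y <- sample(1:4, 7, replace = TRUE)
    r <- rank(c(x, y))
    n <- 15
    h <- (12 / (n * (n + 1))) *
      (sum(r[1:8])^2 / 8 + sum(r[9:15])^2 / 7) - 3 * (n + 1)
    ties <- table(r)
    h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
    expect_equal(unname(kruskal.test(list(x, y))$statistic), h,
                 tolerance = 1e-12)
  }
})

test_that("genomic-feature comparison reports medians, direction and FDR", {
  set.seed(21)
  mags <- make_mags(20)
  mags$genome_size <- c(rlnorm(10, log(4e6), 0.1), rlnorm(10, log(2e6), 0.1))
  mags$gc <- c(rnorm(10, 42, 1), rnorm(10, 52, 1))
  spec <- tibble::tibble(
    mag_id = mags$mag_id,
    label = rep(c("host_specific", "seawater_specific"), each = 10)
  )
  res <- compare_genomic_features(mags, spec)
  expect_equal(nrow(res), 4)
  expect_equal(res$direction[res$feature == "genome_size"], "host_specific")
  expect_equal(res$direction[res$feature == "gc"], "seawater_specific")
  # constant features (identical groups) get H = 0, p = 1 by convention
  expect_equal(res$statistic[res$feature == "n_genes"], 0)
  expect_equal(res$raw_p[res$feature == "n_genes"], 1)
  expect_true(all(res$adjusted_p >= res$raw_p - 1e-15))
  expect_equal(res$adjusted_p, adjust_bh(res$raw_p))
})

test_that("Fisher enrichment p-values equal hand enumeration on forced tables", {
  ann <- tibble::tibble(
    mag_id = sprintf("M%02d", 1:20),
    full_split = rep(c(1L, 0L), c(10, 10)), # 10/10 vs 0/10
    balanced = rep(c(1L, 0L, 1L, 0L), c(5, 5, 5, 5)), # equal proportions
    nothing = 0L
  )
  spec <- tibble::tibble(mag_id = ann$mag_id,
                         label = rep(c("host_specific", "seawater_specific"),
                                     each = 10))
  expect_message(res <- fisher_enrichment(ann, spec, namespace = "KO"),
                 "absent from all")
  expect_equal(res$raw_p[res$feature == "full_split"], 2 / 184756)
  expect_equal(res$raw_p[res$feature == "balanced"], 1)
  expect_false("nothing" %in% res$feature)
  expect_equal(res$direction[res$feature == "full_split"], "host_specific")

  # the (3,1,1,3) table: p = 34/70
  ann2 <- tibble::tibble(mag_id = sprintf("M%d", 1:8),
                         f = c(1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L))
  spec2 <- tibble::tibble(mag_id = ann2$mag_id,
                          label = rep(c("host_specific", "seawater_specific"),
                                      each = 4))
  res2 <- fisher_enrichment(ann2, spec2)
  expect_equal(res2$raw_p, 34 / 70)
})

test_that("exact Mann-Whitney matches enumeration and wilcox.test on tie-free data", {
  # complete separation 3 vs 3: U = 9, two-sided p = 2/20
  mw <- mann_whitney(c(7, 8, 9), c(1, 2, 3))
  expect_equal(mw$statistic, 9)
  expect_equal(mw$p_value, 0.1)
  # identical values: all ties, p = 1
  expect_equal(mann_whitney(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  # dual route: tie-free small samples agree with the exact wilcox.test
  set.seed(13)
  for (i in 1:20) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(mann_whitney(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large samples take the tie-corrected normal approximation
  set.seed(14)
  big <- mann_whitney(rnorm(25), rnorm(25) + 0.1)
  expect_true(big$p_value > 0 && big$p_value <= 1)
})

test_that("weighted cluster enrichment computes weights and skips degenerate cases", {
  samples <- make_samples(6, 0)
  samples$wq_category <- rep(c("Coastal", "NorthMarine"), each = 3)
  # two MAGs; cluster_a carried only by M1, cluster_none by nobody
  clusters <- tibble::tibble(mag_id = c("M1", "M2"),
                             cluster_a = c(2L, 0L),
                             cluster_none = c(0L, 0L))
  rel <- matrix(c(10, 20, 30, 1, 2, 3,   # M1 across samples
                  90, 80, 70, 99, 98, 97), # M2
                nrow = 2, byrow = TRUE,
                dimnames = list(c("M1", "M2"), samples$sample_id))
  ab <- tibble::tibble(
    mag_id = rep(rownames(rel), times = 6),
    sample_id = rep(colnames(rel), each = 2),
    detected = TRUE,
    normalized_coverage = as.vector(rel),
    relative_abundance = as.vector(rel)
  )
  res <- cluster_enrichment(clusters, ab, samples)
  expect_false("cluster_none" %in% res$cluster)
  row <- res[res$cluster == "cluster_a", ]
  # weights 2*abundance: (20,40,60) vs (2,4,6) -> complete separation, p = 0.1
  expect_equal(row$raw_p, 0.1)
  expect_equal(row$median1, 40)
  expect_equal(row$median2, 4)

  # a category with < 2 samples is skipped with a warning per affected pair
  samples2 <- samples
  samples2$wq_category[1] <- "SouthPlume"
  w <- capture_warnings(res2 <- cluster_enrichment(clusters, ab, samples2))
  expect_true(all(grepl("fewer than 2", w)))
  expect_false(any(res2$group1 == "SouthPlume" | res2$group2 == "SouthPlume"))
})
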