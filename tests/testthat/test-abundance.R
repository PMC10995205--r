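test_that("detection filter zeroes sub-threshold entries, inclusive at 0.10", {
  cov <- tibble::tibble(
    mag_id = c("A", "B", "C"),
    sample_id = "S1",
    mean_coverage = c(50, 5, 3),
    covered_fraction = c(0.05, 0.10, 0.5)
  )
  out <- apply_detection_filter(cov)
  expect_equal(out$detected, c(FALSE, TRUE, TRUE))
  expect_equal(out$mean_coverage, c(0, 5, 3))

  zero <- tibble::tibble(mag_id = "A", sample_id = "S1",
                         mean_coverage = 0, covered_fraction = 0)
  expect_equal(apply_detection_filter(zero)$mean_coverage, 0)
})

test_that("normalization produces the forced proportions", {
  samples <- make_samples(1, 1)
  cov <- tibble::tibble(
    mag_id = c("A", "B", "A", "B"),
    sample_id = c("C01", "C01", "W01", "W01"),
    mean_coverage = c(3, 1, 4, 0),
    covered_fraction = c(0.9, 0.6, 0.9, 0)
  ) |> apply_detection_filter()
  ab <- normalize_abundance(cov, samples)
  c01 <- ab[ab$sample_id == "C01", ]
  expect_equal(c01$relative_abundance[match(c("A", "B"), c01$mag_id)], c(75, 25))
  # single detected MAG in W01 -> 100%
  expect_equal(ab$relative_abundance[ab$sample_id == "W01" & ab$mag_id == "A"], 100)
})

test_that("library scaling changes normalized coverage but not relative abundance", {
  samples <- make_samples(2, 1)[1:2, ]
  samples$sample_type <- "coral"
  samples$library_size_gbp <- c(2, 4)
  cov <- tibble::tibble(
    mag_id = rep(c("A", "B"), 2),
    sample_id = rep(c("C01", "C02"), each = 2),
    mean_coverage = c(6, 2, 6, 2),
    covered_fraction = 0.9
  ) |> apply_detection_filter()
  ab <- normalize_abundance(cov, samples)
  w <- tidyr::pivot_wider(ab, id_cols = "mag_id",
                          names_from = "sample_id",
                          values_from = c("normalized_coverage", "relative_abundance"))
  expect_equal(w$normalized_coverage_C02, w$normalized_coverage_C01 / 2)
  expect_equal(w$relative_abundance_C01, w$relative_abundance_C02)
})

test_that("samples with no detected MAG are flagged, not zeroed", {
  samples <- make_samples(2, 0)
  cov <- tibble::tibble(
    mag_id = c("A", "A"),
    sample_id = c("C01", "C02"),
    mean_coverage = c(5, 0.01),
    covered_fraction = c(0.99, 0.01)
  ) |> apply_detection_filter()
  expect_warning(ab <- normalize_abundance(cov, samples), "C02")
  expect_true(is.na(ab$relative_abundance[ab$sample_id == "C02"]))
  expect_equal(attr(ab, "flagged_samples"), "C02")
})

test_that("prevalence counts detected samples per type", {
  samples <- make_samples(4, 6)
  cov_mat <- matrix(0, 3, 10,
                    dimnames = list(c("A", "B", "C"), samples$sample_id))
  cov_mat["A", c("W01", "W02", "W03")] <- 5 # 3 of 6 seawater
  cov_mat["B", ] <- 5                       # everywhere
  ab <- make_coverage(cov_mat) |>
    apply_detection_filter() |>
    normalize_abundance(samples) |>
    suppressWarnings()
  prev <- mag_prevalence(ab, samples)
  get <- function(m, t) prev$prevalence[prev$mag_id == m & prev$sample_type == t]
  expect_equal(get("A", "seawater"), 0.5)
  expect_equal(get("A", "coral"), 0)
  expect_equal(get("B", "coral"), 1)
  expect_equal(get("B", "seawater"), 1)
  expect_equal(get("C", "seawater"), 0)
})

test_that("relative abundance is column-stochastic, scale-invariant and monotone", {
  set.seed(7)
  samples <- make_samples(5, 3)
  n_mag <- 12
  cov_mat <- matrix(rlnorm(n_mag * 8, 1, 1), n_mag, 8,
                    dimnames = list(sprintf("M%02d", 1:n_mag),
                                    samples$sample_id))
  cov <- make_coverage(cov_mat) |> apply_detection_filter()
  ab <- normalize_abundance(cov, samples)
  sums <- tapply(ab$relative_abundance, ab$sample_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))

  # scale invariance: multiply one sample's coverages by 13
  cov2 <- cov
  idx <- cov2$sample_id == "C03"
  cov2$mean_coverage[idx] <- cov2$mean_coverage[idx] * 13
  ab2 <- normalize_abundance(cov2, samples)
  expect_equal(ab2$relative_abundance[ab2$sample_id == "C03"],
               ab$relative_abundance[ab$sample_id == "C03"],
               tolerance = 1e-12)

  # monotonicity: raising one MAG's coverage raises it, lowers the rest
  cov3 <- cov
  up <- cov3$sample_id == "C01" & cov3$mag_id == "M01"
  cov3$mean_coverage[up] <- cov3$mean_coverage[up] * 2
  ab3 <- normalize_abundance(cov3, samples)
  old <- ab[ab$sample_id == "C01", ]
  new <- ab3[ab3$sample_id == "C01", ]
  expect_gt(new$relative_abundance[new$mag_id == "M01"],
            old$relative_abundance[old$mag_id == "M01"])
  expect_true(all(new$relative_abundance[new$mag_id != "M01"] <
                    old$relative_abundance[old$mag_id != "M01"]))
})
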