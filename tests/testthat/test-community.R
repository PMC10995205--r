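test_that("Hellinger transform matches hand arithmetic and normalizes rows", {
  m <- matrix(c(1, 1, 2), nrow = 1, dimnames = list("s1", NULL))
  expect_equal(as.vector(hellinger_transform(m)),
               c(0.5, 0.5, sqrt(0.5)), tolerance = 1e-12)
  single <- matrix(5, 1, 1, dimnames = list("s1", "m1"))
  expect_equal(as.vector(hellinger_transform(single)), 1)
  set.seed(2)
  r <- matrix(runif(60), 6, 10, dimnames = list(paste0("s", 1:6), NULL))
  expect_equal(unname(rowSums(hellinger_transform(r)^2)), rep(1, 6),
               tolerance = 1e-12)
  r[3, ] <- 0
  expect_error(hellinger_transform(r), "s3")
})

test_that("Bray-Curtis matches hand arithmetic; binary mode is Sorensen", {
  m <- rbind(a = c(1, 2), b = c(2, 1), c = c(1, 2))
  d <- bray_curtis(m)
  dm <- as.matrix(d)
  expect_equal(dm["a", "b"], 1 / 3)
  expect_equal(dm["a", "c"], 0)
  disj <- rbind(a = c(1, 0), b = c(0, 3), c = c(1, 1))
  expect_equal(as.matrix(bray_curtis(disj))["a", "b"], 1)
  # binary: (1,2,0) vs (3,0,1) share 1 of (2,2) -> Sorensen 1 - 2*1/4 = 0.5
  bb <- rbind(a = c(1, 2, 0), b = c(3, 0, 1), c = c(1, 1, 1))
  expect_equal(as.matrix(bray_curtis(bb, binary = TRUE))["a", "b"], 0.5)
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))),
               "all-zero")
})

test_that("PCoA reconstructs Euclidean-embeddable distances and obeys the trace identity", {
  set.seed(3)
  for (i in 1:5) {
    x <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(paste0("s", 1:5), NULL))
    d <- dist(x)
    pc <- pcoa(d)
    rec <- dist(pc$scores)
    expect_lt(max(abs(as.vector(rec) - as.vector(d))), 1e-9)
    # Gower identity: sum of eigenvalues = sum d^2 / n
    expect_equal(sum(pc$eigenvalues), sum(as.matrix(d)^2) / (2 * 5),
                 tolerance = 1e-9)
  }
  expect_error(pcoa(dist(matrix(rnorm(4), 2, 2))), "at least 3")
})

test_that("db-RDA conserves inertia and saturates for perfectly separated clusters", {
  set.seed(4)
  x <- rbind(matrix(rnorm(30, 0), 10, 3), matrix(rnorm(30, 50), 10, 3))
  rownames(x) <- paste0("s", 1:20)
  d <- dist(x)
  fac <- rep(c("g1", "g2"), each = 10)
  db <- dbrda(d, fac)
  expect_equal(db$constrained_inertia + db$unconstrained_inertia,
               db$total_inertia, tolerance = 1e-8)
  expect_lte(db$n_constrained_axes, 1)
  expect_gt(db$constrained_inertia / db$total_inertia, 0.99)
  expect_error(dbrda(d, rep("g1", 20)), "constant")
})

test_that("db-RDA constrained proportion agrees with vegan::capscale", {
  set.seed(6)
  m <- matrix(rlnorm(12 * 8), 12, 8, dimnames = list(paste0("s", 1:12), NULL))
  fac <- rep(c("a", "b", "c"), each = 4)
  d <- bray_curtis(hellinger_transform(m))
  db <- dbrda(d, fac)
  cs <- vegan::capscale(d ~ fac)
  expect_equal(db$constrained_inertia / db$total_inertia,
               cs$CCA$tot.chi / (cs$CCA$tot.chi + cs$CA$tot.chi),
               tolerance = 1e-6)
})

test_that("PERMANOVA pseudo-F agrees with the brute-force partition and adonis2", {
  set.seed(7)
  x <- matrix(rnorm(10 * 4), 10, 4)
  rownames(x) <- paste0("s", 1:10)
  d <- dist(x)
  fac <- rep(c("a", "b"), each = 5)
  pm <- permanova(d, fac, n_perm = 99, seed = 1)
  expect_equal(pm$statistic, permanova_f_brute(as.matrix(d), fac),
               tolerance = 1e-10)
  ad <- vegan::adonis2(d ~ fac, permutations = 99)
  expect_equal(pm$statistic, ad$F[1], tolerance = 1e-8)
  expect_equal(pm$R_squared, ad$R2[1], tolerance = 1e-8)
})

test_that("PERMANOVA enumerates exhaustively on small designs and is seeded", {
  set.seed(8)
  x <- matrix(rnorm(6 * 3), 6, 3)
  d <- dist(x)
  fac <- rep(c("a", "b"), each = 3)
  pm <- permanova(d, fac, n_perm = 999, seed = 1)
  expect_equal(pm$method, "exhaustive")
  expect_equal(pm$n_permutations, 20)
  expect_equal(pm$p_value * 20, round(pm$p_value * 20))
  # sampled path is reproducible under the same seed
  x2 <- matrix(rnorm(12 * 3), 12, 3)
  d2 <- dist(x2)
  fac2 <- rep(c("a", "b", "c"), each = 4)
  p1 <- permanova(d2, fac2, n_perm = 199, seed = 5)$p_value
  p2 <- permanova(d2, fac2, n_perm = 199, seed = 5)$p_value
  expect_identical(p1, p2)
  expect_warning(permanova(dist(matrix(rnorm(9), 3, 3)), c("a", "a", "b")),
                 "single sample")
})

test_that("envfit recovers exact alignments and agrees with vegan", {
  set.seed(9)
  x <- matrix(rnorm(15 * 4), 15, 4, dimnames = list(paste0("s", 1:15), NULL))
  pc <- pcoa(dist(x))
  sc <- pc$scores[, 1:2]
  env <- data.frame(
    ax1 = sc[, 1],
    diag = sc[, 1] + sc[, 2],
    noise = rnorm(15),
    flat = rep(1, 15)
  )
  expect_warning(ef <- fit_env_vectors(pc, env, n_perm = 199, seed = 2),
                 "constant")
  expect_false("flat" %in% ef$variable)
  expect_equal(ef$r_squared[ef$variable == "ax1"], 1, tolerance = 1e-12)
  # variable = axis1 + axis2 with equal weights -> direction cosines 1/sqrt(2)
  dg <- ef[ef$variable == "diag", ]
  expect_equal(abs(c(dg$axis1, dg$axis2)), rep(1 / sqrt(2), 2),
               tolerance = 1e-8)
  # r-squared values match vegan::envfit on the same scores
  vf <- vegan::envfit(sc, env[, c("ax1", "diag", "noise")], permutations = 0)
  expect_equal(ef$r_squared[match(c("ax1", "diag", "noise"), ef$variable)],
               unname(vf$vectors$r), tolerance = 1e-8)
})

test_that("pairwise factor fits separate the planted pair", {
  set.seed(10)
  sc <- rbind(matrix(rnorm(12, 0, 0.3), 6, 2),
              matrix(rnorm(12, 0, 0.3), 6, 2),
              matrix(rnorm(12, 6, 0.3), 6, 2))
  rownames(sc) <- paste0("s", 1:18)
  fac <- rep(c("a", "b", "far"), each = 6)
  res <- pairwise_factor_fit(sc, fac, n_perm = 199, seed = 3)
  expect_equal(nrow(res), 3)
  ab <- res[res$group1 == "a" & res$group2 == "b", ]
  expect_gt(ab$raw_p, 0.2) # same distribution
  far_rows <- res[res$group2 == "far", ]
  # near the permutation floor (ties with the observed partition can occur)
  expect_true(all(far_rows$raw_p >= 1 / 200 & far_rows$raw_p <= 5 / 200))
  expect_true(all(res$adjusted_p >= res$raw_p - 1e-15))
})

test_that("environmental preprocessing standardizes and prunes collinear columns", {
  set.seed(11)
  n <- 30
  a <- rnorm(n)
  make_cor <- function(base, r) {
    e <- residuals(lm(rnorm(n) ~ base))
    r * scale(base)[, 1] + sqrt(1 - r^2) * scale(e)[, 1]
  }
  env <- data.frame(
    a = a,
    dup = a * 3 + 1,          # r = 1 with a
    near = make_cor(a, 0.69), # below the strict 0.7 threshold
    flat = rep(2, n),
    b = rnorm(n)
  )
  out <- preprocess_env(env, r_threshold = 0.7)
  expect_setequal(colnames(out), c("a", "near", "b"))
  log <- attr(out, "removal_log")
  expect_equal(log$reason[log$variable == "dup"], "collinear")
  expect_equal(log$partner[log$variable == "dup"], "a")
  expect_equal(log$reason[log$variable == "flat"], "zero_variance")
  expect_true(all(abs(colMeans(out)) < 1e-12))
  expect_equal(unname(apply(out, 2, sd)), rep(1, 3), tolerance = 1e-12)
})

test_that("the Hellinger/Bray-Curtis pipeline is invariant to per-sample rescaling", {
  set.seed(12)
  m <- matrix(rlnorm(8 * 12), 8, 12, dimnames = list(paste0("s", 1:8), NULL))
  d1 <- bray_curtis(hellinger_transform(m))
  m2 <- m * runif(8, 0.1, 10) # row-wise rescale
  d2 <- bray_curtis(hellinger_transform(m2))
  expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-12)
})
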