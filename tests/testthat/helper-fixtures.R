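# In-code fixtures shared across test files.

make_mags <- function(n = 3, site = "SiteA",
                      completeness = rep(95, n),
                      contamination = rep(1, n),
                      ids = sprintf("MAG%03d", seq_len(n))) {
  tibble::tibble(
    mag_id = ids,
    site = rep_len(site, n),
    completeness = completeness,
    contamination = contamination,
    genome_size = rep(3e6, n),
    gc = rep(50, n),
    n_genes = rep(3000L, n),
    coding_density = rep(90, n),
    taxonomy = rep("d__Bacteria;p__Pseudomonadota;c__;o__;f__;g__;s__", n)
  )
}

make_samples <- function(n_coral = 4, n_seawater = 6) {
  tibble::tibble(
    sample_id = c(sprintf("C%02d", seq_len(n_coral)),
                  sprintf("W%02d", seq_len(n_seawater))),
    sample_type = rep(c("coral", "seawater"), c(n_coral, n_seawater)),
    site = "SiteA",
    wq_category = c(rep("NorthMarine", n_coral), rep(NA_character_, n_seawater)),
    library_size_gbp = rep(10, n_coral + n_seawater)
  )
}

# long coverage tibble from a MAGs x samples coverage matrix
make_coverage <- function(cov, kappa = 1) {
  tibble::tibble(
    mag_id = rep(rownames(cov), times = ncol(cov)),
    sample_id = rep(colnames(cov), each = nrow(cov)),
    mean_coverage = as.vector(cov),
    covered_fraction = 1 - exp(-as.vector(cov) / kappa)
  )
}

# symmetric ANI matrix with given ids, constant background
make_ani <- function(ids, background = 80) {
  n <- length(ids)
  m <- matrix(background, n, n, dimnames = list(ids, ids))
  diag(m) <- 100
  m
}

# independent two-sided Fisher oracle: enumerate all tables with the
# observed margins, sum the probabilities of tables no more likely than
# the observed one (multinomial-coefficient arithmetic, no dhyper)
fisher_two_sided_enum <- function(a, b, nA, nB) {
  k <- a + b
  support <- max(0, k - nB):min(nA, k)
  prob <- vapply(support, function(x) {
    exp(lchoose(nA, x) + lchoose(nB, k - x) - lchoose(nA + nB, k))
  }, numeric(1))
  p_obs <- prob[support == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# brute-force min-over-tail Benjamini-Hochberg
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj_sorted <- vapply(seq_len(m), function(k) {
    min(1, min(m * ps[k:m] / (k:m)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# independent PERMANOVA pseudo-F via explicit double loops
permanova_f_brute <- function(dm, groups) {
  n <- nrow(dm)
  a <- length(unique(groups))
  ss_t <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + dm[i, j]^2
  ss_t <- ss_t / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ng <- length(idx)
    if (ng < 2) next
    s <- 0
    for (i in idx) for (j in idx) if (i < j) s <- s + dm[i, j]^2
    ss_w <- ss_w + s / ng
  }
  ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
}
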