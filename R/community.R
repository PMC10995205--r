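# Community-ecology statistics on samples x MAGs (or MAGs x features)
# matrices. All permutation procedures are seeded and use the +1 convention
# p = (1 + #{permuted statistic >= observed}) / (1 + n_perm), so the minimum
# attainable p with 999 permutations is 0.001.

as_sample_matrix <- function(x, value = "relative_abundance") {
  if (inherits(x, "magniche_abundance")) x <- abundance_matrix(x, value)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("expected an abundance tibble or a numeric samples-by-features matrix")
  }
  x
}

#' Hellinger transform
#'
#' Square root of within-sample proportions: `h = sqrt(x / rowSum)`. Squared
#' row sums are 1, which makes downstream Bray-Curtis analysis insensitive
#' to per-sample rescaling of the raw values.
#'
#' @param x Abundance tibble from [normalize_abundance()] or a non-negative
#'   samples-by-features matrix.
#' @return Transformed matrix of the same shape.
#' @export
hellinger_transform <- function(x) {
  m <- as_sample_matrix(x)
  if (any(m < 0)) abort("Hellinger transform requires non-negative values")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    abort(paste0("all-zero sample(s): ",
                 paste(rownames(m)[zero] %||% which(zero), collapse = ", ")))
  }
  vegan::decostand(m, method = "hellinger")
}

#' Bray-Curtis dissimilarity
#'
#' `d(i, j) = sum|x_i - x_j| / sum(x_i + x_j)` between sample rows. In
#' binary mode values are reduced to presence/absence (> 0) first, which
#' makes the coefficient equal to the Sorensen dissimilarity.
#'
#' @param x Abundance tibble or non-negative samples-by-features matrix.
#' @param binary Use presence/absence instead of quantities.
#' @return A `dist` object with attribute `metric` set to `"bray_curtis"`
#'   or `"binary_bray_curtis"`.
#' @export
bray_curtis <- function(x, binary = FALSE) {
  m <- as_sample_matrix(x)
  if (any(m < 0)) abort("Bray-Curtis requires non-negative values")
  if (sum(rowSums(m) == 0) >= 2) {
    abort("distance between two all-zero samples is undefined")
  }
  d <- vegan::vegdist(m, method = "bray", binary = binary)
  attr(d, "metric") <- if (binary) "binary_bray_curtis" else "bray_curtis"
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering of −d²/2 followed by eigendecomposition. Axes are
#' ordered by descending eigenvalue; axes with non-positive eigenvalues are
#' dropped (no correction is applied) and the negative eigenvalues are
#' reported so the user can judge how non-Euclidean the input is. When the
#' distances are Euclidean-embeddable the returned coordinates reproduce
#' them exactly.
#'
#' @param d A `dist` object or symmetric distance matrix (>= 3 samples).
#' @return Object of class `magniche_pcoa`: `scores` (samples x positive
#'   axes), `eigenvalues` (all, descending), `prop_var` (share of positive
#'   inertia per kept axis), `negative_eigenvalues`, `total_inertia`.
#' @export
pcoa <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 3) abort("PCoA needs at least 3 samples")
  fit <- suppressWarnings(cmdscale(dm, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > max(eig) * 1e-10
  scores <- fit$points[, seq_len(sum(pos[seq_len(ncol(fit$points))])), drop = FALSE]
  colnames(scores) <- paste0("PCo", seq_len(ncol(scores)))
  rownames(scores) <- rownames(dm)
  structure(list(
    scores = scores,
    eigenvalues = eig,
    prop_var = eig[seq_len(ncol(scores))] / sum(eig[pos]),
    negative_eigenvalues = eig[eig < 0],
    total_inertia = sum(eig[pos])
  ), class = "magniche_pcoa")
}

#' @export
print.magniche_pcoa <- function(x, ...) {
  cat("<magniche_pcoa> ", nrow(x$scores), " samples, ", ncol(x$scores),
      " positive axes\n", sep = "")
  cat("  first axes explain ",
      paste0(sprintf("%.1f%%", 100 * head(x$prop_var, 3)), collapse = ", "),
      " of positive inertia\n", sep = "")
  if (length(x$negative_eigenvalues) > 0) {
    cat("  ", length(x$negative_eigenvalues),
        " negative eigenvalues dropped (largest magnitude ",
        sprintf("%.3g", max(abs(x$negative_eigenvalues))), ")\n", sep = "")
  }
  invisible(x)
}

#' Distance-based redundancy analysis
#'
#' Constrained ordination: the PCoA axes of the distance matrix are
#' regressed on the (centered) design of the constraining variables; the
#' eigen-structure of the fitted component gives the constrained axes (at
#' most levels − 1 for a single factor) and the residual component gives
#' the unconstrained axes. Constrained plus unconstrained inertia equals
#' the total positive PCoA inertia.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param constraints A factor/character vector (one level per sample) or a
#'   data frame of constraining variables (factors and/or numeric).
#' @return Object of class `magniche_dbrda`: constrained and unconstrained
#'   eigenvalues and sample scores (axes `CAP1...`, `MDS1...`), the two
#'   inertia components, `total_inertia`, and the constraint levels.
#' @export
dbrda <- function(d, constraints) {
  base <- pcoa(d)
  y <- base$scores
  n <- nrow(y)
  if (is.data.frame(constraints)) {
    df <- constraints
  } else {
    if (length(unique(constraints)) < 2) abort("constraint factor is constant")
    df <- data.frame(constraint = factor(constraints))
  }
  if (nrow(df) != n) abort("constraints must have one row per sample")
  x <- stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
  x <- scale(x, center = TRUE, scale = FALSE)
  if (qr(x)$rank == 0) abort("constraint design has no variation")
  qx <- qr(x)
  fitted <- qr.fitted(qx, y)
  resid <- y - fitted
  sv_c <- svd(fitted)
  sv_u <- svd(resid)
  keep_c <- sv_c$d^2 > max(sv_c$d^2, 1) * 1e-10
  keep_u <- sv_u$d^2 > max(sv_u$d^2, 1) * 1e-10
  cap <- (sv_c$u %*% diag(sv_c$d, length(sv_c$d)))[, keep_c, drop = FALSE]
  mds <- (sv_u$u %*% diag(sv_u$d, length(sv_u$d)))[, keep_u, drop = FALSE]
  colnames(cap) <- paste0("CAP", seq_len(ncol(cap)))
  colnames(mds) <- paste0("MDS", seq_len(ncol(mds)))
  rownames(cap) <- rownames(mds) <- rownames(y)
  structure(list(
    scores = cbind(cap, mds),
    eigenvalues_constrained = sv_c$d[keep_c]^2,
    eigenvalues_unconstrained = sv_u$d[keep_u]^2,
    constrained_inertia = sum(sv_c$d^2),
    unconstrained_inertia = sum(sv_u$d^2),
    total_inertia = base$total_inertia,
    n_constrained_axes = sum(keep_c),
    constraints = df
  ), class = "magniche_dbrda")
}

#' @export
print.magniche_dbrda <- function(x, ...) {
  cat("<magniche_dbrda> ", nrow(x$scores), " samples\n", sep = "")
  cat(sprintf("  constrained inertia   %.4f (%.1f%%), %d axes\n",
              x$constrained_inertia,
              100 * x$constrained_inertia / x$total_inertia,
              x$n_constrained_axes))
  cat(sprintf("  unconstrained inertia %.4f\n", x$unconstrained_inertia))
  invisible(x)
}

# grouped within-cluster sum of squared distances, the PERMANOVA kernel
ss_within <- function(d2, groups) {
  s <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- s + sum(d2[idx, idx]) / (2 * length(idx))
  }
  s
}

# all assignments of n items into labeled groups of the given sizes,
# as an integer matrix (rows = assignments, cols = items)
enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  out <- list()
  rec <- function(remaining, g, acc) {
    if (g == length(sizes)) {
      acc[remaining] <- g
      out[[length(out) + 1]] <<- acc
      return(invisible(NULL))
    }
    for (pk in combn(remaining, sizes[g], simplify = FALSE)) {
      acc2 <- acc
      acc2[pk] <- g
      rec(setdiff(remaining, pk), g + 1L, acc2)
    }
  }
  rec(seq_len(n), 1L, integer(n))
  do.call(rbind, out)
}

#' One-factor PERMANOVA
#'
#' Partitions the total sum of squared distances (`SS_total = sum of
#' squared pairwise distances / n`) into within-group and between-group
#' components and forms the pseudo-F
#' `((SS_total - SS_within)/(a-1)) / (SS_within/(n-a))`. The p-value comes
#' from free permutation of the group labels with the +1 convention. When
#' the number of distinct label arrangements does not exceed `n_perm`, all
#' arrangements are enumerated instead and the p-value is exact
#' (`#{F_perm >= F_obs} / n_arrangements`, the observed arrangement
#' included).
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param groups Factor/character vector of group labels, one per sample.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `magniche_permanova` with `statistic` (pseudo-F),
#'   `R_squared`, `p_value`, `df`, sums of squares, `n_permutations` and
#'   `method` (`"sampled"` or `"exhaustive"`).
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- as.character(groups)
  if (length(groups) != n) abort("groups must have one label per sample")
  a <- length(unique(groups))
  if (a < 2) abort("need at least 2 group levels")
  if (any(table(groups) == 1)) {
    warn("group(s) with a single sample contribute zero within-group SS")
  }
  d2 <- dm^2
  ss_t <- sum(d2) / (2 * n)
  ss_w <- ss_within(d2, groups)
  ss_b <- ss_t - ss_w
  f_obs <- (ss_b / (a - 1)) / (ss_w / (n - a))

  sizes <- as.integer(table(groups))
  log_n_arr <- lgamma(n + 1) - sum(lgamma(sizes + 1))
  exhaustive <- log_n_arr <= log(n_perm)
  if (exhaustive) {
    lv <- unique(groups)
    # enumerate with the observed size per label, in observed label order
    sizes_lv <- as.integer(table(factor(groups, levels = lv)))
    assign <- enumerate_assignments(sizes_lv)
    f_all <- apply(assign, 1, function(gidx) {
      ssw <- ss_within(d2, gidx)
      ((ss_t - ssw) / (a - 1)) / (ssw / (n - a))
    })
    p <- mean(f_all >= f_obs - 1e-12)
    n_used <- nrow(assign)
  } else {
    set.seed(seed)
    count <- 0L
    for (b in seq_len(n_perm)) {
      gp <- groups[sample.int(n)]
      ssw <- ss_within(d2, gp)
      fb <- ((ss_t - ssw) / (a - 1)) / (ssw / (n - a))
      if (fb >= f_obs - 1e-12) count <- count + 1L
    }
    p <- (1 + count) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(
    statistic = f_obs, R_squared = ss_b / ss_t, p_value = p,
    df = c(groups = a - 1, residual = n - a),
    ss = c(between = ss_b, within = ss_w, total = ss_t),
    n_permutations = n_used,
    method = if (exhaustive) "exhaustive" else "sampled",
    n = n
  ), class = "magniche_permanova")
}

#' @export
print.magniche_permanova <- function(x, ...) {
  cat("<magniche_permanova>\n")
  cat(sprintf("  pseudo-F = %.4g, R^2 = %.3f, p = %.4g (%s, %d %s)\n",
              x$statistic, x$R_squared, x$p_value, x$method,
              x$n_permutations,
              if (x$method == "exhaustive") "arrangements" else "permutations"))
  invisible(x)
}

ordination_scores <- function(ord, n_axes = 2) {
  s <- if (is.matrix(ord)) ord else ord$scores
  if (is.null(s)) abort("cannot extract scores from ordination object")
  if (ncol(s) < n_axes) abort(paste0("ordination has fewer than ", n_axes, " axes"))
  s[, seq_len(n_axes), drop = FALSE]
}

#' Fit environmental vectors to an ordination
#'
#' Least-squares projection of each (standardized) environmental variable
#' onto the first two ordination axes: `r² = 1 − SS_resid / SS_total` of
#' the regression of the variable on the axis scores, with unit-norm
#' direction cosines. Permutation p-values shuffle the variable across
#' samples (+1 convention); BH adjustment is applied across variables.
#' Missing values are excluded per variable; constant variables are skipped
#' with a warning. The conventional downstream selection rule keeps
#' variables with R² > 0.65.
#'
#' @param ord A `magniche_pcoa`/`magniche_dbrda` object or a score matrix.
#' @param env Data frame or matrix of numeric variables, rows aligned with
#'   the ordination's samples.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return Tibble of class `magniche_envfit`: `variable`, direction
#'   cosines `axis1`, `axis2`, `r_squared`, `raw_p`, `adjusted_p`, `n_used`.
#' @export
fit_env_vectors <- function(ord, env, n_perm = 999, seed = 1L) {
  x <- ordination_scores(ord, 2)
  env <- as.data.frame(env)
  if (nrow(env) != nrow(x)) abort("env must have one row per sample")
  set.seed(seed)
  res <- purrr::map_dfr(names(env), function(v) {
    vv <- env[[v]]
    ok <- !is.na(vv)
    if (sum(ok) < 3) {
      warn(paste0("variable '", v, "' has <3 non-missing values; skipped"))
      return(tibble())
    }
    vsub <- vv[ok]
    if (sd(vsub) == 0) {
      warn(paste0("variable '", v, "' is constant; skipped"))
      return(tibble())
    }
    xs <- scale(x[ok, , drop = FALSE], center = TRUE, scale = FALSE)
    vc <- vsub - mean(vsub)
    qx <- qr(xs)
    r2 <- function(vcent) {
      fit <- qr.fitted(qx, vcent)
      sum(fit^2) / sum(vcent^2)
    }
    r2_obs <- r2(vc)
    b <- unname(qr.coef(qx, vc))
    b[is.na(b)] <- 0
    cosine <- b / sqrt(sum(b^2))
    perm <- replicate(n_perm, r2(vc[sample.int(length(vc))]))
    p <- (1 + sum(perm >= r2_obs - 1e-12)) / (1 + n_perm)
    tibble(variable = v, axis1 = cosine[1], axis2 = cosine[2],
           r_squared = r2_obs, raw_p = p, n_used = sum(ok))
  })
  if (nrow(res) > 0) res$adjusted_p <- adjust_bh(res$raw_p)
  class(res) <- c("magniche_envfit", class(res))
  res
}

#' Pairwise post-hoc factor fit on ordination scores
#'
#' For each unordered pair of factor levels, restricts the first two axes'
#' scores to the pair's samples and measures the between-centroid goodness
#' of fit `r² = 1 − SS_within / SS_total` (sums of squared deviations over
#' both axes). Significance by label permutation within the pair (+1
#' convention), BH-adjusted across pairs. Pairs with fewer than two samples
#' in a level are skipped.
#'
#' @param ord Ordination object or score matrix.
#' @param groups Factor/character labels, one per sample.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return Tibble: `group1`, `group2`, `r_squared`, `raw_p`, `adjusted_p`.
#' @export
pairwise_factor_fit <- function(ord, groups, n_perm = 999, seed = 1L) {
  x <- ordination_scores(ord, 2)
  groups <- as.character(groups)
  if (length(groups) != nrow(x)) abort("groups must have one label per sample")
  lv <- sort(unique(groups))
  if (length(lv) < 2) abort("need at least 2 levels")
  set.seed(seed)
  r2_stat <- function(xs, g) {
    grand <- colMeans(xs)
    ss_t <- sum(sweep(xs, 2, grand)^2)
    ss_w <- 0
    for (l in unique(g)) {
      sub <- xs[g == l, , drop = FALSE]
      ss_w <- ss_w + sum(sweep(sub, 2, colMeans(sub))^2)
    }
    1 - ss_w / ss_t
  }
  res <- purrr::map_dfr(combn(lv, 2, simplify = FALSE), function(pr) {
    idx <- groups %in% pr
    g <- groups[idx]
    if (min(table(g)) < 2) return(tibble())
    xs <- x[idx, , drop = FALSE]
    obs <- r2_stat(xs, g)
    perm <- replicate(n_perm, r2_stat(xs, g[sample.int(length(g))]))
    p <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
    tibble(group1 = pr[1], group2 = pr[2], r_squared = obs, raw_p = p)
  })
  if (nrow(res) > 0) res$adjusted_p <- adjust_bh(res$raw_p)
  res
}

#' Standardize and prune environmental variables
#'
#' Z-scores every variable (mean 0, sample sd 1, missing values excluded
#' pairwise), then walks the columns in input order and removes any column
#' whose pairwise-complete Pearson correlation with an already-retained
#' column strictly exceeds `r_threshold` in magnitude (default 0.7).
#' Zero-variance variables cannot be standardized and are removed with a
#' log entry.
#'
#' @param env Data frame or matrix of numeric environmental variables.
#' @param r_threshold Strict |r| threshold for collinearity removal.
#' @return Standardized matrix of the retained variables with attribute
#'   `removal_log`, a tibble (`variable`, `reason`, `partner`, `r`).
#' @export
preprocess_env <- function(env, r_threshold = 0.7) {
  env <- as.data.frame(env)
  if (nrow(env) < 2) abort("need at least 2 samples")
  log_rows <- list()
  keep <- character()
  z <- list()
  for (v in names(env)) {
    vv <- env[[v]]
    if (sd(vv, na.rm = TRUE) == 0 || all(is.na(vv))) {
      log_rows[[length(log_rows) + 1]] <-
        tibble(variable = v, reason = "zero_variance",
               partner = NA_character_, r = NA_real_)
      next
    }
    zv <- as.numeric(scale(vv))
    collinear_with <- NULL
    r_hit <- NA_real_
    for (k in keep) {
      r <- suppressWarnings(cor(zv, z[[k]], use = "pairwise.complete.obs"))
      if (!is.na(r) && abs(r) > r_threshold) {
        collinear_with <- k
        r_hit <- r
        break
      }
    }
    if (is.null(collinear_with)) {
      keep <- c(keep, v)
      z[[v]] <- zv
    } else {
      log_rows[[length(log_rows) + 1]] <-
        tibble(variable = v, reason = "collinear",
               partner = collinear_with, r = r_hit)
    }
  }
  if (length(keep) == 0) abort("no environmental variables retained")
  out <- do.call(cbind, z[keep])
  colnames(out) <- keep
  rownames(out) <- rownames(env)
  attr(out, "removal_log") <- dplyr::bind_rows(log_rows)
  out
}
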