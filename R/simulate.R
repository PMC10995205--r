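#' Synthetic study design
#'
#' Parameters of the seeded generator that emulates the structure of a
#' host-associated microbiome survey: a MAG catalog recovered from coral
#' and seawater samples across six reef sites in five water-quality
#' categories (22 coral + 6 seawater samples by default), with planted
#' habitat specificity, strain groups, functional enrichment and an
#' environmental gradient.
#'
#' Defaults reproduce the study-scale conditions: quality metrics centred
#' on 91.2% completeness (sd 7.12, Beta on \[75, 100\] so the mean is exact
#' despite the bounded support) and 2.03% contamination (sd 2.16, Gamma);
#' library sizes spanning roughly 2–100 Gbp; host-specific MAGs drawn from
#' a larger-genome, lower-GC regime than seawater-specific MAGs; and a
#' latent compositional gradient across coral samples correlated with one
#' planted driver variable (`temperature`) at `env_gradient_strength`.
#'
#' @param n_host_specific,n_seawater_specific Number of MAGs planted as
#'   host-specific / seawater-specific.
#' @param n_coral_samples,n_seawater_samples Sample counts per type.
#' @param sites Site labels (seawater samples are assigned one per site,
#'   recycled; coral samples round-robin).
#' @param wq_categories Named map site -> water-quality category.
#' @param n_strain_groups Number of planted strain pairs sharing
#'   ANI >= 99 across different sites.
#' @param effect_enriched_features Per-namespace list with `n_features`,
#'   `n_enriched`, `log_odds` controlling planted presence/absence
#'   enrichment.
#' @param n_clusters Number of orthologous clusters (copy-count matrix).
#' @param n_modules Number of synthetic KEGG-style module definitions over
#'   the KO universe.
#' @param env_gradient_strength Target correlation between the planted
#'   driver variable and the latent compositional gradient, in \[0, 1).
#' @param noise_sd Dispersion (sd of log coverage) of the coverage model;
#'   at 0 the planted specificity labels are recovered exactly.
#' @param kappa Saturation constant of the detection model
#'   `covered_fraction = 1 - exp(-mean_coverage / kappa)`.
#' @param seed Integer seed; the full study is bit-reproducible.
#' @return A list of class `magniche_design`.
#' @export
simulation_design <- function(n_host_specific = 40,
                              n_seawater_specific = 30,
                              n_coral_samples = 22,
                              n_seawater_samples = 6,
                              sites = paste0("Site", LETTERS[1:6]),
                              wq_categories = c(
                                SiteA = "NorthMarine", SiteB = "NorthMarine",
                                SiteC = "NorthPlume", SiteD = "SouthMarine",
                                SiteE = "SouthPlume", SiteF = "Coastal"
                              ),
                              n_strain_groups = 4,
                              effect_enriched_features = list(
                                KO = list(n_features = 300, n_enriched = 40, log_odds = 2.5),
                                Pfam = list(n_features = 300, n_enriched = 40, log_odds = 2.5),
                                CAZy = list(n_features = 60, n_enriched = 8, log_odds = 2.5)
                              ),
                              n_clusters = 150,
                              n_modules = 10,
                              env_gradient_strength = 0.8,
                              noise_sd = 0.7,
                              kappa = 1,
                              seed = 1L) {
  design <- list(
    n_host_specific = as.integer(n_host_specific),
    n_seawater_specific = as.integer(n_seawater_specific),
    n_coral_samples = as.integer(n_coral_samples),
    n_seawater_samples = as.integer(n_seawater_samples),
    sites = sites,
    wq_categories = wq_categories,
    n_strain_groups = as.integer(n_strain_groups),
    effect_enriched_features = effect_enriched_features,
    n_clusters = as.integer(n_clusters),
    n_modules = as.integer(n_modules),
    env_gradient_strength = env_gradient_strength,
    noise_sd = noise_sd,
    kappa = kappa,
    seed = as.integer(seed)
  )
  if (design$n_host_specific + design$n_seawater_specific < 1) {
    abort("design must generate at least one MAG")
  }
  if (design$n_host_specific < 1 || design$n_seawater_specific < 1 ||
      design$n_coral_samples < 1 || design$n_seawater_samples < 1) {
    abort("all design counts must be >= 1")
  }
  if (env_gradient_strength < 0 || env_gradient_strength >= 1) {
    abort("env_gradient_strength must lie in [0, 1)")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (!all(sites %in% names(wq_categories))) {
    abort("every site needs a wq_categories entry")
  }
  for (ns in names(effect_enriched_features)) {
    e <- effect_enriched_features[[ns]]
    if (e$n_enriched > e$n_features) {
      abort(paste0("namespace ", ns, ": more enriched features than total"))
    }
  }
  structure(design, class = "magniche_design")
}

# quality-metric draws: Beta on [75,100] matching the target mean/sd exactly,
# Gamma matched by moments for contamination
draw_completeness <- function(n, mean = 91.2, sd = 7.12) {
  m <- (mean - 75) / 25
  s <- sd / 25
  common <- m * (1 - m) / s^2 - 1
  75 + 25 * rbeta(n, m * common, (1 - m) * common)
}

draw_contamination <- function(n, mean = 2.03, sd = 2.16) {
  rgamma(n, shape = (mean / sd)^2, rate = mean / sd^2)
}

#' Generate the synthetic MAG catalog, ground truth and ANI matrix
#'
#' Host-specific MAGs are drawn from a larger-genome, lower-GC, lower
#' coding-density regime than seawater-specific MAGs; quality metrics match
#' the design means in expectation. Planted strain pairs (members placed at
#' different sites) share ANI >= 99 while all other pairs lie well below.
#'
#' @param design A [simulation_design()].
#' @return List with `mags` (tibble), `ground_truth` (tibble: `mag_id`,
#'   `true_label`, `strain_group`), `ani` (matrix).
#' @export
simulate_mag_catalog <- function(design = simulation_design()) {
  stopifnot(inherits(design, "magniche_design"))
  set.seed(design$seed)
  nh <- design$n_host_specific
  ns <- design$n_seawater_specific
  n <- nh + ns
  label <- rep(c("host_specific", "seawater_specific"), c(nh, ns))
  mag_id <- sprintf("MAG%03d", seq_len(n))
  site <- sample(design$sites, n, replace = TRUE)

  genome_size <- round(ifelse(label == "host_specific",
                              rlnorm(n, log(4.0e6), 0.35),
                              rlnorm(n, log(2.5e6), 0.30)))
  gc <- pmin(75, pmax(25, ifelse(label == "host_specific",
                                 rnorm(n, 42, 5), rnorm(n, 52, 5))))
  coding_density <- pmin(98, pmax(75, ifelse(label == "host_specific",
                                             rnorm(n, 87.5, 1.5),
                                             rnorm(n, 90.5, 1.2))))
  n_genes <- pmax(100L, round(genome_size / 1000 * rnorm(n, 1, 0.05)))
  phyla <- c("Pseudomonadota", "Bacteroidota", "Cyanobacteriota",
             "Desulfobacterota", "Verrucomicrobiota", "Actinobacteriota")
  taxonomy <- paste0("d__Bacteria;p__", sample(phyla, n, replace = TRUE),
                     ";c__;o__;f__;g__;s__")

  mags <- tibble(
    mag_id = mag_id, site = site,
    completeness = draw_completeness(n),
    contamination = draw_contamination(n),
    genome_size = genome_size, gc = gc, n_genes = n_genes,
    coding_density = coding_density, taxonomy = taxonomy
  )

  # ANI: background well below threshold, planted pairs at/above it
  ani <- matrix(runif(n * n, 75, 85), n, n, dimnames = list(mag_id, mag_id))
  ani[lower.tri(ani)] <- t(ani)[lower.tri(ani)]
  diag(ani) <- 100
  strain_group <- rep(NA_character_, n)
  n_pairs <- min(design$n_strain_groups, floor(n / 2))
  if (n_pairs > 0) {
    members <- matrix(seq_len(2 * n_pairs), nrow = 2)
    for (g in seq_len(n_pairs)) {
      i <- members[1, g]; j <- members[2, g]
      ani[i, j] <- ani[j, i] <- runif(1, 99, 100)
      strain_group[c(i, j)] <- paste0("strain", g)
      # strain pairs come from different sites so per-site dereplication
      # keeps both and overall dereplication collapses them
      if (mags$site[i] == mags$site[j]) {
        mags$site[j] <- sample(setdiff(design$sites, mags$site[i]), 1)
      }
    }
  }

  list(
    mags = mags,
    ground_truth = tibble(mag_id = mag_id, true_label = label,
                          strain_group = strain_group),
    ani = ani
  )
}

#' Generate synthetic samples and coverage
#'
#' Log-normal coverage with MAG-level means and a latent compositional
#' gradient across coral samples that is correlated with the planted driver
#' variable (`temperature`) at the designed strength. At `noise_sd = 0`
#' every planted host-specific MAG is absent from seawater (all three
#' specificity criteria hold) and every planted seawater-specific MAG is
#' detected in all seawater samples (prevalence 1, so it fails the
#' prevalence criterion); label recovery is exact. At positive noise, host
#' MAGs spill into seawater samples at low level with small probability,
#' mimicking horizontal acquisition from the water column. Covered fraction
#' follows the saturating detection model `1 - exp(-coverage / kappa)`.
#' Environmental variables are site-level means plus within-site noise and
#' include two deliberately collinear pairs (NO3 ~ NH4, TDN ~ POC) to
#' exercise collinearity pruning.
#'
#' @param catalog Result of [simulate_mag_catalog()].
#' @param design The same [simulation_design()].
#' @return List with `samples` (tibble incl. environmental columns) and
#'   `coverage` (long tibble, one entry per MAG x sample pair).
#' @export
simulate_coverage <- function(catalog, design = simulation_design()) {
  stopifnot(inherits(design, "magniche_design"))
  set.seed(design$seed + 1L)
  truth <- catalog$ground_truth
  n_mag <- nrow(truth)
  nc <- design$n_coral_samples
  nw <- design$n_seawater_samples
  sites <- design$sites

  coral_sites <- rep(sites, length.out = nc)
  sea_sites <- rep(sites, length.out = nw)
  samples <- tibble(
    sample_id = c(sprintf("C%02d", seq_len(nc)), sprintf("W%02d", seq_len(nw))),
    sample_type = rep(c("coral", "seawater"), c(nc, nw)),
    site = c(coral_sites, sea_sites),
    wq_category = c(unname(design$wq_categories[coral_sites]),
                    rep(NA_character_, nw)),
    library_size_gbp = c(exp(runif(nc, log(2), log(100))),
                         exp(runif(nw, log(10), log(30))))
  )

  # site gradient scores and the planted driver variable
  g_site <- setNames(seq(-1, 1, length.out = length(sites)), sites)
  rho <- design$env_gradient_strength
  g_coral <- g_site[coral_sites]
  g_std <- if (sd(g_coral) > 0) (g_coral - mean(g_coral)) / sd(g_coral) else g_coral * 0
  z_coral <- rho * g_std + sqrt(1 - rho^2) * rnorm(nc)

  env_var <- function(site_sd = 1, within_sd = 1) {
    mu <- setNames(rnorm(length(sites), 0, site_sd), sites)
    mu[samples$site] + rnorm(nrow(samples), 0, within_sd)
  }
  samples$temperature <- g_site[samples$site] + rnorm(nrow(samples), 0, 0.1)
  samples$salinity <- env_var()
  samples$NH4 <- env_var()
  samples$NO3 <- samples$NH4 + rnorm(nrow(samples), 0, 0.2)   # collinear pair 1
  samples$Si <- env_var()
  samples$POC <- env_var()
  samples$TDN <- samples$POC + rnorm(nrow(samples), 0, 0.25)  # collinear pair 2
  samples$chla <- env_var()

  host <- truth$true_label == "host_specific"
  mu_mag <- rnorm(n_mag, log(5), 1)
  loading <- rnorm(n_mag)
  gamma <- 2
  noise <- design$noise_sd
  spill_p <- 0.15 * min(1, noise / 0.7)

  cov <- matrix(0, n_mag, nrow(samples),
                dimnames = list(truth$mag_id, samples$sample_id))
  coral_idx <- which(samples$sample_type == "coral")
  sea_idx <- which(samples$sample_type == "seawater")
  for (m in seq_len(n_mag)) {
    if (host[m]) {
      cov[m, coral_idx] <- exp(mu_mag[m] + gamma * loading[m] * z_coral +
                                 rnorm(nc, 0, noise))
      spill <- rbinom(nw, 1, spill_p) == 1
      cov[m, sea_idx[spill]] <- rlnorm(sum(spill), log(0.08), max(noise, 1e-8))
    } else {
      cov[m, sea_idx] <- exp(mu_mag[m] + rnorm(nw, 0, noise))
      in_coral <- rbinom(nc, 1, 0.5) == 1
      cov[m, coral_idx[in_coral]] <- exp(log(0.5) + rnorm(sum(in_coral), 0, noise))
    }
  }

  coverage <- tibble(
    mag_id = rep(truth$mag_id, times = nrow(samples)),
    sample_id = rep(samples$sample_id, each = n_mag),
    mean_coverage = as.vector(cov),
    covered_fraction = 1 - exp(-as.vector(cov) / design$kappa)
  )
  list(samples = samples, coverage = coverage)
}

#' Generate synthetic annotations, clusters and module definitions
#'
#' Per namespace, background features share one presence probability across
#' both specificity groups while planted enriched features differ by the
#' designed log-odds (three quarters enriched toward host-specific MAGs,
#' one quarter toward seawater-specific, echoing the asymmetry typical of
#' host-associated genomes). Counts are presence times (1 + Poisson).
#' Cluster copy numbers are sparse Poisson counts. Module definitions are
#' drawn from grammar templates over the KO universe (serial steps,
#' alternatives, complexes, one optional component).
#'
#' @param catalog Result of [simulate_mag_catalog()].
#' @param design The same [simulation_design()].
#' @return List with `annotations` (named list of wide tibbles per
#'   namespace), `clusters` (wide tibble), `modules` (tibble), and
#'   `truth_features` (tibble: namespace, feature, direction).
#' @export
simulate_annotations <- function(catalog, design = simulation_design()) {
  stopifnot(inherits(design, "magniche_design"))
  set.seed(design$seed + 2L)
  truth <- catalog$ground_truth
  host <- truth$true_label == "host_specific"
  n_mag <- nrow(truth)

  feature_ids <- function(ns, k) {
    switch(ns,
      KO = sprintf("K%05d", seq_len(k)),
      Pfam = sprintf("PF%05d", seq_len(k)),
      CAZy = sprintf("GH%03d", seq_len(k)),
      sprintf("%s_%d", ns, seq_len(k))
    )
  }

  truth_rows <- list()
  annotations <- list()
  for (ns in names(design$effect_enriched_features)) {
    e <- design$effect_enriched_features[[ns]]
    ids <- feature_ids(ns, e$n_features)
    p0 <- runif(e$n_features, 0.05, 0.9)
    enriched_idx <- sample.int(e$n_features, e$n_enriched)
    dir_host <- rbinom(e$n_enriched, 1, 0.75) == 1
    p_host <- p0
    p_sea <- p0
    lo <- e$log_odds
    shift <- ifelse(dir_host, lo / 2, -lo / 2)
    p_host[enriched_idx] <- stats::plogis(stats::qlogis(p0[enriched_idx]) + shift)
    p_sea[enriched_idx] <- stats::plogis(stats::qlogis(p0[enriched_idx]) - shift)

    pres <- matrix(0L, n_mag, e$n_features)
    pres[host, ] <- rbinom(sum(host) * e$n_features, 1,
                           rep(p_host, each = sum(host)))
    pres[!host, ] <- rbinom(sum(!host) * e$n_features, 1,
                            rep(p_sea, each = sum(!host)))
    counts <- pres * (1L + matrix(rpois(n_mag * e$n_features, 1),
                                  n_mag, e$n_features))
    tbl <- as_tibble(counts, .name_repair = "minimal")
    names(tbl) <- ids
    tbl <- dplyr::bind_cols(tibble(mag_id = truth$mag_id), tbl)
    attr(tbl, "namespace") <- ns
    annotations[[ns]] <- tbl
    if (lo != 0 && e$n_enriched > 0) {
      truth_rows[[ns]] <- tibble(
        namespace = ns, feature = ids[enriched_idx],
        direction = ifelse(dir_host, "host_specific", "seawater_specific")
      )
    }
  }

  k_cl <- design$n_clusters
  carry <- matrix(rbinom(n_mag * k_cl, 1, 0.3), n_mag, k_cl)
  copies <- carry * (1L + matrix(rpois(n_mag * k_cl, 0.7), n_mag, k_cl))
  clusters <- as_tibble(copies, .name_repair = "minimal")
  names(clusters) <- sprintf("cluster_%03d", seq_len(k_cl))
  clusters <- dplyr::bind_cols(tibble(mag_id = truth$mag_id), clusters)
  attr(clusters, "namespace") <- "cluster"

  ko_universe <- names(annotations$KO)[-1] %||% sprintf("K%05d", 1:50)
  modules <- purrr::map_dfr(seq_len(design$n_modules), function(i) {
    kos <- sample(ko_universe, 5)
    def <- switch(1 + (i %% 5),
      paste(kos[1:3], collapse = " "),
      paste0(kos[1], " ", kos[2], ",", kos[3], " ", kos[4]),
      paste0("(", kos[1], "+", kos[2], ") ", kos[3]),
      paste0(kos[1], " (", kos[2], " ", kos[3], ") ", kos[4]),
      paste0(kos[1], "+", kos[2], "-", kos[3], " ", kos[4], ",", kos[5])
    )
    tibble(module_id = sprintf("M%05d", i),
           name = paste("synthetic module", i),
           definition = def)
  })

  list(annotations = annotations, clusters = clusters, modules = modules,
       truth_features = dplyr::bind_rows(truth_rows))
}

#' Generate a complete synthetic study
#'
#' Runs [simulate_mag_catalog()], [simulate_coverage()] and
#' [simulate_annotations()] under one seed and assembles the result in the
#' layout consumed by [run_pipeline()] / [write_study()].
#'
#' @param design A [simulation_design()].
#' @return A list of class `magniche_study` with elements `mags`,
#'   `samples`, `coverage`, `ani`, `annotations`, `clusters`, `modules`,
#'   `ground_truth`, `truth_features`, `driver_variable`, `design`.
#' @export
simulate_study <- function(design = simulation_design()) {
  cat_ <- simulate_mag_catalog(design)
  cov_ <- simulate_coverage(cat_, design)
  ann_ <- simulate_annotations(cat_, design)
  structure(list(
    mags = cat_$mags,
    samples = cov_$samples,
    coverage = cov_$coverage,
    ani = cat_$ani,
    annotations = ann_$annotations,
    clusters = ann_$clusters,
    modules = ann_$modules,
    ground_truth = cat_$ground_truth,
    truth_features = ann_$truth_features,
    driver_variable = "temperature",
    design = design
  ), class = "magniche_study")
}
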