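# Tabular interchange: UTF-8 TSV, one header row, literal "NA" for missing.

mag_required_cols <- c("mag_id", "site", "completeness", "contamination",
                       "genome_size", "gc", "n_genes", "coding_density",
                       "taxonomy")
sample_required_cols <- c("sample_id", "sample_type", "site", "wq_category",
                          "library_size_gbp")
coverage_required_cols <- c("mag_id", "sample_id", "mean_coverage",
                            "covered_fraction")

read_tsv_strict <- function(path, required, numeric_cols, key = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = "NA")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s) in ", basename(path), ": ",
                 paste(missing, collapse = ", ")))
  }
  for (col in intersect(numeric_cols, names(tbl))) {
    if (!is.numeric(tbl[[col]])) {
      parsed <- suppressWarnings(as.numeric(tbl[[col]]))
      bad <- which(!is.na(tbl[[col]]) & is.na(parsed))
      if (length(bad) > 0) {
        abort(paste0("unparseable numeric in column '", col, "' of ",
                     basename(path), " at data row(s) ",
                     paste(head(bad, 5), collapse = ", ")))
      }
      tbl[[col]] <- parsed
    }
  }
  if (!is.null(key)) {
    keys <- do.call(paste, c(tbl[key], sep = "\r"))
    if (anyDuplicated(keys)) {
      abort(paste0("duplicate ", paste(key, collapse = "+"), " in ",
                   basename(path)))
    }
  }
  tbl
}

validate_mags <- function(mags) {
  stopifnot(is.data.frame(mags))
  missing <- setdiff(mag_required_cols, names(mags))
  if (length(missing) > 0) {
    abort(paste0("MAG table missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(mags$mag_id)) abort("duplicate mag_id in MAG table")
  if (any(mags$completeness < 0 | mags$completeness > 100)) {
    abort("completeness must lie in [0, 100]")
  }
  if (any(mags$contamination < 0)) abort("contamination must be >= 0")
  if (any(mags$genome_size <= 0)) abort("genome_size must be > 0")
  invisible(mags)
}

validate_samples <- function(samples) {
  missing <- setdiff(sample_required_cols, names(samples))
  if (length(missing) > 0) {
    abort(paste0("sample table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id")
  if (!all(samples$sample_type %in% c("coral", "seawater"))) {
    abort("sample_type must be 'coral' or 'seawater'")
  }
  if (any(samples$library_size_gbp <= 0)) abort("library_size_gbp must be > 0")
  invisible(samples)
}

validate_coverage <- function(coverage) {
  missing <- setdiff(coverage_required_cols, names(coverage))
  if (length(missing) > 0) {
    abort(paste0("coverage table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(paste(coverage$mag_id, coverage$sample_id, sep = "\r"))) {
    abort("duplicate (mag_id, sample_id) pair in coverage table")
  }
  if (any(coverage$mean_coverage < 0)) abort("mean_coverage must be >= 0")
  if (any(coverage$covered_fraction < 0 | coverage$covered_fraction > 1)) {
    abort("covered_fraction must lie in [0, 1]")
  }
  bad <- coverage$mean_coverage == 0 & coverage$covered_fraction > 0
  if (any(bad)) {
    abort(paste0(sum(bad), " coverage entr",
                 if (sum(bad) == 1) "y has" else "ies have",
                 " mean_coverage = 0 but covered_fraction > 0"))
  }
  invisible(coverage)
}

#' Read a MAG quality/feature table
#'
#' Required columns: `mag_id`, `site`, `completeness`, `contamination`,
#' `genome_size`, `gc`, `n_genes`, `coding_density`, `taxonomy`
#' (semicolon-delimited rank string). Extra columns are preserved.
#'
#' @param path Path to a tab-separated file with one header row.
#' @return A tibble of validated MAG records.
#' @export
read_mag_table <- function(path) {
  tbl <- read_tsv_strict(path, mag_required_cols,
                         c("completeness", "contamination", "genome_size",
                           "gc", "n_genes", "coding_density"),
                         key = "mag_id")
  validate_mags(tbl)
  tbl
}

#' Read a sample metadata table
#'
#' Required columns: `sample_id`, `sample_type` (coral/seawater), `site`,
#' `wq_category`, `library_size_gbp`. Any further numeric columns are
#' treated as environmental variables; missing values are literal `NA` and
#' excluded pairwise downstream.
#'
#' @inheritParams read_mag_table
#' @return A tibble of validated sample records.
#' @export
read_sample_table <- function(path) {
  tbl <- read_tsv_strict(path, sample_required_cols, "library_size_gbp",
                         key = "sample_id")
  validate_samples(tbl)
  tbl
}

#' Read a long-format coverage table
#'
#' Required columns: `mag_id`, `sample_id`, `mean_coverage`,
#' `covered_fraction`. An entry with zero mean coverage must have zero
#' covered fraction.
#'
#' @inheritParams read_mag_table
#' @return A tibble of validated coverage entries.
#' @export
read_coverage_table <- function(path) {
  tbl <- read_tsv_strict(path, coverage_required_cols,
                         c("mean_coverage", "covered_fraction"),
                         key = c("mag_id", "sample_id"))
  validate_coverage(tbl)
  tbl
}

#' Read a wide MAG-by-feature annotation count matrix
#'
#' First column `mag_id`, then one non-negative integer count column per
#' feature identifier (KO, Pfam, CAZy family, or orthologous cluster).
#'
#' @inheritParams read_mag_table
#' @param namespace Annotation namespace tag, one of `"KO"`, `"Pfam"`,
#'   `"CAZy"`, `"cluster"`.
#' @return A tibble with attribute `namespace`.
#' @export
read_annotation_matrix <- function(path,
                                   namespace = c("KO", "Pfam", "CAZy", "cluster")) {
  namespace <- match.arg(namespace)
  tbl <- read_tsv_strict(path, "mag_id", character(), key = "mag_id")
  feat <- setdiff(names(tbl), "mag_id")
  if (anyDuplicated(feat)) abort("duplicate feature ids in annotation matrix")
  counts <- as.matrix(tbl[feat])
  if (!is.numeric(counts) || any(counts < 0) || any(counts != floor(counts))) {
    abort("annotation counts must be non-negative integers")
  }
  attr(tbl, "namespace") <- namespace
  tbl
}

#' Read a square ANI matrix
#'
#' Tab-separated square matrix with MAG ids as both row and column labels
#' (first column holds the row labels). Values are ANI percentages; the
#' diagonal must be 100. Mild asymmetries are tolerated and resolved by
#' max-symmetrization in [dereplicate_mags()].
#'
#' @inheritParams read_mag_table
#' @return A numeric matrix with dimnames.
#' @export
read_ani_matrix <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(tbl[[1]])
  m <- as.matrix(tbl[-1])
  rownames(m) <- ids
  if (!identical(sort(ids), sort(colnames(m)))) {
    abort("ANI matrix row and column labels differ")
  }
  m <- m[, ids, drop = FALSE]
  if (!isTRUE(all.equal(unname(diag(m)), rep(100, nrow(m)), tolerance = 1e-8))) {
    abort("ANI matrix diagonal must be 100")
  }
  m
}

#' Read KEGG-module definitions
#'
#' Columns: `module_id`, `name`, `definition` (expression over KO
#' identifiers; see [parse_module_definition()]).
#'
#' @inheritParams read_mag_table
#' @return A tibble of module definitions.
#' @export
read_module_definitions <- function(path) {
  read_tsv_strict(path, c("module_id", "name", "definition"), character(),
                  key = "module_id")
}

#' Write a result table as TSV
#'
#' Deterministic column order (as given), literal `NA` for missing values,
#' full float precision so that a read-back reproduces values to better
#' than 1e-9.
#'
#' @param x A data frame.
#' @param path Output path; the parent directory must exist.
#' @return `x`, invisibly.
#' @export
write_result_table <- function(x, path) {
  if (!dir.exists(dirname(path))) {
    abort(paste0("parent directory does not exist: ", dirname(path)))
  }
  readr::write_tsv(as_tibble(x), path, na = "NA", progress = FALSE)
  invisible(x)
}

#' Read back a result table written by [write_result_table()]
#'
#' @param path Path to the TSV file.
#' @return A tibble.
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, na = "NA")
}

#' Write a JSON run manifest
#'
#' Records the configuration, seed and MD5 checksums of the input files so
#' permutation results can be reproduced exactly.
#'
#' @param path Output path for the manifest JSON.
#' @param config A [run_config()] object.
#' @param inputs Character vector of input file paths to checksum.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, config, inputs = character()) {
  sums <- if (length(inputs) > 0) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    package = "magniche",
    seed = config$seed,
    config = unclass(config),
    input_md5 = sums
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Read a full study directory
#'
#' Expects the file layout produced by [write_study()]: `mags.tsv`,
#' `samples.tsv`, `coverage.tsv`, `ani.tsv`, `modules.tsv`, one
#' `annotations_<namespace>.tsv` per namespace, and optionally
#' `ground_truth.tsv`.
#'
#' @param dir Directory containing the study TSV files.
#' @return A named list of class `magniche_study`.
#' @export
read_study <- function(dir) {
  p <- function(f) file.path(dir, f)
  ann <- list()
  for (ns in c("KO", "Pfam", "CAZy")) {
    f <- p(paste0("annotations_", ns, ".tsv"))
    if (file.exists(f)) ann[[ns]] <- read_annotation_matrix(f, ns)
  }
  study <- list(
    mags = read_mag_table(p("mags.tsv")),
    samples = read_sample_table(p("samples.tsv")),
    coverage = read_coverage_table(p("coverage.tsv")),
    ani = read_ani_matrix(p("ani.tsv")),
    annotations = ann,
    clusters = if (file.exists(p("annotations_cluster.tsv"))) {
      read_annotation_matrix(p("annotations_cluster.tsv"), "cluster")
    },
    modules = if (file.exists(p("modules.tsv"))) {
      read_module_definitions(p("modules.tsv"))
    },
    ground_truth = if (file.exists(p("ground_truth.tsv"))) {
      read_result_table(p("ground_truth.tsv"))
    },
    truth_features = if (file.exists(p("truth_features.tsv"))) {
      read_result_table(p("truth_features.tsv"))
    }
  )
  structure(study, class = "magniche_study")
}

#' Write a full study to a directory
#'
#' Inverse of [read_study()]. Creates the directory if needed.
#'
#' @param study A `magniche_study` list (e.g. from [simulate_study()]).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_result_table(study$mags, p("mags.tsv"))
  write_result_table(study$samples, p("samples.tsv"))
  write_result_table(study$coverage, p("coverage.tsv"))
  ani <- as_tibble(study$ani, rownames = "mag_id")
  write_result_table(ani, p("ani.tsv"))
  for (ns in names(study$annotations)) {
    write_result_table(study$annotations[[ns]],
                       p(paste0("annotations_", ns, ".tsv")))
  }
  if (!is.null(study$clusters)) {
    write_result_table(study$clusters, p("annotations_cluster.tsv"))
  }
  if (!is.null(study$modules)) {
    write_result_table(study$modules, p("modules.tsv"))
  }
  if (!is.null(study$ground_truth)) {
    write_result_table(study$ground_truth, p("ground_truth.tsv"))
  }
  if (!is.null(study$truth_features)) {
    write_result_table(study$truth_features, p("truth_features.tsv"))
  }
  invisible(dir)
}
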