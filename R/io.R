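#' Marker map from "scaffold:pos" marker ids
#'
#' @param ids Character vector of marker ids of the form `"scaffold:pos"`
#'   (1-based positions, the VCF convention).
#' @return Tibble with `marker`, `scaffold`, `pos`.
#' @export
marker_map_from_ids <- function(ids) {
  has <- grepl(":", ids, fixed = TRUE)
  tibble::tibble(
    marker = ids,
    scaffold = ifelse(has, sub(":[^:]*$", "", ids), ids),
    pos = ifelse(has, suppressWarnings(as.integer(sub(".*:", "", ids))),
                 NA_integer_)
  )
}

.matrix_to_tbl <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(m) %||% paste0("S", seq_len(nrow(m)))),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
}

.read_matrix_tsv <- function(path, col_type) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = col_type
  ), na = "NA", progress = FALSE)
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    stop("malformed table ", path, ": row ", pr$row[1], ", column ",
         pr$col[1], " (", pr$expected[1], ")")
  }
  if (!"sample_id" %in% names(df)) {
    stop("first column of ", path, " must be `sample_id`")
  }
  ids <- df$sample_id
  if (anyDuplicated(ids)) {
    stop("duplicate sample id: ", ids[duplicated(ids)][1])
  }
  mk <- setdiff(names(df), "sample_id")
  if (anyDuplicated(mk)) {
    stop("duplicate marker id: ", mk[duplicated(mk)][1])
  }
  m <- as.matrix(df[, mk])
  rownames(m) <- ids
  m
}

#' Read / write allele-frequency matrices as TSV
#'
#' Tab-separated text with a header row of marker ids (`"scaffold:pos"`,
#' 1-based) and sample ids in the first (`sample_id`) column; missing entries
#' are `NA`. Values are validated into \[0, 1\] and duplicated ids rejected;
#' the writer is deterministic and round-trips bit-identically.
#'
#' @param path File path.
#' @return `read_frequency_matrix()`: samples x markers numeric matrix with
#'   dimnames. `write_frequency_matrix()`: `path`, invisibly.
#' @export
read_frequency_matrix <- function(path) {
  m <- .read_matrix_tsv(path, readr::col_double())
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("frequency out of [0, 1] at (", rownames(m)[bad[1, 1]], ", ",
         colnames(m)[bad[1, 2]], "): ", m[bad[1, , drop = FALSE]])
  }
  m
}

#' @param freq Samples x markers matrix with dimnames.
#' @rdname read_frequency_matrix
#' @export
write_frequency_matrix <- function(freq, path) {
  stopifnot(is.matrix(freq))
  readr::write_tsv(.matrix_to_tbl(freq), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read / write depth matrices as TSV
#'
#' Same layout as [read_frequency_matrix()] with non-negative integer
#' entries; depth 0 marks a missing frequency.
#'
#' @param path File path.
#' @export
read_depth_matrix <- function(path) {
  m <- .read_matrix_tsv(path, readr::col_integer())
  if (any(m < 0, na.rm = TRUE)) stop("depths must be non-negative")
  m[is.na(m)] <- 0L
  m
}

#' @param depth Samples x markers integer matrix.
#' @rdname read_depth_matrix
#' @export
write_depth_matrix <- function(depth, path) {
  stopifnot(is.matrix(depth))
  readr::write_tsv(.matrix_to_tbl(depth), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Write a GRM and its per-sample diagnostics
#'
#' The GRM is written as a square TSV with sample ids as both header and
#' first column; the optional sidecar records the per-sample diagonal and,
#' for corrected GRMs, the uncorrected diagonal and inflation fraction.
#'
#' @param grm A [pool_grm][compute_grm] object or square matrix.
#' @param path Output TSV path.
#' @param sidecar Optional path for the per-sample diagnostics TSV.
#' @export
write_grm <- function(grm, path, sidecar = NULL) {
  m <- if (inherits(grm, "pool_grm")) grm$matrix else grm
  readr::write_tsv(.matrix_to_tbl(m), path, na = "NA", progress = FALSE)
  if (!is.null(sidecar) && inherits(grm, "pool_grm")) {
    readr::write_tsv(grm_diagonal(grm), sidecar, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  m <- .read_matrix_tsv(path, readr::col_double())
  if (nrow(m) != ncol(m)) stop("GRM must be square")
  m
}

#' Read / write phenotype tables
#'
#' TSV with columns `sample_id`, `trait`, `value`, `trial`, `location`,
#' `year`, `replicate`.
#'
#' @param path File path.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), trait = readr::col_character(),
    value = readr::col_double(), trial = readr::col_character(),
    location = readr::col_character(), year = readr::col_integer(),
    replicate = readr::col_integer()
  ), progress = FALSE)
  .check_phenos(df)
}

#' @param phenos Phenotype tibble.
#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(phenos, path) {
  readr::write_tsv(phenos, path, progress = FALSE)
  invisible(path)
}

#' Read pool allele frequencies from a VCF with allelic depths
#'
#' Extracts per-sample allele-frequency estimates and coverage depths from
#' the `AD` FORMAT field of a VCF: `p_hat = alt / (ref + alt)` and
#' `S_T = ref + alt`, missing where no reads were observed. Only biallelic
#' SNPs are used; other sites are skipped and counted. Contigs become
#' scaffolds in the marker ids (`CHROM:POS`).
#'
#' @param path Path to a VCF (4.x, plain or bgzipped).
#' @return List with `freq` and `depth` (samples x markers matrices) and
#'   `n_skipped` (non-biallelic site count).
#' @export
read_vcf_pool <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!any(grepl("AD", v@gt[, 1]))) {
    stop("VCF has no AD (allelic depth) FORMAT field")
  }
  bi <- vcfR::is.biallelic(v)
  n_skipped <- sum(!bi)
  v <- v[bi, ]
  fix <- vcfR::getFIX(v)
  ad <- vcfR::extract.gt(v, element = "AD")
  ref <- suppressWarnings(apply(ad, 2, function(x) as.numeric(sub(",.*", "", x))))
  alt <- suppressWarnings(apply(ad, 2, function(x) as.numeric(sub(".*,", "", x))))
  if (!is.matrix(ref)) {
    ref <- matrix(ref, nrow = nrow(ad))
    alt <- matrix(alt, nrow = nrow(ad))
  }
  st <- ref + alt
  st[is.na(st)] <- 0
  p <- ifelse(st > 0, alt / st, NA_real_)
  mk <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  freq <- t(p)
  depth <- t(st)
  dimnames(freq) <- list(colnames(ad), mk)
  dimnames(depth) <- list(colnames(ad), mk)
  storage.mode(depth) <- "integer"
  list(freq = freq, depth = depth, n_skipped = n_skipped)
}

#' Filter markers on missingness and minor allele frequency
#'
#' Removes markers with a missing fraction above `max_missing`, then (on the
#' survivors) markers whose folded mean frequency `min(pbar, 1 - pbar)` is
#' below `min_maf`. For continuous pool frequencies the folded column mean
#' is the natural MAF analogue — it reduces to the standard minor allele
#' frequency for individual genotype dosages.
#'
#' @param freq Samples x markers frequency matrix (NA = missing).
#' @param max_missing Maximum tolerated missing fraction (default 0.5).
#' @param min_maf Minimum folded mean frequency (default 0.01).
#' @return List with `freq` (retained columns) and `report`, a one-row
#'   tibble: `n_input`, `n_removed_missingness`, `n_removed_maf`,
#'   `n_retained`.
#' @export
filter_markers <- function(freq, max_missing = 0.5, min_maf = 0.01) {
  stopifnot(is.matrix(freq))
  miss <- colMeans(is.na(freq))
  keep1 <- miss <= max_missing
  pbar <- colMeans(freq[, keep1, drop = FALSE], na.rm = TRUE)
  keep2 <- pmin(pbar, 1 - pbar) >= min_maf
  report <- tibble::tibble(
    n_input = ncol(freq),
    n_removed_missingness = sum(!keep1),
    n_removed_maf = sum(!keep2),
    n_retained = sum(keep2)
  )
  list(freq = freq[, which(keep1)[keep2], drop = FALSE], report = report)
}

#' Resolved run configuration
#'
#' Collects every tunable parameter with its default, applies overrides, and
#' serialises losslessly to JSON so each run can write its resolved
#' configuration next to its outputs.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    k = 6, n_trees = 100, max_iter = 10, reference_ploidy = 4,
    mask_fraction = 0.001, n_replicates = 10, scaffold_fraction = 0.1,
    max_missing = 0.5, min_maf = 0.01, ridge = 1e-6, seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @param config A `run_config` object.
#' @param path JSON file path.
#' @rdname run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}
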