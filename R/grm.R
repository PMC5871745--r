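#' Centre an allele-frequency matrix by marker means
#'
#' Subtracts the per-marker mean frequency from every column, the first step
#' of the VanRaden-style allele-frequency GRM. Imputation must have removed
#' all missing entries first.
#'
#' @param freq Samples x markers matrix of frequencies in \[0, 1\], no
#'   missing entries.
#' @return A list with `M` (centred matrix) and `col_means` (per-marker mean
#'   frequencies, reused for the scaling constant).
#' @export
center_frequencies <- function(freq) {
  stopifnot(is.matrix(freq))
  if (anyNA(freq)) {
    stop("frequency matrix has missing entries; impute first ",
         "(impute_mean(), impute_knn() or impute_rf())")
  }
  if (any(freq < 0 | freq > 1)) stop("frequencies must lie in [0, 1]")
  pbar <- colMeans(freq)
  list(M = sweep(freq, 2L, pbar), col_means = pbar)
}

#' Expected SNP variance scaling constant
#'
#' The GRM denominator: the summed expected per-marker variance of genotypes
#' of ploidy `n` at the observed mean frequencies,
#' `sigma2_G = (1/n) * sum_j pbar_j (1 - pbar_j)`. A pool genotype is treated
#' as a polyploid with ploidy equal to the summed parental ploidy, so
#' doubling the ploidy halves the expected variance of its mean frequency.
#'
#' @param col_means Per-marker mean frequencies in \[0, 1\].
#' @param ploidy Assumed ploidy `n >= 1` of the reference material.
#' @return Positive scalar.
#' @export
expected_snp_variance <- function(col_means, ploidy) {
  stopifnot(all(col_means >= 0 & col_means <= 1), ploidy >= 1)
  s <- sum(col_means * (1 - col_means)) / ploidy
  if (s <= 0) {
    stop("all markers are fixed (scaling constant would be 0); ",
         "filter monomorphic markers first")
  }
  s
}

#' Allele-frequency genomic relationship matrix
#'
#' Computes `G = M M' / sigma2_G` from a complete samples x markers
#' frequency matrix, with the expected-SNP-variance denominator evaluated at
#' the reference ploidy. Under own-ploidy scaling the expected diagonal is
#' `1 + F` (inbreeding coefficient); for a sample of ploidy `n_i` scaled at
#' reference ploidy `n_ref` it is `(n_ref / n_i) * (1 + F)`. When individuals
#' and pools are mixed in one GRM the conventional reference is the F2-family
#' ploidy, `n_ref = 4`.
#'
#' @param freq Complete samples x markers frequency matrix (impute first).
#' @param reference_ploidy Ploidy used in the scaling constant (default 4).
#' @param centering `"joint"` (default) centres all samples by the common
#'   marker means; `"per_material"` centres each material of `meta` by its
#'   own marker means (the scaling constant still uses the joint means).
#' @param meta Sample metadata tibble (needed for per-material centering).
#' @return An object of class `pool_grm`: `matrix` (symmetric relationships),
#'   `reference_ploidy`, `sigma2_g`, `col_means`, `corrected` flag and
#'   (after [correct_diagonal()]) the per-sample inflation bookkeeping.
#' @examples
#' pop <- simulate_breeding_population(n_families = 30, n_markers = 500,
#'                                     seed = 1)
#' g <- compute_grm(pop$f2_freq, reference_ploidy = 4)
#' mean(diag(g$matrix)) # close to 1: no inbreeding effect on pool means
#' @export
compute_grm <- function(freq, reference_ploidy = 4,
                        centering = c("joint", "per_material"), meta = NULL) {
  centering <- match.arg(centering)
  stopifnot(is.matrix(freq), nrow(freq) >= 2)
  cf <- center_frequencies(freq)
  M <- cf$M
  if (centering == "per_material") {
    if (is.null(meta)) stop("per-material centering needs `meta`")
    mat <- meta$material[match(rownames(freq), meta$sample_id)]
    if (anyNA(mat)) stop("samples missing from `meta`")
    for (g in unique(mat)) {
      rows <- which(mat == g)
      M[rows, ] <- sweep(freq[rows, , drop = FALSE], 2L,
                         colMeans(freq[rows, , drop = FALSE]))
    }
  }
  if (sum(cf$col_means > 0 & cf$col_means < 1) < 2) {
    stop("need at least 2 polymorphic markers")
  }
  s2 <- expected_snp_variance(cf$col_means, reference_ploidy)
  G <- tcrossprod(M) / s2
  structure(
    list(matrix = G, reference_ploidy = reference_ploidy, sigma2_g = s2,
         col_means = cf$col_means, corrected = FALSE, omega = NULL,
         db = NULL),
    class = "pool_grm"
  )
}

#' @exportS3Method base::print
print.pool_grm <- function(x, ...) {
  cat("Allele-frequency GRM:", nrow(x$matrix), "samples, reference ploidy",
      x$reference_ploidy, "\n")
  cat("  mean diagonal:", format(mean(diag(x$matrix)), digits = 4),
      if (x$corrected) "(depth-bias corrected)" else "(uncorrected)", "\n")
  invisible(x)
}

#' Analytic expected GRM diagonal
#'
#' Expected mean diagonal for a material of the given ploidy and inbreeding
#' level when the GRM is scaled at `reference_ploidy`:
#' `(reference_ploidy / ploidy) * (1 + inbreeding)`.
#'
#' @param ploidy Assumed ploidy of the material.
#' @param reference_ploidy Scaling ploidy of the GRM (default: own ploidy).
#' @param inbreeding Inbreeding coefficient F (0.25 for single plants drawn
#'   from F2 families; 0 for non-inbred pool means).
#' @return Expected diagonal value.
#' @export
expected_grm_diagonal <- function(ploidy, reference_ploidy = ploidy,
                                  inbreeding = 0) {
  stopifnot(ploidy >= 1, reference_ploidy >= 1)
  reference_ploidy / ploidy * (1 + inbreeding)
}

#' Per-sample binomial inflation fraction
#'
#' The share of a sample's apparent marker variance that is read-sampling
#' noise rather than genetic signal:
#' `omega_i = (n_i - 1) / (mean_depth_i + n_i - 1)`,
#' where `mean_depth_i` averages the sample's coverage over markers with at
#' least one read. It does not depend on allele frequencies, vanishes for
#' haploids and as depth grows, and rises with ploidy.
#'
#' @param meta Tibble with columns `sample_id` and `ploidy`.
#' @param depths Samples x markers integer depth matrix; rows are matched to
#'   `meta$sample_id` by rowname (or taken in order when unnamed).
#' @return Tibble with `sample_id`, `ploidy`, `mean_depth`, `omega`.
#' @export
binomial_inflation <- function(meta, depths) {
  stopifnot(is.matrix(depths), all(c("sample_id", "ploidy") %in% names(meta)))
  if (!is.null(rownames(depths))) {
    idx <- match(meta$sample_id, rownames(depths))
    if (anyNA(idx)) stop("depth matrix is missing samples: ",
                         paste(meta$sample_id[is.na(idx)], collapse = ", "))
    depths <- depths[idx, , drop = FALSE]
  } else if (nrow(depths) != nrow(meta)) {
    stop("unnamed depth matrix must have one row per metadata sample")
  }
  covered <- depths > 0
  n_cov <- rowSums(covered)
  if (any(n_cov == 0)) {
    stop("sample(s) with zero covered markers: ",
         paste(meta$sample_id[n_cov == 0], collapse = ", "))
  }
  mean_depth <- rowSums(depths * covered) / n_cov
  n <- meta$ploidy
  stopifnot(all(n >= 1))
  tibble::tibble(
    sample_id = meta$sample_id,
    ploidy = n,
    mean_depth = mean_depth,
    omega = (n - 1) / (mean_depth + n - 1)
  )
}

#' Per-sample binomial and genomic variance sums
#'
#' The exact per-SNP diagnostics behind the closed-form inflation fraction:
#' for each sample, the expected binomial variance contributed by finite
#' depth, `sigma2_bin = (1 - 1/n) * sum_j p_hat_j (1 - p_hat_j) / S_T_j`, and
#' the observed marker variance, `sigma2_g = (1/n) * sum_j p_hat_j (1 -
#' p_hat_j)`, both summed over markers covered for that sample. Under
#' constant depth `d` their ratio is exactly `(n - 1) / d`, and the plug-in
#' inflation `sigma2_bin / (sigma2_bin + sigma2_g)` reduces to the closed
#' form `(n - 1) / (d + n - 1)`.
#'
#' @inheritParams binomial_inflation
#' @param freq Samples x markers frequency matrix aligned with `depths`
#'   (NA exactly where depth is 0).
#' @return Tibble with `sample_id`, `sigma2_bin`, `sigma2_g`, `n_markers`.
#' @export
binomial_variance_components <- function(freq, depths, meta) {
  stopifnot(is.matrix(freq), all(dim(freq) == dim(depths)))
  if (any(depths == 0 & !is.na(freq))) {
    stop("entries with zero depth must be masked as missing in `freq`")
  }
  idx <- match(meta$sample_id, rownames(freq))
  if (anyNA(idx)) stop("frequency matrix is missing metadata samples")
  out <- lapply(seq_along(idx), function(k) {
    i <- idx[k]
    ok <- !is.na(freq[i, ]) & depths[i, ] > 0
    ph <- freq[i, ok]
    st <- depths[i, ok]
    n <- meta$ploidy[k]
    tibble::tibble(
      sample_id = meta$sample_id[k],
      sigma2_bin = (1 - 1 / n) * sum(ph * (1 - ph) / st),
      sigma2_g = sum(ph * (1 - ph)) / n,
      n_markers = sum(ok)
    )
  })
  dplyr::bind_rows(out)
}

#' Correct GRM diagonal inflation from low sequencing depth
#'
#' Deflates each diagonal element by its sample's binomial inflation
#' fraction, `Dc_i = Db_i * (1 - omega_i)`; off-diagonal elements are
#' untouched (read-sampling errors are independent across samples, so they
#' do not bias relationships between samples). Applying the correction twice
#' is refused.
#'
#' @param grm An uncorrected [pool_grm][compute_grm] object.
#' @param omega Either the tibble from [binomial_inflation()] or a numeric
#'   vector aligned with (or named by) the GRM samples; values in \[0, 1).
#' @return The corrected `pool_grm`, with `db` (biased diagonal) and `omega`
#'   recorded.
#' @export
correct_diagonal <- function(grm, omega) {
  stopifnot(inherits(grm, "pool_grm"))
  if (grm$corrected) {
    stop("GRM diagonal is already corrected; refusing to correct twice")
  }
  ids <- rownames(grm$matrix)
  if (is.data.frame(omega)) {
    idx <- match(ids, omega$sample_id)
    if (anyNA(idx)) stop("`omega` table is missing samples: ",
                         paste(ids[is.na(idx)], collapse = ", "))
    w <- omega$omega[idx]
  } else {
    w <- if (!is.null(names(omega)) && !is.null(ids)) omega[ids] else omega
  }
  if (length(w) != nrow(grm$matrix) || anyNA(w)) {
    stop("`omega` must supply one value per GRM sample")
  }
  if (any(w < 0 | w >= 1)) stop("inflation fractions must lie in [0, 1)")
  grm$db <- diag(grm$matrix)
  diag(grm$matrix) <- grm$db * (1 - w)
  grm$omega <- stats::setNames(as.numeric(w), ids)
  grm$corrected <- TRUE
  grm
}

#' Per-sample GRM diagonal as a tibble
#'
#' @param grm A [pool_grm][compute_grm] object.
#' @return Tibble with `sample_id`, `diagonal`, and when corrected also
#'   `db` (uncorrected diagonal) and `omega`.
#' @export
grm_diagonal <- function(grm) {
  stopifnot(inherits(grm, "pool_grm"))
  out <- tibble::tibble(
    sample_id = rownames(grm$matrix) %||% paste0("S", seq_len(nrow(grm$matrix))),
    diagonal = diag(grm$matrix)
  )
  if (grm$corrected) {
    out$db <- grm$db
    out$omega <- unname(grm$omega)
  }
  out
}
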