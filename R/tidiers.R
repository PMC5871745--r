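#' Tidiers for poolgrm result objects
#'
#' broom-style [tidy()] and [glance()] methods. `tidy()` returns the
#' per-element detail (per-sample diagonals for a GRM, variance components
#' for a GBLUP fit, per-sample scores for a cross-validation, per-replicate
#' accuracies for a masking run); `glance()` returns a one-row summary.
#'
#' @param x A `pool_grm`, `gblup_fit`, `cv_result` or `masking_accuracy`
#'   object.
#' @param ... Unused.
#' @return A tibble.
#' @name poolgrm-tidiers
NULL

#' @rdname poolgrm-tidiers
#' @export
tidy.pool_grm <- function(x, ...) grm_diagonal(x)

#' @rdname poolgrm-tidiers
#' @export
glance.pool_grm <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$matrix),
    reference_ploidy = x$reference_ploidy,
    corrected = x$corrected,
    mean_diagonal = mean(diag(x$matrix)),
    mean_off_diagonal = mean(x$matrix[lower.tri(x$matrix)])
  )
}

#' @rdname poolgrm-tidiers
#' @export
tidy.gblup_fit <- function(x, ...) x$varcomp

#' @rdname poolgrm-tidiers
#' @export
glance.gblup_fit <- function(x, ...) {
  tibble::tibble(
    h2 = x$h2,
    loglik = x$loglik,
    converged = x$converged,
    iterations = max(x$trace$iter),
    n_records = nrow(x$records),
    n_samples = nrow(x$gebv),
    grm_ridge = x$grm_ridge
  )
}

#' @rdname poolgrm-tidiers
#' @export
tidy.cv_result <- function(x, ...) x$scores

#' @rdname poolgrm-tidiers
#' @export
glance.cv_result <- function(x, ...) x$summary

#' @rdname poolgrm-tidiers
#' @export
tidy.masking_accuracy <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname poolgrm-tidiers
#' @export
glance.masking_accuracy <- function(x, ...) {
  tibble::tibble(
    method = x$method[1],
    mean_r_squared = mean(x$r_squared, na.rm = TRUE),
    sd_r_squared = stats::sd(x$r_squared, na.rm = TRUE),
    n_replicates = nrow(x)
  )
}
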