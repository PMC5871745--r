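#' Plot GRM diagonals
#'
#' Diagonal elements per sample, against the per-sample mean coverage depth
#' when an inflation table is supplied (the diagnostic view in which depth
#' bias shows up as a depth-dependent trend), otherwise against sample index.
#'
#' @param object A [pool_grm][compute_grm] object.
#' @param inflation Optional tibble from [binomial_inflation()]; adds mean
#'   depth to the x axis.
#' @param meta Optional metadata tibble (`sample_id`, `material`) colouring
#'   points by material.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pool_grm <- function(object, inflation = NULL, meta = NULL, ...) {
  d <- grm_diagonal(object)
  if (!is.null(meta)) {
    d$material <- meta$material[match(d$sample_id, meta$sample_id)]
  }
  if (!is.null(inflation)) {
    d$mean_depth <- inflation$mean_depth[match(d$sample_id,
                                               inflation$sample_id)]
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_depth,
                                         y = .data$diagonal))
    p <- p + ggplot2::labs(x = "mean coverage depth")
  } else {
    d$index <- seq_len(nrow(d))
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$diagonal))
    p <- p + ggplot2::labs(x = "sample")
  }
  if (!is.null(meta)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$material),
                                 alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::geom_hline(yintercept = mean(d$diagonal), linetype = 2) +
    ggplot2::labs(
      y = "GRM diagonal",
      title = paste0("GRM diagonals (",
                     if (object$corrected) "corrected" else "uncorrected",
                     ", reference ploidy ", object$reference_ploidy, ")")
    )
}

#' Plot masking-accuracy replicates
#'
#' Per-replicate imputation R-squared; several methods' results can be
#' row-bound first to compare them side by side.
#'
#' @param object A [masking_accuracy()] tibble (or several bound together).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.masking_accuracy <- function(object, ...) {
  d <- tibble::as_tibble(unclass(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$r_squared)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(x = "imputation method", y = expression(R^2),
                  title = "Imputation accuracy under masking")
}

#' Plot cross-validated GEBVs against corrected phenotypes
#'
#' @param object A `cv_result` from [leave_one_out_cv()] or
#'   [across_set_cv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  d <- object$scores
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$gebv, y = .data$corrected))
  if ("material" %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$material),
                                 alpha = 0.7)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.4) +
    ggplot2::labs(x = "cross-validated GEBV", y = "corrected phenotype",
                  title = paste0("Predictive ability (", object$scheme, ")"))
}
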