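# Scaffold assignment is parsed from "scaffold:pos" marker names; a matrix
# without ":" in its column names is treated as a single scaffold.
.scaffold_of <- function(freq) {
  ids <- colnames(freq)
  if (is.null(ids)) return(rep("scaf1", ncol(freq)))
  ifelse(grepl(":", ids, fixed = TRUE), sub(":[^:]*$", "", ids), "scaf1")
}

# Deterministic per-scaffold seed derived from the global seed and the
# scaffold name, so results do not depend on scaffold processing order.
.scaffold_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) + 7919 * h) %% .Machine$integer.max)
}

.new_imputation <- function(freq, method, log) {
  structure(list(freq = freq, method = method, log = log),
            class = "imputed_freq")
}

#' @exportS3Method base::print
print.imputed_freq <- function(x, ...) {
  cat("Imputed allele-frequency matrix (", x$method, "): ",
      nrow(x$freq), " x ", ncol(x$freq), ", no missing entries\n", sep = "")
  invisible(x)
}

#' Mean imputation of missing allele frequencies
#'
#' Replaces each missing entry with the mean of the non-missing values for
#' that marker — the imputation implicit in the standard VanRaden GRM (a
#' mean-imputed entry contributes zero to the centred matrix).
#'
#' @param freq Samples x markers frequency matrix with NA for missing.
#' @return An `imputed_freq` object; `$freq` holds the completed matrix.
#' @export
impute_mean <- function(freq) {
  stopifnot(is.matrix(freq))
  nmiss <- colSums(is.na(freq))
  if (any(nmiss == nrow(freq))) {
    stop("marker(s) with no observed values: ",
         paste(utils::head(colnames(freq)[nmiss == nrow(freq)], 5),
               collapse = ", "),
         " — filter them out first (filter_markers())")
  }
  cm <- colMeans(freq, na.rm = TRUE)
  idx <- which(is.na(freq))
  if (length(idx)) freq[idx] <- cm[(idx - 1L) %/% nrow(freq) + 1L]
  .new_imputation(freq, "mean",
                  tibble::tibble(scaffold = "(all)", n_imputed = length(idx),
                                 note = NA_character_))
}

# Squared Euclidean distances between target marker columns X (n x s) and
# candidate columns C (n x c) under pairwise-complete observation, rescaled
# by n / n_common. Entries with too little overlap are Inf.
.pairwise_sqdist <- function(X, C, min_overlap) {
  W <- !is.na(X)
  Wc <- !is.na(C)
  X0 <- X; X0[!W] <- 0
  C0 <- C; C0[!Wc] <- 0
  ncom <- crossprod(W, Wc)
  d2 <- crossprod(X0^2, Wc) + crossprod(W, C0^2) - 2 * crossprod(X0, C0)
  d2 <- d2 * nrow(X) / pmax(ncom, 1)
  d2[ncom < min_overlap] <- Inf
  pmax(d2, 0)
}

#' k-nearest-neighbour imputation with flipped-marker candidates
#'
#' Imputes each missing entry as the inverse-squared-distance weighted
#' average of the sample's values at the `k` nearest markers on the same
#' scaffold. Every other marker enters the candidate set twice, in its
#' original and flipped (`1 - x`) state, so markers in strong negative
#' linkage disequilibrium are usable predictors. Distances are Euclidean
#' between marker columns over samples where both are observed, rescaled by
#' the completeness ratio; candidates overlapping the target in fewer than
#' `min_overlap` samples are dropped. Candidates at distance zero (exact
#' duplicates) take full weight and are averaged exclusively. A marker with
#' no usable candidate falls back to mean imputation (logged).
#'
#' @param freq Samples x markers frequency matrix with NA for missing;
#'   marker names `"scaffold:pos"` define the scaffolds.
#' @param k Number of neighbours (default 6).
#' @param min_overlap Minimum pairwise-complete overlap for a candidate.
#' @return An `imputed_freq` object.
#' @export
impute_knn <- function(freq, k = 6, min_overlap = 10) {
  stopifnot(is.matrix(freq), k >= 1)
  nmiss0 <- colSums(is.na(freq))
  if (any(nmiss0 == nrow(freq))) stop("marker(s) with no observed values")
  scaf <- .scaffold_of(freq)
  out <- freq
  logs <- list()
  for (sc in unique(scaf)) {
    cols <- which(scaf == sc)
    X <- freq[, cols, drop = FALSE]
    miss <- is.na(X)
    if (!any(miss)) next
    s <- ncol(X)
    n_fallback <- 0L
    if (s < 2) {
      cm <- colMeans(X, na.rm = TRUE)
      X[miss] <- cm[col(X)[miss]]
      n_fallback <- sum(miss)
    } else {
      C <- cbind(X, 1 - X)
      cand_marker <- rep(seq_len(s), 2L)
      cand_flip <- rep(c(FALSE, TRUE), each = s)
      d2 <- .pairwise_sqdist(X, C, min_overlap)
      cm <- colMeans(X, na.rm = TRUE)
      for (j in seq_len(s)) {
        rows <- which(miss[, j])
        if (!length(rows)) next
        excl <- cand_marker == j  # a marker never predicts itself, either state
        ord <- order(d2[j, ], cand_marker, cand_flip)
        ord <- ord[!excl[ord] & is.finite(d2[j, ord])]
        for (i in rows) {
          vals <- C[i, ord]
          use <- ord[!is.na(vals)]
          if (!length(use)) {
            X[i, j] <- cm[j]
            n_fallback <- n_fallback + 1L
            next
          }
          use <- use[seq_len(min(k, length(use)))]
          dd <- d2[j, use]
          v <- C[i, use]
          est <- if (any(dd == 0)) mean(v[dd == 0]) else {
            sum(v / dd) / sum(1 / dd)
          }
          X[i, j] <- min(max(est, 0), 1)
        }
      }
    }
    out[, cols] <- X
    logs[[sc]] <- tibble::tibble(
      scaffold = sc, n_imputed = sum(miss),
      note = if (n_fallback > 0) {
        paste0(n_fallback, " value(s) fell back to mean imputation")
      } else NA_character_
    )
  }
  .new_imputation(out, "knn", dplyr::bind_rows(logs))
}

#' Iterative random-forest imputation
#'
#' Initialises missing entries by mean imputation, then repeatedly regresses
#' each incomplete marker on the other markers of its scaffold with a
#' regression forest (fit on the samples observed for that marker; each tree
#' uses a bootstrap of those samples and a random predictor subset) and
#' replaces its missing entries with the forest predictions. Iteration stops
#' after `max_iter` rounds or as soon as the sum of squared changes between
#' successive imputed matrices (over missing positions) increases, in which
#' case the state before the divergence is returned.
#'
#' @param freq Samples x markers frequency matrix with NA for missing.
#' @param n_trees Trees per forest (default 100).
#' @param max_iter Maximum update rounds (default 10).
#' @param order Marker update order within a scaffold: `"missing_count"`
#'   (ascending number of missing entries, default) or `"column"`.
#' @param seed Optional integer seed; per-scaffold streams are derived from
#'   it so results are invariant to scaffold processing order.
#' @return An `imputed_freq` object; the log records per-scaffold iteration
#'   counts and whether the stop was convergence or divergence.
#' @export
impute_rf <- function(freq, n_trees = 100, max_iter = 10,
                      order = c("missing_count", "column"), seed = NULL) {
  stopifnot(is.matrix(freq), n_trees >= 1, max_iter >= 1)
  order <- match.arg(order)
  nmiss0 <- colSums(is.na(freq))
  if (any(nmiss0 == nrow(freq))) stop("marker(s) with no observed values")
  scaf <- .scaffold_of(freq)
  out <- freq
  logs <- list()
  for (sc in unique(scaf)) {
    cols <- which(scaf == sc)
    X <- freq[, cols, drop = FALSE]
    miss <- is.na(X)
    if (!any(miss)) {
      logs[[sc]] <- tibble::tibble(scaffold = sc, n_imputed = 0L,
                                   iterations = 0L, status = "complete")
      next
    }
    if (!is.null(seed)) set.seed(.scaffold_seed(seed, sc))
    s <- ncol(X)
    cm <- colMeans(X, na.rm = TRUE)
    Xc <- X
    Xc[miss] <- cm[col(Xc)[miss]]
    if (s < 2) {
      out[, cols] <- Xc
      logs[[sc]] <- tibble::tibble(scaffold = sc, n_imputed = sum(miss),
                                   iterations = 0L,
                                   status = "mean fallback (single marker)")
      next
    }
    upd <- which(colSums(miss) > 0)
    if (order == "missing_count") upd <- upd[base::order(colSums(miss)[upd])]
    prev_change <- Inf
    status <- "max_iter"
    it <- 0L
    for (iter in seq_len(max_iter)) {
      Xprev <- Xc
      for (j in upd) {
        obs <- !miss[, j]
        if (sum(obs) < 2) next
        # suppressWarnings: randomForest warns on near-constant responses,
        # which are routine for low-MAF markers
        fit <- suppressWarnings(randomForest::randomForest(
          x = Xc[obs, -j, drop = FALSE], y = X[obs, j],
          ntree = n_trees, mtry = max(1L, ceiling((s - 1) / 3))
        ))
        pred <- stats::predict(fit, Xc[miss[, j], -j, drop = FALSE])
        Xc[miss[, j], j] <- pmin(pmax(pred, 0), 1)
      }
      change <- sum((Xc[miss] - Xprev[miss])^2)
      if (change > prev_change) {
        Xc <- Xprev  # diverged: return the state before this round
        status <- "diverged"
        break
      }
      it <- iter
      prev_change <- change
      if (change < 1e-8) {
        status <- "converged"
        break
      }
    }
    out[, cols] <- Xc
    logs[[sc]] <- tibble::tibble(scaffold = sc, n_imputed = sum(miss),
                                 iterations = it, status = status)
  }
  .new_imputation(out, "rf", dplyr::bind_rows(logs))
}

.imputer_fun <- function(method, ...) {
  if (is.function(method)) return(method)
  switch(match.arg(method, c("mean", "knn", "rf")),
         mean = function(x) impute_mean(x),
         knn = function(x) impute_knn(x, ...),
         rf = function(x) impute_rf(x, ...))
}

#' Imputation accuracy by masking observed entries
#'
#' Estimates how well an imputation method recovers known values: in each
#' replicate a random subset of scaffolds is selected, a fraction of their
#' observed entries is masked, the matrix is re-imputed, and accuracy is
#' scored as `R2 = 1 - sum((x_true - x_imp)^2) / sum((x_true -
#' mean(x_true))^2)` over the masked entries. R2 is 1 for a perfect imputer,
#' near 0 for the global mean, and may be negative for an imputer worse than
#' the mean. The input matrix is never modified.
#'
#' @param freq Samples x markers frequency matrix (may contain NA).
#' @param method `"mean"`, `"knn"`, `"rf"`, or a function taking a matrix
#'   and returning an `imputed_freq` (or a completed matrix).
#' @param mask_fraction Fraction of observed entries masked per replicate
#'   (at least one entry is always masked).
#' @param n_replicates Number of mask-impute replicates.
#' @param scaffold_fraction Fraction of scaffolds drawn per replicate.
#' @param seed Integer seed.
#' @param ... Passed through to the imputer (e.g. `k`, `n_trees`).
#' @return A tibble of class `masking_accuracy` with one row per replicate:
#'   `replicate`, `r_squared` (NA when the masked truths are constant),
#'   `n_masked`, `method`.
#' @export
masking_accuracy <- function(freq, method = "mean", mask_fraction = 0.001,
                             n_replicates = 10, scaffold_fraction = 0.1,
                             seed, ...) {
  stopifnot(is.matrix(freq), mask_fraction > 0, mask_fraction < 1,
            n_replicates >= 1)
  imputer <- .imputer_fun(method, ...)
  tag <- if (is.function(method)) "custom" else method
  scaf <- .scaffold_of(freq)
  scaffolds <- unique(scaf)
  set.seed(seed)
  res <- lapply(seq_len(n_replicates), function(rep_i) {
    pick <- sample(scaffolds, max(1L, round(scaffold_fraction * length(scaffolds))))
    cols <- which(scaf %in% pick)
    sub <- freq[, cols, drop = FALSE]
    obs <- which(!is.na(sub))
    n_mask <- max(1L, round(mask_fraction * length(obs)))
    if (n_mask >= length(obs)) stop("mask fraction leaves no training data")
    masked_idx <- sample(obs, n_mask)
    truth <- sub[masked_idx]
    sub[masked_idx] <- NA_real_
    res <- imputer(sub)
    completed <- if (inherits(res, "imputed_freq")) res$freq else res
    imputed <- completed[masked_idx]
    den <- sum((truth - mean(truth))^2)
    tibble::tibble(
      replicate = rep_i,
      r_squared = if (den == 0) NA_real_ else 1 - sum((truth - imputed)^2) / den,
      n_masked = n_mask,
      method = tag
    )
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("masking_accuracy", class(out))
  attr(out, "mask_fraction") <- mask_fraction
  out
}
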