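# --- design construction -----------------------------------------------------

.check_phenos <- function(phenos) {
  need <- c("sample_id", "value", "trial")
  if (!all(need %in% names(phenos))) {
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(!nzchar(phenos$trial)) || anyNA(phenos$trial)) {
    stop("trial labels must be non-empty")
  }
  phenos
}

.locyear <- function(phenos) {
  loc <- if ("location" %in% names(phenos)) phenos$location else "L"
  yr <- if ("year" %in% names(phenos)) phenos$year else 0
  paste(loc, yr, sep = "_")
}

.fixed_design <- function(phenos, xlev = NULL) {
  df <- data.frame(trial = factor(phenos$trial,
                                  levels = xlev %||% sort(unique(phenos$trial))))
  if (nlevels(df$trial) >= 2) {
    X <- stats::model.matrix(~trial, df)
  } else {
    X <- stats::model.matrix(~1, df)
  }
  X
}

# Ridge the GRM until its smallest eigenvalue is >= 1e-8; returns the matrix,
# the ridge used and the original smallest eigenvalue.
.ridge_grm <- function(G, ridge = 1e-6) {
  ev_min <- min(eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  delta <- if (ev_min < 1e-8) (1e-8 - ev_min) + ridge else 0
  list(G = G + diag(delta, nrow(G)), delta = delta, min_eigenvalue = ev_min)
}

# --- REML (average-information with EM fallback and step-halving) ------------

.reml_ll <- function(theta, Vlist, y, X) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (k in seq_along(theta)) V <- V + theta[k] * Vlist[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  Vinv <- chol2inv(ch)
  VinvX <- Vinv %*% X
  XtVX <- crossprod(X, VinvX)
  chx <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(chx)) return(list(ll = -Inf))
  P <- Vinv - VinvX %*% chol2inv(chx) %*% t(VinvX)
  Py <- P %*% y
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                  sum(y * Py))
  list(ll = as.numeric(ll), P = P, Py = Py, Vinv = Vinv, XtVX = XtVX,
       VinvX = VinvX)
}

.reml_fit <- function(y, X, Vlist, q_levels, max_iter = 100, tol = 1e-8) {
  n <- length(y)
  K <- length(Vlist)
  vy <- stats::var(y)
  lb <- 1e-8 * vy
  theta <- rep(vy / K, K)
  state <- .reml_ll(theta, Vlist, y, X)
  if (!is.finite(state$ll)) stop("REML likelihood undefined at initialisation")
  trace <- list(tibble::tibble(iter = 0L, loglik = state$ll, step = NA_real_))
  converged <- FALSE
  score <- rep(NA_real_, K)
  for (iter in seq_len(max_iter)) {
    Py <- state$Py
    P <- state$P
    score <- vapply(seq_len(K), function(k) {
      -0.5 * (sum(P * Vlist[[k]]) - sum(Py * (Vlist[[k]] %*% Py)))
    }, numeric(1))
    Tk <- lapply(Vlist, function(Vk) Vk %*% Py)
    AI <- matrix(0, K, K)
    for (k in seq_len(K)) {
      PTk <- P %*% Tk[[k]]
      for (l in k:K) {
        AI[k, l] <- AI[l, k] <- 0.5 * sum(Tk[[l]] * PTk)
      }
    }
    delta <- tryCatch(solve(AI + diag(1e-10, K), score),
                      error = function(e) score)
    step <- 1
    accepted <- FALSE
    for (h in seq_len(20)) {
      cand <- pmax(theta + step * delta, lb)
      cand_state <- .reml_ll(cand, Vlist, y, X)
      if (is.finite(cand_state$ll) && cand_state$ll >= state$ll - 1e-10) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      # EM step: guaranteed uphill, slow but safe
      cand <- pmax(theta + theta^2 *
                     vapply(seq_len(K), function(k) {
                       (sum(Py * (Vlist[[k]] %*% Py)) - sum(P * Vlist[[k]])) /
                         q_levels[k]
                     }, numeric(1)), lb)
      cand_state <- .reml_ll(cand, Vlist, y, X)
      if (!is.finite(cand_state$ll) || cand_state$ll < state$ll - 1e-8) {
        break  # cannot improve further
      }
      step <- NA_real_
    }
    dll <- cand_state$ll - state$ll
    theta <- cand
    state <- cand_state
    trace[[length(trace) + 1L]] <-
      tibble::tibble(iter = iter, loglik = state$ll, step = step)
    if (abs(dll) < tol) {
      converged <- TRUE
      break
    }
  }
  # gradient at the optimum (free components only)
  final_score <- vapply(seq_len(K), function(k) {
    -0.5 * (sum(state$P * Vlist[[k]]) -
              sum(state$Py * (Vlist[[k]] %*% state$Py)))
  }, numeric(1))
  free <- theta > lb * 1.01
  list(theta = theta, ll = state$ll, P = state$P, Py = state$Py,
       Vinv = state$Vinv, XtVX = state$XtVX, VinvX = state$VinvX,
       converged = converged, trace = dplyr::bind_rows(trace),
       gradient_norm = if (any(free)) sqrt(sum(final_score[free]^2)) else 0)
}

# --- fixed-variance solvers (internal oracles) -------------------------------

#' Solve the GBLUP mixed-model equations at fixed variance components
#'
#' Two independent linear-algebra routes to the same fixed-effect estimates
#' and genomic BLUPs for the single-trait model `y = X b + Z u + e` with
#' `u ~ N(0, G sigma2_g)` and `e ~ N(0, I sigma2_e)`:
#' `route = "mme"` solves Henderson's mixed-model equations with `G^{-1}`,
#' while `route = "eigen"` rotates the model by the eigenvectors of `G`
#' (requiring one record per GRM sample, in GRM order) and solves in the
#' diagonal basis. Used as a cross-check of the solver algebra; both routes
#' carry predictions for unphenotyped samples through `G` in the MME case.
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix.
#' @param Z Records x samples incidence matrix (identity for `"eigen"`).
#' @param G Relationship matrix (positive definite; ridge first if needed).
#' @param sigma2_g,sigma2_e Genomic and residual variances.
#' @param route `"mme"` or `"eigen"`.
#' @return List with `beta` and `u` (named by GRM samples).
#' @export
solve_gblup <- function(y, X, Z, G, sigma2_g, sigma2_e,
                        route = c("mme", "eigen")) {
  route <- match.arg(route)
  stopifnot(sigma2_g > 0, sigma2_e > 0)
  if (route == "mme") {
    Ginv <- solve(G)
    lambda <- sigma2_e / sigma2_g
    XtX <- crossprod(X)
    XtZ <- crossprod(X, Z)
    ZtZ <- crossprod(Z)
    C <- rbind(cbind(XtX, XtZ),
               cbind(t(XtZ), ZtZ + lambda * Ginv))
    rhs <- c(crossprod(X, y), crossprod(Z, y))
    sol <- solve(C, rhs)
    p <- ncol(X)
    list(beta = sol[seq_len(p)],
         u = stats::setNames(sol[-seq_len(p)], rownames(G)))
  } else {
    if (nrow(Z) != ncol(Z) || any(Z != diag(nrow(Z)))) {
      stop("the eigendecomposition route needs one record per GRM sample ",
           "in GRM order (Z = I)")
    }
    ev <- eigen((G + t(G)) / 2, symmetric = TRUE)
    U <- ev$vectors
    d <- ev$values
    yt <- crossprod(U, y)
    Xt <- crossprod(U, X)
    w <- 1 / (sigma2_g * d + sigma2_e)
    XtWX <- crossprod(Xt, Xt * w)
    beta <- solve(XtWX, crossprod(Xt, yt * w))
    r <- as.vector(yt - Xt %*% beta)
    u <- as.vector(U %*% (sigma2_g * d * w * r))
    list(beta = as.vector(beta), u = stats::setNames(u, rownames(G)))
  }
}

# --- the user-facing fit -----------------------------------------------------

#' Fit a GBLUP mixed model by REML
#'
#' Fits `y = 1 mu + X t + Z1 i + Z2 l + e`, where `t` are trial fixed
#' effects, `i ~ N(0, G sigma2_i)` are genomic breeding values with `G` an
#' allele-frequency GRM, the optional `l ~ N(0, I sigma2_ily)` is the
#' genotype-by-location-by-year interaction, and `e ~ N(0, I sigma2_e)`.
#' Variance components are estimated by average-information REML with
#' step-halving and an EM fallback; convergence is declared when the
#' restricted log-likelihood changes by less than `tol`. GEBVs are returned
#' for every GRM sample, including unphenotyped ones (predicted through
#' their relationships).
#'
#' @param phenos Phenotype tibble with columns `sample_id`, `value`, `trial`
#'   (optionally `location`, `year`, `replicate`).
#' @param grm A [pool_grm][compute_grm] object or relationship matrix with
#'   sample ids as dimnames; every phenotyped sample must appear in it.
#' @param include_interaction Include the genotype-by-location-by-year term;
#'   silently dropped (with a warning) when fewer than 2 location-year
#'   combinations exist.
#' @param ridge Ridge added to a non-positive-definite GRM (on top of the
#'   amount needed to push the smallest eigenvalue to 1e-8).
#' @param max_iter,tol REML iteration cap and log-likelihood tolerance.
#' @return An object of class `gblup_fit` with variance components, fixed
#'   effects, GEBVs, heritability, the likelihood trace and the GRM
#'   bookkeeping. Methods: [generics::tidy()], [generics::glance()],
#'   `print()`, [ggplot2::autoplot()].
#' @export
fit_gblup <- function(phenos, grm, include_interaction = FALSE,
                      ridge = 1e-6, max_iter = 100, tol = 1e-8) {
  phenos <- .check_phenos(phenos)
  G0 <- if (inherits(grm, "pool_grm")) grm$matrix else grm
  ids <- rownames(G0)
  if (is.null(ids)) stop("GRM must carry sample ids as dimnames")
  missing_ids <- setdiff(unique(phenos$sample_id), ids)
  if (length(missing_ids)) {
    stop("phenotyped sample(s) not in the GRM: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  rg <- .ridge_grm(G0, ridge)
  G <- rg$G

  y <- phenos$value
  n <- length(y)
  X <- .fixed_design(phenos)
  if (qr(X)$rank < ncol(X)) {
    stop("fixed-effect design is singular: trial effects are not ",
         "identifiable from these records")
  }
  Z1 <- matrix(0, n, length(ids), dimnames = list(NULL, ids))
  Z1[cbind(seq_len(n), match(phenos$sample_id, ids))] <- 1

  ly <- .locyear(phenos)
  use_int <- include_interaction
  if (include_interaction && length(unique(ly)) < 2) {
    warning("fewer than 2 location-year combinations: ",
            "genotype-by-location-by-year interaction dropped")
    use_int <- FALSE
  }
  Vlist <- list(genomic = Z1 %*% G %*% t(Z1))
  q_levels <- length(ids)
  if (use_int) {
    combo <- factor(paste(phenos$sample_id, ly, sep = "@"))
    Z2 <- stats::model.matrix(~ combo - 1)
    Vlist$gxly <- tcrossprod(Z2)
    q_levels <- c(q_levels, nlevels(combo))
  }
  Vlist$residual <- diag(n)
  q_levels <- c(q_levels, n)

  fit <- .reml_fit(y, X, Vlist, q_levels, max_iter = max_iter, tol = tol)
  theta <- stats::setNames(fit$theta, names(Vlist))

  beta <- as.vector(solve(fit$XtVX, crossprod(X, fit$Vinv %*% y)))
  names(beta) <- colnames(X)
  u <- as.vector(theta[1] * G %*% crossprod(Z1, fit$Py))

  records <- tibble::as_tibble(phenos)
  records$fixed_fit <- as.vector(X %*% beta)

  structure(
    list(
      varcomp = tibble::tibble(component = names(theta),
                               variance = unname(theta)),
      beta = tibble::tibble(term = names(beta), estimate = unname(beta)),
      gebv = tibble::tibble(sample_id = ids, gebv = u),
      h2 = unname(theta[1] / sum(theta)),
      loglik = fit$ll,
      trace = fit$trace,
      converged = fit$converged,
      gradient_norm = fit$gradient_norm,
      grm_ridge = rg$delta,
      grm_min_eigenvalue = rg$min_eigenvalue,
      G = G,
      theta = theta,
      records = records,
      trial_levels = sort(unique(phenos$trial)),
      interaction = use_int
    ),
    class = "gblup_fit"
  )
}

#' @exportS3Method base::print
print.gblup_fit <- function(x, ...) {
  cat("GBLUP fit (REML",
      if (x$converged) "converged" else "NOT converged", ")\n")
  vc <- x$varcomp
  for (i in seq_len(nrow(vc))) {
    cat(sprintf("  sigma2_%-9s %.5g\n", vc$component[i], vc$variance[i]))
  }
  cat(sprintf("  h2 = %.3f   logLik = %.4f   samples = %d\n",
              x$h2, x$loglik, nrow(x$gebv)))
  invisible(x)
}

#' Correct phenotypes for fixed effects
#'
#' Subtracts the fitted overall mean and trial effects from every record and
#' averages the residuals per sample — the quantity predictive abilities are
#' correlated against. Samples with zero records are simply absent from the
#' output.
#'
#' @param phenos Phenotype tibble (same layout as in [fit_gblup()]).
#' @param fit A `gblup_fit` whose fixed effects are used for the correction.
#' @return Tibble with `sample_id`, `corrected` (per-sample mean of
#'   fixed-effect-corrected records) and `n_records`.
#' @export
correct_phenotypes <- function(phenos, fit) {
  stopifnot(inherits(fit, "gblup_fit"))
  phenos <- .check_phenos(phenos)
  new_lev <- setdiff(unique(phenos$trial), fit$trial_levels)
  if (length(new_lev)) {
    stop("trial level(s) not seen by the fit: ",
         paste(new_lev, collapse = ", "))
  }
  X <- .fixed_design(phenos, xlev = fit$trial_levels)
  beta <- stats::setNames(fit$beta$estimate, fit$beta$term)
  fitted_fixed <- as.vector(X[, names(beta), drop = FALSE] %*% beta)
  tibble::tibble(sample_id = phenos$sample_id,
                 resid = phenos$value - fitted_fixed) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(corrected = mean(.data$resid),
                     n_records = dplyr::n(), .groups = "drop")
}

# Per-sample variance of the corrected phenotype mean given the variance
# components: interaction averages over distinct location-years, residual
# over records.
.sample_level_var <- function(phenos, theta) {
  ly <- .locyear(phenos)
  tibble::tibble(sample_id = phenos$sample_id, ly = ly) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(r = dplyr::n(), L = dplyr::n_distinct(.data$ly),
                     .groups = "drop") |>
    dplyr::mutate(d = (if ("gxly" %in% names(theta)) theta[["gxly"]] else 0) /
                    .data$L + theta[["residual"]] / .data$r)
}

.new_cv_result <- function(scores, summary, scheme) {
  structure(list(scores = scores, summary = summary, scheme = scheme),
            class = "cv_result")
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat("Cross-validation (", x$scheme, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Leave-one-out cross-validation of GBLUP
#'
#' For each sample in turn, its phenotype is removed and its GEBV is
#' predicted from the remaining samples through the GRM; predictive ability
#' is the Pearson correlation between the LOO GEBVs and the per-sample
#' fixed-effect-corrected phenotype means. Fixed effects and variance
#' components come from a single full-data fit (the two-stage scheme);
#' `refit_each_fold = TRUE` re-runs the full REML without the sample's
#' records in every fold instead.
#'
#' @param phenos Phenotype tibble.
#' @param grm [pool_grm][compute_grm] object or relationship matrix.
#' @param include_interaction Passed to [fit_gblup()].
#' @param fit Optional pre-computed full-data `gblup_fit` (saves the refit).
#' @param refit_each_fold Exact per-fold REML refits (slow; small n only).
#' @return A `cv_result`: per-sample scores (`sample_id`, `gebv`,
#'   `corrected`) and a one-row summary with the predictive ability.
#' @export
leave_one_out_cv <- function(phenos, grm, include_interaction = FALSE,
                             fit = NULL, refit_each_fold = FALSE) {
  phenos <- .check_phenos(phenos)
  if (dplyr::n_distinct(phenos$sample_id) < 3) stop("need at least 3 samples")
  if (is.null(fit)) {
    fit <- fit_gblup(phenos, grm, include_interaction = include_interaction)
  }
  corr <- correct_phenotypes(phenos, fit)

  if (refit_each_fold) {
    gebv <- vapply(corr$sample_id, function(id) {
      sub <- phenos[phenos$sample_id != id, , drop = FALSE]
      f <- fit_gblup(sub, grm, include_interaction = include_interaction)
      f$gebv$gebv[f$gebv$sample_id == id]
    }, numeric(1))
  } else {
    theta <- fit$theta
    G <- fit$G
    obs <- match(corr$sample_id, rownames(G))
    Gobs <- G[obs, obs, drop = FALSE]
    dv <- .sample_level_var(phenos, theta)
    d <- dv$d[match(corr$sample_id, dv$sample_id)]
    ybar <- corr$corrected
    V <- theta[["genomic"]] * Gobs + diag(d)
    Vinv <- chol2inv(chol(V))
    a <- as.vector(Vinv %*% ybar)
    q <- length(ybar)
    gebv <- vapply(seq_len(q), function(i) {
      s <- Vinv[i, i]
      adj <- a - Vinv[, i] * ybar[i]        # Vinv %*% (ybar with y_i = 0)
      A <- adj[-i] - Vinv[-i, i] * adj[i] / s
      theta[["genomic"]] * sum(Gobs[i, -i] * A)
    }, numeric(1))
  }

  scores <- tibble::tibble(sample_id = corr$sample_id, gebv = gebv,
                           corrected = corr$corrected)
  pa <- stats::cor(scores$gebv, scores$corrected)
  .new_cv_result(scores,
                 tibble::tibble(scheme = "leave-one-out", pa = pa,
                                n = nrow(scores)),
                 "leave-one-out")
}

#' Across-material cross-validation of GBLUP
#'
#' Masks all phenotypes of one breeding material at a time (single plants,
#' F2 families, synthetics, ...), predicts their GEBVs from the remaining
#' materials through the combined GRM, and reports the predictive ability
#' within each left-out material. Variance components and fixed effects come
#' from the full-data fit (two-stage scheme).
#'
#' @param phenos Phenotype tibble.
#' @param grm Combined [pool_grm][compute_grm] (conventionally built at
#'   reference ploidy 4) or relationship matrix.
#' @param meta Sample metadata with `sample_id` and `material`; every
#'   phenotyped sample must be listed.
#' @param include_interaction Passed to [fit_gblup()].
#' @param fit Optional pre-computed full-data `gblup_fit`.
#' @return A `cv_result` with per-sample scores (incl. `material`) and a
#'   per-material summary of predictive abilities.
#' @export
across_set_cv <- function(phenos, grm, meta, include_interaction = FALSE,
                          fit = NULL) {
  phenos <- .check_phenos(phenos)
  unknown <- setdiff(unique(phenos$sample_id), meta$sample_id)
  if (length(unknown)) {
    stop("phenotyped sample(s) absent from metadata: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (is.null(fit)) {
    fit <- fit_gblup(phenos, grm, include_interaction = include_interaction)
  }
  corr <- correct_phenotypes(phenos, fit)
  corr$material <- meta$material[match(corr$sample_id, meta$sample_id)]
  mats <- unique(corr$material)
  if (length(mats) < 2) stop("need at least 2 materials with phenotypes")

  theta <- fit$theta
  G <- fit$G
  dv <- .sample_level_var(phenos, theta)
  d <- dv$d[match(corr$sample_id, dv$sample_id)]
  idx <- match(corr$sample_id, rownames(G))

  scores <- lapply(mats, function(mm) {
    test <- which(corr$material == mm)
    train <- which(corr$material != mm)
    Vtr <- theta[["genomic"]] * G[idx[train], idx[train], drop = FALSE] +
      diag(d[train])
    u <- theta[["genomic"]] *
      G[idx[test], idx[train], drop = FALSE] %*%
      solve(Vtr, corr$corrected[train])
    tibble::tibble(sample_id = corr$sample_id[test], material = mm,
                   gebv = as.vector(u), corrected = corr$corrected[test])
  })
  scores <- dplyr::bind_rows(scores)
  summary <- scores |>
    dplyr::group_by(.data$material) |>
    dplyr::summarise(pa = stats::cor(.data$gebv, .data$corrected),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(scheme = "across-set", .before = 1)
  .new_cv_result(scores, summary, "across-set")
}
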