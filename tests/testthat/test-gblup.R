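grm_sp <- compute_grm(fix_pop$sp_geno, 2)

test_that("REML recovers the simulated heritability", {
  h2hat <- vapply(1:4, function(s) {
    ph <- simulate_phenotypes(grm_sp, h2 = 0.5, n_reps = 2, seed = 600 + s)
    fit <- fit_gblup(ph, grm_sp)
    expect_true(fit$converged)
    fit$h2
  }, numeric(1))
  expect_lt(abs(mean(h2hat) - 0.5), 0.15)
})

test_that("a heritability-free trait gives a boundary genomic variance", {
  ph <- simulate_phenotypes(grm_sp, h2 = 0, n_reps = 2, seed = 61)
  fit <- fit_gblup(ph, grm_sp)
  expect_lt(fit$h2, 0.1)
})

test_that("REML log-likelihood is non-decreasing along the trace", {
  ph <- simulate_phenotypes(grm_sp, h2 = 0.4, n_reps = 2, seed = 62)
  fit <- fit_gblup(ph, grm_sp)
  expect_true(all(diff(fit$trace$loglik) > -1e-8))
  expect_lt(fit$gradient_norm, 1e-4)
})

test_that("identity GRM with single records reduces to ridge shrinkage", {
  set.seed(63)
  n <- 60
  G <- diag(n); rownames(G) <- colnames(G) <- paste0("s", 1:n)
  y <- rnorm(n)
  s2g <- 0.4; s2e <- 0.6
  sol <- solve_gblup(y, matrix(1, n), diag(n), G, s2g, s2e, route = "mme")
  shrink <- s2g / (s2g + s2e)
  expect_equal(unname(sol$u), shrink * (y - mean(y)), tolerance = 1e-8)
})

test_that("eigendecomposition and MME solver routes agree to 1e-8", {
  set.seed(64)
  n <- nrow(grm_sp$matrix)
  G <- grm_sp$matrix + diag(1e-6, n)
  y <- rnorm(n)
  X <- cbind(1, rnorm(n))
  a <- solve_gblup(y, X, diag(n), G, 0.3, 0.7, route = "mme")
  b <- solve_gblup(y, X, diag(n), G, 0.3, 0.7, route = "eigen")
  expect_lt(max(abs(a$u - b$u)), 1e-8)
  expect_lt(max(abs(a$beta - b$beta)), 1e-8)
  expect_error(solve_gblup(y, X, matrix(0, n, n - 1), G, 0.3, 0.7,
                           route = "eigen"), "one record per")
})

test_that("phenotype correction removes fixed effects", {
  # single trial: corrected value is the record mean minus the overall mean
  ph1 <- simulate_phenotypes(grm_sp, h2 = 0.5, n_reps = 1, seed = 65)
  fit1 <- fit_gblup(ph1, grm_sp)
  corr1 <- correct_phenotypes(ph1, fit1)
  mu <- fit1$beta$estimate[fit1$beta$term == "(Intercept)"]
  means <- tapply(ph1$value, ph1$sample_id, mean)
  expect_equal(corr1$corrected,
               as.numeric(means[corr1$sample_id] - mu), tolerance = 1e-10)

  # balanced two-trial design: +/- delta trial effects vanish from contrasts
  ph2 <- simulate_phenotypes(grm_sp, h2 = 0.5, n_reps = 2,
                             fixed_effect_sd = 2, seed = 66)
  fit2 <- fit_gblup(ph2, grm_sp)
  corr2 <- correct_phenotypes(ph2, fit2)
  resid_by_trial <- tapply(
    ph2$value - fit2$records$fixed_fit, ph2$trial, mean
  )
  expect_lt(max(abs(resid_by_trial)), 1e-8)

  # unbalanced replicate counts use each sample's own records
  ph3 <- ph2[-(1:3), ]
  corr3 <- correct_phenotypes(ph3, fit2)
  expect_true(any(corr3$n_records == 1) && any(corr3$n_records == 2))
})

test_that("leave-one-out predictions never use the sample's own records", {
  ph <- simulate_phenotypes(grm_sp, h2 = 0.5, n_reps = 2, seed = 67)
  fit <- fit_gblup(ph, grm_sp)
  cv <- leave_one_out_cv(ph, grm_sp, fit = fit)
  corr <- correct_phenotypes(ph, fit)
  theta <- fit$theta
  obs <- match(corr$sample_id, rownames(fit$G))
  V <- theta[["genomic"]] * fit$G[obs, obs] +
    diag(theta[["residual"]] / 2, length(obs))
  for (i in c(1, 17, 33)) {
    u_i <- theta[["genomic"]] *
      fit$G[obs[i], obs[-i]] %*% solve(V[-i, -i], corr$corrected[-i])
    expect_equal(cv$scores$gebv[i], as.numeric(u_i), tolerance = 1e-8)
  }
})

test_that("null traits give null predictive ability on average", {
  pas <- vapply(1:4, function(s) {
    ph <- simulate_phenotypes(grm_sp, h2 = 0, n_reps = 2, seed = 680 + s)
    leave_one_out_cv(ph, grm_sp)$summary$pa
  }, numeric(1))
  expect_lt(abs(mean(pas)), 2 / sqrt(nrow(grm_sp$matrix)))
})

test_that("predictive ability rises with heritability on matched seeds", {
  pa <- vapply(c(0.2, 0.8), function(h2) {
    mean(vapply(1:3, function(s) {
      ph <- simulate_phenotypes(grm_sp, h2 = h2, n_reps = 2, seed = 690 + s)
      leave_one_out_cv(ph, grm_sp)$summary$pa
    }, numeric(1)))
  }, numeric(1))
  expect_gt(pa[2], pa[1])
})

test_that("a genomic twin is predicted from its duplicate's phenotype", {
  set.seed(70)
  base <- fix_pop$sp_geno[1:20, ]
  twins <- base
  rownames(twins) <- paste0(rownames(base), "_tw")
  g <- compute_grm(rbind(base, twins), 2)
  ph <- simulate_phenotypes(g, h2 = 0.8, n_reps = 4, seed = 71)
  cv <- leave_one_out_cv(ph, g)
  sc <- cv$scores
  a <- sc[match(rownames(base), sc$sample_id), ]
  b <- sc[match(rownames(twins), sc$sample_id), ]
  expect_gt(cor(a$gebv, b$corrected), 0.6)
})

test_that("across-set prediction works through shared founders and fails without", {
  meta <- sample_metadata(fix_pop, c("SP", "F2"))
  comb <- rbind(fix_pop$sp_geno, fix_pop$f2_freq)
  g <- compute_grm(comb, 4)
  ph <- simulate_phenotypes(g, h2 = 0.6, n_reps = 2, seed = 72)
  cv <- across_set_cv(ph, g, meta)
  expect_setequal(cv$summary$material, c("SP", "F2"))
  expect_true(all(cv$summary$pa > 0.15))

  # unrelated founder sets: permute one material's genotypes across markers
  pop2 <- simulate_breeding_population(n_families = 40, n_markers = 400,
                                       f1_size = 20, f2_size = 20,
                                       seed = 999)
  comb2 <- rbind(fix_pop$sp_geno, pop2$f2_freq)
  g2 <- compute_grm(comb2, 4)
  ph2 <- simulate_phenotypes(g2, h2 = 0.6, n_reps = 2, seed = 73)
  cv2 <- across_set_cv(ph2, g2, meta)
  expect_true(all(abs(cv2$summary$pa) < 3 / sqrt(40)))

  expect_error(across_set_cv(ph, g, meta[1:10, ]), "absent from metadata")
})

test_that("interaction terms need at least two location-years", {
  ph <- simulate_phenotypes(grm_sp, h2 = 0.5, n_reps = 2, seed = 74)
  expect_warning(fit_gblup(ph, grm_sp, include_interaction = TRUE),
                 "location-year")
})

test_that("model guards reject broken inputs", {
  ph <- simulate_phenotypes(grm_sp, h2 = 0.5, n_reps = 1, seed = 75)
  ph$sample_id[1] <- "not_in_grm"
  expect_error(fit_gblup(ph, grm_sp), "not in the GRM")
  ph2 <- simulate_phenotypes(grm_sp, h2 = 0.5, n_reps = 1, seed = 76)
  ph2$trial[2] <- ""
  expect_error(fit_gblup(ph2, grm_sp), "non-empty")
})

test_that("tidiers summarise fits and cross-validations", {
  ph <- simulate_phenotypes(grm_sp, h2 = 0.5, n_reps = 2, seed = 77)
  fit <- fit_gblup(ph, grm_sp)
  expect_named(tidy(fit), c("component", "variance"))
  gl <- glance(fit)
  expect_true(gl$converged)
  cv <- leave_one_out_cv(ph, grm_sp, fit = fit)
  expect_named(glance(cv), c("scheme", "pa", "n"))
  expect_s3_class(ggplot2::autoplot(cv), "ggplot")
})

test_that("refitting each fold agrees in direction with the fast path", {
  # related samples (SPs plus their own F2 pools) so LOO carries real signal
  comb <- rbind(fix_pop$sp_geno[1:12, ], fix_pop$f2_freq[1:12, ])
  small <- compute_grm(comb, 4)
  ph <- simulate_phenotypes(small, h2 = 0.7, n_reps = 3, seed = 78)
  fast <- leave_one_out_cv(ph, small)
  slow <- leave_one_out_cv(ph, small, refit_each_fold = TRUE)
  expect_gt(cor(fast$scores$gebv, slow$scores$gebv), 0.9)
})
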