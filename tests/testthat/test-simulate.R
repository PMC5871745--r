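test_that("founder frequencies follow the Beta moments and are reproducible", {
  p <- sample_founder_frequencies(5000, 2, 8, seed = 1)
  expect_length(p, 5000)
  expect_true(all(p > 0 & p < 1))
  expect_lt(abs(mean(p) - 0.2), 0.01)
  expect_lt(abs(var(p) - 2 * 8 / ((10)^2 * 11)), 0.002)
  expect_identical(p, sample_founder_frequencies(5000, 2, 8, seed = 1))
  expect_error(sample_founder_frequencies(100, alpha = 0, seed = 1),
               "positive")
  expect_error(sample_founder_frequencies(100, beta = -1, seed = 1),
               "positive")
})

test_that("read sampling is exact binomial with the pool-seq variance", {
  expect_equal(sample_reads(0, 10, seed = 1)$p_hat, 0)
  expect_equal(sample_reads(1, 10, seed = 1)$p_hat, 1)
  r <- sample_reads(rep(0.3, 1e5), 10, seed = 2)
  expect_true(all(r$s_a >= 0 & r$s_a <= r$s_t))
  expect_lt(abs(mean(r$p_hat) - 0.3), 0.002)
  expect_lt(abs(var(r$p_hat) - 0.3 * 0.7 / 10), 0.001)
  expect_true(is.na(sample_reads(0.5, 0, seed = 1)$p_hat))
  expect_error(sample_reads(0.5, -1), "non-negative")
})

test_that("inheritance is Mendelian: fixed and contrasting parent cases", {
  founders <- fix_pop$founder_geno
  f1 <- fix_pop$members$f1
  for (f in c(1, 7)) {
    mom <- founders[2 * f - 1, ]
    dad <- founders[2 * f, ]
    both_ref <- which(mom == 0 & dad == 0)
    contrasting <- which((mom == 0 & dad == 1) | (mom == 1 & dad == 0))
    expect_true(all(f1[[f]][, both_ref] == 0))
    expect_true(all(f1[[f]][, contrasting] == 0.5))
    both_alt <- which(mom == 1 & dad == 1)
    expect_true(all(f1[[f]][, both_alt] == 1))
  }
})

test_that("pool frequencies equal the mean of member dosages exactly", {
  for (f in c(2, 5)) {
    expect_identical(unname(fix_pop$f1_freq[f, ]),
                     colMeans(fix_pop$members$f1[[f]]))
    expect_identical(unname(fix_pop$f2_freq[f, ]),
                     colMeans(fix_pop$members$f2[[f]]))
  }
  expect_identical(unname(fix_pop$syn_freq[3, ]),
                   colMeans(fix_pop$syn_members[[3]]))
})

test_that("expected F2 pool frequency equals the grandparent mean", {
  founders <- fix_pop$founder_geno
  gp_mean <- (founders[seq(1, nrow(founders), 2), ] +
                founders[seq(2, nrow(founders), 2), ]) / 2
  dev <- fix_pop$f2_freq - gp_mean
  # per-family mean deviation should be centred on zero
  se <- sd(dev) / sqrt(length(dev))
  expect_lt(abs(mean(dev)), 3 * se)
})

test_that("single plants are members of their own F2 family", {
  for (f in c(1, 4, 9)) {
    sp <- fix_pop$sp_geno[f, ]
    members <- fix_pop$members$f2[[f]]
    hit <- apply(members, 1, function(r) all(r == sp))
    expect_true(any(hit))
  }
})

test_that("SYN parents come from distinct F2 families", {
  fams <- fix_pop$syn_parent_families
  expect_true(all(apply(fams, 1, anyDuplicated) == 0))
  expect_error(
    simulate_breeding_population(n_families = 5, n_markers = 10, n_syn = 2,
                                 syn_parents = 8, seed = 1),
    "distinct F2 families"
  )
})

test_that("population simulation is reproducible for a fixed seed", {
  a <- simulate_breeding_population(n_families = 5, n_markers = 50,
                                    n_syn = 3, syn_parents = 3, seed = 77)
  b <- simulate_breeding_population(n_families = 5, n_markers = 50,
                                    n_syn = 3, syn_parents = 3, seed = 77)
  expect_identical(a$f2_freq, b$f2_freq)
  expect_identical(a$syn_freq, b$syn_freq)
  expect_identical(a$sp_geno, b$sp_geno)
})

test_that("degrade_matrix respects depth model, missingness and limits", {
  f <- fix_pop$f2_freq[1:10, 1:50]
  d5 <- degrade_matrix(f, 5, 0, seed = 1)
  expect_true(all(d5$depth == 5L))
  expect_false(anyNA(d5$freq))
  expect_true(all(abs(d5$freq * 5 - round(d5$freq * 5)) < 1e-12))

  dm <- degrade_matrix(f, 4, missing_fraction = 0.4, seed = 2)
  frac <- mean(dm$depth == 0)
  expect_lt(abs(frac - 0.4), 3 * sqrt(0.4 * 0.6 / length(f)) + 0.05)
  expect_true(all(is.na(dm$freq) == (dm$depth == 0)))

  dinf <- degrade_matrix(f, 1e6, 0, seed = 3)
  expect_lt(max(abs(dinf$freq - f)), 0.01)

  expect_error(degrade_matrix(f, 5, missing_fraction = 1, seed = 1), "\\[0, 1\\)")
  dfun <- degrade_matrix(f, function(n) sample(1:3, n, TRUE), 0, seed = 4)
  expect_true(all(dfun$depth %in% 1:3))
})

test_that("linked scaffolds show LD that decays with recombination", {
  r2w <- adjacent_r_squared(fix_linked$freq, within = TRUE)
  r2b <- adjacent_r_squared(fix_linked$freq, within = FALSE)
  expect_gt(r2w, 3 * r2b)

  r2 <- vapply(c(0.01, 0.1, 0.5), function(r) {
    lp <- simulate_linked_scaffolds(n_families = 80, n_scaffolds = 8,
                                    markers_per_scaffold = 12,
                                    recomb_prob = r, seed = 404)
    adjacent_r_squared(lp$freq, within = TRUE)
  }, numeric(1))
  expect_true(r2[1] > r2[2] && r2[2] > r2[3])

  lp_free <- simulate_linked_scaffolds(n_families = 120, n_scaffolds = 8,
                                       markers_per_scaffold = 12,
                                       recomb_prob = 0.5, seed = 405)
  expect_lt(abs(adjacent_r_squared(lp_free$freq, TRUE) -
                  adjacent_r_squared(lp_free$freq, FALSE)), 0.04)

  expect_error(simulate_linked_scaffolds(recomb_prob = 0.7, seed = 1),
               "\\[0, 0.5\\]")
})

test_that("perfect linkage means co-inheritance within scaffolds", {
  lp0 <- simulate_linked_scaffolds(n_families = 50, n_scaffolds = 6,
                                   markers_per_scaffold = 10,
                                   recomb_prob = 0, n_ancestral = 4,
                                   seed = 42)
  expect_gt(adjacent_r_squared(lp0$freq, TRUE), 0.3)
})

test_that("simulated phenotypes follow the GRM and heritability", {
  g <- compute_grm(fix_pop$sp_geno, 2)
  ph0 <- simulate_phenotypes(g, h2 = 0, n_reps = 2, seed = 1)
  expect_true(all(attr(ph0, "true_bv") == 0))

  ph9 <- simulate_phenotypes(g, h2 = 0.9, n_reps = 8, fixed_effect_sd = 0.5,
                             seed = 2)
  bv <- attr(ph9, "true_bv")
  means <- tapply(ph9$value, ph9$sample_id, mean)[names(bv)]
  expect_gt(cor(means, bv), 0.85)

  bad <- diag(3); bad[1, 1] <- -1
  rownames(bad) <- colnames(bad) <- c("a", "b", "c")
  expect_error(simulate_phenotypes(bad, 0.5, seed = 1), "positive semi")
  expect_error(simulate_phenotypes(g, h2 = 1, seed = 1), "\\[0, 1\\)")
})

test_that("drift sweep reports monotone-decreasing diagonals", {
  sw <- drift_sweep(sizes = c(5, 20), n_families = 60, n_markers = 300,
                    seed = 9)
  expect_equal(nrow(sw), 2)
  expect_gt(sw$mean_diagonal[1], sw$mean_diagonal[2])
  expect_gt(attr(sw, "drift_coefficient"), 0)
})
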