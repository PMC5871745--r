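test_that("centering removes marker means and rejects missing data", {
  f <- cbind(a = c(0.4, 0.4, 0.4), b = c(0, 1, 0.5))
  rownames(f) <- paste0("s", 1:3)
  cf <- center_frequencies(f)
  expect_equal(cf$M[, "a"], c(s1 = 0, s2 = 0, s3 = 0))
  expect_equal(unname(cf$col_means), c(0.4, 0.5))
  two <- center_frequencies(cbind(m = c(0, 1)))
  expect_equal(unname(two$M[, 1]), c(-0.5, 0.5))

  big <- fix_pop$f2_freq
  expect_lt(max(abs(colSums(center_frequencies(big)$M))),
            1e-10 * nrow(big))
  bigNA <- big; bigNA[1, 1] <- NA
  expect_error(center_frequencies(bigNA), "impute")
})

test_that("expected SNP variance follows the ploidy scaling law", {
  expect_equal(expected_snp_variance(0.5, 2), 0.125)
  expect_equal(expected_snp_variance(0.5, 4), 0.0625)
  pb <- runif(20)
  expect_equal(expected_snp_variance(pb, 8),
               expected_snp_variance(pb, 4) / 2)
  expect_error(expected_snp_variance(c(0, 1, 0), 2), "fixed")
})

test_that("GRM is symmetric with near-zero relationships among unrelated founders", {
  g <- compute_grm(fix_pop$founder_geno, reference_ploidy = 2)
  expect_lt(max(abs(g$matrix - t(g$matrix))), 1e-10)
  off <- g$matrix[lower.tri(g$matrix)]
  # centering induces a small negative mean of order -1/(n-1)
  expect_lt(abs(mean(off)), 0.02)
  expect_lt(abs(mean(diag(g$matrix)) - 1), 0.05)
  expect_true(all(diag(g$matrix) > 0))
})

test_that("analytic expected diagonals cover the breeding materials", {
  expect_equal(expected_grm_diagonal(2, 2, 0.25), 1.25)
  expect_equal(expected_grm_diagonal(2, 4, 0.25), 2.5)
  expect_equal(expected_grm_diagonal(4, 4, 0), 1)
  expect_equal(round(expected_grm_diagonal(12, 4, 0), 2), 0.33)
  expect_equal(expected_grm_diagonal(20, 4, 0), 0.2)
})

test_that("inflation fraction follows (n-1)/(depth+n-1) with its limits", {
  meta <- tibble::tibble(sample_id = c("a", "b", "c"),
                         ploidy = c(4L, 1L, 4L))
  dep <- matrix(c(3, 3, 3, 5, 5, 5, 100, 100, 100), 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), NULL))
  om <- binomial_inflation(meta, dep)
  expect_equal(unname(om$omega[om$sample_id == "a"]), 0.5)      # (4-1)/(3+3)
  expect_equal(unname(om$omega[om$sample_id == "b"]), 0)        # haploid
  expect_lt(om$omega[om$sample_id == "c"], 0.03)        # deep coverage

  # monotone decreasing in depth for fixed ploidy
  depths <- c(1, 2, 5, 10, 50)
  meta2 <- tibble::tibble(sample_id = paste0("s", seq_along(depths)),
                          ploidy = 4L)
  dep2 <- matrix(rep(depths, 4), ncol = 4,
                 dimnames = list(meta2$sample_id, NULL))
  om2 <- binomial_inflation(meta2, dep2)
  expect_true(all(diff(om2$omega) < 0))

  dep0 <- dep; dep0["b", ] <- 0
  expect_error(binomial_inflation(meta, dep0), "zero covered")
})

test_that("variance-component sums reduce to the closed form under constant depth", {
  f <- fix_pop$f2_freq[1:8, ]
  n <- 4
  for (d in c(2L, 7L)) {
    dep <- matrix(d, nrow(f), ncol(f), dimnames = dimnames(f))
    meta <- tibble::tibble(sample_id = rownames(f), ploidy = n)
    vc <- binomial_variance_components(f, dep, meta)
    expect_equal(vc$sigma2_bin / vc$sigma2_g, rep((n - 1) / d, nrow(f)),
                 tolerance = 1e-12)
    # plug-in inflation equals the closed form exactly
    expect_equal(vc$sigma2_bin / (vc$sigma2_bin + vc$sigma2_g),
                 rep((n - 1) / (d + n - 1), nrow(f)), tolerance = 1e-12)
    # F2 pools: binomial error carries the (1 - 1/4) = 3/4 coefficient
    expect_equal(vc$sigma2_bin,
                 0.75 * rowSums(f * (1 - f)) / d, ignore_attr = TRUE)
  }
  fixed <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("x", "y"), NULL))
  depf <- matrix(5L, 2, 2, dimnames = dimnames(fixed))
  vc0 <- binomial_variance_components(
    fixed, depf, tibble::tibble(sample_id = c("x", "y"), ploidy = 4)
  )
  expect_equal(vc0$sigma2_bin, c(0, 0))
  expect_equal(vc0$sigma2_g, c(0, 0))

  fNA <- f; dep <- matrix(3L, nrow(f), ncol(f), dimnames = dimnames(f))
  dep[1, 1] <- 0L
  expect_error(
    binomial_variance_components(fNA, dep,
                                 tibble::tibble(sample_id = rownames(f),
                                                ploidy = 4)),
    "masked as missing"
  )
})

test_that("diagonal correction deflates by omega and refuses re-application", {
  g <- compute_grm(fix_pop$f2_freq[1:10, ], 4)
  id <- rownames(g$matrix)
  g0 <- correct_diagonal(g, stats::setNames(rep(0, 10), id))
  expect_equal(g0$matrix, g$matrix)

  gg <- g
  gg$matrix[1, 1] <- 2.0
  gc <- correct_diagonal(gg, stats::setNames(rep(0.5, 10), id))
  expect_equal(gc$matrix[1, 1], 1.0)
  expect_equal(gc$matrix[lower.tri(gc$matrix)],
               gg$matrix[lower.tri(gg$matrix)])
  expect_true(gc$corrected)
  expect_error(correct_diagonal(gc, rep(0, 10)), "twice")
  expect_error(correct_diagonal(g, rep(1.2, 10)), "\\[0, 1\\)")
})

test_that("depth-degraded diagonals inflate by 1/(1-omega) and correct back", {
  # large families so that drift does not contaminate the binomial law
  f2 <- fix_deep$f2_freq
  meta <- sample_metadata(fix_deep, "F2")
  true_mean <- mean(diag(compute_grm(f2, 4)$matrix))
  for (d in c(1L, 5L)) {
    deg <- degrade_matrix(f2, d, 0, seed = 500 + d)
    g <- correct_diagonal(compute_grm(deg$freq, 4),
                          binomial_inflation(meta, deg$depth))
    omega <- 3 / (d + 3)
    sem_db <- sd(g$db) / sqrt(length(g$db))
    expect_lt(abs(mean(g$db) - true_mean / (1 - omega)),
              3 * sem_db + 0.02)
    dc <- diag(g$matrix)
    expect_lt(abs(mean(dc) - true_mean), 3 * sd(dc) / sqrt(length(dc)) + 0.01)
  }
})

test_that("per-material centering is available and changes the centering only", {
  f <- rbind(fix_pop$sp_geno[1:6, ], fix_pop$f2_freq[1:6, ])
  meta <- sample_metadata(fix_pop)
  gj <- compute_grm(f, 4)
  gp <- compute_grm(f, 4, centering = "per_material", meta = meta)
  expect_equal(gj$sigma2_g, gp$sigma2_g)  # scaling constant stays joint
  expect_false(isTRUE(all.equal(gj$matrix, gp$matrix)))
  expect_error(compute_grm(f, 4, centering = "per_material"), "meta")
})

test_that("tidiers and autoplot work on GRM objects", {
  g <- compute_grm(fix_pop$f2_freq[1:10, ], 4)
  td <- tidy(g)
  expect_named(td, c("sample_id", "diagonal"))
  gl <- glance(g)
  expect_equal(gl$n_samples, 10)
  expect_false(gl$corrected)
  p <- ggplot2::autoplot(g)
  expect_s3_class(p, "ggplot")
})
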