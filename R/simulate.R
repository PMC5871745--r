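#' Sample founder allele frequencies
#'
#' Draws per-marker founder allele frequencies from a Beta distribution.
#' Ryegrass GBS panels are dominated by low-frequency variants, which a
#' Beta(2, 8) emulates (mean 0.2); both shape parameters can be overridden.
#'
#' @param n_markers Number of markers to draw.
#' @param alpha,beta Beta shape parameters, both > 0.
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#' @return Numeric vector of length `n_markers` with values in (0, 1).
#' @examples
#' p <- sample_founder_frequencies(1000, seed = 1)
#' mean(p) # close to 2 / (2 + 8)
#' @export
sample_founder_frequencies <- function(n_markers, alpha = 2, beta = 8, seed) {
  stopifnot(n_markers >= 1)
  if (alpha <= 0 || beta <= 0) {
    stop("Beta shape parameters `alpha` and `beta` must be positive")
  }
  set.seed(seed)
  stats::rbeta(n_markers, alpha, beta)
}

#' Sample sequence reads at a marker
#'
#' Draws the alternative-allele read count at a locus as an exact
#' Binomial(depth, true_freq) sample, the generative model for pool-seq
#' allele-frequency estimates. The frequency estimate is the read ratio
#' `s_a / s_t`, missing when no reads were observed.
#'
#' @param true_freq True allele frequency (or frequencies), in \[0, 1\].
#' @param depth Total read count(s), non-negative; recycled against
#'   `true_freq`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `s_a`, `s_t`, `p_hat` (NA where `s_t == 0`).
#' @export
sample_reads <- function(true_freq, depth, seed = NULL) {
  stopifnot(all(true_freq >= 0 & true_freq <= 1))
  if (any(depth < 0)) stop("`depth` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  k <- max(length(true_freq), length(depth))
  p <- rep_len(true_freq, k)
  s_t <- as.integer(rep_len(depth, k))
  s_a <- stats::rbinom(k, s_t, p)
  tibble::tibble(
    s_a = s_a,
    s_t = s_t,
    p_hat = ifelse(s_t > 0, s_a / s_t, NA_real_)
  )
}

# One gamete per row: with unlinked markers, the transmitted allele count at a
# marker is Bernoulli(parent dosage), identical in law to picking one of the
# parent's two alleles at random. `dosage` is a (individuals x markers) matrix
# in {0, 0.5, 1} (or any value in [0,1] for pool-derived probabilities).
.gametes_from_dosage <- function(dosage) {
  matrix(
    stats::rbinom(length(dosage), 1L, as.vector(dosage)),
    nrow = nrow(dosage)
  )
}

# Draw `size` offspring from a parent dosage matrix by random union of
# gametes: each offspring picks two distinct parents uniformly.
.random_union_offspring <- function(parent_dosage, size) {
  n_par <- nrow(parent_dosage)
  idx <- t(vapply(seq_len(size), function(i) sample.int(n_par, 2L),
                  integer(2)))
  g1 <- .gametes_from_dosage(parent_dosage[idx[, 1], , drop = FALSE])
  g2 <- .gametes_from_dosage(parent_dosage[idx[, 2], , drop = FALSE])
  (g1 + g2) / 2
}

.marker_names <- function(n_markers, markers_per_scaffold) {
  scaf <- ceiling(seq_len(n_markers) / markers_per_scaffold)
  pos <- (seq_len(n_markers) - 1L) %% markers_per_scaffold * 500L + 1L
  paste0("scaf", scaf, ":", pos)
}

#' Simulate a multi-material ryegrass breeding population
#'
#' Generates unlinked SNP genotypes through the standard forage-grass breeding
#' funnel: unrelated founder pairs (allele frequencies Beta(`alpha`, `beta`)),
#' F1 full-sib families, F2 families produced by within-family crossing of F1
#' members, single plants (SPs) drawn from F2 members, and synthetic varieties
#' (SYNs) produced by polycrossing SPs taken from distinct F2 families. Family
#' pools are represented by their allele frequencies (mean member dosage).
#'
#' @param n_families Number of founder pairs / F1 / F2 families.
#' @param n_markers Number of unlinked SNP markers.
#' @param f1_size,f2_size Individuals per F1 and F2 family.
#' @param n_syn Number of synthetic varieties (0 to skip).
#' @param syn_parents Parents polycrossed per SYN; must not exceed
#'   `n_families` since each parent comes from a distinct F2 family.
#' @param syn_cross_size Progeny per parent slot; a SYN pool averages
#'   `syn_parents * syn_cross_size` progeny.
#' @param sp_per_family Single plants retained per F2 family.
#' @param alpha,beta Founder frequency Beta shape parameters.
#' @param markers_per_scaffold Markers assigned per (nominal) scaffold in the
#'   marker map. Markers are unlinked regardless; see
#'   [simulate_linked_scaffolds()] for linkage.
#' @param keep_members Keep per-family member dosage matrices (memory-heavy;
#'   intended for small validation runs). When `FALSE`, SYN pool frequencies
#'   are drawn by the distribution-identical aggregated per-parent binomial.
#' @param seed Integer seed (mandatory); output is reproducible bit-for-bit.
#' @return An object of class `breeding_pop`: founder, F1/F2/SYN pool
#'   frequency matrices, SP dosage matrix, marker map and sample metadata
#'   (see [sample_metadata()]).
#' @examples
#' pop <- simulate_breeding_population(n_families = 20, n_markers = 200,
#'                                     n_syn = 10, seed = 1)
#' pop
#' @export
simulate_breeding_population <- function(n_families = 300,
                                         n_markers = 5000,
                                         f1_size = 50,
                                         f2_size = 50,
                                         n_syn = 0,
                                         syn_parents = 8,
                                         syn_cross_size = 50,
                                         sp_per_family = 1,
                                         alpha = 2,
                                         beta = 8,
                                         markers_per_scaffold = 100,
                                         keep_members = FALSE,
                                         seed) {
  stopifnot(n_families >= 1, n_markers >= 1, f1_size >= 1, f2_size >= 1,
            n_syn >= 0, syn_cross_size >= 1, sp_per_family >= 1)
  if (sp_per_family > f2_size) {
    stop("`sp_per_family` cannot exceed `f2_size`")
  }
  if (n_syn > 0 && syn_parents > n_families) {
    stop("`syn_parents` must not exceed `n_families`: SYN parents are taken ",
         "from distinct F2 families")
  }
  set.seed(seed)

  m <- n_markers
  mk <- .marker_names(m, markers_per_scaffold)
  p <- stats::rbeta(m, alpha, beta)

  # Founder diploid dosages: allele count ~ Binomial(2, p) per parent.
  founder <- matrix(stats::rbinom(2L * n_families * m, 2L, rep(p, each = 2L * n_families)),
                    nrow = 2L * n_families) / 2
  rownames(founder) <- paste0(rep(c("P1_", "P2_"), n_families),
                              rep(sprintf("%03d", seq_len(n_families)), each = 2L))
  colnames(founder) <- mk

  # Pre-assign SYN parent draws so F2 member matrices need not be retained.
  syn_fam <- NULL
  syn_member <- NULL
  if (n_syn > 0) {
    syn_fam <- t(vapply(seq_len(n_syn),
                        function(s) sample.int(n_families, syn_parents),
                        integer(syn_parents)))
    syn_member <- matrix(sample.int(f2_size, n_syn * syn_parents, replace = TRUE),
                         nrow = n_syn)
  }

  f1_freq <- matrix(NA_real_, n_families, m)
  f2_freq <- matrix(NA_real_, n_families, m)
  sp_geno <- matrix(NA_real_, n_families * sp_per_family, m)
  sp_family <- rep(seq_len(n_families), each = sp_per_family)
  syn_parent_geno <- if (n_syn > 0) {
    lapply(seq_len(n_syn), function(s) matrix(NA_real_, syn_parents, m))
  }
  members <- if (keep_members) list(f1 = vector("list", n_families),
                                    f2 = vector("list", n_families))

  for (f in seq_len(n_families)) {
    mom <- founder[2L * f - 1L, ]
    dad <- founder[2L * f, ]
    f1 <- (matrix(stats::rbinom(f1_size * m, 1L, rep(mom, each = f1_size)), f1_size) +
           matrix(stats::rbinom(f1_size * m, 1L, rep(dad, each = f1_size)), f1_size)) / 2
    f2 <- .random_union_offspring(f1, f2_size)
    f1_freq[f, ] <- colMeans(f1)
    f2_freq[f, ] <- colMeans(f2)
    sp_geno[sp_family == f, ] <- f2[sample.int(f2_size, sp_per_family), , drop = FALSE]
    if (n_syn > 0) {
      hits <- which(syn_fam == f, arr.ind = TRUE)
      for (r in seq_len(nrow(hits))) {
        s <- hits[r, 1]
        slot <- hits[r, 2]
        syn_parent_geno[[s]][slot, ] <- f2[syn_member[s, slot], ]
      }
    }
    if (keep_members) {
      members$f1[[f]] <- f1
      members$f2[[f]] <- f2
    }
  }

  syn_freq <- NULL
  syn_members <- if (keep_members && n_syn > 0) vector("list", n_syn)
  if (n_syn > 0) {
    syn_freq <- matrix(NA_real_, n_syn, m)
    n_prog <- syn_parents * syn_cross_size
    for (s in seq_len(n_syn)) {
      par_geno <- syn_parent_geno[[s]]
      if (keep_members) {
        prog <- .random_union_offspring(par_geno, n_prog)
        syn_freq[s, ] <- colMeans(prog)
        syn_members[[s]] <- prog
      } else {
        # Aggregated draw: progeny pick two distinct parents each; given the
        # per-parent gamete-slot counts, the pool allele total is a sum of
        # per-parent Binomial(slots, dosage) draws.
        pairs <- vapply(seq_len(n_prog),
                        function(i) sample.int(syn_parents, 2L), integer(2))
        slots <- tabulate(pairs, nbins = syn_parents)
        tot <- numeric(m)
        for (q in seq_len(syn_parents)) {
          if (slots[q] > 0) {
            tot <- tot + stats::rbinom(m, slots[q], par_geno[q, ])
          }
        }
        syn_freq[s, ] <- tot / (2 * n_prog)
      }
    }
  }

  fam_id <- sprintf("%03d", seq_len(n_families))
  dimnames(f1_freq) <- list(paste0("F1_", fam_id), mk)
  dimnames(f2_freq) <- list(paste0("F2_", fam_id), mk)
  rownames(sp_geno) <- paste0("SP_", sprintf("%03d", sp_family),
                              if (sp_per_family > 1) {
                                paste0("_", sequence(rep(sp_per_family, n_families)))
                              } else "")
  colnames(sp_geno) <- mk
  if (n_syn > 0) {
    dimnames(syn_freq) <- list(paste0("SYN_", sprintf("%03d", seq_len(n_syn))), mk)
  }

  structure(
    list(
      founder_freq = stats::setNames(p, mk),
      founder_geno = founder,
      f1_freq = f1_freq,
      f2_freq = f2_freq,
      sp_geno = sp_geno,
      sp_family = sp_family,
      syn_freq = syn_freq,
      syn_parent_families = syn_fam,
      members = members,
      syn_members = syn_members,
      marker_map = marker_map_from_ids(mk),
      params = list(n_families = n_families, n_markers = n_markers,
                    f1_size = f1_size, f2_size = f2_size, n_syn = n_syn,
                    syn_parents = syn_parents, syn_cross_size = syn_cross_size,
                    sp_per_family = sp_per_family, alpha = alpha, beta = beta,
                    seed = seed)
    ),
    class = "breeding_pop"
  )
}

#' @exportS3Method base::print
print.breeding_pop <- function(x, ...) {
  p <- x$params
  cat("Simulated breeding population\n")
  cat("  families:", p$n_families, " markers:", p$n_markers, "\n")
  cat("  F1/F2 family size:", p$f1_size, "/", p$f2_size,
      "  SPs per family:", p$sp_per_family, "\n")
  if (p$n_syn > 0) {
    cat("  SYNs:", p$n_syn, "(", p$syn_parents, "parents,",
        p$syn_parents * p$syn_cross_size, "progeny each )\n")
  }
  invisible(x)
}

#' Sample metadata for a simulated population
#'
#' Material classes carry the assumed ploidy used in GRM scaling: 2 for single
#' plants, 4 for F2 family pools (two diploid parents), and `2 * n_parents`
#' for synthetic varieties.
#'
#' @param population A `breeding_pop` object.
#' @param materials Materials to include, subset of `c("SP", "F2", "SYN")`.
#' @return A tibble with columns `sample_id`, `material`, `ploidy`,
#'   `n_parents`, `family`.
#' @export
sample_metadata <- function(population, materials = c("SP", "F2", "SYN")) {
  stopifnot(inherits(population, "breeding_pop"))
  materials <- match.arg(materials, several.ok = TRUE)
  out <- list()
  if ("SP" %in% materials) {
    out$sp <- tibble::tibble(
      sample_id = rownames(population$sp_geno),
      material = "SP", ploidy = 2L, n_parents = 2L,
      family = population$sp_family
    )
  }
  if ("F2" %in% materials) {
    out$f2 <- tibble::tibble(
      sample_id = rownames(population$f2_freq),
      material = "F2", ploidy = 4L, n_parents = 2L,
      family = seq_len(nrow(population$f2_freq))
    )
  }
  if ("SYN" %in% materials && !is.null(population$syn_freq)) {
    np <- population$params$syn_parents
    out$syn <- tibble::tibble(
      sample_id = rownames(population$syn_freq),
      material = "SYN", ploidy = 2L * np, n_parents = np,
      family = NA_integer_
    )
  }
  dplyr::bind_rows(out)
}

#' Degrade a frequency matrix by finite-depth read sampling
#'
#' Replaces true allele frequencies with read-ratio estimates obtained by
#' binomial sampling at a given coverage depth, optionally knocking out a
#' fraction of entries as missing (depth 0).
#'
#' @param freq Samples x markers matrix of true frequencies in \[0, 1\].
#' @param depth Either a single fixed depth, a matrix of per-entry depths
#'   matching `freq`, or a function `function(n)` returning `n` integer
#'   depths.
#' @param missing_fraction Fraction of entries set missing, in \[0, 1).
#' @param seed Integer seed.
#' @return A list with elements `freq` (estimates, NA where missing) and
#'   `depth` (integer matrix, 0 where missing).
#' @export
degrade_matrix <- function(freq, depth, missing_fraction = 0, seed) {
  stopifnot(is.matrix(freq), all(freq >= 0 & freq <= 1, na.rm = TRUE))
  if (missing_fraction < 0 || missing_fraction >= 1) {
    stop("`missing_fraction` must be in [0, 1)")
  }
  set.seed(seed)
  n <- length(freq)
  d <- if (is.function(depth)) {
    as.integer(depth(n))
  } else if (is.matrix(depth)) {
    stopifnot(all(dim(depth) == dim(freq)))
    as.integer(depth)
  } else {
    stopifnot(length(depth) == 1, depth >= 0)
    rep.int(as.integer(depth), n)
  }
  if (any(d < 0)) stop("depths must be non-negative")
  if (missing_fraction > 0) {
    d[stats::runif(n) < missing_fraction] <- 0L
  }
  s_a <- stats::rbinom(n, d, as.vector(freq))
  est <- ifelse(d > 0, s_a / d, NA_real_)
  list(
    freq = matrix(est, nrow(freq), dimnames = dimnames(freq)),
    depth = matrix(d, nrow(freq), dimnames = dimnames(freq))
  )
}

#' Drift sweep: F2 pool GRM diagonal versus family size
#'
#' Re-simulates the breeding population at a range of family sizes (applied
#' to both the F1 and F2 generations) and records the mean own-ploidy GRM
#' diagonal of the F2 pools computed from true frequencies. Small families
#' inflate the diagonal through genetic drift and pool-level gamete
#' sampling; the inflation decays roughly as 1/size.
#'
#' @param sizes Family sizes to test.
#' @param n_families,n_markers Simulation dimensions per size.
#' @param tolerance Relative deviation from 1.0 below which drift is deemed
#'   negligible.
#' @param seed Integer seed (each size uses a sub-seed derived from it).
#' @return A tibble with `size`, `mean_diagonal`, `sem`; the smallest tested
#'   size whose mean diagonal is within `tolerance` of 1.0 is attached as
#'   attribute `"negligible_size"` (NA when no tested size qualifies), and a
#'   1 + a/size least-squares fit of the inflation as `"drift_coefficient"`.
#' @export
drift_sweep <- function(sizes = c(5, 10, 25, 50, 100), n_families = 300,
                        n_markers = 5000, tolerance = 0.01, seed) {
  stopifnot(length(sizes) >= 1, all(sizes >= 2))
  res <- lapply(seq_along(sizes), function(k) {
    s <- sizes[k]
    pop <- simulate_breeding_population(
      n_families = n_families, n_markers = n_markers,
      f1_size = s, f2_size = s, seed = seed + 1000L * k
    )
    d <- diag(compute_grm(pop$f2_freq, reference_ploidy = 4)$matrix)
    tibble::tibble(size = s, mean_diagonal = mean(d),
                   sem = stats::sd(d) / sqrt(length(d)))
  })
  out <- dplyr::bind_rows(res)
  ok <- out$size[abs(out$mean_diagonal - 1) <= tolerance]
  # inflation ~ a/size fit, usable to extrapolate where the bound is reached
  a <- sum((out$mean_diagonal - 1) / out$size) / sum(1 / out$size^2)
  attr(out, "negligible_size") <- if (length(ok)) min(ok) else NA_real_
  attr(out, "drift_coefficient") <- a
  out
}
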