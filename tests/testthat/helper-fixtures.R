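# Shared fixtures, built once per test run. Sizes are kept small; the
# acceptance suite re-simulates at the study scale.

# Member-retaining population for invariant checks.
fix_pop <- simulate_breeding_population(
  n_families = 40, n_markers = 400, f1_size = 20, f2_size = 20,
  n_syn = 15, syn_parents = 6, syn_cross_size = 20,
  keep_members = TRUE, seed = 101
)

# Large-family population: drift suppressed, used for depth-bias checks.
fix_deep <- simulate_breeding_population(
  n_families = 50, n_markers = 500, f1_size = 300, f2_size = 300,
  seed = 202
)

# Linked scaffolds for imputation.
fix_linked <- simulate_linked_scaffolds(
  n_families = 80, n_scaffolds = 16, markers_per_scaffold = 15,
  recomb_prob = 0.02, seed = 303
)

# A small complete frequency matrix with scaffold-named markers.
make_freq <- function(n = 12, m = 9, n_scaf = 3, seed = 1) {
  set.seed(seed)
  f <- matrix(runif(n * m), n, m)
  scaf <- rep(seq_len(n_scaf), each = ceiling(m / n_scaf))[seq_len(m)]
  dimnames(f) <- list(paste0("s", seq_len(n)),
                      paste0("scaf", scaf, ":", seq_len(m)))
  f
}

# Minimal VCF text with AD fields: 3 samples, 4 sites (one triallelic).
write_fixture_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=scaf1>",
    "##contig=<ID=scaf2>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "p1", "p2", "p3", sep = "\t"),
    paste("scaf1", "101", ".", "A", "G", ".", "PASS", ".", "GT:AD",
          "0/1:3,1", "0/0:5,0", "1/1:0,4", sep = "\t"),
    paste("scaf1", "250", ".", "C", "T", ".", "PASS", ".", "GT:AD",
          "./.:0,0", "0/1:2,2", "0/1:1,3", sep = "\t"),
    paste("scaf2", "77", ".", "G", "A,T", ".", "PASS", ".", "GT:AD",
          "0/1:1,1,1", "0/0:2,0,0", "0/0:2,1,0", sep = "\t"),
    paste("scaf2", "300", ".", "T", "C", ".", "PASS", ".", "GT:AD",
          "0/1:5,5", "0/1:4,6", "0/0:9,1", sep = "\t")
  )
  writeLines(lines, path)
  path
}
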