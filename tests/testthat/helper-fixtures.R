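# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# Small genotype matrix with known dosages.
make_gm <- function(dosage, depth = NULL, samples = NULL, loci = NULL) {
  m <- as.matrix(dosage)
  if (!is.null(samples)) rownames(m) <- samples
  if (!is.null(loci)) colnames(m) <- loci
  if (!is.null(depth)) depth <- matrix(depth, nrow = nrow(m))
  geno_matrix(m, depth = depth)
}

# Random genotype matrix with missingness, for brute-force comparisons.
random_gm <- function(n_samples, n_loci, miss = 0.1, depth = FALSE) {
  m <- matrix(sample(0:2, n_samples * n_loci, replace = TRUE),
              nrow = n_samples)
  m[matrix(runif(length(m)) < miss, nrow = n_samples)] <- NA_integer_
  dp <- if (depth) matrix(rpois(length(m), 35), nrow = n_samples)
  make_gm(m, depth = dp)
}

# Parental frequency table with all loci fixed for alternative alleles.
fixed_freqs <- function(n_loci) {
  tibble::tibble(locus_id = paste0("l", seq_len(n_loci)),
                 p1 = rep(0, n_loci), p2 = rep(1, n_loci),
                 fixed_diff = TRUE, informative = TRUE)
}

# Genotypes of an n-generation backcross toward P1 from fixed-difference
# parents: start at F1 (all heterozygous) and cross to the all-0 parent.
bx_toward_p1 <- function(n_gen, n_loci) {
  g <- rep(1L, n_loci)
  for (i in seq_len(n_gen)) g <- breed(g, rep(0L, n_loci))
  g
}

# Alignment fixture with independently verified statistics:
# S = 3, mean pairwise differences 1.6, Tajima's D 0.6989954,
# R2 0.2403701, singletons (0,0,0,0,1).
oracle_alignment <- function() {
  seqs <- c("ACGTACGTAC", "ACGTACGTAT", "ACGAACGTAC", "ACGAACGTAT",
            "ACGTACGGAC")
  hap_alignment(do.call(rbind, strsplit(seqs, "")))
}

# Two-population dosage fixture with independently computed
# Weir-Cockerham theta 0.1841155 and Jost's D 0.1854978.
oracle_two_pops <- function() {
  dos <- rbind(c(0, 1, 2), c(1, 1, 0), c(2, 0, 1), c(0, 1, 1),
               c(2, 2, 1), c(1, 2, 0), c(2, 1, 1), c(2, 2, 2), c(1, 2, 1))
  gm <- make_gm(dos, samples = paste0("s", 1:9))
  samples <- tibble::tibble(id = paste0("s", 1:9),
                            species_morph = rep(c("a", "b"), c(4, 5)),
                            population = rep(c("pop1", "pop2"), c(4, 5)))
  list(gm = gm, samples = samples)
}
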