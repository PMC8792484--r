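#' Configuration for the two-species hybrid-zone simulator
#'
#' Defines a synthetic dataset with the statistical structure of a
#' two-species deer hybrid zone genotyped at unlinked biallelic ddRAD SNPs
#' plus an aligned mitochondrial fragment. Species 1 plays the mule-deer
#' role (hybrid index 0), species 2 the white-tailed-deer role (hybrid index
#' 1). Defaults emulate the study system: ~25k SNPs across 92 individuals of
#' which a small minority are multi-generation backcrosses, strong
#' between-species divergence with a fraction of fixed differences, a
#' 1103-bp mitochondrial alignment in two clades, and frequent
#' "mitochondrial capture" of species-2 haplotypes by species-1 individuals.
#'
#' @param n_loci Number of biallelic SNP loci.
#' @param frac_fixed Fraction of loci fixed for alternative alleles between
#'   the species.
#' @param fst_target Divergence scale of the remaining loci: they are drawn
#'   from a Balding-Nichols model whose F parameter equals this value.
#' @param n_per_class Named integer vector of individuals per pedigree class.
#'   Names follow `P1`, `P2`, `F1`, `F2`, `BX<n>_P1`, `BX<n>_P2` (an n-th
#'   generation backcross toward that parent).
#' @param missing_rate Per-genotype probability of a missing call.
#' @param depth_mean,depth_size Mean and dispersion of the negative-binomial
#'   per-genotype read depth (mean 40 leaves the depth-20 mask real work).
#' @param mt_length Length (bp) of the mitochondrial alignment.
#' @param mt_diag_sites Number of fixed clade-diagnostic substitutions
#'   separating the two mitochondrial clades.
#' @param mt_private_mean Mean number of private mutations per haplotype
#'   (Poisson), creating within-clade haplotype diversity.
#' @param capture_prob Probability that a species-1 individual carries a
#'   clade-2 (captured) haplotype. The default reflects a zone where more
#'   than half of species-1 matrilines descend from species-2 females.
#' @param hybrid_maternal Which parental species is the female parent of
#'   pedigree hybrids (`"P1"` or `"P2"`); hybrids inherit that lineage's
#'   mitochondrial clade.
#' @param seed RNG seed; identical configurations give bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 25018, frac_fixed = 0.05, fst_target = 0.4,
                       n_per_class = c(P1 = 42, P2 = 42, BX3_P1 = 4, BX3_P2 = 4),
                       missing_rate = 0.03, depth_mean = 40, depth_size = 8,
                       mt_length = 1103, mt_diag_sites = 25,
                       mt_private_mean = 2, capture_prob = 0.58,
                       hybrid_maternal = "P2", seed = 1L) {
  stopifnot(n_loci > 0, frac_fixed >= 0, frac_fixed <= 1, fst_target >= 0,
            fst_target < 1, length(n_per_class) > 0, all(n_per_class > 0),
            missing_rate >= 0, missing_rate < 1, mt_diag_sites < mt_length,
            capture_prob >= 0, capture_prob <= 1,
            hybrid_maternal %in% c("P1", "P2"))
  cfg <- as.list(environment())
  bad <- !grepl("^(P1|P2|F1|F2|BX[0-9]+_P[12])$", names(n_per_class))
  if (any(bad)) stop("unknown pedigree class: ",
                     paste(names(n_per_class)[bad], collapse = ", "))
  structure(cfg, class = "sim_config")
}

#' Draw per-locus parental allele frequencies
#'
#' A fraction `frac_fixed` of loci are fixed for alternative alleles between
#' the species ((p1, p2) = (0, 1) or (1, 0), alternating deterministically);
#' the remainder take a shared ancestral frequency from Uniform(0.05, 0.95)
#' and species frequencies from the Balding-Nichols beta distribution with
#' F = `fst_target` (both frequencies equal the ancestral one when
#' `fst_target` is 0).
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `locus_id`, `p1`, `p2`, `fixed_diff`.
#' @export
build_parental_freqs <- function(cfg) {
  n <- cfg$n_loci
  n_fixed <- round(cfg$frac_fixed * n)
  anc <- stats::runif(n, 0.05, 0.95)
  if (cfg$fst_target > 0) {
    f <- cfg$fst_target
    shape <- (1 - f) / f
    p1 <- stats::rbeta(n, anc * shape, (1 - anc) * shape)
    p2 <- stats::rbeta(n, anc * shape, (1 - anc) * shape)
  } else {
    p1 <- p2 <- anc
  }
  if (n_fixed > 0) {
    idx <- seq_len(n_fixed)
    p1[idx] <- rep_len(c(0, 1), n_fixed)
    p2[idx] <- 1 - p1[idx]
  }
  tibble::tibble(locus_id = sprintf("tag%06d_01", seq_len(n)),
                 p1 = p1, p2 = p2,
                 fixed_diff = seq_len(n) <= n_fixed)
}

#' Sample parental genotypes under Hardy-Weinberg
#'
#' Genotypes are independent Binomial(2, p) draws per locus, with p the
#' allele frequency of the requested species.
#'
#' @param freqs Parental-frequency tibble from [build_parental_freqs()] or
#'   [estimate_parental_freqs()].
#' @param n Number of individuals.
#' @param which `"P1"` or `"P2"`.
#' @return Integer dosage matrix, `n` x loci.
#' @export
sample_parental_genotypes <- function(freqs, n, which = c("P1", "P2")) {
  which <- match.arg(which)
  p <- if (which == "P1") freqs$p1 else freqs$p2
  L <- length(p)
  m <- matrix(stats::rbinom(n * L, 2L, rep(p, each = n)), nrow = n)
  colnames(m) <- freqs$locus_id
  m
}

#' Mendelian cross of two diploid genotype vectors
#'
#' One allele is drawn uniformly from each parent's two alleles at every
#' locus, independently across loci (no linkage).
#'
#' @param parent_a,parent_b Integer dosage vectors over the same loci.
#' @return Integer offspring dosage vector.
#' @export
breed <- function(parent_a, parent_b) {
  if (length(parent_a) != length(parent_b)) stop("mismatched locus sets")
  stats::rbinom(length(parent_a), 1L, parent_a / 2) +
    stats::rbinom(length(parent_b), 1L, parent_b / 2)
}

# Draw one individual of a pedigree class from the parental frequencies.
sample_class_genotype <- function(freqs, class) {
  draw <- function(which) drop(sample_parental_genotypes(freqs, 1L, which))
  f1 <- function() breed(draw("P1"), draw("P2"))
  if (class == "P1") return(draw("P1"))
  if (class == "P2") return(draw("P2"))
  if (class == "F1") return(f1())
  if (class == "F2") return(breed(f1(), f1()))
  m <- regmatches(class, regexec("^BX([0-9]+)_(P[12])$", class))[[1]]
  if (length(m) == 0) stop("unknown pedigree class: ", class)
  n_bx <- as.integer(m[2]); par <- m[3]
  g <- f1()
  for (i in seq_len(n_bx)) g <- breed(g, draw(par))
  g
}

#' Simulate genotypes for a table of pedigree classes
#'
#' @param freqs Parental-frequency tibble.
#' @param n_per_class Named counts of individuals per pedigree class.
#' @return A list with `gm` (integer dosage matrix, individuals x loci) and
#'   `samples` (tibble of `id`, `true_class`).
#' @export
simulate_pedigree <- function(freqs, n_per_class) {
  rows <- list(); ids <- character(); classes <- character()
  for (cl in names(n_per_class)) {
    for (i in seq_len(n_per_class[[cl]])) {
      rows[[length(rows) + 1L]] <- sample_class_genotype(freqs, cl)
      ids <- c(ids, sprintf("%s_%02d", cl, i))
      classes <- c(classes, cl)
    }
  }
  gm <- do.call(rbind, rows)
  rownames(gm) <- ids
  colnames(gm) <- freqs$locus_id
  list(gm = gm, samples = tibble::tibble(id = ids, true_class = classes))
}

class_species <- function(class, hybrid_maternal) {
  dplyr::case_when(
    class == "P1" | grepl("_P1$", class) ~ "species1",
    class == "P2" | grepl("_P2$", class) ~ "species2",
    TRUE ~ if (hybrid_maternal == "P1") "species1" else "species2"
  )
}

#' Simulate the mitochondrial haplotype alignment
#'
#' Two clades separated by `mt_diag_sites` fixed substitutions; every
#' haplotype additionally carries a Poisson number of private mutations at
#' non-diagnostic sites. Clade membership: species-2 individuals carry
#' clade-2 haplotypes; species-1 individuals carry clade-2 ("captured")
#' haplotypes with probability `capture_prob`, otherwise clade 1. Pedigree
#' hybrids inherit the clade of their maternal species, capture included.
#'
#' @param cfg A [sim_config()].
#' @param samples Tibble with columns `id` and `true_class`.
#' @return A list with `aln` (a [hap_alignment()]) and `mt_clade`, the
#'   per-individual clade labels (`"clade1"`/`"clade2"`).
#' @export
simulate_mtdna <- function(cfg, samples) {
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, cfg$mt_length, replace = TRUE)
  diag_sites <- sample.int(cfg$mt_length, cfg$mt_diag_sites)
  clade2_hap <- anc
  clade2_hap[diag_sites] <- vapply(anc[diag_sites], function(b)
    sample(setdiff(bases, b), 1L), character(1))
  maternal_sp <- class_species(samples$true_class, cfg$hybrid_maternal)
  captured <- stats::runif(nrow(samples)) < cfg$capture_prob
  clade <- ifelse(maternal_sp == "species2" | captured, "clade2", "clade1")
  free_sites <- setdiff(seq_len(cfg$mt_length), diag_sites)
  aln <- matrix("", nrow(samples), cfg$mt_length,
                dimnames = list(samples$id, NULL))
  for (i in seq_len(nrow(samples))) {
    h <- if (clade[i] == "clade2") clade2_hap else anc
    k <- stats::rpois(1L, cfg$mt_private_mean)
    if (k > 0) {
      at <- sample(free_sites, min(k, length(free_sites)))
      h[at] <- vapply(h[at], function(b) sample(setdiff(bases, b), 1L),
                      character(1))
    }
    aln[i, ] <- h
  }
  list(aln = hap_alignment(aln), mt_clade = clade)
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs the full simulator under `cfg$seed` and writes three files to
#' `out_dir`: `genotypes.vcf` (GT:DP, with negative-binomial read depths and
#' random missingness), `mtdna.fasta`, and `samples.tsv` (columns `id`,
#' `species_morph`, `population`, `true_class`, `mt_clade`; populations
#' alternate N/S within each class). Identical configurations produce
#' byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return A list with the three `paths` and the in-memory objects
#'   (`gm`, `samples`, `aln`, `freqs`).
#' @export
generate_dataset <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  freqs <- build_parental_freqs(cfg)
  ped <- simulate_pedigree(freqs, cfg$n_per_class)
  dos <- ped$gm
  depth <- matrix(stats::rnbinom(length(dos), mu = cfg$depth_mean,
                                 size = cfg$depth_size),
                  nrow = nrow(dos), dimnames = dimnames(dos))
  miss <- matrix(stats::runif(length(dos)) < cfg$missing_rate, nrow = nrow(dos))
  dos[miss] <- NA_integer_
  gm <- geno_matrix(dos, chrom = rep("1", ncol(dos)),
                    pos = seq_len(ncol(dos)) * 100L, depth = depth)
  mt <- simulate_mtdna(cfg, ped$samples)
  samples <- dplyr::mutate(
    ped$samples,
    species_morph = class_species(.data$true_class, cfg$hybrid_maternal),
    population = stats::ave(seq_along(.data$id), .data$true_class,
                            FUN = function(i) c("N", "S")[(seq_along(i) + 1) %% 2 + 1]),
    mt_clade = mt$mt_clade
  )
  samples <- samples[, c("id", "species_morph", "population", "true_class",
                         "mt_clade")]
  paths <- list(vcf = file.path(out_dir, "genotypes.vcf"),
                fasta = file.path(out_dir, "mtdna.fasta"),
                samples = file.path(out_dir, "samples.tsv"))
  write_vcf(gm, paths$vcf)
  write_fasta(mt$aln, paths$fasta)
  write_sample_table(samples, paths$samples)
  list(paths = paths, gm = gm, samples = samples, aln = mt$aln, freqs = freqs)
}
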