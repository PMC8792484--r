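#' Per-population nuclear diversity summaries
#'
#' Computes, for each population, the standard SNP diversity panel: sample
#' size, number of polymorphic sites, private alleles, mean number of
#' alleles (N_A), mean effective number of alleles (N_E = 1/(p^2+q^2)),
#' observed and unbiased expected heterozygosity, per-SNP nucleotide
#' diversity, and the inbreeding coefficient F_IS = 1 - H_O/H_E averaged
#' over polymorphic loci.
#'
#' All per-locus quantities use called genotypes only. Unbiased expected
#' heterozygosity applies the 2n/(2n-1) small-sample correction; at a
#' biallelic SNP this equals the mean pairwise difference, so `pi` is
#' reported per SNP. Private alleles are alleles observed in one population
#' and in no other.
#'
#' @param gm A [geno_matrix()].
#' @param samples Sample tibble with an `id` column matching `gm`.
#' @param by Name of the grouping column in `samples` (default
#'   `"population"`).
#' @return A tibble with one row per population and columns `population`,
#'   `n`, `n_poly`, `a_private`, `n_a`, `n_e`, `h_o`, `h_e`, `pi`, `f_is`.
#' @export
nuclear_diversity <- function(gm, samples, by = "population") {
  groups <- split_samples(gm, samples, by)
  # allele presence per population for private-allele counting
  presence <- lapply(groups, function(idx) {
    d <- gm$dosage[idx, , drop = FALSE]
    rbind(ref = colSums(d < 2L, na.rm = TRUE) > 0,
          alt = colSums(d > 0L, na.rm = TRUE) > 0)
  })
  purrr::imap_dfr(groups, function(idx, pop) {
    d <- gm$dosage[idx, , drop = FALSE]
    if (length(idx) < 2) stop("population ", pop, " has fewer than 2 individuals")
    n_called <- colSums(!is.na(d))
    ok <- n_called > 0
    p <- colMeans(d, na.rm = TRUE)[ok] / 2
    nn <- n_called[ok]
    ho <- colMeans(d == 1L, na.rm = TRUE)[ok]
    he <- 2 * p * (1 - p) * (2 * nn) / (2 * nn - 1)
    poly <- p > 0 & p < 1
    n_a <- ifelse(poly, 2, 1)
    n_e <- 1 / (p^2 + (1 - p)^2)
    fis_l <- 1 - ho[poly] / he[poly]
    other_pops <- setdiff(names(groups), pop)
    here <- presence[[pop]][, ok, drop = FALSE]
    if (length(other_pops)) {
      others <- Reduce(`|`, lapply(presence[other_pops],
                                   function(m) m[, ok, drop = FALSE]))
      a_priv <- sum(here & !others)
    } else {
      a_priv <- sum(here)
    }
    tibble::tibble(population = pop, n = length(idx), n_poly = sum(poly),
                   a_private = a_priv, n_a = mean(n_a), n_e = mean(n_e),
                   h_o = mean(ho), h_e = mean(he), pi = mean(he),
                   f_is = mean(fis_l))
  })
}

split_samples <- function(gm, samples, by) {
  if (!by %in% names(samples)) stop("no column `", by, "` in samples")
  idx <- match(samples$id, sample_ids(gm))
  keep <- !is.na(idx)
  split(idx[keep], samples[[by]][keep])
}

# Weir & Cockerham (1984) variance components at one biallelic locus for a
# set of populations: n_i called diploids, p_i alt frequencies, h_i observed
# heterozygote fractions. Returns c(a, b, c).
wc_components <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

pop_locus_summaries <- function(gm, idx) {
  d <- gm$dosage[idx, , drop = FALSE]
  list(n = colSums(!is.na(d)),
       p = colMeans(d, na.rm = TRUE) / 2,
       h = colMeans(d == 1L, na.rm = TRUE))
}

#' Pairwise population differentiation (Weir-Cockerham FST and Jost's D)
#'
#' FST is the Weir & Cockerham (1984) theta, combined across loci as the
#' ratio of summed variance components. Jost's D uses Nei-Chesser
#' sample-size-corrected gene diversities per locus, averaged across loci
#' before the ratio (global estimator):
#' D = (Ht - Hs) / (1 - Hs) * k/(k-1) with k = 2 populations.
#'
#' @param gm A [geno_matrix()].
#' @param samples Sample tibble with `id` and the grouping column.
#' @param by Grouping column name (default `"population"`).
#' @return A tibble of unordered population pairs with columns `pop_a`,
#'   `pop_b`, `fst`, `jost_d`.
#' @export
pairwise_differentiation <- function(gm, samples, by = "population") {
  groups <- split_samples(gm, samples, by)
  if (length(groups) < 2) stop("need at least two populations")
  small <- names(groups)[lengths(groups) < 2]
  if (length(small)) stop("populations with fewer than 2 individuals: ",
                          paste(small, collapse = ", "))
  sums <- lapply(groups, function(idx) pop_locus_summaries(gm, idx))
  pairs <- utils::combn(names(groups), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- sums[[pairs[1, k]]]; b <- sums[[pairs[2, k]]]
    ok <- a$n > 0 & b$n > 0
    tibble::tibble(
      pop_a = pairs[1, k], pop_b = pairs[2, k],
      fst = fst_from_summaries(a, b, ok),
      jost_d = jost_from_summaries(a, b, ok)
    )
  })
}

fst_from_summaries <- function(a, b, ok) {
  comps <- vapply(which(ok), function(l)
    wc_components(c(a$n[l], b$n[l]), c(a$p[l], b$p[l]), c(a$h[l], b$h[l])),
    numeric(3))
  tot <- rowSums(comps)
  unname(tot["a"] / sum(tot))
}

jost_from_summaries <- function(a, b, ok) {
  n1 <- a$n[ok]; n2 <- b$n[ok]
  p1 <- a$p[ok]; p2 <- b$p[ok]
  n_harm <- 2 / (1 / n1 + 1 / n2)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  hs_est <- (2 * n_harm / (2 * n_harm - 1)) * hs
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  ht_est <- ht + hs_est / (2 * n_harm * 2)
  hs_bar <- mean(hs_est); ht_bar <- mean(ht_est)
  if (hs_bar >= 1) stop("Jost's D undefined: mean within-population gene diversity is 1")
  max(0, (ht_bar - hs_bar) / (1 - hs_bar) * 2)
}

## ---- mitochondrial sequence statistics --------------------------------

valid_base <- function(m) m %in% c("A", "C", "G", "T")

#' Haplotype and nucleotide diversity of an alignment
#'
#' @param aln A [hap_alignment()].
#' @return A one-row tibble with `n`, `h` (distinct haplotypes), `s`
#'   (segregating sites among gap/N-free columns), `hd` (unbiased haplotype
#'   diversity, n/(n-1) (1 - sum p_i^2)) and `pi` (mean pairwise difference
#'   per site, gap/N sites excluded pairwise).
#' @export
mtdna_summary <- function(aln) {
  n <- nrow(aln)
  if (n < 2) stop("need at least 2 sequences")
  haps <- apply(aln, 1, paste0, collapse = "")
  freqs <- table(haps) / n
  hd <- n / (n - 1) * (1 - sum(freqs^2))
  tibble::tibble(n = n, h = length(freqs), s = count_segregating(aln),
                 hd = hd, pi = mean_pairwise_diff(aln, per_site = TRUE))
}

count_segregating <- function(aln) {
  complete <- apply(aln, 2, function(col) all(valid_base(col)))
  sum(apply(aln[, complete, drop = FALSE], 2,
            function(col) length(unique(col)) > 1))
}

mean_pairwise_diff <- function(aln, per_site = FALSE) {
  n <- nrow(aln)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- valid_base(aln[i, ]) & valid_base(aln[j, ])
    d <- sum(aln[i, ok] != aln[j, ok])
    tot <- tot + if (per_site) d / sum(ok) else d
  }
  tot / choose(n, 2)
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

tajima_d_from_counts <- function(n, s, khat) {
  if (s < 1) stop("Tajima's D undefined when there are no segregating sites")
  k <- tajima_constants(n)
  (khat - s / k$a1) / sqrt(k$e1 * s + k$e2 * s * (s - 1))
}

r2_from_counts <- function(n, s, khat, singletons) {
  if (s < 1) stop("R2 undefined when there are no segregating sites")
  sqrt(sum((singletons - khat / 2)^2) / n) / s
}

#' Tajima's D of an alignment
#'
#' D = (k - S/a1) / sqrt(e1 S + e2 S (S-1)), where k is the mean number of
#' pairwise differences and S the number of segregating sites, both over
#' gap/N-free columns, with the standard coefficients in n. Errors when
#' S = 0.
#'
#' @param aln A [hap_alignment()].
#' @return The D statistic (scalar).
#' @export
tajimas_d <- function(aln) {
  cs <- complete_columns(aln)
  tajima_d_from_counts(nrow(aln), count_segregating(aln),
                       mean_pairwise_diff(cs, per_site = FALSE))
}

complete_columns <- function(aln) {
  keep <- apply(aln, 2, function(col) all(valid_base(col)))
  aln[, keep, drop = FALSE]
}

#' Ramos-Onsins & Rozas R2 of an alignment
#'
#' R2 = sqrt( sum_i (U_i - k/2)^2 / n ) / S, with U_i the number of
#' singleton sites carried by sequence i (minor allele observed exactly
#' once), k the mean number of pairwise differences and S the number of
#' segregating sites, over gap/N-free columns. Small values indicate
#' star-like genealogies (demographic expansion).
#'
#' @param aln A [hap_alignment()].
#' @return The R2 statistic (scalar).
#' @export
r2_statistic <- function(aln) {
  cs <- complete_columns(aln)
  n <- nrow(cs)
  u <- numeric(n)
  for (j in seq_len(ncol(cs))) {
    tab <- table(cs[, j])
    if (length(tab) > 1) {
      minor <- names(tab)[tab == min(tab)]
      if (min(tab) == 1 && length(minor) == 1) {
        u[which(cs[, j] == minor)] <- u[which(cs[, j] == minor)] + 1
      }
    }
  }
  r2_from_counts(n, count_segregating(cs),
                 mean_pairwise_diff(cs, per_site = FALSE), u)
}
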