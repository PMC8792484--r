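#' Simulate one standard-coalescent genealogy with S mutations
#'
#' Simulates a constant-size neutral coalescent for `n` samples (exponential
#' waiting times with rate k(k-1)/2 while k lineages remain, uniform pair
#' merging) and places exactly `S` mutations on the genealogy with
#' probability proportional to branch length (fixed-S conditioning). Each
#' mutation is carried by the leaves descending from its branch.
#'
#' @param n Number of sampled sequences.
#' @param s Number of segregating sites to place.
#' @return A list with `n`, `s`, `khat` (mean pairwise differences),
#'   `derived_counts` (per-mutation carrier counts) and `singletons`
#'   (per-sequence minor-allele singleton counts).
#' @export
sim_coalescent_stats <- function(n, s) {
  desc <- as.list(seq_len(n))
  seg_len <- numeric(0)
  seg_desc <- list()
  k <- n
  while (k > 1) {
    t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
    seg_len <- c(seg_len, rep(t_k, k))
    seg_desc <- c(seg_desc, desc)
    pair <- sample.int(k, 2)
    desc[[pair[1]]] <- c(desc[[pair[1]]], desc[[pair[2]]])
    desc[[pair[2]]] <- NULL
    k <- k - 1
  }
  hit <- sample.int(length(seg_len), s, replace = TRUE, prob = seg_len)
  counts <- lengths(seg_desc)[hit]
  khat <- sum(2 * counts * (n - counts)) / (n * (n - 1))
  u <- numeric(n)
  for (m in seq_len(s)) {
    if (counts[m] == 1L) {
      i <- seg_desc[[hit[m]]]
      u[i] <- u[i] + 1
    } else if (counts[m] == n - 1L) {
      i <- setdiff(seq_len(n), seg_desc[[hit[m]]])
      u[i] <- u[i] + 1
    }
  }
  list(n = n, s = s, khat = khat, derived_counts = counts, singletons = u)
}

#' Coalescent p-value for a neutrality statistic
#'
#' Builds the null distribution of a statistic under the standard neutral
#' coalescent conditioned on the observed number of segregating sites and
#' returns the lower-tail p-value Pr(sim <= observed): both supported
#' statistics (Tajima's D and R2) take small values under demographic
#' expansion, the alternative the tests target.
#'
#' @param stat `"tajima_d"`, `"r2"`, or a function taking the list returned
#'   by [sim_coalescent_stats()] and returning a scalar.
#' @param n Sample size of the observed data.
#' @param s Observed number of segregating sites.
#' @param observed Observed value of the statistic.
#' @param reps Number of coalescent replicates (default 10000).
#' @return A list with `p`, the simulated `null` values, and `observed`.
#' @export
coalescent_pvalue <- function(stat, n, s, observed, reps = 10000) {
  stopifnot(reps >= 1000, s >= 1, n >= 2)
  stat_fn <- if (is.function(stat)) stat else switch(
    match.arg(stat, c("tajima_d", "r2")),
    tajima_d = function(sim) tajima_d_from_counts(sim$n, sim$s, sim$khat),
    r2 = function(sim) r2_from_counts(sim$n, sim$s, sim$khat, sim$singletons)
  )
  null <- vapply(seq_len(reps), function(i) stat_fn(sim_coalescent_stats(n, s)),
                 numeric(1))
  list(p = mean(null <= observed), null = null, observed = observed)
}

#' Mitochondrial diversity table with coalescent tests
#'
#' Per-group haplotype summaries plus Tajima's D and the Ramos-Onsins &
#' Rozas R2, each with a p-value from `reps` fixed-S coalescent
#' simulations. Groups with no segregating sites get `NA` statistics.
#'
#' @param aln A [hap_alignment()].
#' @param samples Sample tibble with `id` matching the alignment row names.
#' @param by Grouping column in `samples` (default `"mt_clade"`).
#' @param reps Coalescent replicates per test (default 10000).
#' @return A tibble with one row per group: `group`, `n`, `h`, `s`, `hd`,
#'   `pi`, `tajima_d`, `tajima_p`, `r2`, `r2_p`.
#' @export
mt_diversity <- function(aln, samples, by = "mt_clade", reps = 10000) {
  if (!by %in% names(samples)) stop("no column `", by, "` in samples")
  ids <- intersect(samples$id, rownames(aln))
  groups <- split(ids, samples[[by]][match(ids, samples$id)])
  purrr::imap_dfr(groups, function(gids, grp) {
    sub <- hap_alignment(aln[gids, , drop = FALSE])
    sm <- mtdna_summary(sub)
    if (sm$s >= 1) {
      d <- tajimas_d(sub)
      r2 <- r2_statistic(sub)
      dp <- coalescent_pvalue("tajima_d", sm$n, sm$s, d, reps)$p
      r2p <- coalescent_pvalue("r2", sm$n, sm$s, r2, reps)$p
    } else {
      d <- r2 <- dp <- r2p <- NA_real_
    }
    tibble::tibble(group = grp, n = sm$n, h = sm$h, s = sm$s, hd = sm$hd,
                   pi = sm$pi, tajima_d = d, tajima_p = dp, r2 = r2,
                   r2_p = r2p)
  })
}
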