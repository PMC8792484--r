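#' Specify a four-taxon trio for the ABBA-BABA test
#'
#' The test operates on the topology (((P1, P2), P3), outgroup) and asks
#' whether P3 shares excess derived alleles with P2 (ABBA) over P1 (BABA).
#'
#' @param p1,p2,p3,outgroup Population labels (must be distinct).
#' @return A named list of class `trio_spec`.
#' @export
trio_spec <- function(p1, p2, p3, outgroup) {
  labs <- c(p1, p2, p3, outgroup)
  if (anyDuplicated(labs)) stop("trio labels must be distinct")
  structure(list(p1 = p1, p2 = p2, p3 = p3, outgroup = outgroup),
            class = "trio_spec")
}

# Per-locus weighted site-pattern contributions. Sites are polarized on the
# outgroup major allele (treated as ancestral); sites where the outgroup
# minor-allele frequency exceeds `max_outgroup_minor`, or where any
# population has no called genotype, are skipped and counted.
site_pattern_contributions <- function(gm, samples, trio, by = "population",
                                       max_outgroup_minor = 0.1) {
  groups <- split_samples(gm, samples, by)
  labs <- unlist(trio[c("p1", "p2", "p3", "outgroup")])
  missing_pop <- setdiff(labs, names(groups))
  if (length(missing_pop)) stop("populations not found: ",
                                paste(missing_pop, collapse = ", "))
  fr <- vapply(labs, function(g)
    colMeans(gm$dosage[groups[[g]], , drop = FALSE], na.rm = TRUE) / 2,
    numeric(ncol(gm$dosage)))
  if (is.null(dim(fr))) fr <- matrix(fr, nrow = 1)
  colnames(fr) <- c("p1", "p2", "p3", "out")
  uncalled <- rowSums(is.na(fr)) > 0
  out_minor <- pmin(fr[, "out"], 1 - fr[, "out"])
  poly_out <- !uncalled & out_minor > max_outgroup_minor
  used <- !uncalled & !poly_out
  # derived allele = allele opposite the outgroup major allele
  flip <- fr[, "out"] > 0.5
  d <- fr
  d[flip, ] <- 1 - fr[flip, , drop = FALSE]
  tibble::tibble(
    locus_id = locus_ids(gm),
    used = used,
    abba = ifelse(used, (1 - d[, "p1"]) * d[, "p2"] * d[, "p3"] * (1 - d[, "out"]), 0),
    baba = ifelse(used, d[, "p1"] * (1 - d[, "p2"]) * d[, "p3"] * (1 - d[, "out"]), 0),
    bbaa = ifelse(used, d[, "p1"] * d[, "p2"] * (1 - d[, "p3"]) * (1 - d[, "out"]), 0),
    # denominator patterns with P3 substituted for P2 (complete-introgression
    # ceiling for the admixture fraction)
    abba_sub = ifelse(used, (1 - d[, "p1"]) * d[, "p3"] * d[, "p3"] * (1 - d[, "out"]), 0),
    baba_sub = ifelse(used, d[, "p1"] * (1 - d[, "p3"]) * d[, "p3"] * (1 - d[, "out"]), 0),
    skipped_missing = uncalled,
    skipped_polymorphic_outgroup = poly_out
  )
}

#' Weighted site-pattern counts for a trio
#'
#' Sums, over polarized sites, the allele-frequency-weighted probabilities
#' of the BBAA, ABBA and BABA patterns: with derived-allele frequencies
#' p1, p2, p3, p4 (p4 = outgroup), a site contributes
#' (1-p1) p2 p3 (1-p4) to ABBA, p1 (1-p2) p3 (1-p4) to BABA and
#' p1 p2 (1-p3) (1-p4) to BBAA.
#'
#' @param gm A [geno_matrix()].
#' @param samples Sample tibble with `id` and the grouping column.
#' @param trio A [trio_spec()].
#' @param by Grouping column (default `"population"`).
#' @param max_outgroup_minor Skip sites whose outgroup minor-allele
#'   frequency exceeds this (default 0.1).
#' @return A one-row tibble: `bbaa`, `abba`, `baba`, `n_used`,
#'   `n_skipped_missing`, `n_skipped_polymorphic_outgroup`.
#' @export
site_patterns <- function(gm, samples, trio, by = "population",
                          max_outgroup_minor = 0.1) {
  ct <- site_pattern_contributions(gm, samples, trio, by, max_outgroup_minor)
  tibble::tibble(bbaa = sum(ct$bbaa), abba = sum(ct$abba),
                 baba = sum(ct$baba), n_used = sum(ct$used),
                 n_skipped_missing = sum(ct$skipped_missing),
                 n_skipped_polymorphic_outgroup = sum(ct$skipped_polymorphic_outgroup))
}

#' Patterson's D from weighted pattern counts
#'
#' D = (ABBA - BABA) / (ABBA + BABA).
#'
#' @param abba,baba Weighted pattern counts (non-negative).
#' @return The D statistic in `[-1, 1]`.
#' @export
patterson_d <- function(abba, baba) {
  if (abba + baba <= 0) stop("ABBA + BABA is zero: D undefined")
  (abba - baba) / (abba + baba)
}

#' ABBA-BABA test with block-jackknife significance
#'
#' Computes weighted site-pattern counts, Patterson's D, the admixture
#' fraction f (D numerator over the same numerator with P3 substituted for
#' P2 — the complete-introgression ceiling), and a delete-one-block
#' jackknife standard error over contiguous locus blocks, giving Z = D/SE
#' and a two-tailed normal p-value.
#'
#' @inheritParams site_patterns
#' @param block_size Number of consecutive used loci per jackknife block
#'   (default 1000).
#' @return A one-row tibble of class `dstat_result`: `p1`, `p2`, `p3`,
#'   `outgroup`, `d`, `se`, `z`, `p`, `f_admix`, `bbaa`, `abba`, `baba`,
#'   `n_blocks`, `n_used`.
#' @export
abba_baba <- function(gm, samples, trio, by = "population",
                      block_size = 1000, max_outgroup_minor = 0.1) {
  ct <- site_pattern_contributions(gm, samples, trio, by, max_outgroup_minor)
  used <- ct[ct$used, ]
  abba <- sum(used$abba); baba <- sum(used$baba)
  d <- patterson_d(abba, baba)
  denom_sub <- sum(used$abba_sub) - sum(used$baba_sub)
  f <- if (denom_sub == 0) NA_real_ else (abba - baba) / denom_sub
  jk <- jackknife_d(used$abba, used$baba, block_size)
  out <- tibble::tibble(
    p1 = trio$p1, p2 = trio$p2, p3 = trio$p3, outgroup = trio$outgroup,
    d = d, se = jk$se, z = d / jk$se,
    p = 2 * stats::pnorm(-abs(d / jk$se)),
    f_admix = f, bbaa = sum(used$bbaa), abba = abba, baba = baba,
    n_blocks = jk$n_blocks, n_used = nrow(used)
  )
  class(out) <- c("dstat_result", class(out))
  out
}

#' Admixture-fraction estimate for a trio
#'
#' f = sum(ABBA - BABA) / sum(ABBA - BABA with P3 substituted for P2): the
#' observed pattern asymmetry scaled by its value under complete
#' introgression from P3 into P2. Equals 1 when P2 and P3 are the same
#' individuals.
#'
#' @inheritParams site_patterns
#' @return The admixture fraction (scalar).
#' @export
f_admix <- function(gm, samples, trio, by = "population",
                    max_outgroup_minor = 0.1) {
  ct <- site_pattern_contributions(gm, samples, trio, by, max_outgroup_minor)
  denom <- sum(ct$abba_sub) - sum(ct$baba_sub)
  if (denom == 0) stop("complete-introgression denominator is zero")
  (sum(ct$abba) - sum(ct$baba)) / denom
}

# Delete-one-block jackknife of D over contiguous blocks of the per-locus
# ABBA/BABA contributions.
jackknife_d <- function(abba_l, baba_l, block_size) {
  n <- length(abba_l)
  blocks <- ceiling(seq_len(n) / block_size)
  b <- max(blocks)
  if (b < 2) stop("fewer than 2 jackknife blocks: increase loci or reduce block_size")
  ab_tot <- sum(abba_l); ba_tot <- sum(baba_l)
  theta <- vapply(seq_len(b), function(j) {
    in_j <- blocks == j
    patterson_d(ab_tot - sum(abba_l[in_j]), ba_tot - sum(baba_l[in_j]))
  }, numeric(1))
  var_jk <- (b - 1) / b * sum((theta - mean(theta))^2)
  list(se = sqrt(var_jk), n_blocks = b)
}
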