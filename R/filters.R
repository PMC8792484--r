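#' Genotype quality-filter configuration
#'
#' Thresholds mirroring the standard ddRADseq post-calling cleanup for a
#' two-species SNP panel: per-genotype depth masking, per-locus call-rate /
#' minor-allele-frequency / heterozygosity screens, and a per-individual
#' missingness cap. Boundary semantics are kept strict: a locus is retained
#' when call rate >= `min_locus_presence`, MAF >= `min_maf` and observed
#' heterozygote fraction <= `max_obs_het`; an individual is retained when its
#' missing fraction is strictly below `max_indiv_missing`.
#'
#' @param min_locus_presence Minimum fraction of samples with a called
#'   genotype at a locus (default 0.80).
#' @param min_maf Minimum minor-allele frequency, computed over called
#'   genotypes only (default 0.05).
#' @param max_obs_het Maximum observed heterozygote fraction per locus
#'   (default 0.8).
#' @param min_depth Minimum per-genotype read depth; shallower calls are set
#'   to missing before the locus screens (default 20).
#' @param max_indiv_missing Individuals with a missing-genotype fraction at
#'   or above this value are removed (default 0.30).
#' @param one_snp_per_locus Keep only the first SNP of each RAD tag when
#'   locus ids encode a tag as `<tag>_<offset>`; a no-op otherwise.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_locus_presence = 0.80, min_maf = 0.05,
                          max_obs_het = 0.8, min_depth = 20,
                          max_indiv_missing = 0.30,
                          one_snp_per_locus = FALSE) {
  stopifnot(min_locus_presence >= 0, min_locus_presence <= 1,
            min_maf >= 0, min_maf <= 1, max_obs_het >= 0, max_obs_het <= 1,
            min_depth >= 0, max_indiv_missing >= 0, max_indiv_missing <= 1)
  structure(list(min_locus_presence = min_locus_presence, min_maf = min_maf,
                 max_obs_het = max_obs_het, min_depth = min_depth,
                 max_indiv_missing = max_indiv_missing,
                 one_snp_per_locus = one_snp_per_locus),
            class = "filter_config")
}

#' Mask genotypes below the read-depth threshold
#'
#' Sets every genotype whose depth is below `cfg$min_depth` to missing. A
#' matrix without depth information is returned unchanged.
#'
#' @param gm A [geno_matrix()] with a depth matrix.
#' @param cfg A [filter_config()].
#' @return A `geno_matrix` with shallow calls masked.
#' @export
apply_depth_filter <- function(gm, cfg = filter_config()) {
  if (is.null(gm$depth)) return(gm)
  mask <- !is.na(gm$depth) & gm$depth < cfg$min_depth
  dos <- gm$dosage
  dos[mask] <- NA_integer_
  geno_matrix(dos, chrom = gm$chrom, pos = gm$pos, depth = gm$depth)
}

per_locus_stats <- function(gm) {
  dos <- gm$dosage
  called <- colSums(!is.na(dos))
  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  het <- colMeans(dos == 1L, na.rm = TRUE)
  tibble::tibble(locus_id = locus_ids(gm),
                 call_rate = called / nrow(dos),
                 maf = ifelse(called > 0, maf, 0),
                 obs_het = ifelse(called > 0, het, 0))
}

#' Apply the per-locus filters
#'
#' Drops loci failing, in order: call rate, minor-allele frequency, observed
#' heterozygosity; when `one_snp_per_locus` is set, additionally keeps only
#' the first SNP per RAD tag. Each dropped locus is reported with the first
#' rule it failed.
#'
#' @param gm A [geno_matrix()].
#' @param cfg A [filter_config()].
#' @return A list with `gm` (filtered matrix) and `dropped`, a tibble of
#'   `locus_id` and `reason` (`"presence"`, `"maf"`, `"het"`, `"duplicate_snp"`).
#' @export
apply_locus_filters <- function(gm, cfg = filter_config()) {
  st <- per_locus_stats(gm)
  reason <- rep(NA_character_, nrow(st))
  reason[st$call_rate < cfg$min_locus_presence] <- "presence"
  sel <- is.na(reason) & st$maf < cfg$min_maf
  reason[sel] <- "maf"
  sel <- is.na(reason) & st$obs_het > cfg$max_obs_het
  reason[sel] <- "het"
  if (isTRUE(cfg$one_snp_per_locus)) {
    tag <- sub("_[0-9]+$", "", st$locus_id)
    dup <- duplicated(tag)
    reason[is.na(reason) & dup] <- "duplicate_snp"
  }
  keep <- is.na(reason)
  list(gm = gm[, keep],
       dropped = tibble::tibble(locus_id = st$locus_id[!keep],
                                reason = reason[!keep]))
}

#' Apply the per-individual missingness filter
#'
#' Removes samples whose fraction of missing genotypes is at or above
#' `max_indiv_missing` (strictly-less-than retention).
#'
#' @param gm A [geno_matrix()].
#' @param cfg A [filter_config()].
#' @return A `geno_matrix` with failing individuals removed.
#' @export
apply_individual_filter <- function(gm, cfg = filter_config()) {
  miss <- rowMeans(is.na(gm$dosage))
  keep <- miss < cfg$max_indiv_missing
  if (!any(keep)) stop("all individuals removed by the missingness filter")
  gm[keep, ]
}

#' Run the full genotype QC filter chain
#'
#' Depth mask, then locus filters, then the individual filter — the order is
#' fixed and part of the contract; the chain is idempotent.
#'
#' @param gm A [geno_matrix()].
#' @param cfg A [filter_config()].
#' @return A list with `gm` (the filtered matrix), `dropped_loci` (tibble of
#'   locus drop reasons) and `log`, a tibble of stage-by-stage sample and
#'   locus counts.
#' @export
filter_genotypes <- function(gm, cfg = filter_config()) {
  stages <- list(input = gm)
  gm1 <- apply_depth_filter(gm, cfg)
  lf <- apply_locus_filters(gm1, cfg)
  gm3 <- apply_individual_filter(lf$gm, cfg)
  log <- tibble::tibble(
    stage = c("input", "depth_mask", "locus_filters", "individual_filter"),
    n_samples = c(nrow(gm$dosage), nrow(gm1$dosage), nrow(lf$gm$dosage),
                  nrow(gm3$dosage)),
    n_loci = c(ncol(gm$dosage), ncol(gm1$dosage), ncol(lf$gm$dosage),
               ncol(gm3$dosage))
  )
  list(gm = gm3, dropped_loci = lf$dropped, log = log)
}
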