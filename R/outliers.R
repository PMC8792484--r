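#' PCA-correlation outlier-locus scan
#'
#' Identifies loci excessively correlated with population structure:
#' standardized dosages are regressed on the first `k` principal-component
#' scores, the per-locus vector of regression z-scores is summarised by a
#' robust Mahalanobis distance, distances are rescaled by the genomic
#' inflation factor (median distance over the chi-square median), and
#' p-values come from a chi-square with `k` degrees of freedom.
#' Benjamini-Hochberg q-values flag outliers at level `alpha`.
#'
#' @param gm A [geno_matrix()] (no monomorphic loci; run the MAF filter
#'   first).
#' @param k Number of principal components describing structure
#'   (default 2).
#' @param alpha FDR level for the outlier flags (default 0.05).
#' @return A tibble of class `outlier_scan` with columns `locus_id`,
#'   `stat` (rescaled Mahalanobis distance), `p`, `q`, `outlier`, plus
#'   attributes `gif` (inflation factor) and `zscores` (loci x k matrix).
#' @export
pc_outlier_scan <- function(gm, k = 2, alpha = 0.05) {
  n <- nrow(gm$dosage)
  stopifnot(k >= 1, k < n)
  mono <- apply(gm$dosage, 2, function(g) length(unique(g[!is.na(g)])) <= 1)
  if (any(mono)) stop(sum(mono), " constant loci present: filter them first")
  G <- impute_standardize(gm)
  pca <- genotype_pca(gm, n_pcs = k)
  X <- pca$scores
  xtx_inv <- solve(crossprod(X))
  B <- xtx_inv %*% crossprod(X, G)                    # k x L coefficients
  resid <- G - X %*% B
  df <- n - k - 1
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(outer(diag(xtx_inv), sigma2))            # k x L
  z <- t(B / se)                                      # L x k
  rob <- MASS::cov.rob(z)
  d2 <- unname(stats::mahalanobis(z, center = rob$center, cov = rob$cov))
  gif <- stats::median(d2) / stats::qchisq(0.5, df = k)
  p <- stats::pchisq(d2 / gif, df = k, lower.tail = FALSE)
  fdr <- bh_fdr(p, alpha)
  out <- tibble::tibble(locus_id = locus_ids(gm), stat = d2 / gif,
                        p = p, q = fdr$q, outlier = fdr$flag)
  attr(out, "gif") <- gif
  attr(out, "zscores") <- z
  class(out) <- c("outlier_scan", class(out))
  out
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted p-values (q-values) with discovery flags at level
#' `alpha`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return A tibble with columns `p`, `q`, `flag`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, flag = !is.na(q) & q <= alpha)
}

#' Partition loci into neutral and non-neutral sets
#'
#' Combines the outlier flags of one or two scans into a non-neutral locus
#' set (union of flags by default, intersection optionally — the second
#' scan slot accepts any externally produced flag list) and its neutral
#' complement. The two sets always form a disjoint cover of the input loci.
#'
#' @param scan_a An `outlier_scan` tibble, or any tibble with `locus_id`
#'   and logical `outlier` columns.
#' @param scan_b Optional second scan over the same loci (same form), or
#'   a character vector of flagged locus ids.
#' @param mode `"union"` (default) or `"intersection"`.
#' @return A list with character vectors `neutral` and `non_neutral`.
#' @export
partition_loci <- function(scan_a, scan_b = NULL,
                           mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  all_ids <- scan_a$locus_id
  flags_a <- scan_a$locus_id[scan_a$outlier]
  if (is.null(scan_b)) {
    non_neutral <- flags_a
  } else {
    flags_b <- if (is.character(scan_b)) scan_b else {
      if (!setequal(scan_b$locus_id, all_ids)) stop("mismatched locus sets")
      scan_b$locus_id[scan_b$outlier]
    }
    non_neutral <- if (mode == "union") union(flags_a, flags_b)
                   else intersect(flags_a, flags_b)
  }
  non_neutral <- intersect(all_ids, non_neutral)
  list(neutral = setdiff(all_ids, non_neutral), non_neutral = non_neutral)
}

#' Folded site frequency spectrum of a population
#'
#' Per polymorphic locus with complete genotypes, the minor-allele count
#' m = min(c, 2n - c) (c = alt-allele count over n diploids) increments bin
#' m; bins run 1..n. Monomorphic loci are excluded from the bins but
#' counted in the total `L`; loci with any missing genotype are dropped.
#'
#' @param gm A [geno_matrix()].
#' @param ids Optional sample ids defining the population (default: all
#'   samples).
#' @return A tibble of class `sfs_vector` with columns `bin` and `count`,
#'   and attributes `n_dip`, `n_seq` (= 2 n_dip), `L` (loci considered,
#'   monomorphic included) and `n_poly`.
#' @export
folded_sfs <- function(gm, ids = NULL) {
  if (is.null(ids)) ids <- sample_ids(gm)
  if (length(ids) == 0) stop("empty population")
  d <- gm$dosage[match(ids, sample_ids(gm)), , drop = FALSE]
  complete <- colSums(is.na(d)) == 0
  d <- d[, complete, drop = FALSE]
  n <- nrow(d)
  cnt <- colSums(d)
  m <- pmin(cnt, 2L * n - cnt)
  poly <- m >= 1L
  bins <- tabulate(m[poly], nbins = n)
  out <- tibble::tibble(bin = seq_len(n), count = bins)
  attr(out, "n_dip") <- n
  attr(out, "n_seq") <- 2L * n
  attr(out, "L") <- sum(complete)
  attr(out, "n_poly") <- sum(poly)
  class(out) <- c("sfs_vector", class(out))
  out
}

#' Write a demographic-inference blueprint file
#'
#' Emits the plain-text input consumed by stairway-style demographic
#' inference from a folded SFS: population id, number of sequences, total
#' locus count, folded flag, the SFS line, the per-site per-generation
#' mutation rate and the generation time in years. Defaults use a cervid
#' mutation rate of 1.1e-8 and 5-year generations.
#'
#' @param sfs An `sfs_vector` from [folded_sfs()].
#' @param path Output path.
#' @param popid Population identifier written to the file.
#' @param mu Mutation rate per site per generation (default 1.1e-8).
#' @param gen_years Years per generation (default 5).
#' @return `path`, invisibly.
#' @export
write_blueprint <- function(sfs, path, popid = "pop1", mu = 1.1e-8,
                            gen_years = 5) {
  n_seq <- attr(sfs, "n_seq")
  lines <- c(
    sprintf("popid: %s", popid),
    sprintf("nseq: %d", n_seq),
    sprintf("L: %d", attr(sfs, "L")),
    "whether_folded: true",
    paste("SFS:", paste(sfs$count, collapse = "\t")),
    sprintf("pct_training: %g", 0.67),
    sprintf("mu: %.3g", mu),
    sprintf("year_per_generation: %g", gen_years)
  )
  writeLines(lines, path)
  invisible(path)
}
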