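## Shared maximum-likelihood ancestry machinery.
##
## Both the hybrid index and the supervised ancestry proportion Q maximise
## the same binomial mixture likelihood over h in [0, 1]:
##   P(alt allele) = h * p2 + (1 - h) * p1  per locus,
##   genotype ~ Binomial(2, .).
## The likelihood is evaluated on a 1001-point grid and refined by local
## 1-D optimisation; allele-frequency arguments are clamped away from 0/1
## so fixed loci keep a finite log-likelihood at interior h.

CLAMP_EPS <- 1e-9

# Grid log-likelihood for a cohort. G: individuals x loci dosage matrix
# (NA = missing), p1/p2 per-locus parental frequencies. Returns a
# grid x individuals matrix (binomial coefficient terms dropped: constant
# in h).
ancestry_loglik_grid <- function(G, p1, p2, grid) {
  P <- pmin(pmax(grid %o% p2 + (1 - grid) %o% p1, CLAMP_EPS), 1 - CLAMP_EPS)
  g0 <- G; g0[is.na(g0)] <- 0L
  comp <- 2L - G; comp[is.na(comp)] <- 0L
  log(P) %*% t(g0) + log1p(-P) %*% t(comp)
}

ancestry_loglik_at <- function(h, g, p1, p2) {
  ok <- !is.na(g)
  p <- pmin(pmax(h * p2[ok] + (1 - h) * p1[ok], CLAMP_EPS), 1 - CLAMP_EPS)
  sum(g[ok] * log(p) + (2 - g[ok]) * log1p(-p))
}

# ML ancestry proportions for a cohort; returns a tibble with one row per
# individual: estimate plus the 2-log-likelihood-unit support interval.
ml_ancestry <- function(G, p1, p2, grid_n = 1001) {
  if (is.null(dim(G))) G <- matrix(G, nrow = 1)
  if (nrow(G) == 0) {
    return(tibble::tibble(est = numeric(0), low = numeric(0),
                          high = numeric(0)))
  }
  grid <- seq(0, 1, length.out = grid_n)
  ll <- ancestry_loglik_grid(G, p1, p2, grid)
  purrr::map_dfr(seq_len(nrow(G)), function(i) {
    lli <- ll[, i]
    best <- which.max(lli)
    est <- grid[best]; best_ll <- lli[best]
    # golden-section refinement inside the bracketing grid cells; the grid
    # value is kept unless refinement strictly improves the likelihood
    lo <- grid[max(1, best - 1)]; hi <- grid[min(grid_n, best + 1)]
    if (hi > lo) {
      opt <- stats::optimize(ancestry_loglik_at, c(lo, hi), g = G[i, ],
                             p1 = p1, p2 = p2, maximum = TRUE, tol = 1e-9)
      if (opt$objective > best_ll) {
        est <- opt$maximum; best_ll <- opt$objective
      }
    }
    inside <- lli >= best_ll - 2
    tibble::tibble(est = est, low = min(grid[inside]), high = max(grid[inside]))
  })
}

#' Estimate parental allele frequencies from designated panels
#'
#' Alt-allele frequencies per locus in each parental panel, computed over
#' called genotypes, with ancestry-informativeness flags: `fixed_diff` when
#' the panels are fixed for alternative alleles, `informative` when
#' `|p1 - p2| >= delta` (fixed differences included).
#'
#' @param gm A [geno_matrix()].
#' @param parental_ids_1,parental_ids_2 Sample ids of the two parental
#'   panels (species 1 carries hybrid index 0, species 2 index 1).
#' @param delta Minimum between-panel frequency difference for a locus to
#'   count as ancestry-informative (default 0.8).
#' @return A tibble with columns `locus_id`, `p1`, `p2`, `n1`, `n2`,
#'   `fixed_diff`, `informative`.
#' @export
estimate_parental_freqs <- function(gm, parental_ids_1, parental_ids_2,
                                    delta = 0.8) {
  if (length(parental_ids_1) < 2 || length(parental_ids_2) < 2) {
    stop("each parental panel needs at least 2 individuals")
  }
  if (length(parental_ids_1) < 5 || length(parental_ids_2) < 5) {
    warning("parental panel with fewer than 5 individuals: frequency ",
            "estimates will be noisy")
  }
  d1 <- gm$dosage[match(parental_ids_1, sample_ids(gm)), , drop = FALSE]
  d2 <- gm$dosage[match(parental_ids_2, sample_ids(gm)), , drop = FALSE]
  n1 <- unname(colSums(!is.na(d1))); n2 <- unname(colSums(!is.na(d2)))
  p1 <- unname(colMeans(d1, na.rm = TRUE)) / 2
  p2 <- unname(colMeans(d2, na.rm = TRUE)) / 2
  fixed <- !is.na(p1) & !is.na(p2) & abs(p1 - p2) == 1
  informative <- !is.na(p1) & !is.na(p2) & abs(p1 - p2) >= delta
  tibble::tibble(locus_id = locus_ids(gm), p1 = p1, p2 = p2,
                 n1 = n1, n2 = n2, fixed_diff = fixed,
                 informative = informative)
}

freq_cols <- function(freqs) {
  need <- c("locus_id", "p1", "p2")
  if (!all(need %in% names(freqs))) {
    stop("parental frequencies need columns: ", paste(need, collapse = ", "))
  }
  if (!"informative" %in% names(freqs)) {
    freqs$informative <- abs(freqs$p1 - freqs$p2) >= 0.8
  }
  if (!"fixed_diff" %in% names(freqs)) {
    freqs$fixed_diff <- abs(freqs$p1 - freqs$p2) == 1
  }
  freqs
}

#' Maximum-likelihood hybrid index
#'
#' Estimates, for each individual, the proportion of its genome derived
#' from parental species 2 (hybrid index 1) versus species 1 (hybrid index
#' 0), by maximising the binomial mixture likelihood over the
#' ancestry-informative loci. A 2-log-likelihood-unit support interval is
#' reported alongside the estimate. An F1 between panels fixed for
#' alternative alleles has hybrid index 0.5; each backcross generation
#' halves the distance to the recurrent parent.
#'
#' @param gm A [geno_matrix()], or a single dosage vector over the loci of
#'   `freqs`.
#' @param freqs Parental-frequency tibble from [estimate_parental_freqs()]
#'   or [build_parental_freqs()].
#' @return A tibble with columns `id`, `hi`, `hi_low`, `hi_high`,
#'   `n_informative`.
#' @export
hybrid_index <- function(gm, freqs) {
  freqs <- freq_cols(freqs)
  use <- which(freqs$informative)
  if (length(use) == 0) stop("no ancestry-informative loci")
  if (inherits(gm, "geno_matrix")) {
    cols <- match(freqs$locus_id[use], locus_ids(gm))
    if (anyNA(cols)) stop("informative loci missing from the genotype matrix")
    G <- gm$dosage[, cols, drop = FALSE]
    ids <- sample_ids(gm)
    if (is.null(ids)) ids <- character(0)
  } else {
    G <- matrix(gm[use], nrow = 1)
    ids <- "individual_1"
  }
  res <- ml_ancestry(G, freqs$p1[use], freqs$p2[use])
  tibble::tibble(id = ids, hi = res$est, hi_low = res$low,
                 hi_high = res$high,
                 n_informative = rowSums(!is.na(G)))
}

#' Interspecific heterozygosity
#'
#' Fraction of diagnostic loci at which an individual carries one allele
#' characteristic of each parental species. By default only fixed-difference
#' loci are used (where a heterozygote necessarily carries one allele from
#' each species); `mode = "delta"` relaxes to all informative loci
#' (`|p1 - p2| >= delta` from the frequency table), for datasets without
#' fixed differences.
#'
#' @param gm A [geno_matrix()] or a single dosage vector.
#' @param freqs Parental-frequency tibble.
#' @param mode `"fixed"` (default) or `"delta"`.
#' @return A tibble with columns `id`, `het`, `n_loci_used`.
#' @export
interspecific_heterozygosity <- function(gm, freqs, mode = c("fixed", "delta")) {
  mode <- match.arg(mode)
  freqs <- freq_cols(freqs)
  use <- which(if (mode == "fixed") freqs$fixed_diff else freqs$informative)
  if (length(use) == 0) stop("no usable diagnostic loci (mode = ", mode, ")")
  if (inherits(gm, "geno_matrix")) {
    cols <- match(freqs$locus_id[use], locus_ids(gm))
    if (anyNA(cols)) stop("diagnostic loci missing from the genotype matrix")
    G <- gm$dosage[, cols, drop = FALSE]
    ids <- sample_ids(gm)
    if (is.null(ids)) ids <- character(0)
  } else {
    G <- matrix(gm[use], nrow = 1)
    ids <- "individual_1"
  }
  tibble::tibble(id = ids,
                 het = unname(rowMeans(G == 1L, na.rm = TRUE)),
                 n_loci_used = rowSums(!is.na(G)))
}

#' Triangle-plot generation classification
#'
#' Applies the hybrid-generation rules on the (hybrid index,
#' interspecific heterozygosity) plane: individuals with hybrid index
#' strictly between 0.25 and 0.75 are recent-generation hybrids when
#' heterozygosity exceeds 0.5 and later-generation hybrids otherwise;
#' hybrid index at or outside those bounds marks a multi-generation
#' backcross. Boundary values (0.25, 0.75 on the index; 0.5 on
#' heterozygosity) resolve to the outer class.
#'
#' @param hi,het Numeric vectors in `[0, 1]`.
#' @return Character vector with values `"recent_generation"`,
#'   `"later_generation"` or `"multigen_backcross"`.
#' @export
classify_hybrid <- function(hi, het) {
  stopifnot(all(hi >= 0 & hi <= 1, na.rm = TRUE),
            all(het >= 0 & het <= 1, na.rm = TRUE))
  dplyr::case_when(
    hi <= 0.25 | hi >= 0.75 ~ "multigen_backcross",
    het > 0.5 ~ "recent_generation",
    TRUE ~ "later_generation"
  )
}

#' Per-individual hybrid report
#'
#' Combines the hybrid index (with support interval), interspecific
#' heterozygosity and the triangle classification into one table.
#' Individuals listed in `parental_ids` are labelled `"parental"` instead
#' of a hybrid-generation class.
#'
#' @param gm A [geno_matrix()].
#' @param freqs Parental-frequency tibble.
#' @param het_mode Passed to [interspecific_heterozygosity()].
#' @param parental_ids Optional ids to label as parental.
#' @return A tibble of class `hybrid_report`: `id`, `hi`, `hi_low`,
#'   `hi_high`, `het`, `n_informative`, `generation_class`.
#' @export
hybrid_report <- function(gm, freqs, het_mode = "fixed",
                          parental_ids = character()) {
  hi <- hybrid_index(gm, freqs)
  het <- interspecific_heterozygosity(gm, freqs, mode = het_mode)
  out <- dplyr::left_join(hi, het[, c("id", "het")], by = "id")
  out$generation_class <- classify_hybrid(out$hi, out$het)
  out$generation_class[out$id %in% parental_ids] <- "parental"
  out <- out[, c("id", "hi", "hi_low", "hi_high", "het", "n_informative",
                 "generation_class")]
  class(out) <- c("hybrid_report", class(out))
  out
}
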