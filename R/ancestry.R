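#' Principal component analysis of a genotype matrix
#'
#' Loci are centred on their mean dosage and scaled to unit variance;
#' missing genotypes are imputed to the locus mean before decomposition.
#' Loci that are constant after imputation carry no information and are
#' left centred but unscaled.
#'
#' @param gm A [geno_matrix()].
#' @param n_pcs Number of components to retain (default
#'   `min(10, n_samples - 1)`).
#' @return An object of class `geno_pca`: list with `scores`
#'   (individuals x components), `var_explained`, `loadings`
#'   (loci x components) and `sdev`.
#' @export
genotype_pca <- function(gm, n_pcs = NULL) {
  if (nrow(gm$dosage) < 2 || ncol(gm$dosage) < 2) {
    stop("need at least 2 individuals and 2 loci")
  }
  if (any(colSums(!is.na(gm$dosage)) == 0)) stop("all-missing locus present")
  X <- impute_standardize(gm)
  if (is.null(n_pcs)) n_pcs <- min(10L, nrow(X) - 1L)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  structure(list(scores = pc$x[, seq_len(n_pcs), drop = FALSE],
                 var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_pcs)],
                 loadings = pc$rotation[, seq_len(n_pcs), drop = FALSE],
                 sdev = pc$sdev),
            class = "geno_pca")
}

impute_standardize <- function(gm) {
  X <- gm$dosage
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  X <- sweep(X, 2, mu)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(X, 2, sdv, "/")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d individuals, %d components (PC1 %.1f%%)\n",
              nrow(x$scores), ncol(x$scores), 100 * x$var_explained[1]))
  invisible(x)
}

#' Choose the number of genetic clusters by BIC
#'
#' Fits spherical Gaussian mixtures (the probabilistic counterpart of
#' k-means: equal-volume spherical components, `mclust` model `EII`) to the
#' retained principal components for K = 1..`k_max` and selects the K with
#' the lowest BIC. The mixture likelihood is what makes the criterion
#' honest at both ends: a homogeneous sample selects K = 1 instead of
#' fragmenting noise, while well-separated gene pools select their true
#' count. BIC is reported on the lower-is-better scale.
#'
#' @param pca A [genotype_pca()] result.
#' @param k_max Largest cluster count to consider (default 10).
#' @return A list of class `cluster_model`: `k` (chosen), `assignments`,
#'   `bic` (tibble of K and BIC, lower preferred), `centers` (component
#'   means on the retained PCs).
#' @importFrom mclust Mclust mclustBIC
#' @export
choose_k_bic <- function(pca, k_max = 10) {
  X <- pca$scores
  n <- nrow(X)
  k_max <- min(k_max, n - 1L)
  fit <- Mclust(X, G = seq_len(k_max), modelNames = "EII", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed for every candidate K")
  bic_vals <- -as.numeric(fit$BIC[, "EII"])  # mclust maximises; flip sign
  structure(list(k = fit$G,
                 assignments = as.integer(fit$classification),
                 bic = tibble::tibble(k = seq_len(k_max), bic = bic_vals),
                 centers = t(fit$parameters$mean)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> K = %d selected by BIC (candidates 1..%d)\n",
              x$k, nrow(x$bic)))
  invisible(x)
}

#' Supervised ancestry proportions (Q)
#'
#' Maximum-likelihood ancestry proportion of each individual toward the
#' species-2 parental gene pool, under the two-cluster binomial mixture
#' model P(alt) = Q p2 + (1 - Q) p1 per locus. This shares its estimator
#' with [hybrid_index()]: Q and the hybrid index agree on identical inputs.
#'
#' @param gm A [geno_matrix()].
#' @param parental_freqs Parental-frequency tibble
#'   ([estimate_parental_freqs()] or [build_parental_freqs()]).
#' @return A tibble of class `ancestry_table`: `id`, `q`, `q_low`,
#'   `q_high`, `n_informative`.
#' @export
supervised_q <- function(gm, parental_freqs) {
  hi <- hybrid_index(gm, parental_freqs)
  out <- tibble::tibble(id = hi$id, q = hi$hi, q_low = hi$hi_low,
                        q_high = hi$hi_high,
                        n_informative = hi$n_informative)
  class(out) <- c("ancestry_table", class(out))
  out
}

#' Designate parental and putative-hybrid individuals from Q
#'
#' Applies the ancestry-proportion bands: Q > 0.98 -> parental species 2,
#' Q < 0.02 -> parental species 1, 0.05 < Q < 0.95 -> putative hybrid;
#' individuals in the remaining gaps (\[0.02, 0.05\] and \[0.95, 0.98\]) are
#' left unassigned rather than forced into a class.
#'
#' @param q_table Tibble with a `q` column (e.g. from [supervised_q()]).
#' @return The input with a `designation` column added
#'   (`"parental_P1"`, `"parental_P2"`, `"putative_hybrid"`,
#'   `"unassigned"`).
#' @export
designate_classes <- function(q_table) {
  stopifnot("q" %in% names(q_table), all(q_table$q >= 0 & q_table$q <= 1))
  q_table$designation <- dplyr::case_when(
    q_table$q > 0.98 ~ "parental_P2",
    q_table$q < 0.02 ~ "parental_P1",
    q_table$q > 0.05 & q_table$q < 0.95 ~ "putative_hybrid",
    TRUE ~ "unassigned"
  )
  q_table
}
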