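#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PCA of genotypes
#'
#' @param x A `geno_pca`.
#' @param ... Unused.
#' @return A tibble of per-individual scores in long form: `id`,
#'   `component`, `score`.
#' @method tidy geno_pca
#' @export
tidy.geno_pca <- function(x, ...) {
  sc <- tibble::as_tibble(x$scores, rownames = "id")
  tidyr::pivot_longer(sc, -"id", names_to = "component", values_to = "score")
}

#' @rdname tidy.geno_pca
#' @return `glance()`: a one-row tibble with `n_components` and the
#'   variance explained by the first two components.
#' @method glance geno_pca
#' @export
glance.geno_pca <- function(x, ...) {
  tibble::tibble(n_components = ncol(x$scores),
                 var_pc1 = x$var_explained[1],
                 var_pc2 = if (length(x$var_explained) > 1)
                   x$var_explained[2] else NA_real_)
}

#' Tidy a cluster model
#'
#' @param x A `cluster_model`.
#' @param ... Unused.
#' @return `tidy()`: the per-K BIC table; `glance()`: one row with the
#'   selected `k` and its BIC.
#' @method tidy cluster_model
#' @export
tidy.cluster_model <- function(x, ...) x$bic

#' @rdname tidy.cluster_model
#' @method glance cluster_model
#' @export
glance.cluster_model <- function(x, ...) {
  tibble::tibble(k = x$k, bic = x$bic$bic[x$k],
                 n = length(x$assignments))
}

#' Tidy an ABBA-BABA result
#'
#' @param x A `dstat_result`.
#' @param ... Unused.
#' @return `tidy()`: the result row as a plain tibble; `glance()`: the
#'   headline statistics (`d`, `z`, `p`, `f_admix`).
#' @method tidy dstat_result
#' @export
tidy.dstat_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidy.dstat_result
#' @method glance dstat_result
#' @export
glance.dstat_result <- function(x, ...) {
  tibble::tibble(d = x$d, z = x$z, p = x$p, f_admix = x$f_admix)
}
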