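#' Genotype matrix container
#'
#' Builds the container used throughout the package for diploid biallelic SNP
#' genotypes: an integer matrix of alt-allele dosages (samples in rows, loci
#' in columns) with values 0, 1, 2 or `NA` for a missing call, optionally
#' accompanied by a same-shape read-depth matrix and per-locus coordinates.
#'
#' @param dosage Integer matrix, samples x loci, entries in `{0, 1, 2, NA}`.
#'   Row names are sample ids, column names locus ids; both are required and
#'   must be unique.
#' @param chrom Character vector of chromosome/contig names, one per locus.
#'   Defaults to `"1"` for every locus.
#' @param pos Integer vector of 1-based positions, one per locus. Defaults to
#'   `seq_len(ncol(dosage))`.
#' @param depth Optional integer matrix of per-genotype read depths with the
#'   same dimensions as `dosage`.
#'
#' @return An object of class `geno_matrix`.
#' @export
#' @examples
#' gm <- geno_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("l1", "l2"))))
#' dim(gm)
geno_matrix <- function(dosage, chrom = NULL, pos = NULL, depth = NULL) {
  if (!is.matrix(dosage)) stop("`dosage` must be a matrix")
  storage.mode(dosage) <- "integer"
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  if (is.null(rownames(dosage)) && nrow(dosage) > 0) {
    rownames(dosage) <- paste0("sample_", seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage)) && ncol(dosage) > 0) {
    colnames(dosage) <- paste0("locus_", seq_len(ncol(dosage)))
  }
  if (anyDuplicated(rownames(dosage))) stop("sample ids must be unique")
  if (anyDuplicated(colnames(dosage))) stop("locus ids must be unique")
  if (is.null(chrom)) chrom <- rep("1", ncol(dosage))
  if (is.null(pos)) pos <- seq_len(ncol(dosage))
  stopifnot(length(chrom) == ncol(dosage), length(pos) == ncol(dosage))
  if (!is.null(depth)) {
    if (!identical(dim(depth), dim(dosage))) {
      stop("`depth` must have the same dimensions as `dosage`")
    }
    storage.mode(depth) <- "integer"
    dimnames(depth) <- dimnames(dosage)
  }
  structure(
    list(dosage = dosage, chrom = as.character(chrom), pos = as.integer(pos),
         depth = depth),
    class = "geno_matrix"
  )
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Sample and locus ids of a genotype matrix
#' @param gm A [geno_matrix()].
#' @return Character vector of ids.
#' @export
sample_ids <- function(gm) rownames(gm$dosage)

#' @rdname sample_ids
#' @export
locus_ids <- function(gm) colnames(gm$dosage)

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d loci", nrow(x$dosage),
              ncol(x$dosage)))
  miss <- mean(is.na(x$dosage))
  cat(sprintf(" (%.1f%% missing%s)\n", 100 * miss,
              if (is.null(x$depth)) "" else ", depth present"))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param i Sample selector (indices, logical or names).
#' @param j Locus selector.
#' @param ... Unused.
#' @return A `geno_matrix` restricted to the selected samples and loci.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(j)) j <- match(j, colnames(x$dosage))
  if (is.logical(j)) j <- which(j)
  geno_matrix(x$dosage[i, j, drop = FALSE],
              chrom = x$chrom[j], pos = x$pos[j],
              depth = if (!is.null(x$depth)) x$depth[i, j, drop = FALSE])
}

#' Convert a genotype matrix to a long tibble
#'
#' @param x A [geno_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `locus_id`, `dosage` and,
#'   when present, `depth`.
#' @importFrom tibble as_tibble tibble
#' @method as_tibble geno_matrix
#' @export
as_tibble.geno_matrix <- function(x, ...) {
  out <- tibble::tibble(
    sample_id = rep(rownames(x$dosage), times = ncol(x$dosage)),
    locus_id = rep(colnames(x$dosage), each = nrow(x$dosage)),
    dosage = as.integer(x$dosage)
  )
  if (!is.null(x$depth)) out$depth <- as.integer(x$depth)
  out
}

#' Per-locus allele frequencies over called genotypes
#'
#' Alt-allele frequency per locus, ignoring missing calls.
#'
#' @param gm A [geno_matrix()].
#' @return Named numeric vector (NaN where no genotype is called).
#' @export
allele_freqs <- function(gm) {
  colMeans(gm$dosage, na.rm = TRUE) / 2
}

locus_tibble <- function(gm) {
  tibble::tibble(locus_id = locus_ids(gm), chrom = gm$chrom, pos = gm$pos)
}
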