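#' Read a VCF file into a genotype matrix
#'
#' Parses a VCFv4.x file of diploid biallelic SNPs into a [geno_matrix()].
#' Genotypes are decoded from the GT field (`0/0 -> 0`, `0/1` or `1/0 -> 1`,
#' `1/1 -> 2`, `./.` or `.` -> missing); phased separators (`|`) are accepted.
#' Per-genotype read depths are taken from the DP format field when present.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param drop_multiallelic Drop records whose ALT field contains more than
#'   one allele (default) instead of failing.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, drop_multiallelic = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  if (any(multi)) {
    if (!drop_multiallelic) stop("multi-allelic records present")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # normalise phased genotypes and decode to dosage
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  dos[gt_clean %in% "0/0"] <- 0L
  dos[gt_clean %in% c("0/1", "1/0")] <- 1L
  dos[gt_clean %in% "1/1"] <- 2L
  unknown <- !is.na(gt_clean) & !(gt_clean %in% c("0/0", "0/1", "1/0", "1/1", "./.", "."))
  if (any(unknown)) {
    stop("unsupported GT values (non-diploid or non-biallelic): ",
         paste(utils::head(unique(gt_clean[unknown]), 3), collapse = ", "))
  }
  locus <- unname(fix[, "ID"])
  blank <- is.na(locus) | locus == "."
  locus[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])
  dimnames(dos) <- list(locus, colnames(gt))
  depth <- NULL
  if ("DP" %in% unlist(strsplit(v@gt[, "FORMAT"], ":"))) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    depth <- t(matrix(as.integer(dp), nrow = nrow(dp), dimnames = dimnames(dos)))
  }
  geno_matrix(t(dos), chrom = unname(fix[, "CHROM"]),
              pos = unname(as.integer(fix[, "POS"])), depth = depth)
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal plain-text VCFv4.2 file with GT (and DP, when depths are
#' present) per genotype. Missing dosages become `./.`. REF/ALT are written
#' as A/T placeholders: this container carries dosages, not nucleotides.
#'
#' @param gm A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  fmt <- if (is.null(gm$depth)) "GT" else "GT:DP"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hybridzone",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(gm$depth))
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(gm)), collapse = "\t")
  )
  lines <- character(ncol(gm$dosage))
  for (j in seq_len(ncol(gm$dosage))) {
    g <- gm$dosage[, j]
    cells <- ifelse(is.na(g), "./.", code[as.character(g)])
    if (!is.null(gm$depth)) {
      dp <- gm$depth[, j]
      cells <- paste0(cells, ":", ifelse(is.na(dp), ".", dp))
    }
    lines[j] <- paste(c(gm$chrom[j], gm$pos[j], locus_ids(gm)[j], "A", "T",
                        ".", "PASS", ".", fmt, cells), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' Reads a FASTA alignment into the package's haplotype-alignment form: a
#' character matrix (sequences in rows, sites in columns) over
#' `A/C/G/T/N/-`, upper-cased, with unique ids. All records must have equal
#' length.
#'
#' @param path Path to a FASTA file.
#' @return A character matrix of class `hap_alignment`.
#' @export
read_fasta <- function(path) {
  seqs <- ape::read.FASTA(path)
  chars <- lapply(as.character(seqs), function(s) toupper(s))
  lens <- lengths(chars)
  if (length(unique(lens)) > 1) {
    stop("sequences are not aligned: lengths ", paste(unique(lens), collapse = ", "))
  }
  hap_alignment(do.call(rbind, chars))
}

#' Construct a haplotype alignment
#'
#' @param m Character matrix, sequences x sites, entries in `A/C/G/T/N/-`.
#' @return The matrix with class `hap_alignment`.
#' @export
hap_alignment <- function(m) {
  if (!is.matrix(m) || !is.character(m)) stop("alignment must be a character matrix")
  m[] <- toupper(m)
  ok <- m %in% c("A", "C", "G", "T", "N", "-")
  if (!all(ok)) stop("alignment contains characters outside A/C/G/T/N/-")
  if (is.null(rownames(m))) rownames(m) <- paste0("seq_", seq_len(nrow(m)))
  if (anyDuplicated(rownames(m))) stop("sequence ids must be unique")
  structure(m, class = c("hap_alignment", class(m)))
}

#' Write a haplotype alignment to FASTA
#'
#' @param aln A `hap_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  lines <- character(2L * nrow(aln))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln))
  lines[c(FALSE, TRUE)] <- apply(aln, 1, paste0, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' Read or write the sample metadata table
#'
#' The metadata TSV has one row per sequenced individual with at least the
#' columns `id`, `species_morph` and `population`; simulator output adds
#' `true_class` and `mt_clade`.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble.
#' @export
read_sample_table <- function(path) {
  tb <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                            colClasses = "character"))
  need <- c("id", "species_morph", "population")
  if (!all(need %in% names(tb))) {
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tb$id)) stop("sample ids must be unique")
  tb
}

#' @rdname read_sample_table
#' @param samples Tibble of sample metadata.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
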