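#' Pipeline configuration
#'
#' Bundles the inputs and thresholds for a full hybrid-zone analysis run.
#' Provide either a [sim_config()] (the simulator generates the dataset)
#' or paths to a VCF, a FASTA mtDNA alignment and a sample TSV.
#'
#' @param sim A [sim_config()], or `NULL` when reading files.
#' @param vcf,fasta,samples Input paths (ignored when `sim` is given).
#' @param filter A [filter_config()].
#' @param pca_k Principal components used by the outlier scan (default 2).
#' @param k_max Largest K for BIC cluster selection (default 10).
#' @param alpha FDR level of the outlier scan (default 0.05).
#' @param delta Informative-locus threshold for parental frequencies.
#' @param het_mode Loci used for interspecific heterozygosity
#'   (`"fixed"`/`"delta"`).
#' @param block_size Jackknife block size for the ABBA-BABA test.
#' @param coalescent_reps Replicates for the mtDNA neutrality-test
#'   p-values (default 10000).
#' @param use_neutral Run clustering, hybrid and introgression stages on
#'   the neutral locus partition (default `TRUE`).
#' @param out_dir Output directory for reports.
#' @param seed Seed for every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, vcf = NULL, fasta = NULL,
                            samples = NULL, filter = filter_config(),
                            pca_k = 2, k_max = 10, alpha = 0.05,
                            delta = 0.8, het_mode = "fixed",
                            block_size = 1000, coalescent_reps = 10000,
                            use_neutral = TRUE, out_dir = tempfile("hzrun"),
                            seed = 1L) {
  if (is.null(sim) && (is.null(vcf) || is.null(fasta) || is.null(samples))) {
    stop("provide either `sim` or all of `vcf`, `fasta`, `samples`")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

mt_group_labels <- function(samples) {
  ifelse(samples$species_morph == "species2", "species2_all",
         paste0("species1_", samples$mt_clade))
}

#' Run the full hybrid-zone analysis pipeline
#'
#' Executes simulate/read -> QC filter -> diversity and differentiation ->
#' outlier partition -> clustering -> supervised ancestry and designation ->
#' hybrid index / heterozygosity / triangle classes -> ABBA-BABA ->
#' folded SFS, writing tidy TSV reports and a run log to
#' `cfg$out_dir`. Clustering, hybrid and introgression stages consume the
#' neutral partition when `cfg$use_neutral` is set, mirroring standard
#' practice of separating putatively selected loci before demographic
#' inference. Runs are deterministic under a fixed seed.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `hybridzone_run` with all stage results.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  if (!is.null(cfg$sim)) {
    sim <- generate_dataset(cfg$sim, file.path(cfg$out_dir, "data"))
    gm_raw <- read_vcf(sim$paths$vcf)
    aln <- read_fasta(sim$paths$fasta)
    samples <- read_sample_table(sim$paths$samples)
  } else {
    gm_raw <- read_vcf(cfg$vcf)
    aln <- read_fasta(cfg$fasta)
    samples <- read_sample_table(cfg$samples)
  }
  flt <- filter_genotypes(gm_raw, cfg$filter)
  gm <- flt$gm
  samples <- samples[samples$id %in% sample_ids(gm), ]
  samples$group <- paste(samples$species_morph, samples$population, sep = "_")

  diversity <- nuclear_diversity(gm, samples, by = "group")
  differentiation <- pairwise_differentiation(gm, samples, by = "group")
  mt_samples <- samples
  mt_samples$mt_group <- mt_group_labels(samples)
  mtdiv <- mt_diversity(aln, mt_samples, by = "mt_group",
                        reps = cfg$coalescent_reps)

  scan <- pc_outlier_scan(gm, k = cfg$pca_k, alpha = cfg$alpha)
  part <- partition_loci(scan)
  gm_neutral <- if (cfg$use_neutral) gm[, part$neutral] else gm

  pca <- genotype_pca(gm_neutral)
  clusters <- choose_k_bic(pca, k_max = cfg$k_max)

  sp1 <- samples$id[samples$species_morph == "species1"]
  sp2 <- samples$id[samples$species_morph == "species2"]
  freqs0 <- estimate_parental_freqs(gm_neutral, sp1, sp2, delta = cfg$delta)
  q_tbl <- designate_classes(supervised_q(gm_neutral, freqs0))
  par1 <- q_tbl$id[q_tbl$designation == "parental_P1"]
  par2 <- q_tbl$id[q_tbl$designation == "parental_P2"]
  if (length(par1) >= 2 && length(par2) >= 2) {
    freqs <- estimate_parental_freqs(gm_neutral, par1, par2, delta = cfg$delta)
  } else {
    freqs <- freqs0
  }
  hyb <- hybrid_report(gm_neutral, freqs, het_mode = cfg$het_mode,
                       parental_ids = c(par1, par2))
  hyb <- dplyr::left_join(hyb, q_tbl[, c("id", "q", "designation")], by = "id")

  dres <- NULL
  trio_groups <- c("species1_N", "species1_S", "species2_N", "species2_S")
  if (all(trio_groups %in% samples$group)) {
    trio <- trio_spec("species1_N", "species1_S", "species2_N", "species2_S")
    n_loci_used <- ncol(gm_neutral$dosage)
    bs <- min(cfg$block_size, max(1L, floor(n_loci_used / 2)))
    dres <- abba_baba(gm_neutral, samples, trio, by = "group",
                      block_size = bs)
  }

  sfs <- list(
    species1 = folded_sfs(gm, ids = sp1),
    species2 = folded_sfs(gm, ids = sp2)
  )
  for (sp in names(sfs)) {
    write_blueprint(sfs[[sp]], file.path(cfg$out_dir,
                                         paste0("blueprint_", sp, ".txt")),
                    popid = sp)
  }

  res <- structure(list(
    config = cfg, filter_log = flt$log, dropped_loci = flt$dropped_loci,
    gm = gm, gm_neutral = gm_neutral, samples = samples,
    diversity = diversity, differentiation = differentiation,
    mt_diversity = mtdiv, outlier_scan = scan, partition = part,
    pca = pca, clusters = clusters, ancestry = q_tbl,
    parental_freqs = freqs, hybrid_report = hyb, dstat = dres, sfs = sfs
  ), class = "hybridzone_run")
  write_report(res, cfg$out_dir)
  res
}

fmt3 <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 3, format = "f"))
  df
}

write_tsv_report <- function(df, path, round3 = TRUE) {
  if (round3) df <- fmt3(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the tidy TSV report bundle for a pipeline run
#'
#' Emits one TSV per stage (diversity, differentiation, mitochondrial
#' diversity with neutrality tests, ancestry, hybrid report, ABBA-BABA,
#' folded SFS, filter log and locus drop reasons) plus `run_log.txt` with
#' the package version, seed and per-stage record counts. Numeric report
#' columns are formatted to 3 decimal places; the column order is fixed.
#'
#' @param res A `hybridzone_run` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(out_dir, name)
  write_tsv_report(res$diversity, f("diversity_nuclear.tsv"))
  write_tsv_report(res$differentiation, f("differentiation.tsv"))
  write_tsv_report(res$mt_diversity, f("diversity_mtdna.tsv"))
  write_tsv_report(res$ancestry, f("ancestry.tsv"))
  write_tsv_report(res$hybrid_report, f("hybrid_report.tsv"))
  if (!is.null(res$dstat)) write_tsv_report(res$dstat, f("dstat.tsv"))
  for (sp in names(res$sfs)) {
    write_tsv_report(as.data.frame(res$sfs[[sp]]),
                     f(paste0("sfs_", sp, ".tsv")), round3 = FALSE)
  }
  write_tsv_report(res$filter_log, f("filter_log.tsv"), round3 = FALSE)
  write_tsv_report(res$dropped_loci, f("dropped_loci.tsv"), round3 = FALSE)
  log <- c(
    sprintf("hybridzone version: %s",
            as.character(utils::packageVersion("hybridzone"))),
    sprintf("seed: %d", res$config$seed),
    sprintf("samples analysed: %d", nrow(res$samples)),
    sprintf("loci after filtering: %d", ncol(res$gm$dosage)),
    sprintf("neutral loci: %d", length(res$partition$neutral)),
    sprintf("non-neutral loci: %d", length(res$partition$non_neutral)),
    sprintf("clusters selected (BIC): %d", res$clusters$k),
    sprintf("putative hybrids: %d",
            sum(res$ancestry$designation == "putative_hybrid"))
  )
  writeLines(log, f("run_log.txt"))
  invisible(list.files(out_dir, full.names = TRUE))
}

#' @export
print.hybridzone_run <- function(x, ...) {
  cat("<hybridzone_run>\n")
  cat(sprintf("  %d samples, %d loci (%d neutral)\n", nrow(x$samples),
              ncol(x$gm$dosage), length(x$partition$neutral)))
  cat(sprintf("  K = %d clusters; %d putative hybrids\n", x$clusters$k,
              sum(x$ancestry$designation == "putative_hybrid")))
  if (!is.null(x$dstat)) {
    cat(sprintf("  Patterson's D = %.3f (Z = %.2f)\n", x$dstat$d, x$dstat$z))
  }
  invisible(x)
}
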