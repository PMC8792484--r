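test_that("parental frequency draws respect the fixed-difference fraction", {
  set.seed(1)
  cfg <- sim_config(n_loci = 200, frac_fixed = 1)
  fr <- build_parental_freqs(cfg)
  expect_true(all(abs(fr$p1 - fr$p2) == 1))
  cfg0 <- sim_config(n_loci = 200, frac_fixed = 0, fst_target = 0)
  fr0 <- build_parental_freqs(cfg0)
  expect_identical(fr0$p1, fr0$p2)
  expect_true(all(fr0$p1 >= 0 & fr0$p1 <= 1))
})

test_that("Balding-Nichols divergence hits the FST target", {
  set.seed(2)
  cfg <- sim_config(n_loci = 10000, frac_fixed = 0, fst_target = 0.2)
  fr <- build_parental_freqs(cfg)
  g1 <- sample_parental_genotypes(fr, 30, "P1")
  g2 <- sample_parental_genotypes(fr, 30, "P2")
  gm <- make_gm(rbind(g1, g2), samples = paste0("s", 1:60))
  samples <- tibble::tibble(id = paste0("s", 1:60),
                            species_morph = rep(c("P1", "P2"), each = 30),
                            population = rep(c("P1", "P2"), each = 30))
  fst <- pairwise_differentiation(gm, samples)$fst
  expect_lt(abs(fst - 0.2), 0.03)
})

test_that("parental sampling is Hardy-Weinberg binomial", {
  fr <- tibble::tibble(locus_id = c("fix1", "fix0", "half"),
                       p1 = c(1, 0, 0.5), p2 = c(1, 0, 0.5))
  set.seed(3)
  g <- sample_parental_genotypes(fr, 10000, "P1")
  expect_true(all(g[, "fix1"] == 2L))
  expect_true(all(g[, "fix0"] == 0L))
  frac <- tabulate(g[, "half"] + 1L, 3) / 10000
  expect_true(all(abs(frac - c(0.25, 0.5, 0.25)) < 0.02))
})

test_that("breeding follows Mendelian gamete draws", {
  expect_identical(breed(rep(2L, 5), rep(2L, 5)), rep(2L, 5))
  # fixed-difference parents give an all-heterozygous F1
  expect_identical(breed(rep(0L, 100), rep(2L, 100)), rep(1L, 100))
  expect_error(breed(0:1, 0:2), "mismatched")
  # F1 x P1 at fixed loci: expected mean dosage 0.5 (hybrid index 0.25)
  set.seed(4)
  off <- breed(rep(1L, 2000), rep(0L, 2000))
  expect_lt(abs(mean(off) - 0.5), 0.05)
})

test_that("backcross dosage converges to the pedigree expectation", {
  # enumeration: mean alt dosage of BXn toward P1 is 2 * (1/2)^(n+1)
  set.seed(5)
  for (n_gen in 1:3) {
    g <- bx_toward_p1(n_gen, 4000)
    expect_lt(abs(mean(g) - 2 * 0.5^(n_gen + 1)), 0.04)
  }
})

test_that("mitochondrial capture hits the configured probability", {
  samples <- tibble::tibble(id = paste0("s", 1:500),
                            true_class = rep("P1", 500))
  set.seed(6)
  cfg0 <- sim_config(n_loci = 10, capture_prob = 0,
                     n_per_class = c(P1 = 500))
  expect_true(all(simulate_mtdna(cfg0, samples)$mt_clade == "clade1"))
  cfg1 <- sim_config(n_loci = 10, capture_prob = 1,
                     n_per_class = c(P1 = 500))
  expect_true(all(simulate_mtdna(cfg1, samples)$mt_clade == "clade2"))
  cfg4 <- sim_config(n_loci = 10, capture_prob = 0.4,
                     n_per_class = c(P1 = 500))
  frac <- mean(simulate_mtdna(cfg4, samples)$mt_clade == "clade2")
  expect_lt(abs(frac - 0.4), 0.07)
})

test_that("clades differ by the diagnostic sites and hybrids follow the maternal line", {
  cfg <- sim_config(n_loci = 10, mt_length = 300, mt_diag_sites = 12,
                    mt_private_mean = 0, capture_prob = 0,
                    hybrid_maternal = "P2",
                    n_per_class = c(P1 = 3, P2 = 3, F1 = 2))
  samples <- tibble::tibble(id = paste0("s", 1:8),
                            true_class = rep(c("P1", "P2", "F1"), c(3, 3, 2)))
  set.seed(7)
  mt <- simulate_mtdna(cfg, samples)
  expect_equal(mt$mt_clade, rep(c("clade1", "clade2", "clade2"), c(3, 3, 2)))
  diffs <- sum(mt$aln[1, ] != mt$aln[4, ])
  expect_equal(diffs, 12)
})

test_that("dataset generation is deterministic and round-trips exactly", {
  cfg <- sim_config(n_loci = 120, frac_fixed = 0.1, fst_target = 0.3,
                    n_per_class = c(P1 = 20, P2 = 20, F1 = 5), seed = 99)
  d1 <- generate_dataset(cfg, withr::local_tempdir())
  d2 <- generate_dataset(cfg, withr::local_tempdir())
  for (f in names(d1$paths)) {
    expect_identical(readLines(d1$paths[[f]]), readLines(d2$paths[[f]]))
  }
  # 45 sample columns in the VCF
  header <- grep("^#CHROM", readLines(d1$paths$vcf), value = TRUE)
  expect_equal(length(strsplit(header, "\t")[[1]]) - 9L, 45L)
  # reading back reproduces the in-memory matrices exactly
  gm <- read_vcf(d1$paths$vcf)
  expect_identical(gm$dosage, d1$gm$dosage)
  expect_identical(gm$depth, d1$gm$depth)
  aln <- read_fasta(d1$paths$fasta)
  expect_identical(unclass(aln)[, ], unclass(d1$aln)[, ])
})

test_that("F1s from fixed-difference parents are heterozygous everywhere", {
  cfg <- sim_config(n_loci = 300, frac_fixed = 1, missing_rate = 0,
                    n_per_class = c(P1 = 2, P2 = 2, F1 = 4), seed = 13)
  d <- generate_dataset(cfg, withr::local_tempdir())
  f1 <- d$gm$dosage[d$samples$true_class == "F1", ]
  expect_true(all(f1 == 1L))
})
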