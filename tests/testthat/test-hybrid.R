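test_that("parental frequency estimation matches direct counting", {
  set.seed(51)
  gm <- random_gm(12, 30, miss = 0.15)
  ids1 <- sample_ids(gm)[1:6]; ids2 <- sample_ids(gm)[7:12]
  fr <- suppressWarnings(estimate_parental_freqs(gm, ids1, ids2))
  for (j in c(1, 13, 30)) {
    g1 <- gm$dosage[1:6, j]; g1 <- g1[!is.na(g1)]
    g2 <- gm$dosage[7:12, j]; g2 <- g2[!is.na(g2)]
    expect_equal(fr$p1[j], sum(g1) / (2 * length(g1)))
    expect_equal(fr$p2[j], sum(g2) / (2 * length(g2)))
  }
  expect_error(estimate_parental_freqs(gm, ids1[1], ids2), "at least 2")
  # fixed panels are informative, identical panels are not
  gm2 <- make_gm(rbind(matrix(0L, 3, 4), matrix(2L, 3, 4)))
  fr2 <- suppressWarnings(
    estimate_parental_freqs(gm2, sample_ids(gm2)[1:3], sample_ids(gm2)[4:6]))
  expect_true(all(fr2$fixed_diff) && all(fr2$informative))
  gm3 <- make_gm(matrix(1L, 6, 4))
  fr3 <- suppressWarnings(
    estimate_parental_freqs(gm3, sample_ids(gm3)[1:3], sample_ids(gm3)[4:6]))
  expect_false(any(fr3$informative))
})

test_that("hybrid index hits its analytic anchors exactly", {
  freqs <- fixed_freqs(500)
  # fully heterozygous F1: HI exactly 0.5
  hi_f1 <- hybrid_index(rep(1L, 500), freqs)
  expect_identical(hi_f1$hi, 0.5)
  # homozygous for panel-2 alleles everywhere: HI = 1
  expect_identical(hybrid_index(rep(2L, 500), freqs)$hi, 1)
  expect_identical(hybrid_index(rep(0L, 500), freqs)$hi, 0)
  # support interval brackets the estimate
  expect_true(hi_f1$hi_low <= 0.5 && hi_f1$hi_high >= 0.5)
  expect_error(hybrid_index(rep(1L, 4), fixed_freqs(4)[0, ]), "informative")
})

test_that("BX2 hybrid index converges to the pedigree expectation", {
  set.seed(52)
  # BX2 toward P2: expected HI = 1 - (1/2)^3 = 0.875
  G <- t(replicate(100, 2L - bx_toward_p1(2, 2000)))
  gm <- make_gm(G, loci = fixed_freqs(2000)$locus_id)
  hi <- hybrid_index(gm, fixed_freqs(2000))
  expect_lt(abs(mean(hi$hi) - 0.875), 0.02)
})

test_that("estimator error shrinks as informative loci grow", {
  set.seed(53)
  err <- vapply(c(200, 2000, 20000), function(L) {
    G <- t(replicate(10, breed(rep(1L, L), rep(0L, L))))  # BX1, expect 0.25
    gm <- make_gm(G, loci = fixed_freqs(L)$locus_id)
    mean(abs(hybrid_index(gm, fixed_freqs(L))$hi - 0.25))
  }, numeric(1))
  expect_lt(err[3], 0.02)
  expect_true(all(diff(err) < 0))
})

test_that("interspecific heterozygosity follows Mendelian expectations", {
  freqs <- fixed_freqs(400)
  expect_equal(interspecific_heterozygosity(rep(1L, 400), freqs)$het, 1)
  expect_equal(interspecific_heterozygosity(rep(0L, 400), freqs)$het, 0)
  # F2: half the fixed loci heterozygous in expectation
  set.seed(54)
  f2 <- t(replicate(50, breed(rep(1L, 2000), rep(1L, 2000))))
  gm <- make_gm(f2, loci = fixed_freqs(2000)$locus_id)
  het <- interspecific_heterozygosity(gm, fixed_freqs(2000))
  expect_lt(abs(mean(het$het) - 0.5), 0.02)
  # at fixed loci het equals the raw heterozygote fraction exactly
  g <- c(rep(1L, 120), rep(0L, 280))
  expect_equal(interspecific_heterozygosity(g, freqs)$het, 120 / 400)
  expect_error(interspecific_heterozygosity(rep(1L, 4),
                                            tibble::tibble(locus_id = "l1",
                                                           p1 = 0.5, p2 = 0.5)),
               "usable")
})

test_that("triangle classification applies the generation rules", {
  expect_equal(classify_hybrid(0.5, 1.0), "recent_generation")
  expect_equal(classify_hybrid(0.5, 0.3), "later_generation")
  expect_equal(classify_hybrid(0.63, 0.08), "later_generation")
  expect_equal(classify_hybrid(0.10, 0.05), "multigen_backcross")
  expect_equal(classify_hybrid(0.80, 0.3), "multigen_backcross")
  # boundaries resolve to the outer class
  expect_equal(classify_hybrid(0.25, 0.9), "multigen_backcross")
  expect_equal(classify_hybrid(0.75, 0.9), "multigen_backcross")
  expect_equal(classify_hybrid(0.5, 0.5), "later_generation")
})

test_that("the hybrid report combines index, heterozygosity and classes", {
  freqs <- fixed_freqs(300)
  G <- rbind(P1 = rep(0L, 300), P2 = rep(2L, 300), F1 = rep(1L, 300))
  colnames(G) <- freqs$locus_id
  gm <- geno_matrix(G)
  rep_tbl <- hybrid_report(gm, freqs, parental_ids = c("P1", "P2"))
  expect_equal(rep_tbl$generation_class,
               c("parental", "parental", "recent_generation"))
  expect_equal(rep_tbl$hi, c(0, 1, 0.5))
  expect_equal(rep_tbl$het, c(0, 0, 1))
  # empty input gives an empty table with the same columns
  empty <- hybrid_report(gm[integer(0), ], freqs)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("id", "hi", "het", "generation_class") %in% names(empty)))
  # the triangle plot is a ggplot with one point per individual
  p <- plot_triangle(rep_tbl)
  expect_s3_class(p, "ggplot")
  expect_equal(nrow(p$data), 3)
})
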