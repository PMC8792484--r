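test_that("nuclear diversity matches a brute-force per-locus enumeration", {
  set.seed(21)
  gm <- random_gm(10, 10, miss = 0.1)
  samples <- tibble::tibble(id = sample_ids(gm),
                            species_morph = "x",
                            population = rep(c("A", "B"), each = 5))
  res <- nuclear_diversity(gm, samples)
  for (pop in c("A", "B")) {
    rows <- which(samples$population == pop)
    ho <- he <- ne <- na <- fis <- c(); npoly <- 0
    for (j in 1:10) {
      g <- gm$dosage[rows, j]; g <- g[!is.na(g)]
      if (length(g) == 0) next
      p <- sum(g) / (2 * length(g))
      ho_l <- mean(g == 1)
      he_l <- 2 * p * (1 - p) * 2 * length(g) / (2 * length(g) - 1)
      ho <- c(ho, ho_l); he <- c(he, he_l)
      ne <- c(ne, 1 / (p^2 + (1 - p)^2))
      na <- c(na, if (p > 0 && p < 1) 2 else 1)
      if (p > 0 && p < 1) { npoly <- npoly + 1; fis <- c(fis, 1 - ho_l / he_l) }
    }
    row <- res[res$population == pop, ]
    expect_equal(row$h_o, mean(ho))
    expect_equal(row$h_e, mean(he))
    expect_equal(row$pi, mean(he))
    expect_equal(row$n_e, mean(ne))
    expect_equal(row$n_a, mean(na))
    expect_equal(row$n_poly, npoly)
    expect_equal(row$f_is, mean(fis))
  }
})

test_that("complete heterozygote excess gives strongly negative F_IS", {
  dos <- matrix(1L, nrow = 6, ncol = 4)  # everyone heterozygous, p = 0.5
  gm <- make_gm(dos)
  samples <- tibble::tibble(id = sample_ids(gm), species_morph = "x",
                            population = "A")
  res <- nuclear_diversity(gm, samples)
  expect_equal(res$h_o, 1)
  expect_lt(res$f_is, -0.8)
})

test_that("private alleles are counted against all other populations", {
  dos <- rbind(c(0L, 2L), c(0L, 2L),   # pop A: only ref at locus1, only alt at locus2
               c(1L, 2L), c(1L, 2L))   # pop B: both alleles at locus1, only alt at locus2
  gm <- make_gm(dos)
  samples <- tibble::tibble(id = sample_ids(gm), species_morph = "x",
                            population = rep(c("A", "B"), each = 2))
  res <- nuclear_diversity(gm, samples)
  # locus1 alt allele is private to B; nothing is private to A
  expect_equal(res$a_private[res$population == "A"], 0)
  expect_equal(res$a_private[res$population == "B"], 1)
})

test_that("FST and Jost's D reach their analytic extremes", {
  dos <- rbind(matrix(0L, 8, 5), matrix(2L, 8, 5))
  gm <- make_gm(dos)
  samples <- tibble::tibble(id = sample_ids(gm), species_morph = "x",
                            population = rep(c("A", "B"), each = 8))
  res <- pairwise_differentiation(gm, samples)
  expect_equal(res$fst, 1)
  expect_equal(res$jost_d, 1)
  # identical allele frequencies: both near zero
  set.seed(22)
  g <- matrix(rbinom(2 * 40 * 200, 2, 0.4), nrow = 80)
  gm2 <- make_gm(g)
  samples2 <- tibble::tibble(id = sample_ids(gm2), species_morph = "x",
                             population = rep(c("A", "B"), each = 40))
  res2 <- pairwise_differentiation(gm2, samples2)
  expect_lt(abs(res2$fst), 0.01)
  expect_lt(res2$jost_d, 0.01)
})

test_that("FST and Jost's D match independently computed values", {
  fx <- oracle_two_pops()
  res <- pairwise_differentiation(fx$gm, fx$samples)
  expect_equal(res$fst, 0.1841155, tolerance = 1e-6)
  expect_equal(res$jost_d, 0.1854978, tolerance = 1e-6)
})

test_that("haplotype summaries follow their definitions", {
  # 13 pairwise-distinct sequences: unbiased Hd is exactly 1
  m <- matrix("A", 13, 20)
  for (i in 1:13) m[i, i] <- "C"
  aln <- hap_alignment(m)
  sm <- mtdna_summary(aln)
  expect_equal(sm$h, 13)
  expect_equal(sm$hd, 1)
  # all identical
  sm0 <- mtdna_summary(hap_alignment(matrix("G", 5, 10)))
  expect_equal(unlist(sm0[c("h", "s", "hd", "pi")]),
               c(h = 1, s = 0, hd = 0, pi = 0))
  # two haplotypes at counts {2,2}: Hd = 4/3 * (1 - 0.5) = 2/3
  m2 <- rbind(rep("A", 10), rep("A", 10), c("C", rep("A", 9)),
              c("C", rep("A", 9)))
  sm2 <- mtdna_summary(hap_alignment(m2))
  expect_equal(sm2$hd, 2 / 3)
  # pi equals the mean over all C(4,2) pairwise distances: 4 mismatching
  # pairs of 6, 1 site of 10 differs
  expect_equal(sm2$pi, (4 * (1 / 10)) / 6)
})

test_that("Tajima's D and R2 match independent evaluations and error at S=0", {
  aln <- oracle_alignment()
  expect_equal(tajimas_d(aln), 0.6989954, tolerance = 1e-6)
  expect_equal(r2_statistic(aln), 0.2403701, tolerance = 1e-6)
  mono <- hap_alignment(matrix("T", 4, 8))
  expect_error(tajimas_d(mono), "undefined")
  expect_error(r2_statistic(mono), "undefined")
})

test_that("gap and N sites are excluded pairwise for pi, listwise for S", {
  m <- rbind(c("A", "A", "N", "T"),
             c("A", "C", "G", "T"),
             c("A", "C", "G", "-"))
  sm <- mtdna_summary(hap_alignment(m))
  # only columns 1-2 are complete; column 2 segregates
  expect_equal(sm$s, 1)
  # pairwise: d12 over 3 shared sites = 1/3; d13 over 2 shared = 1/2;
  # d23 over 3 shared = 0
  expect_equal(sm$pi, mean(c(1 / 3, 1 / 2, 0)))
})
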