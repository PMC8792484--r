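make_trio_fixture <- function(freq_mat, n_per_pop = 4) {
  # freq_mat: loci x 4 matrix of alt frequencies for P1, P2, P3, OUT;
  # individuals are drawn deterministically fixed at the given frequency
  # (0, 0.5 or 1) so population frequencies are exact
  pops <- c("p1", "p2", "p3", "out")
  dos <- NULL; ids <- c(); pop <- c()
  for (k in 1:4) {
    block <- vapply(freq_mat[, k], function(p) {
      if (p == 0) rep(0L, n_per_pop)
      else if (p == 1) rep(2L, n_per_pop)
      else rep(1L, n_per_pop)  # p = 0.5 via all-heterozygous
    }, integer(n_per_pop))
    dos <- rbind(dos, block)
    ids <- c(ids, paste0(pops[k], "_", seq_len(n_per_pop)))
    pop <- c(pop, rep(pops[k], n_per_pop))
  }
  rownames(dos) <- ids
  list(gm = geno_matrix(dos),
       samples = tibble::tibble(id = ids, species_morph = pop,
                                population = pop))
}

test_that("pure site patterns contribute where they should", {
  # one pure ABBA site, one pure BABA, one pure BBAA
  fm <- rbind(c(0, 1, 1, 0), c(1, 0, 1, 0), c(1, 1, 0, 0))
  fx <- make_trio_fixture(fm)
  trio <- trio_spec("p1", "p2", "p3", "out")
  sp <- site_patterns(fx$gm, fx$samples, trio)
  expect_equal(sp$abba, 1)
  expect_equal(sp$baba, 1)
  expect_equal(sp$bbaa, 1)
  expect_equal(sp$n_used, 3)
})

test_that("sites are polarized on the outgroup major allele", {
  # outgroup fixed for the alt allele: derived = ref allele
  fm <- rbind(c(1, 0, 0, 1))  # after polarization: (0, 1, 1, 0) = pure ABBA
  fx <- make_trio_fixture(fm)
  sp <- site_patterns(fx$gm, fx$samples, trio_spec("p1", "p2", "p3", "out"))
  expect_equal(sp$abba, 1)
  expect_equal(sp$baba, 0)
  # polymorphic outgroup above the threshold is skipped
  fm2 <- rbind(c(0, 1, 1, 0.5))
  fx2 <- make_trio_fixture(fm2)
  sp2 <- site_patterns(fx2$gm, fx2$samples, trio_spec("p1", "p2", "p3", "out"))
  expect_equal(sp2$n_used, 0)
  expect_equal(sp2$n_skipped_polymorphic_outgroup, 1)
})

test_that("pattern counts equal brute-force per-site arithmetic", {
  set.seed(61)
  L <- 50
  fm <- matrix(sample(c(0, 0.5, 1), L * 4, replace = TRUE), ncol = 4)
  fm[, 4] <- sample(c(0, 1), L, replace = TRUE)  # fixed outgroup
  fx <- make_trio_fixture(fm)
  sp <- site_patterns(fx$gm, fx$samples, trio_spec("p1", "p2", "p3", "out"))
  abba <- baba <- bbaa <- 0
  for (l in seq_len(L)) {
    d <- fm[l, ]
    if (d[4] > 0.5) d <- 1 - d  # polarize
    abba <- abba + (1 - d[1]) * d[2] * d[3] * (1 - d[4])
    baba <- baba + d[1] * (1 - d[2]) * d[3] * (1 - d[4])
    bbaa <- bbaa + d[1] * d[2] * (1 - d[3]) * (1 - d[4])
  }
  expect_equal(sp$abba, abba)
  expect_equal(sp$baba, baba)
  expect_equal(sp$bbaa, bbaa)
})

test_that("Patterson's D follows its definition and symmetry", {
  expect_equal(patterson_d(10, 10), 0)
  expect_error(patterson_d(0, 0), "undefined")
  # equal P1 and P2 frequencies give ABBA = BABA
  set.seed(62)
  L <- 40
  f12 <- sample(c(0, 0.5, 1), L, replace = TRUE)
  fm <- cbind(f12, f12, sample(c(0, 0.5, 1), L, replace = TRUE),
              sample(c(0, 1), L, replace = TRUE))
  fx <- make_trio_fixture(fm)
  sp <- site_patterns(fx$gm, fx$samples, trio_spec("p1", "p2", "p3", "out"))
  expect_equal(sp$abba, sp$baba)
  # swapping P1 and P2 negates D
  fm2 <- matrix(sample(c(0, 0.5, 1), 200 * 4, replace = TRUE), ncol = 4)
  fm2[, 4] <- sample(c(0, 1), 200, replace = TRUE)
  fx2 <- make_trio_fixture(fm2)
  s12 <- site_patterns(fx2$gm, fx2$samples, trio_spec("p1", "p2", "p3", "out"))
  s21 <- site_patterns(fx2$gm, fx2$samples, trio_spec("p2", "p1", "p3", "out"))
  expect_equal(patterson_d(s12$abba, s12$baba),
               -patterson_d(s21$abba, s21$baba))
})

test_that("the admixture fraction is 1 when P2 equals P3", {
  set.seed(63)
  L <- 60
  fm <- matrix(sample(c(0, 0.5, 1), L * 4, replace = TRUE), ncol = 4)
  fm[, 4] <- sample(c(0, 1), L, replace = TRUE)
  fm[, 3] <- fm[, 2]
  fx <- make_trio_fixture(fm)
  # relabel P3 individuals as their own population but with P2 genotypes
  f <- f_admix(fx$gm, fx$samples, trio_spec("p1", "p2", "p3", "out"))
  expect_equal(f, 1)
})

test_that("the block jackknife matches the leave-one-out formula", {
  set.seed(64)
  abba_l <- runif(100); baba_l <- runif(100)
  jackknife_d <- getFromNamespace("jackknife_d", "hybridzone")
  jk <- jackknife_d(abba_l, baba_l, block_size = 10)
  expect_equal(jk$n_blocks, 10)
  theta <- vapply(1:10, function(j) {
    drop <- ((j - 1) * 10 + 1):(j * 10)
    patterson_d(sum(abba_l[-drop]), sum(baba_l[-drop]))
  }, numeric(1))
  expect_equal(jk$se, sqrt(9 / 10 * sum((theta - mean(theta))^2)))
  expect_error(jackknife_d(abba_l, baba_l, block_size = 100), "blocks")
})

test_that("introgression is detected and the null is calibrated", {
  set.seed(65)
  n_loci <- 5000
  one_rep <- function(introgress) {
    anc <- runif(n_loci, 0.05, 0.95)
    shape <- (1 - 0.3) / 0.3
    pa <- rbeta(n_loci, anc * shape, (1 - anc) * shape)
    pb <- rbeta(n_loci, anc * shape, (1 - anc) * shape)
    po <- rbeta(n_loci, anc * shape, (1 - anc) * shape)
    draw <- function(p, n) matrix(rbinom(n * n_loci, 2, rep(p, each = n)),
                                  nrow = n)
    g2 <- draw(pa, 8)
    if (introgress) {
      swap <- sample.int(n_loci, round(0.15 * n_loci))
      g2[, swap] <- draw(pb, 8)[, swap]
    }
    dos <- rbind(draw(pa, 8), g2, draw(pb, 8), draw(po, 4))
    rownames(dos) <- paste0("i", seq_len(nrow(dos)))
    gm <- geno_matrix(dos)
    samples <- tibble::tibble(id = rownames(dos), species_morph = "x",
                              population = rep(c("p1", "p2", "p3", "out"),
                                               c(8, 8, 8, 4)))
    abba_baba(gm, samples, trio_spec("p1", "p2", "p3", "out"),
              block_size = 250)
  }
  null_z <- vapply(1:25, function(i) one_rep(FALSE)$z, numeric(1))
  expect_lte(sum(abs(null_z) >= 3), 1)
  alt <- one_rep(TRUE)
  expect_gt(alt$d, 0)
  expect_gt(alt$z, 3)
})
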