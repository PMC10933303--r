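# Per-statistic oracles are hand evaluations of the defining formulas on
# tiny matrices; the assembled vector is checked against those same calls.

test_that("nucleotide diversity matches hand-counted pairwise differences", {
  # 2 haplotypes differing at 2 of 100 sites
  hm <- toy_hm(rbind(c(0, 0), c(1, 1)), c("murphyi", "murphyi"), L = 100)
  expect_equal(nucleotide_diversity(hm), 0.02)
  # identical haplotypes
  hm0 <- toy_hm(matrix(0L, 3, 0), rep("murphyi", 3), L = 100)
  expect_equal(nucleotide_diversity(hm0), 0)
  # 4 haplotypes, one site with 2 derived copies: pi = (4/6)/L
  hm2 <- toy_hm(matrix(c(1, 1, 0, 0), 4, 1), rep("murphyi", 4), L = 50)
  expect_equal(nucleotide_diversity(hm2), (4 / 6) / 50)
})

test_that("Watterson's theta is S over the harmonic number", {
  hm <- toy_hm(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)),
               rep("murphyi", 4))
  expect_equal(watterson_theta(hm), 3 / (1 + 1 / 2 + 1 / 3), tolerance = 1e-6)
  expect_equal(watterson_theta(toy_hm(matrix(0L, 4, 0), rep("murphyi", 4))), 0)
  hm2 <- toy_hm(rbind(rep(1, 5), rep(0, 5)), rep("murphyi", 2))
  expect_equal(watterson_theta(hm2), 5)  # a_1 = 1
})

test_that("Tajima's D follows the standard normalization and conventions", {
  hm0 <- toy_hm(matrix(0L, 5, 0), rep("murphyi", 5))
  expect_warning(d0 <- tajimas_d(hm0), "no segregating")
  expect_equal(d0, 0)
  # singletons only: excess of rare variants, D < 0
  hm <- toy_hm(diag(1L, 10), rep("murphyi", 10))
  expect_lt(tajimas_d(hm), 0)
  # neutral equilibrium: mean D near 0 (weakly negative-biased small-n)
  set.seed(7)
  draw <- one_pop_draw(2500)
  spec <- one_pop_locus(20)
  d <- replicate(500, tajimas_d(simulate_locus(draw, spec, 1e-6)))
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(500) + 0.1)
})

test_that("Hudson's Fst matches hand counts and boundary cases", {
  pops <- c("murphyi", "murphyi", "plumbeus", "plumbeus")
  # alternative fixation at every site
  hm_fix <- toy_hm(rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1)), pops)
  expect_equal(pairwise_fst(hm_fix, "murphyi", "plumbeus"), 1)
  # identical populations: random halves of one panmictic sample give
  # Fst centered on 0
  set.seed(19)
  spec16 <- locus_spec("L", 1000,
                       c(murphyi = 16, plumbeus = 0, matannensis = 0),
                       1, c(1e-6, 1e-6))
  draw <- one_pop_draw(2500)
  fst0 <- replicate(300, {
    hm <- simulate_locus(draw, spec16, 1e-6)
    if (ncol(hm$mat) == 0) return(NA_real_)
    pops2 <- rep("murphyi", 16)
    pops2[sample(16, 8)] <- "plumbeus"
    hm2 <- haplotype_matrix(hm$mat, pops2, hm$positions, hm$locus,
                            hm$length, check = FALSE)
    pairwise_fst(hm2, "murphyi", "plumbeus")
  })
  expect_lt(abs(mean(fst0, na.rm = TRUE)), 0.02)
  # hand case: A = {00, 00}, B = {01, 11}; Hw = 0.5, Hb = 1.5
  hm <- toy_hm(rbind(c(0, 0), c(0, 0), c(0, 1), c(1, 1)), pops)
  expect_equal(pairwise_fst(hm, "murphyi", "plumbeus"), 1 - 0.5 / 1.5,
               tolerance = 1e-9)
})

test_that("shared/private/fixed site classes are counted correctly", {
  pops <- c("murphyi", "murphyi", "plumbeus", "plumbeus")
  hm_fix <- toy_hm(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1), c(1, 1, 1)), pops)
  out <- shared_private_fixed(hm_fix, "murphyi", "plumbeus")
  expect_equal(unname(out), c(0, 0, 0, 3))
  hm_priv <- toy_hm(matrix(c(0, 1, 0, 0), 4, 1), pops)
  expect_equal(shared_private_fixed(hm_priv, "murphyi", "plumbeus")[["private_a"]], 1)
  hm_shared <- toy_hm(matrix(c(0, 1, 0, 1), 4, 1), pops)
  expect_equal(shared_private_fixed(hm_shared, "murphyi", "plumbeus")[["shared"]], 1)
})

test_that("the assembled vector matches the per-statistic functions on a toy", {
  set.seed(11)
  specs <- tiny_specs()
  sim <- simulate_dataset(demographic_model("Is"), specs)
  v <- summarize_dataset(sim$matrices, mtdna = "cytb")
  mt <- sim$matrices$cytb
  expect_equal(v[["mt_pi_total"]], nucleotide_diversity(mt))
  expect_equal(v[["mt_thetaW_total"]], watterson_theta(mt))
  expect_equal(v[["mt_tajD_total"]], tajimas_d(mt))
  expect_equal(v[["mt_fst_MP"]], pairwise_fst(mt, "murphyi", "plumbeus"))
  expect_equal(v[["mt_S_total"]], ncol(mt$mat))
  spf <- shared_private_fixed(mt, "plumbeus", "matannensis")
  expect_equal(v[["mt_shared_PT"]], spf[["shared"]])
  expect_equal(v[["mt_fixed_PT"]], spf[["fixed"]])
  # nuclear mean/variance across the two nuclear loci
  pi1 <- nucleotide_diversity(sim$matrices$nuc1)
  pi2 <- nucleotide_diversity(sim$matrices$nuc2)
  expect_equal(v[["nucmean_pi_total"]], mean(c(pi1, pi2)))
  expect_equal(v[["nucvar_pi_total"]], var(c(pi1, pi2)))
})

test_that("statistics are invariant to haplotype order", {
  set.seed(5)
  sim <- simulate_dataset(demographic_model("Im"), tiny_specs())
  hm <- sim$matrices$nuc1
  v1 <- summarize_dataset(sim$matrices, mtdna = "cytb")
  perm <- sample(nrow(hm$mat))
  hm_p <- haplotype_matrix(hm$mat[perm, ], hm$pops[perm], hm$positions,
                           hm$locus, hm$length, check = FALSE)
  sim$matrices$nuc1 <- hm_p
  v2 <- summarize_dataset(sim$matrices, mtdna = "cytb")
  expect_equal(v1, v2)
})

test_that("monomorphic data and a single nuclear locus hit the conventions", {
  pops <- rep(c("murphyi", "plumbeus", "matannensis"), each = 2)
  mono <- toy_hm(matrix(0L, 6, 0), pops)
  v <- summarize_dataset(list(cytb = mono, nuc1 = mono), mtdna = "cytb")
  diversity <- grep("_(S|Sp)_|_(pi|thetaW)_|S_total", names(v), value = TRUE)
  expect_true(all(v[diversity] == 0))
  expect_true(all(v[grep("^nucvar_", names(v))] == 0))  # single nuclear locus
  expect_equal(sum(v != 0), 0)
})

test_that("theta-W and pi agree in expectation at neutral equilibrium", {
  set.seed(13)
  draw <- one_pop_draw(2000)
  spec <- one_pop_locus(12)
  diffs <- replicate(2000, {
    hm <- simulate_locus(draw, spec, 1e-6)
    nucleotide_diversity(hm) * hm$length - watterson_theta(hm)
  })
  # paired comparison: mean difference indistinguishable from 0 at alpha=.01
  t <- abs(mean(diffs)) / (sd(diffs) / sqrt(length(diffs)))
  expect_lt(t, qnorm(0.995))
})

test_that("Fst rises with divergence time in isolation simulations", {
  set.seed(17)
  spec <- locus_spec("L", 1500, c(murphyi = 8, plumbeus = 8, matannensis = 0),
                     1, c(1e-6, 1e-6))
  times <- seq(2e3, 4e4, length.out = 10)
  fst <- vapply(times, function(tt) {
    mean(replicate(50, {
      d <- one_pop_draw(2000)
      d$ne_plumbeus <- 2000
      d$t_root <- tt
      d$t_pt <- tt * 0.5
      hm <- simulate_locus(d, spec, 1e-6)
      if (ncol(hm$mat) == 0) NA_real_
      else pairwise_fst(hm, "murphyi", "plumbeus")
    }), na.rm = TRUE)
  }, numeric(1))
  expect_gt(cor(times, fst, method = "spearman"), 0)
})
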