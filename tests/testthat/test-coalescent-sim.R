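test_that("prior draws respect their supports and the time ordering", {
  set.seed(3)
  m <- demographic_model("Imd")
  d <- draw_parameters(m, 10000)
  expect_true(all(d$ne_murphyi >= 5e5 & d$ne_murphyi <= 2e6))
  expect_true(all(d$ne_plumbeus >= 1e5 & d$ne_plumbeus <= 1.5e6))
  expect_true(all(d$ne_matannensis >= 1e5 & d$ne_matannensis <= 1.5e6))
  expect_true(all(d$t_root >= 1e6 & d$t_root <= 6e6))
  expect_true(all(d$t_pt >= 1e6 & d$t_pt <= 6e6))
  expect_true(all(d$t_pt < d$t_root))
  expect_true(all(d$mig_mp >= 0 & d$mig_mp <= 2))
  expect_true(all(d$chg_time_murphyi >= 1e4 & d$chg_time_murphyi <= 5e5))
  # draws nearly fill the murphyi Ne prior box
  expect_lt(min(d$ne_murphyi), 5.1e5)
  expect_gt(max(d$ne_murphyi), 1.99e6)
  # isolation models carry no migration or change parameters
  d_is <- draw_parameters(demographic_model("Is"), 1000)
  expect_true(all(d_is[, c("mig_mp", "mig_mt", "mig_pt",
                           "chg_time_murphyi", "founder_f_mat")] == 0))
})

test_that("pairwise coalescence times follow 2N (nuclear) and N/2 (mtDNA)", {
  set.seed(21)
  draw <- one_pop_draw(2500)
  nuc <- one_pop_locus(2)
  tm <- replicate(2000, simulate_genealogy(draw, nuc)$tmrca)
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 5000), 3 * se)
  mt <- one_pop_locus(2, scaling = 0.25)
  tm_mt <- replicate(2000, simulate_genealogy(draw, mt)$tmrca)
  se_mt <- sd(tm_mt) / sqrt(length(tm_mt))
  expect_lt(abs(mean(tm_mt) - 1250), 3 * se_mt)
})

test_that("mutation dropping on stored genealogies matches Watterson", {
  set.seed(23)
  draw <- one_pop_draw(2500)
  spec <- one_pop_locus(10)  # theta = 4 * 2500 * 1e-6 * 1000 = 10
  S <- replicate(2000, {
    tree <- simulate_genealogy(draw, spec)
    ncol(drop_mutations(tree, 1e-6, spec)$mat)
  })
  a9 <- sum(1 / 1:9)
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - 10 * a9), 3 * se)
  # zero mutation rate: no columns
  tree <- simulate_genealogy(draw, spec)
  expect_equal(ncol(drop_mutations(tree, 0, spec)$mat), 0)
  # every column segregates
  hm <- drop_mutations(tree, 5e-6, spec)
  expect_true(all(colSums(hm$mat) >= 1 & colSums(hm$mat) <= nrow(hm$mat) - 1))
  expect_true(all(diff(hm$positions) > 0))
})

test_that("datasets reproduce the printed locus structure deterministically", {
  specs <- default_locus_specs()
  expect_equal(vapply(specs, function(s) sum(s$n_samples), numeric(1)),
               c(cytb = 118, BNC1 = 53, PRLR = 96, WFIKKN = 62,
                 RAG2 = 48, VPS13B = 80, AGBL5 = 65))
  set.seed(31)
  sim <- simulate_dataset(demographic_model("Is"), specs)
  expect_equal(vapply(sim$matrices, function(h) nrow(h$mat), numeric(1)),
               c(cytb = 118, BNC1 = 53, PRLR = 96, WFIKKN = 62,
                 RAG2 = 48, VPS13B = 80, AGBL5 = 65))
  set.seed(99)
  s1 <- simulate_dataset(demographic_model("Imd"), tiny_specs())
  set.seed(99)
  s2 <- simulate_dataset(demographic_model("Imd"), tiny_specs())
  expect_identical(s1$params, s2$params)
  expect_identical(s1$matrices, s2$matrices)
})

test_that("out-of-support parameters are rejected with a message", {
  m <- demographic_model("Is")
  d <- draw_parameters(m, 1)
  d$ne_murphyi <- 100  # below the prior floor
  expect_error(simulate_dataset(m, tiny_specs(), params = d),
               "outside the prior support")
  d2 <- draw_parameters(m, 1)
  d2$mig_mp <- 1  # migration in an isolation model
  expect_error(simulate_dataset(m, tiny_specs(), params = d2),
               "outside the prior support")
})

test_that("a founder bottleneck depresses matannensis diversity", {
  set.seed(41)
  spec <- locus_spec("L", 2000, c(murphyi = 2, plumbeus = 2, matannensis = 10),
                     1, c(1e-7, 1e-7))
  base <- draw_parameters(demographic_model("Is"), 1)
  base$ne_murphyi <- 5e5
  base$ne_plumbeus <- base$ne_matannensis <- 3e5
  base$t_root <- 4e6
  base$t_pt <- 2e6
  found <- base
  found$founder_f_mat <- 0.01
  found$founder_f_ptanc <- 0.2
  found$founder_d_mat <- 1.9e6  # long bottleneck after the split
  found$founder_d_ptanc <- 5e5
  pi_of <- function(d) mean(replicate(500,
    nucleotide_diversity(simulate_locus(d, spec, 1e-7), "matannensis")))
  expect_lt(pi_of(found), pi_of(base))
})

test_that("strong migration approaches panmixia", {
  set.seed(43)
  spec <- locus_spec("L", 1500, c(murphyi = 8, plumbeus = 8, matannensis = 0),
                     1, c(1e-6, 1e-6))
  d <- one_pop_draw(2000)
  d$ne_plumbeus <- 2000
  d$t_root <- 4e6  # deep split, structure maintained only by drift vs migration
  d$t_pt <- 2e6
  d$mig_mp <- 100
  fst <- replicate(300, {
    hm <- simulate_locus(d, spec, 1e-6)
    if (ncol(hm$mat) == 0) NA_real_ else pairwise_fst(hm, "murphyi", "plumbeus")
  })
  expect_lt(abs(mean(fst, na.rm = TRUE)), 0.05)
})

test_that("reference tables round-trip through columnar text", {
  set.seed(47)
  tab <- simulate_reference_table(c("Is", "Im"), 20, tiny_specs())
  expect_s3_class(tab, "reference_table")
  expect_equal(nrow(tab), 40)
  expect_false(anyNA(tab))
  f <- tempfile(fileext = ".csv")
  write_reference_table(tab, f)
  tab2 <- read_reference_table(f)
  expect_equal(as.data.frame(tab), as.data.frame(tab2), tolerance = 1e-12)
  # a corrupted layout header must be refused
  lines <- readLines(f)
  lines[1] <- "# paddydiv reference_table layout=ssv0"
  writeLines(lines, f)
  expect_error(read_reference_table(f), "layout")
})
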