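test_that("synthetic sequences mirror the printed locus structure", {
  cfg <- synthetic_sequence_config(model_id = "Is", seed = 202)
  out <- gen_sequences(cfg, tempfile())
  counts <- vapply(out$fasta, function(f)
    length(read_fasta_alignment(f)$ids), numeric(1))
  expect_equal(unname(counts), c(118, 53, 96, 62, 48, 80, 65))
  # mtDNA: one sequence per individual; nuclear: <indiv>_<allele> pairs
  cytb_ids <- read_fasta_alignment(out$fasta[["cytb"]])$ids
  expect_false(any(grepl("_[12]$", cytb_ids)))
  prlr_ids <- read_fasta_alignment(out$fasta[["PRLR"]])$ids
  expect_true(all(grepl("_[12]$", prlr_ids)))
  indiv <- unique(sub("_[12]$", "", prlr_ids))
  # individuals follow the per-population allocation (odd shares get a
  # singleton allele): sum of ceiling(n_pop / 2)
  alloc <- allocate_samples(96)
  expect_equal(length(indiv), sum(ceiling(alloc / 2)))
  expect_true(all(table(sub("_[12]$", "", prlr_ids)) <= 2))
  # odd totals: exactly one individual carries a single allele
  bnc1_ids <- read_fasta_alignment(out$fasta[["BNC1"]])$ids
  expect_equal(sum(table(sub("_[12]$", "", bnc1_ids)) == 1), 1)
  popmap <- read_popmap(out$popmap)
  expect_setequal(unique(unname(popmap)),
                  c("murphyi", "plumbeus", "matannensis"))
})

test_that("sequence generation is deterministic and honors mu = 0", {
  cfg <- synthetic_sequence_config(locus_specs = tiny_specs(), seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  gen_sequences(cfg, d1)
  gen_sequences(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  specs <- tiny_specs()
  mu0 <- setNames(rep(0, length(specs)), names(specs))
  cfg0 <- synthetic_sequence_config(locus_specs = specs, mu = mu0, seed = 7)
  out0 <- gen_sequences(cfg0, tempfile())
  for (f in out0$fasta) {
    aln <- read_fasta_alignment(f)
    expect_equal(length(unique(aln$seqs)), 1)  # no mutation, no variation
  }
})

test_that("true parameters outside the prior support are rejected", {
  bad <- draw_parameters(demographic_model("Is"), 1)
  bad$t_root <- 7e6
  cfg <- synthetic_sequence_config(model_id = "Is", true_params = bad,
                                   locus_specs = tiny_specs(), seed = 1)
  expect_error(gen_sequences(cfg, tempfile()), "outside the prior support")
})

test_that("environmental layers and occurrences are deterministic and valid", {
  cfg <- synthetic_niche_config(nrow = 40, ncol = 40, n_layers = 3,
                                n_occurrences = c(native = 30, invaded = 30),
                                seed = 15)
  d1 <- tempfile(); d2 <- tempfile()
  o1 <- gen_env_occurrences(cfg, d1)
  o2 <- gen_env_occurrences(cfg, d2)
  expect_identical(readLines(file.path(d1, "occurrences.csv")),
                   readLines(file.path(d2, "occurrences.csv")))
  occ <- o1$occurrences
  expect_true(all(occ$lon >= 0 & occ$lon <= 40))
  expect_true(all(occ$lat >= 0 & occ$lat <= 40))
  # layers round-trip through the .asc files on disk
  stack2 <- env_stack(d1)
  expect_equal(stack2$layers[["env_01"]], o1$stack$layers[["env_01"]],
               tolerance = 1e-6)
  expect_error(synthetic_niche_config(n_occurrences = c(a = 3, b = 30),
                                      centroids = list(a = 0, b = 0),
                                      widths = list(a = 1, b = 1)),
               ">= 5")
})

test_that("sampled occurrences recover the configured niche centroid", {
  cfg <- synthetic_niche_config(
    nrow = 70, ncol = 70, n_layers = 4, autocorr_length = 5,
    centroids = list(lo = 0, hi = 0.8),
    widths = list(lo = 0.5, hi = 0.5),
    n_occurrences = c(lo = 300, hi = 300), seed = 23)
  out <- gen_env_occurrences(cfg, tempfile())
  vals <- extract_env(out$stack, out$occurrences)
  env_mean <- rowMeans(as.matrix(vals))
  lo <- env_mean[out$occurrences$species == "lo"]
  hi <- env_mean[out$occurrences$species == "hi"]
  # centered niche: mean recovered within 3 SE at n = 300
  expect_lt(abs(mean(lo) - 0), 3 * sd(lo) / sqrt(length(lo)))
  # offset niche: pulled toward the configured centroid
  expect_gt(mean(hi), mean(lo) + 0.3)
})

test_that("trait tables respect sizes, juveniles, and the covariance check", {
  cfg <- default_morph_config(separation = 1, juvenile_fraction = 0.2,
                              seed = 29)
  t1 <- gen_morphology(cfg)
  t2 <- gen_morphology(cfg)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 86)
  expect_equal(ncol(t1), 28)  # 27 variables + group
  expect_equal(sum(t1$total_length < 300),
               round(0.2 * 44) + round(0.2 * 21) * 2)
  expect_error(synthetic_morph_config(
    means = matrix(1, 2, 2, dimnames = list(NULL, c("a", "total_length"))),
    cov = matrix(c(1, 2, 2, 1), 2, 2),  # not PSD
    sizes = c(g1 = 5, g2 = 5)), "positive semi-definite")
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  gen_morphology(cfg, path = f)
  expect_equal(read.csv(f)$group, as.character(t1$group))
})
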