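mk_density <- function(z, support = z >= 0) {
  R <- nrow(z)
  structure(list(z = z, o = z / max(sum(z), 1), e = matrix(1 / R^2, R, R),
                 support = support, x = seq(0, 1, length.out = R),
                 y = seq(0, 1, length.out = R)),
            class = "niche_density")
}

test_that("Schoener's D identities and hand value hold", {
  z <- matrix(runif(25), 5, 5)
  expect_equal(schoeners_d(z, z), 1)
  a <- matrix(0, 4, 4); a[1, 1] <- 1
  b <- matrix(0, 4, 4); b[4, 4] <- 1
  expect_equal(schoeners_d(a, b), 0)
  p1 <- matrix(c(1, 0), 1, 2)
  p2 <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(schoeners_d(p1, p2), 0.5)
  expect_equal(schoeners_d(p2, p1), 0.5)  # symmetry
  expect_error(schoeners_d(matrix(0, 2, 2), p1), "grids")
  expect_error(schoeners_d(matrix(0, 2, 2), matrix(1, 2, 2)), "all-zero")
})

test_that("density grids integrate to one and respect the support", {
  set.seed(87)
  bg <- cbind(rnorm(800), rnorm(800))
  occ <- cbind(rnorm(40, 1, 0.3), rnorm(40, -0.5, 0.3))
  g <- density_grid(occ, bg, R = 60)
  expect_equal(sum(g$o), 1)
  expect_true(all(g$z >= 0 & g$z <= 1))
  expect_equal(max(g$z), 1)
  expect_true(all(g$z[!g$support] == 0))
  # tight cluster: corrected occupancy peaks at the cluster's cell
  occ2 <- cbind(rnorm(30, 1.5, 0.01), rnorm(30, 1.5, 0.01))
  g2 <- density_grid(occ2, bg, R = 60)
  peak <- which(g2$z == 1, arr.ind = TRUE)[1, ]
  expect_lt(abs(g2$x[peak[1]] - 1.5), 0.35)
  expect_lt(abs(g2$y[peak[2]] - 1.5), 0.35)
  expect_error(density_grid(occ[1:3, ], bg), ">= 5")
})

test_that("environmental PCA spans the background plane", {
  set.seed(89)
  v <- rnorm(50)
  line <- data.frame(a = v, b = 2 * v + 1e-9 * rnorm(50), c = -v)
  expect_error(env_pca(data.frame(a = v, b = rep(1, 50))), "constant")
  epc <- env_pca(line)
  expect_gt(epc$var_explained[1], 0.999)
  cloud <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  epc2 <- env_pca(cloud)
  rot <- epc2$pca$rotation
  expect_equal(unname(crossprod(rot)), diag(ncol(rot)), tolerance = 1e-8)
  # the background centroid projects to the origin
  ctr <- project_env(epc2, as.data.frame(t(colMeans(cloud))))
  expect_equal(as.numeric(ctr), c(0, 0), tolerance = 1e-10)
})

test_that("correlated and constant layers are pruned deterministically", {
  set.seed(97)
  base <- matrix(rnorm(400), 20, 20)
  mk_grid <- function(m, name) structure(
    list(data = m, xll = 0, yll = 0, cellsize = 1, name = name),
    class = "env_grid")
  stack <- env_stack(list(mk_grid(base, "l1"),
                          mk_grid(base * 1.5 + 2, "dup"),
                          mk_grid(matrix(rnorm(400), 20, 20), "indep"),
                          mk_grid(matrix(3, 20, 20), "flat")))
  expect_message(keep <- prune_correlated(stack, threshold = 0.8), "flat")
  expect_setequal(setdiff(c("l1", "dup"), keep), "dup")  # one of the pair
  expect_true("indep" %in% keep)
  expect_false("flat" %in% keep)
  # independent layers all retained
  stack2 <- env_stack(lapply(1:4, function(i)
    mk_grid(matrix(rnorm(400), 20, 20), paste0("x", i))))
  expect_length(prune_correlated(stack2, threshold = 0.8), 4)
})

test_that("COUE indices hit their identities", {
  set.seed(101)
  z <- matrix(runif(100), 10, 10)
  g <- mk_density(z, support = matrix(TRUE, 10, 10))
  same <- coue_indices(g, g, quantile = 0.1)
  expect_equal(same$expansion, 0)
  expect_equal(same$unfilling, 0)
  expect_equal(same$stability, 1)
  expect_equal(unname(same$centroid_shift), c(0, 0))
  za <- matrix(0, 10, 10); za[1:3, 1:3] <- 1
  zb <- matrix(0, 10, 10); zb[7:10, 7:10] <- 1
  disj <- coue_indices(mk_density(za, matrix(TRUE, 10, 10)),
                       mk_density(zb, matrix(TRUE, 10, 10)), quantile = 0)
  expect_equal(disj$expansion, 1)
  expect_equal(disj$unfilling, 1)
  expect_equal(disj$expansion + disj$stability, 1)
})

test_that("equivalency test is lower-tailed and seed-reproducible", {
  set.seed(103)
  bg <- cbind(rnorm(600), rnorm(600))
  occ <- cbind(rnorm(40, 0, 0.4), rnorm(40, 0, 0.4))
  # identical occurrence sets: observed D is at the top of the null
  r_same <- equivalency_test(occ, occ, bg, reps = 99, R = 60)
  expect_gt(r_same$p, 0.9)
  # clearly distinct niches: small lower-tail p
  occ_b <- cbind(rnorm(40, 2.2, 0.2), rnorm(40, -2.2, 0.2))
  r_diff <- equivalency_test(occ, occ_b, bg, reps = 199, R = 60)
  expect_lte(r_diff$p, 0.05)
  expect_gt(r_diff$p, 0)
  set.seed(11); p1 <- equivalency_test(occ, occ_b, bg, reps = 49, R = 40)$p
  set.seed(11); p2 <- equivalency_test(occ, occ_b, bg, reps = 49, R = 40)$p
  expect_identical(p1, p2)
})

test_that("similarity test rewards overlap beyond availability", {
  set.seed(107)
  bg <- cbind(rnorm(800, sd = 1.5), rnorm(800, sd = 1.5))
  occ1 <- cbind(rnorm(50, 0.8, 0.25), rnorm(50, 0.8, 0.25))
  occ2 <- cbind(rnorm(50, 0.8, 0.25), rnorm(50, 0.8, 0.25))
  r <- similarity_test(occ1, occ2, bg, shift_background = bg,
                       reps = 199, R = 60)
  expect_lte(r$p, 0.05)
  set.seed(3); q1 <- similarity_test(occ1, occ2, bg, shift_background = bg,
                                     reps = 49, R = 40)$p
  set.seed(3); q2 <- similarity_test(occ1, occ2, bg, shift_background = bg,
                                     reps = 49, R = 40)$p
  expect_identical(q1, q2)
})

test_that("overlap declines as configured niche separation grows", {
  seps <- c(0, 0.6, 1.2, 1.8, 2.4)
  d <- vapply(seq_along(seps), function(i) {
    mean(vapply(1:3, function(r) {
      cfg <- synthetic_niche_config(
        nrow = 50, ncol = 50, n_layers = 3, autocorr_length = 4,
        centroids = list(native = seps[i] / 2, invaded = -seps[i] / 2),
        widths = list(native = 0.5, invaded = 0.5),
        n_occurrences = c(native = 80, invaded = 80),
        seed = 1000 + 10 * i + r)
      out <- gen_env_occurrences(cfg, tempfile())
      vals <- stack_values(out$stack)
      epc <- env_pca(vals)
      bgd <- background_density(epc$background, R = 60)
      sc <- function(sp) project_env(epc, extract_env(
        out$stack, out$occurrences[out$occurrences$species == sp, ]))
      schoeners_d(density_grid(sc("native"), bgd),
                  density_grid(sc("invaded"), bgd))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(cor(seps, d, method = "spearman"), 0)
  expect_equal(order(-d)[1], 1)  # identical centroids overlap the most
})

test_that("climate envelopes are exact five-number summaries", {
  g <- structure(list(data = matrix(as.numeric(1:25), 5, 5), xll = 0, yll = 0,
                      cellsize = 1, name = "v1"), class = "env_grid")
  stack <- env_stack(list(g))
  # centers of cells (col, row-from-top); values = column-major 1:25
  occ <- data.frame(species = "sp",
                    lon = c(0.5, 0.5, 1.5, 2.5, 3.5),
                    lat = c(4.5, 3.5, 2.5, 1.5, 0.5))
  vals <- extract_env(stack, occ)$v1
  env <- climate_envelope(occ, stack)
  q <- quantile(vals, c(0, .25, .5, .75, 1), names = FALSE)
  expect_equal(unlist(env[1, c("min", "q1", "median", "q3", "max")],
                      use.names = FALSE), q)
  # single occurrence: all five numbers collapse to its value
  env1 <- climate_envelope(occ[3, ], stack)
  expect_true(all(env1[, c("min", "q1", "median", "q3", "max")] == vals[3]))
  # order invariance
  env_r <- climate_envelope(occ[sample(5), ], stack)
  expect_equal(env_r, env)
})

test_that("ASCII grids round-trip including nodata cells", {
  m <- matrix(rnorm(30), 5, 6)
  m[2, 3] <- NA
  g <- structure(list(data = m, xll = 10, yll = -5, cellsize = 0.5,
                      name = "layer"), class = "env_grid")
  f <- tempfile(fileext = ".asc")
  write_ascii_grid(g, f)
  g2 <- read_ascii_grid(f, name = "layer")
  expect_equal(g2$data, m, tolerance = 1e-12)
  expect_equal(g2$cellsize, 0.5)
  expect_equal(g2$xll, 10)
  # points outside the extent or on nodata are dropped with a message
  stack <- env_stack(list(g))
  pts <- data.frame(lon = c(10.2, 11.8, 11.3, 99),
                    lat = c(-4.9, -3.3, -3.3, 0))  # last two: nodata, outside
  expect_message(v <- extract_env(stack, pts), "2 point")
  expect_equal(nrow(v), 2)
})
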