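test_that("overlap statistics hit their fixed points", {
  a <- toy_raster(matrix(c(1, 0), 1, 2))
  b <- toy_raster(matrix(c(0.5, 0.5), 1, 2))
  expect_equal(schoener_d(a, a), 1)
  expect_equal(warren_i(a, a), 1)
  disj <- toy_raster(matrix(c(0, 1), 1, 2))
  expect_equal(schoener_d(a, disj), 0)
  expect_equal(warren_i(a, disj), 0)
  expect_equal(schoener_d(a, b), 0.5)
  expect_equal(warren_i(a, b), 1 - 0.5 * ((1 - sqrt(0.5))^2 + 0.5),
               tolerance = 1e-12)
  expect_equal(round(warren_i(a, b), 4), 0.7071)
})

test_that("overlap is symmetric, scale-invariant, and D <= I", {
  set.seed(8)
  for (i in 1:5) {
    a <- toy_raster(matrix(runif(30), 5, 6))
    b <- toy_raster(matrix(runif(30), 5, 6))
    expect_equal(schoener_d(a, b), schoener_d(b, a), tolerance = 1e-12)
    expect_equal(warren_i(a, b), warren_i(b, a), tolerance = 1e-12)
    a2 <- a; a2$values <- a$values * 13.7
    expect_equal(schoener_d(a2, b), schoener_d(a, b), tolerance = 1e-12)
    expect_equal(warren_i(a2, b), warren_i(a, b), tolerance = 1e-12)
    expect_lte(schoener_d(a, b), warren_i(a, b) + 1e-12)
  }
})

test_that("overlap uses only jointly valid cells and validates grids", {
  a <- toy_raster(matrix(c(1, NA, 2, 3), 2, 2))
  b <- toy_raster(matrix(c(2, 5, 4, NA), 2, 2))
  # joint support: cells (1,1) and (1,2); normalization over those only
  pa <- c(1, 2) / 3; pb <- c(2, 4) / 6
  expect_equal(schoener_d(a, b), 1 - 0.5 * sum(abs(pa - pb)))
  off <- toy_raster(matrix(1, 2, 2), xll = 5)
  expect_error(schoener_d(a, off), "same grid")
  allna <- toy_raster(matrix(NA_real_, 2, 2))
  expect_error(schoener_d(allna, allna), "valid")
})

test_that("prune_correlated drops by the greedy |r| rule", {
  base <- matrix(rnorm(400, 10), 20, 20)
  dup <- toy_raster(base)
  noise <- toy_raster(matrix(rnorm(400), 20, 20))
  expect_equal(prune_correlated(list(dup, toy_raster(base), noise)), c(1, 3))
  set.seed(2)
  indep <- lapply(1:3, function(i) toy_raster(matrix(rnorm(400), 20, 20)))
  expect_equal(prune_correlated(indep), 1:3)
  # r(1,2) >= 0.8, r(1,3) and r(2,3) small -> retain 1 and 3
  l1 <- base
  l2 <- 0.99 * scale(as.vector(base)) + 0.02 * rnorm(400)
  l3 <- matrix(rnorm(400), 20, 20)
  stopifnot(abs(cor(as.vector(l1), as.vector(l2))) >= 0.8)
  expect_equal(prune_correlated(list(toy_raster(l1),
                                     toy_raster(matrix(l2, 20, 20)),
                                     toy_raster(l3))), c(1, 3))
})

test_that("max SSS threshold follows the enumeration rule", {
  suit <- toy_raster(matrix(seq(0, 1, length.out = 25), 5, 5))
  ax <- haplogeo:::raster_axes(suit)
  pt_at <- function(vals) {
    idx <- sapply(vals, function(v) which.min(abs(suit$values - v)))
    rc <- arrayInd(idx, dim(suit$values))
    occurrences(ax$x[rc[, 2]], ax$y[rc[, 1]])
  }
  pres <- pt_at(c(0.8, 0.9, 1.0))
  bg <- pt_at(c(0.0, 0.1, 0.2))
  thr <- max_sss_threshold(suit, pres, bg)
  expect_equal(thr$sensitivity + thr$specificity, 2)
  expect_equal(thr$threshold, min(haplogeo:::raster_extract(
    suit, pres$lon, pres$lat)))
  # all points at the same suitability: that value, sens + spec = 1
  flat <- toy_raster(matrix(0.5, 3, 3))
  p1 <- occurrences(1.5, 1.5); b1 <- occurrences(0.5, 0.5)
  thr2 <- max_sss_threshold(flat, p1, b1)
  expect_equal(thr2$threshold, 0.5)
  expect_equal(thr2$sensitivity + thr2$specificity, 1)
  # single presence above all background
  thr3 <- max_sss_threshold(suit, pt_at(0.9), bg)
  expect_equal(thr3$threshold,
               haplogeo:::raster_extract(suit, pt_at(0.9)$lon, pt_at(0.9)$lat))
})

test_that("the envelope model matches its closed form", {
  env <- generate_landscape(n_layers = 2, noise_sd = 0.1, seed = 4)
  occ <- sample_occurrences(toy_raster(matrix(1, env[[1]]$nrows,
                                              env[[1]]$ncols),
                                       cellsize = env[[1]]$cellsize,
                                       xll = env[[1]]$xllcorner,
                                       yll = env[[1]]$yllcorner),
                            n = 15, seed = 4)
  suit <- envelope_suitability(occ, env)
  z2 <- 0
  for (r in env) {
    v <- haplogeo:::raster_extract(r, occ$lon, occ$lat)
    z2 <- z2 + ((r$values - mean(v)) / sd(v))^2
  }
  expected <- exp(-0.5 * z2 / 2)
  expected <- expected / max(expected)
  expect_equal(suit$values, expected, tolerance = 1e-12)
  expect_true(all(suit$values >= 0 & suit$values <= 1))
})

test_that("a zero-variance layer is tolerated with a message", {
  flat <- toy_raster(matrix(1, 10, 10))
  grad <- toy_raster(matrix(seq(0, 1, length.out = 100), 10, 10))
  occ <- occurrences(c(1.5, 2.5, 3.5), c(1.5, 2.5, 3.5))
  expect_message(s <- envelope_suitability(occ, list(flat, grad)),
                 "zero-variance")
  expect_true(all(is.finite(s$values)))
})

test_that("planted niche divergence is rejected at the minimum attainable p", {
  env <- generate_landscape(extent = c(100, 110, 25, 35), cellsize = 0.5,
                            n_layers = 2, noise_sd = 0.05, seed = 21)
  base <- toy_raster(matrix(1, env[[1]]$nrows, env[[1]]$ncols),
                     cellsize = 0.5, xll = 100, yll = 25)
  occ <- sample_occurrences(base, n = 30, mode = "divergent-pair", seed = 22)
  it <- identity_test(occ$a, occ$b, env, n_reps = 100, seed = 23)
  expect_equal(it$p_D, 1 / 101)
  expect_equal(it$p_I, 1 / 101)
  expect_lt(it$D, min(it$null_D))
})

test_that("identity-test p-values are not anti-conservative under the null", {
  env <- generate_landscape(extent = c(100, 105, 25, 30), cellsize = 0.5,
                            n_layers = 2, noise_sd = 0.05, seed = 31)
  base <- toy_raster(matrix(1, env[[1]]$nrows, env[[1]]$ncols),
                     cellsize = 0.5, xll = 100, yll = 25)
  ps <- sapply(1:20, function(s) {
    a <- sample_occurrences(base, n = 12, seed = 100 + s)
    b <- sample_occurrences(base, n = 12, seed = 200 + s)
    identity_test(a, b, env, n_reps = 19, seed = s)$p_D
  })
  # under the null, P(p <= 0.25) should be near 0.25; guard the tail
  expect_lte(mean(ps <= 0.25), 0.55)
  expect_gt(mean(ps), 0.3)
})

test_that("normalization is idempotent for overlap computation", {
  set.seed(5)
  a <- toy_raster(matrix(runif(36), 6, 6))
  b <- toy_raster(matrix(runif(36), 6, 6))
  an <- a; an$values <- a$values / sum(a$values)
  bn <- b; bn$values <- b$values / sum(b$values)
  expect_equal(schoener_d(an, bn), schoener_d(a, b), tolerance = 1e-12)
  expect_equal(warren_i(an, bn), warren_i(a, b), tolerance = 1e-12)
})

test_that("ESRI ASCII grids round-trip through disk", {
  r <- toy_raster(matrix(c(0.1, NA, 0.7, 1), 2, 2), cellsize = 0.25,
                  xll = 100, yll = 30)
  path <- tempfile(fileext = ".asc")
  write_asc(r, path)
  back <- read_asc(path)
  expect_equal(back$values, r$values, tolerance = 1e-6)
  expect_equal(back$cellsize, r$cellsize)
  expect_equal(back$xllcorner, r$xllcorner)
  expect_error(read_asc(tempfile()), "not found")
})
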