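test_that("presence/absence thresholding follows the rule", {
  r <- toy_raster(matrix(c(0.3, 0.7, NA, 0.5), 2, 2))
  expect_equal(presence_absence(r, 0)$values,
               matrix(c(1, 1, NA, 1), 2, 2))
  expect_equal(presence_absence(r, 2)$values,
               matrix(c(0, 0, NA, 0), 2, 2))
  expect_equal(presence_absence(r, 0.5)$values,
               matrix(c(0, 1, NA, 1), 2, 2))
})

test_that("friction inversion is an involution on [0, 1]", {
  r <- toy_raster(matrix(c(0, 1, 0.25, NA), 2, 2))
  f <- friction_layer(r)
  expect_equal(f$values, matrix(c(1, 0, 0.75, NA), 2, 2))
  expect_equal(friction_layer(f)$values, r$values)
  bad <- toy_raster(matrix(c(0.5, 1.2), 1, 2))
  expect_error(friction_layer(bad), "outside")
})

test_that("block centroids average presence cell centers", {
  pa <- toy_raster(matrix(0, 4, 4), cellsize = 0.5)
  pa$values[4, 1] <- 1                     # single cell, center (0.25, 0.25)
  c1 <- block_centroids(pa, block_deg = 1)
  expect_equal(c1$lon, 0.25)
  expect_equal(c1$lat, 0.25)
  # full block of presence: centroid at the block center
  pa2 <- toy_raster(matrix(1, 4, 4), cellsize = 0.5)
  c2 <- block_centroids(pa2, block_deg = 2)
  expect_equal(c2$lon, 1)
  expect_equal(c2$lat, 1)
  # L-shaped 3-cell presence within one block
  pa3 <- toy_raster(matrix(0, 4, 4), cellsize = 0.5)
  pa3$values[4, 1] <- pa3$values[4, 2] <- pa3$values[3, 1] <- 1
  c3 <- block_centroids(pa3, block_deg = 2)
  expect_equal(c3$lon, mean(c(0.25, 0.75, 0.25)))
  expect_equal(c3$lat, mean(c(0.25, 0.25, 0.75)))
  expect_error(block_centroids(pa, block_deg = 0.8), "multiple")
})

test_that("migration vectors map to nearest second-period centroids", {
  c1 <- data.frame(lon = c(100, 101), lat = c(30, 31))
  expect_equal(migration_vectors(c1, c1)$length_km, c(0, 0))
  c2 <- c1; c2$lon <- c2$lon + 0.625
  mv <- migration_vectors(c1, c2)
  expect_equal(mv$to_lon - mv$from_lon, c(0.625, 0.625))
  expect_equal(mv$to_lat, mv$from_lat)
  one <- data.frame(lon = 100.5, lat = 30.5)
  mv2 <- migration_vectors(c1, one)
  expect_equal(mv2$to_lon, c(100.5, 100.5))
  expect_error(migration_vectors(c1, one[0, ]), "empty")
})

test_that("cost distance matches closed form on uniform friction", {
  f <- toy_raster(matrix(0.4, 1, 6))
  cd <- cost_distance(f, c(0.5, 0.5))
  expect_equal(cd$values[1, ], 0.4 * (0:5))
  expect_equal(cd$values[1, 1], 0)
})

test_that("cost distance equals exhaustive path enumeration on small grids", {
  set.seed(6)
  for (i in 1:2) {
    f <- toy_raster(matrix(runif(16, 0.1, 1), 4, 4))
    if (i == 2) f$values[2, 2] <- NA
    cd <- cost_distance(f, c(0.5, 3.5))      # cell (row 1, col 1)
    for (target in list(c(4, 4), c(1, 4), c(3, 2))) {
      if (is.na(f$values[target[1], target[2]])) next
      expect_equal(cd$values[target[1], target[2]],
                   brute_min_cost(f$values, c(1, 1), target),
                   tolerance = 1e-9)
    }
  }
})

test_that("cost distance satisfies the triangle property", {
  set.seed(7)
  f <- toy_raster(matrix(runif(25, 0.1, 1), 5, 5))
  ax <- haplogeo:::raster_axes(f)
  pt <- function(r, c) c(ax$x[c], ax$y[r])
  ab <- cost_distance(f, pt(1, 1))$values[5, 5]
  ac <- cost_distance(f, pt(1, 1))$values[3, 4]
  cb <- cost_distance(f, pt(3, 4))$values[5, 5]
  expect_lte(ab, ac + cb + 1e-9)
})

test_that("corridor classes match a brute-force two-field computation", {
  set.seed(9)
  f <- toy_raster(matrix(runif(25, 0.2, 1), 5, 5))
  ax <- haplogeo:::raster_axes(f)
  a <- c(ax$x[1], ax$y[3]); b <- c(ax$x[5], ax$y[3])
  lcc <- least_cost_corridor(f, a, b)
  ca <- sapply(1:5, function(r) sapply(1:5, function(c)
    brute_min_cost(f$values, c(3, 1), c(r, c))))
  cb <- sapply(1:5, function(r) sapply(1:5, function(c)
    brute_min_cost(f$values, c(3, 5), c(r, c))))
  cc <- t(ca) + t(cb)
  lcp <- min(cc)
  expect_equal(lcc$lcp_cost, lcp, tolerance = 1e-9)
  ratio <- (cc - lcp) / lcp
  expected <- matrix(0, 5, 5)
  expected[ratio < 0.05] <- 1
  expected[ratio < 0.02] <- 2
  expected[ratio < 0.01] <- 5
  expect_equal(lcc$surface$values, expected)
})

test_that("least-cost corridors are symmetric and LCP cells carry weight 5", {
  f <- toy_raster(matrix(0.5, 6, 8))
  ax <- haplogeo:::raster_axes(f)
  a <- c(ax$x[2], ax$y[3]); b <- c(ax$x[7], ax$y[3])
  l1 <- least_cost_corridor(f, a, b)
  l2 <- least_cost_corridor(f, b, a)
  expect_equal(l1$surface$values, l2$surface$values)
  expect_equal(l1$lcp_cost, l2$lcp_cost)
  # cells on the straight path attain the LCP cost -> weight 5
  expect_true(all(l1$surface$values[3, 2:7] == 5))
})

test_that("unreachable endpoints give an empty surface with a warning", {
  f <- toy_raster(matrix(0.5, 3, 5))
  f$values[, 3] <- NA
  ax <- haplogeo:::raster_axes(f)
  expect_warning(
    lcc <- least_cost_corridor(f, c(ax$x[1], ax$y[2]), c(ax$x[5], ax$y[2])),
    "unreachable")
  expect_true(all(lcc$surface$values == 0, na.rm = TRUE))
  expect_equal(lcc$lcp_cost, Inf)
})

make_corridor_ds <- function(lon, lat, haps) {
  codes <- sprintf("P%d", seq_along(lon))
  sites <- data.frame(code = codes, locality = "X, Simland",
                      lon = lon, lat = lat, elev_m = 0,
                      country = "Simland", group = "none",
                      row.names = codes)
  allh <- c("H1", "H2")
  wild <- matrix(0, length(lon), 2, dimnames = list(codes, allh))
  for (i in seq_along(haps)) wild[i, haps[[i]]] <- 3
  haplogeo:::new_dataset(sites, wild, wild * 0)
}

test_that("corridor network sums per-pair surfaces additively", {
  suit <- toy_raster(matrix(0.5, 8, 8), cellsize = 1)
  ds3 <- make_corridor_ds(c(1.5, 4.5, 6.5), c(1.5, 6.5, 2.5),
                          list("H1", c("H1", "H2"), "H2"))
  net <- corridor_network(ds3, suit)
  expect_equal(nrow(net$pair_costs), 2)
  f <- friction_layer(suit)
  single <- function(i, j) {
    least_cost_corridor(f, c(ds3$sites$lon[i], ds3$sites$lat[i]),
                        c(ds3$sites$lon[j], ds3$sites$lat[j]))$surface$values
  }
  expect_equal(net$surface$values, single(1, 2) + single(2, 3))
  # duplicated pair doubles the surface
  pairs2 <- data.frame(a = c("P1", "P1"), b = c("P2", "P2"))
  net2 <- corridor_network(ds3, suit, pairs = pairs2)
  expect_equal(net2$surface$values, 2 * single(1, 2))
})

test_that("no shared haplotypes yields a zero surface with warning", {
  suit <- toy_raster(matrix(0.5, 4, 4), cellsize = 1)
  ds2 <- make_corridor_ds(c(0.5, 3.5), c(0.5, 3.5), list("H1", "H2"))
  expect_warning(net <- corridor_network(ds2, suit), "no shared")
  expect_true(all(net$surface$values == 0, na.rm = TRUE))
})
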