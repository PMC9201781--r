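ds <- load_fixture()
dm <- fixture_distances(ds)
am_ds <- dataset_preset(ds, "paper_amova_sites")

test_that("AMOVA reproduces the published three-level table", {
  am <- amova(am_ds, dm = dm, n_perm = 0)
  expect_equal(am$df, c(1, 73, 310))
  expect_equal(round(am$SS, 2), c(413.19, 4.05, 7.61))
  expect_equal(round(am$sigma2[["a"]], 2), 2.49)
  expect_equal(round(am$pct[1], 2), 98.78)
  expect_equal(round(am$FCT, 3), 0.988)
  expect_equal(round(am$FSC, 3), 0.199)
  expect_equal(round(am$FST, 3), 0.990)
})

test_that("AMOVA sums of squares match a brute-force individual-level oracle", {
  set.seed(4)
  # 4 sites x 3 individuals, 2 groups, planted frequencies
  m <- rbind(S1 = c(H1 = 3, H3 = 0, H5 = 0),
             S2 = c(H1 = 2, H3 = 1, H5 = 0),
             S3 = c(H1 = 0, H3 = 2, H5 = 1),
             S4 = c(H1 = 0, H3 = 1, H5 = 2))
  grp <- c(S1 = "w", S2 = "w", S3 = "e", S4 = "e")
  d <- dm[colnames(m), colnames(m)]
  ss_oracle <- brute_amova_ss(m, grp, d)
  am <- amova(m, grouping = grp, dm = d, n_perm = 0)
  expect_equal(unname(am$SS), unname(ss_oracle), tolerance = 1e-12)
  # variance components from the mean-square equations, solved in-test
  N <- sum(m); S <- nrow(m); G <- 2
  n_s <- rowSums(m); n_g <- tapply(n_s, grp[rownames(m)], sum)
  ms <- ss_oracle / c(G - 1, S - G, N - S)
  s2c <- ms[3]
  n_c <- (N - sum(n_s^2 / n_g[grp[rownames(m)]])) / (S - G)
  s2b <- (ms[2] - s2c) / n_c
  n_b <- (sum(n_s^2 / n_g[grp[rownames(m)]]) - sum(n_s^2) / N) / (G - 1)
  n_a <- (N - sum(n_g^2) / N) / (G - 1)
  s2a <- (ms[1] - s2c - n_b * s2b) / n_a
  expect_equal(unname(am$sigma2), unname(c(s2a, s2b, s2c)), tolerance = 1e-12)
})

test_that("the AMOVA sum-of-squares identity holds on generated data", {
  for (seed in 1:3) {
    g <- generate_sites(n_sites = 8, n_per_site = 6, seed = seed)
    m <- site_counts(g)
    d <- dm[colnames(m), colnames(m)]
    am <- amova(m, grouping = stats::setNames(g$sites$group, g$sites$code),
                dm = d, n_perm = 0)
    total <- haplogeo:::pool_ss(colSums(m), d)
    expect_equal(sum(am$SS), total, tolerance = 1e-10)
  }
})

test_that("complete fixation at distance 1 gives FST = 1 and zero within SS", {
  m <- rbind(A = c(H1 = 2, H2 = 0), B = c(H1 = 0, H2 = 2))
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("H1", "H2"), c("H1", "H2")))
  am <- amova(m, grouping = c(A = "g1", B = "g1"), dm = d, n_perm = 0)
  expect_equal(am$levels, 2L)
  expect_equal(am$SS[2], 0)
  expect_equal(am$FST, 1)
})

test_that("AMOVA permutation p-values detect the east-west structure", {
  am <- amova(am_ds, dm = dm, n_perm = 100, seed = 2)
  expect_lt(am$p[["FCT"]], 0.05)
  expect_lt(am$p[["FST"]], 0.05)
})

test_that("pairwise PhiST has the expected fixed points", {
  m <- rbind(A = c(H1 = 5, H3 = 5), B = c(H1 = 5, H3 = 5),
             C = c(H1 = 10, H3 = 0), D = c(H1 = 0, H3 = 10))
  d <- dm[c("H1", "H3"), c("H1", "H3")]
  phi <- pairwise_phist(m, d, convention = "steps")
  expect_equal(phi["A", "B"], 0)
  expect_equal(phi["C", "D"], 1)
})

test_that("pairwise PhiST equals a direct two-population AMOVA", {
  m <- rbind(X = c(H1 = 9, H4 = 1), Y = c(H1 = 10, H4 = 0))
  d <- dm[c("H1", "H4"), c("H1", "H4")]
  phi <- pairwise_phist(m, d, convention = "steps", clamp = FALSE)
  ss <- brute_amova_ss(m, c(X = "x", Y = "y"), d)
  # two-level solution from the oracle SS: among-site + within
  N <- 20; n1 <- 10; n2 <- 10
  ss_w <- ss[["among_sites"]] + ss[["within"]]  # oracle groups == sites here
  ss_a <- ss[["among_groups"]]
  msw <- ss_w / (N - 2)
  nc <- N - (n1^2 + n2^2) / N
  s2a <- (ss_a - msw) / nc
  expect_equal(phi["X", "Y"], s2a / (s2a + msw), tolerance = 1e-12)
})

test_that("PCoA recovers simple geometry", {
  # equilateral triangle: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  p <- pcoa(d3, k = 2)
  pos <- p$eig[p$eig > 1e-10]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)
  # duplicated point: identical coordinates
  d4 <- as.matrix(dist(c(0, 0, 3)))
  p4 <- pcoa(d4, k = 1)
  expect_equal(unname(p4$coordinates[1, 1]), unname(p4$coordinates[2, 1]))
  expect_error(pcoa(matrix(0, 3, 3)), "all-zero")
})

test_that("PCoA of the fixture PhiST matrix loads most variance on axis 1", {
  phi <- pairwise_phist(am_ds, dm)
  p <- pcoa(phi)
  expect_gte(p$percent[1], 80)
  expect_lte(p$percent[1], 95)
})

test_that("mantel_test returns r = 1 for an exact log-linear relation", {
  set.seed(1)
  pts <- cbind(runif(8, 0, 10), runif(8, 0, 10))
  geo <- as.matrix(dist(pts)) + 1
  gen <- 0.3 * log(geo) + 2
  diag(gen) <- 0
  r <- mantel_test(gen, geo, n_perm = 99, seed = 1)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_lt(r$p, 0.05)
})

test_that("mantel p approximates the exact 4-site enumeration", {
  gen <- matrix(c(0, 1, 2, 3,
                  1, 0, 1.5, 2,
                  2, 1.5, 0, 1,
                  3, 2, 1, 0), 4, 4)
  geo <- matrix(c(0, 10, 40, 90,
                  10, 0, 20, 60,
                  40, 20, 0, 15,
                  90, 60, 15, 0), 4, 4)
  lt <- lower.tri(gen)
  r_obs <- cor(gen[lt], log(geo)[lt])
  perms <- haplogeo:::perm_enumerate(4)
  r_all <- sapply(perms, function(p) cor(gen[lt], log(geo)[p, p][lt]))
  exact <- mean(r_all >= r_obs - 1e-12)
  mt <- mantel_test(gen, geo, n_perm = 4999, seed = 5)
  expect_equal(mt$r, r_obs)
  expect_lt(abs(mt$p - exact), 0.04)
})

test_that("mantel r is invariant to the logarithm base", {
  set.seed(2)
  pts <- cbind(runif(6), runif(6))
  geo <- as.matrix(dist(pts)) * 100 + 1
  gen <- as.matrix(dist(rnorm(6)))
  r1 <- mantel_test(gen, geo, n_perm = 9, seed = 1)$r
  lt <- lower.tri(geo)
  r2 <- cor(gen[lt], log10(geo[lt]))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("mantel statistic agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  set.seed(3)
  pts <- cbind(runif(10), runif(10))
  geo <- as.matrix(dist(pts)) + 0.5
  gen <- as.matrix(dist(rnorm(10)))
  ours <- mantel_test(gen, geo, n_perm = 9, seed = 1)
  ref <- vegan::mantel(as.dist(gen), as.dist(log(geo)), permutations = 9)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
})

test_that("isolation by distance holds on the 75-site dataset", {
  phi <- pairwise_phist(am_ds, dm)
  coords <- as.matrix(am_ds$sites[match(rownames(phi), am_ds$sites$code),
                                  c("lon", "lat")])
  S <- nrow(coords)
  geo <- matrix(0, S, S)
  for (i in 1:(S - 1)) for (j in (i + 1):S)
    geo[i, j] <- geo[j, i] <- great_circle_km(coords[i, ], coords[j, ])
  mt <- mantel_test(phi, geo, n_perm = 999, seed = 11)
  expect_gte(mt$r, 0.60)
  expect_lte(mt$r, 0.75)
  expect_lt(mt$p, 0.05)
})

test_that("strict-clock divergence follows the closed form", {
  m <- rbind(A = c(H1 = 5, H3 = 0), B = c(H1 = 0, H3 = 5))
  d <- dm[c("H1", "H3"), c("H1", "H3")]
  est <- clock_divergence(m, c(A = "west", B = "east"), d, L = 717)
  expect_equal(est$d_net, 5 / 717)
  expect_equal(est$T_years, 5 / (717 * 2 * 2.0e-9), tolerance = 1e-9)
  est2 <- clock_divergence(m, c(A = "west", B = "east"), d, L = 717, mu = 4.0e-9)
  expect_equal(est2$T_years, est$T_years / 2)
  # identical clades: zero net divergence
  m2 <- rbind(A = c(H1 = 3, H3 = 3), B = c(H1 = 3, H3 = 3))
  est3 <- clock_divergence(m2, c(A = "west", B = "east"), d, L = 717)
  expect_equal(est3$d_net, 0, tolerance = 1e-12)
  expect_equal(est3$T_years, 0)
})

test_that("SAMOVA recovers a planted two-cluster partition", {
  g <- generate_sites(n_sites = 12, n_per_site = 10, seed = 5)
  m <- site_counts(g)
  truth <- g$sites$group
  sam <- samova(g, dm, K = 2, n_runs = 5, seed = 3, moves_per_site = 20)
  split1 <- sam$assignment == sam$assignment[1]
  expect_true(all(split1 == (truth == truth[1])))
  # best F_CT equals the direct AMOVA value of the planted grouping
  am <- amova(m, grouping = stats::setNames(truth, g$sites$code),
              dm = dm[colnames(m), colnames(m)], n_perm = 0)
  expect_equal(sam$FCT, am$FCT, tolerance = 1e-9)
})

test_that("the annealing objective equals the full AMOVA F_CT", {
  g <- generate_sites(n_sites = 10, n_per_site = 8, seed = 2)
  m <- site_counts(g)
  d <- dm[colnames(m), colnames(m)]
  ev <- haplogeo:::make_fct_evaluator(m, d)
  set.seed(1)
  for (i in 1:5) {
    grp <- sample(c("a", "b", "c"), nrow(m), replace = TRUE)
    if (length(unique(grp)) < 3) next
    expect_equal(ev(grp),
                 amova(m, grouping = stats::setNames(grp, rownames(m)),
                       dm = d, n_perm = 0)$FCT,
                 tolerance = 1e-12)
  }
})

test_that("delaunay edges of a unit square include the hull", {
  ed <- delaunay_edges(c(0, 1, 0, 1), c(0, 0, 1, 1))
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(c("1 2", "1 3", "2 4", "3 4") %in% key))
})
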