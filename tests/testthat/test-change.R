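make_surface <- function(P1, P2, area = 1) {
  occupancy_probability(list(t1 = -log(1 - P1) / area,
                             t2 = -log(1 - P2) / area), area = rep(area, ncol(P1)))
}

test_that("occupancy probability applies the cloglog relation", {
  lam <- list(t1 = matrix(c(0, log(2), 50), 1), t2 = matrix(c(0, 0, 0), 1))
  s <- occupancy_probability(lam, area = rep(1, 3))
  expect_equal(s$P$t1[1, ], c(0, 0.5, 1 - exp(-50)))
  expect_true(all(s$P$t1 <= 1 & s$P$t1 >= 0))
  expect_error(occupancy_probability(list(t1 = matrix(1, 2, 3),
                                          t2 = matrix(1, 2, 2)),
                                     area = rep(1, 3)), "mismatched")
  expect_error(occupancy_probability(list(t1 = matrix(-1, 1, 1),
                                          t2 = matrix(1, 1, 1)),
                                     area = 1), "negative")
})

test_that("area of occupancy sums occupancy and differences within draws", {
  # single draw, hand sum: P = (0.2, 0.5, 0.9) -> 1.6 cells = 16,000 km2
  P1 <- matrix(c(0.2, 0.5, 0.9), 1)
  P2 <- matrix(c(0.3, 0.5, 0.8), 1)
  s <- make_surface(P1, P2, area = 10000)
  a <- area_of_occupancy(s)
  expect_equal(a$A_t1, 1.6)
  expect_equal(a$summary$median_km2[a$summary$quantity == "A_t1"], 16000)
  expect_equal(a$dA, 0.1 - 0.1)  # +0.1 and -0.1 cancel
  # all P = 1 over N cells: A = N
  PN <- matrix(1 - 1e-12, 1, 7)
  expect_equal(area_of_occupancy(make_surface(PN, PN))$A_t1, 7,
               tolerance = 1e-6)
})

test_that("a change in cells converts to km2 by the cell area", {
  # 14.6 cells at 100-km resolution is 146,000 km2
  set.seed(7)
  P1 <- matrix(runif(300, 0.2, 0.6), 100, 3)
  P2 <- pmin(pmax(P1 + matrix(rnorm(300, 0.05, 0.1), 100, 3), 0.01), 0.95)
  s <- make_surface(pmin(P1, 0.99), pmin(P2, 0.99), area = 10000)
  a <- area_of_occupancy(s)
  i <- a$summary$quantity == "dA"
  expect_equal(a$summary$median_km2[i], a$summary$median_cells[i] * 10000)
  expect_equal(14.6 * 10000, 146000)
  # credible intervals on the change come from per-draw differences, not
  # from differencing the two marginal intervals
  lo_marg <- quantile(a$A_t2, 0.025) - quantile(a$A_t1, 0.025)
  expect_false(isTRUE(all.equal(a$summary$lower_cells[i], unname(lo_marg))))
  expect_equal(a$summary$lower_cells[i],
               unname(quantile(a$A_t2 - a$A_t1, 0.025)))
})

test_that("AOO is linear in a global occupancy rescaling", {
  set.seed(8)
  P <- matrix(runif(200, 0.1, 0.9), 50, 4)
  for (c_scale in c(0.3, 0.7, 1)) {
    s <- occupancy_probability(list(t1 = -log(1 - P * c_scale),
                                    t2 = -log(1 - P * c_scale)),
                               area = rep(1, 4))
    a0 <- occupancy_probability(list(t1 = -log(1 - P), t2 = -log(1 - P)),
                                area = rep(1, 4))
    expect_equal(area_of_occupancy(s)$A_t1,
                 c_scale * area_of_occupancy(a0)$A_t1, tolerance = 1e-9)
  }
})

test_that("change classification splits sign by certainty", {
  n_draw <- 200
  dP <- cbind(rep(0.3, n_draw),                      # certain gain
              c(rep(-0.05, 50), rep(0.25, 150)),     # uncertain gain
              rep(0, n_draw),                        # no change
              rep(-0.3, n_draw),                     # certain loss
              c(rep(0.05, 50), rep(-0.25, 150)))     # uncertain loss
  cls <- classify_change(dP)
  expect_equal(as.character(cls),
               c("certain gain", "uncertain gain", "no change",
                 "certain loss", "uncertain loss"))
  expect_error(classify_change(dP[1:20, ]), "100 draws")
})

test_that("stacked richness sums per-species median occupancy", {
  set.seed(9)
  n_draw <- 1200
  mk <- function(p1, p2) {
    occupancy_probability(
      list(t1 = matrix(-log(1 - p1), n_draw, length(p1), byrow = TRUE),
           t2 = matrix(-log(1 - p2), n_draw, length(p2), byrow = TRUE)),
      area = rep(1, length(p1)))
  }
  surfaces <- list(a = mk(c(1 - 1e-9, 0), c(1 - 1e-9, 0)),
                   b = mk(c(1 - 1e-9, 0), c(1 - 1e-9, 0.2)))
  sr <- stack_richness(surfaces, n_samples = 1000, seed = 3)
  expect_equal(unname(sr$SR[1, ]), c(2, 2), tolerance = 1e-6)
  expect_equal(unname(sr$dSR), c(0, 0.2), tolerance = 1e-6)
  # fewer draws than requested: warns and uses all
  surfaces_small <- list(a = mk(c(0.5, 0.5), c(0.5, 0.5)))
  expect_warning(stack_richness(surfaces_small, n_samples = 5000, seed = 1),
                 "using all")
  # deterministic given the seed
  sr2 <- stack_richness(surfaces, n_samples = 1000, seed = 3)
  expect_identical(sr$SR, sr2$SR)
})

test_that("Whittaker beta follows gamma over mean alpha", {
  # every species everywhere: beta = 1
  P <- matrix(1, 3, 4)
  expect_equal(unname(whittaker_beta(P)), c(3, 3, 1))
  # two cells, two fully distinct singletons: alpha_bar = 1, gamma = 2
  P2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(unname(whittaker_beta(P2)), c(2, 1, 2))
  # duplicating every cell leaves beta unchanged for a binary stack (for
  # probabilistic stacks the expected pooled richness grows with extent)
  set.seed(10)
  P3 <- matrix(rbinom(12, 1, 0.5), 3, 4)
  P3[1, 1] <- 1  # some species present somewhere
  b1 <- whittaker_beta(P3)["beta"]
  b2 <- whittaker_beta(cbind(P3, P3))["beta"]
  expect_equal(b2, b1, tolerance = 1e-12)
  expect_warning(b0 <- whittaker_beta(matrix(0, 2, 3)), "undefined")
  expect_true(is.na(b0["beta"]))
})

test_that("Whittaker beta is at least 1 on probabilistic stacks", {
  set.seed(11)
  for (i in 1:20) {
    P <- matrix(runif(5 * 8), 5, 8)
    expect_gte(whittaker_beta(P)["beta"] + 1e-12, 1)
  }
})

test_that("Ruzicka dissimilarity matches its definition and metric properties", {
  expect_equal(ruzicka(c(0.2, 0.5, 0), c(0.4, 0.1, 0)), 1 - 0.3 / 0.9)
  expect_equal(ruzicka(c(1, 2), c(1, 2)), 0)
  expect_equal(ruzicka(c(1, 0), c(0, 2)), 1)  # disjoint supports
  expect_warning(r0 <- ruzicka(c(0, 0), c(0, 0)), "undefined")
  expect_true(is.na(r0))
  set.seed(12)
  for (i in 1:50) {
    x <- runif(6); y <- runif(6)
    r <- ruzicka(x, y)
    expect_true(r >= 0 && r <= 1)
    expect_equal(r, ruzicka(y, x))
    expect_equal(ruzicka(x, x), 0)
    # scale invariance
    expect_equal(ruzicka(3 * x, 3 * y), r, tolerance = 1e-12)
  }
})

test_that("temporal dissimilarity maps apply Ruzicka per cell", {
  P1 <- rbind(c(1, 0.3, 0), c(0, 0.3, 0))
  P2 <- rbind(c(0, 0.3, 0), c(1, 0.3, 0))
  r <- temporal_dissimilarity_map(P1, P2)
  expect_equal(r[1], 1)   # complete turnover
  expect_equal(r[2], 0)   # identical composition
  expect_true(is.na(r[3]))  # empty in both periods
  expect_equal(temporal_dissimilarity_map(P1, P1), c(0, 0, NA))
})

test_that("distance decay rises along a constructed composition gradient", {
  # species ranges drift along x: nearby cells share species, distant do not
  g <- build_grid(extent_km = c(0, 1500, 0, 1500))
  xs <- g$cells$x
  centres <- seq(0, 1500, length.out = 12)
  P <- t(vapply(centres, function(m) exp(-((xs - m) / 250)^2),
                numeric(length(xs))))
  decay <- spatial_distance_decay(list(t1 = P, t2 = P),
                                  cbind(g$cells$x, g$cells$y),
                                  n_pairs = 4000, bins = 8, seed = 5)
  d1 <- decay[decay$period == "t1", ]
  ok <- !is.na(d1$median_dissim)
  expect_gt(cor(d1$bin_mid[ok], d1$median_dissim[ok], method = "spearman"),
            0.9)
  # identical composition everywhere: zero dissimilarity in every bin
  Pflat <- matrix(0.4, 5, length(xs))
  flat <- spatial_distance_decay(list(t1 = Pflat, t2 = Pflat),
                                 cbind(g$cells$x, g$cells$y),
                                 n_pairs = 500, bins = 5, seed = 5)
  expect_true(all(flat$median_dissim[!is.na(flat$median_dissim)] == 0))
  # seeded determinism
  again <- spatial_distance_decay(list(t1 = P, t2 = P),
                                  cbind(g$cells$x, g$cells$y),
                                  n_pairs = 4000, bins = 8, seed = 5)
  expect_identical(decay, again)
})

test_that("Ruzicka agrees with vegan's quantitative Jaccard", {
  skip_if_not_installed("vegan")
  set.seed(13)
  for (i in 1:20) {
    x <- runif(8); y <- runif(8)
    v <- as.numeric(vegan::vegdist(rbind(x, y), method = "jaccard"))
    expect_equal(ruzicka(x, y), v, tolerance = 1e-10)
  }
})
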