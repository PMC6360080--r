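est2 <- function(mu, sigma, n, species = "sp") {
  list(mu = mu, sigma = sigma, n = n, species = species)
}

test_that("coverage profiles vanish at each species' own mean", {
  ctl <- test_ctl()
  e1 <- est2(c(0, 0), diag(2), 10, "a")
  e2 <- est2(c(3, 1), matrix(c(1, 0.4, 0.4, 0.8), 2), 14, "b")
  pr <- beta_profile(e1, e2, grid_size = 65, control = ctl)
  expect_equal(pr$beta1[1], 0)
  expect_equal(pr$beta2[65], 0)
  expect_true(all(pr$beta1 >= 0 & pr$beta1 < 1))
  expect_true(all(pr$beta2 >= 0 & pr$beta2 < 1))
})

test_that("identical species estimates can never support a gap", {
  ctl <- test_ctl()
  e <- est2(c(1, 2), diag(2), 12, "same")
  pr <- beta_profile(e, est2(c(1, 2), diag(2), 12, "same2"),
                     grid_size = 65, control = ctl)
  expect_true(all(pmin(pr$beta1, pr$beta2) == 0))
  dec <- detect_gap_bivariate(pr)
  expect_false(dec$supported)
  expect_equal(dec$criterion_value, 0)
})

test_that("with equal covariances each profile is monotone along the segment", {
  # Mahalanobis distance from a mean grows monotonically along a straight
  # line leaving it, so beta must inherit the monotonicity
  ctl <- test_ctl()
  S <- matrix(c(1, 0.5, 0.5, 2), 2)
  pr <- beta_profile(est2(c(0, 0), S, 10, "a"), est2(c(4, 3), S, 15, "b"),
                     grid_size = 129, control = ctl)
  expect_true(all(diff(pr$beta1) >= -1e-12))
  expect_true(all(diff(pr$beta2) <= 1e-12))
})

test_that("extreme separation is detected and coincidence is not", {
  ctl <- test_ctl()
  far <- beta_profile(est2(c(0, 0), diag(2), 30, "a"),
                      est2(c(10, 0), diag(2), 30, "b"),
                      grid_size = 129, control = ctl)
  expect_true(detect_gap_bivariate(far)$supported)
  near <- beta_profile(est2(c(0, 0), diag(2), 30, "a"),
                       est2(c(0.5, 0), diag(2), 30, "b"),
                       grid_size = 129, control = ctl)
  expect_false(detect_gap_bivariate(near)$supported)
})

test_that("the reported criterion matches a dense-grid maximisation", {
  ctl <- test_ctl()
  e1 <- est2(c(0, 0), matrix(c(1, 0.3, 0.3, 0.7), 2), 12, "a")
  e2 <- est2(c(5, 2), matrix(c(1.6, -0.4, -0.4, 1.1), 2), 9, "b")
  dec <- detect_gap_bivariate(beta_profile(e1, e2, grid_size = 513,
                                           control = ctl))
  dense <- beta_profile(e1, e2, grid_size = 8193, control = ctl)
  brute <- max(pmin(dense$beta1, dense$beta2))
  expect_equal(dec$criterion_value, brute, tolerance = 1e-3)
})

test_that("stricter thresholds never create support", {
  ctl <- test_ctl()
  pr <- beta_profile(est2(c(0, 0), diag(2), 20, "a"),
                     est2(c(4.5, 0), diag(2), 20, "b"),
                     grid_size = 129, control = ctl)
  for (th in c(0.30, 0.15, 0.05)) {
    dec_loose <- detect_gap_bivariate(pr, threshold = th)
    dec_strict <- detect_gap_bivariate(pr, threshold = th / 2)
    expect_false(!dec_loose$supported && dec_strict$supported)
  }
  # univariate analogue: widening the content makes limits more extreme
  c1 <- c(2, 3, 2, 4, 3, 2); c2 <- c(30, 45, 38, 52, 41)
  u_loose <- detect_gap_univariate(c1, c2, threshold = 0.30)
  u_strict <- detect_gap_univariate(c1, c2, threshold = 0.05)
  expect_lte(u_strict$criterion_value, u_loose$criterion_value)
})

test_that("flower-number decisions reproduce the obvious patterns", {
  # single-flowered species against a mass-flowering one: clear gap
  ones <- c(1, 1, 1, 1, 1, 1)
  many <- c(800, 950, 881, 900, 850, 910, 820, 870, 940, 860, 905)
  dec <- detect_gap_univariate(ones, many, species = c("unifloral", "massive"))
  expect_true(dec$supported)
  expect_equal(dec$species_low, "unifloral")
  # zero variance collapses the limit to the sample mean
  expect_equal(dec$upper_limit, 1)
  # identical samples: no gap
  same <- detect_gap_univariate(c(5, 8, 6, 9), c(5, 8, 6, 9))
  expect_false(same$supported)
  expect_lt(same$criterion_value, 0)
})

test_that("the univariate decision is symmetric in its arguments", {
  withr::with_seed(88, {
    for (i in 1:5) {
      a <- pmax(1, round(exp(rnorm(8, 2, 0.8))))
      b <- pmax(1, round(exp(rnorm(11, 3.5, 0.6))))
      d1 <- detect_gap_univariate(a, b, species = c("A", "B"))
      d2 <- detect_gap_univariate(b, a, species = c("B", "A"))
      expect_equal(d1$supported, d2$supported)
      expect_equal(d1$criterion_value, d2$criterion_value, tolerance = 1e-12)
      expect_equal(d1$species_low, d2$species_low)
    }
  })
})

test_that("the bivariate decision is affine-invariant on untransformed data", {
  ctl <- test_ctl()
  sp <- dplyr::bind_rows(
    generate_species("p", 15, c(2.0, 1.0), diag(0.05, 2), 2, 0.3, seed = 3),
    generate_species("q", 15, c(3.5, 2.2), diag(0.05, 2), 2, 0.3, seed = 4)
  )
  means <- specimen_means(sp)
  A <- matrix(c(2, 0.5, -0.3, 1.5), 2); cc <- c(10, 20)
  tr <- means
  xy <- t(A %*% rbind(means$leaf_length, means$leaf_width) + cc)
  tr$leaf_length <- xy[, 1]; tr$leaf_width <- xy[, 2]
  run_dec <- function(m) {
    est <- estimate_bivariate(m, transform = "none")
    detect_gap_bivariate(beta_profile(est[1, ], est[2, ], grid_size = 257,
                                      control = ctl))
  }
  d0 <- run_dec(means); d1 <- run_dec(tr)
  expect_equal(d0$supported, d1$supported)
  expect_equal(d0$criterion_value, d1$criterion_value, tolerance = 1e-6)
})

test_that("the pairwise scan produces consistent decision bookkeeping", {
  panel <- three_species_panel(seed = 13)
  cfg <- morphogap_config(grid_size = 129, n_rep = 1500, n_inner = 800)
  scan <- suppressMessages(run_all_pairs(specimen_means(panel), "far away", cfg))
  expect_equal(scan$summary$n_pairs, 2L)
  expect_equal(scan$summary$either, 2L) # far species separated from both
  s <- scan$summary
  expect_equal(s$either, s$both + s$leaf_only + s$flower_only)
  expect_equal(s$n_pairs, s$either + s$neither)
  expect_equal(nrow(tidy(scan)), 4L) # 2 pairs x 2 traits
  expect_s3_class(glance(scan), "tbl_df")
  expect_error(
    suppressMessages(run_all_pairs(specimen_means(panel), "absent", cfg)),
    "absent"
  )
})
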