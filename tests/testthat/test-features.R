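test_that("auto-MI delay finds the quarter period of a sine", {
  set.seed(41)
  s <- sin(2 * pi * (1:3000) / 20) + rnorm(3000, 0, 0.05)
  tau <- delay_from_automi(s, 30)
  expect_true(abs(tau - 5) <= 2)
  expect_lte(as.integer(delay_from_automi(rnorm(3000), 30)), 3)
  expect_error(delay_from_automi(rep(1, 1000), 30), "constant")
  expect_error(delay_from_automi(rnorm(100), 50), "max_lag")
})

test_that("Cao's method separates deterministic from stochastic series", {
  lx <- lorenz_series(10000)
  tau <- delay_from_automi(lx, 60)
  ca <- cao_embedding_dim(lx, tau, max_m = 10)
  expect_true(ca$m %in% 3:5)
  expect_true(ca$is_deterministic)
  expect_false(ca$flagged)

  set.seed(42)
  cn <- cao_embedding_dim(rnorm(3000), 1, max_m = 8)
  expect_identical(cn$m, 8L)                 # E1 saturates slowly for noise
  expect_true(cn$flagged)
  expect_false(cn$is_deterministic)

  cs <- cao_embedding_dim(sin(2 * pi * (1:3000) / 23.7), 6, max_m = 8)
  expect_lte(cs$m, 6)                        # low-dimensional limit cycle
  expect_error(cao_embedding_dim(rnorm(50), 5, max_m = 10), "short")
})

test_that("correlation dimension recovers known geometries", {
  set.seed(43)
  t <- runif(2500)
  line <- cbind(t, 2 * t + 1)
  expect_lt(abs(corr_dim_points(line)$d2 - 1), 0.1)

  sq <- cbind(runif(2500), runif(2500))
  d2sq <- corr_dim_points(sq)$d2
  expect_lt(abs(d2sq - 2), 0.15)
  expect_lt(abs(d2sq - brute_corr_dim(sq[1:1500, ])), 0.2)  # oracle route

  lx <- lorenz_series(12000)
  tau <- delay_from_automi(lx, 60)
  d2 <- correlation_dimension(lx, 5, tau)$d2
  expect_gt(d2, 1.8); expect_lt(d2, 2.3)
  expect_error(correlation_dimension(lx[1:400], 5, tau), "500")
})

test_that("noise correlation dimension grows with embedding dimension", {
  set.seed(44)
  x <- rnorm(3000)
  d2s <- vapply(c(2, 4, 6), function(m)
    correlation_dimension(x, m, 1)$d2, 0)
  expect_true(all(diff(d2s) > 0))
})

test_that("approximate entropy ranks regularity correctly", {
  expect_equal(approximate_entropy(rep(2, 100)), 0)
  expect_lt(approximate_entropy(rep(c(0, 1), 100)), 0.05)
  set.seed(45)
  wins <- vapply(1:50, function(i) {
    noise <- rnorm(750)
    sine <- sin(2 * pi * (1:750) / 25 + runif(1, 0, 2 * pi))
    approximate_entropy(noise) > approximate_entropy(sine)
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("approximate entropy agrees with the direct-definition oracle", {
  set.seed(46)
  x <- rnorm(300)
  expect_equal(approximate_entropy(x), brute_apen(x), tolerance = 1e-10)
})

test_that("Hurst estimation recovers planted exponents", {
  errs <- vapply(c(0.3, 0.5, 0.8), function(h) {
    est <- vapply(1:20, function(s)
      as.numeric(hurst_rs(generate_fgn(h, 4096, seed = 1000 * h + s))), 0)
    mean(abs(est - h))
  }, 0)
  expect_true(all(errs < 0.1))
  set.seed(47)
  hw <- mean(vapply(1:20, function(i) as.numeric(hurst_rs(rnorm(4096))), 0))
  expect_lt(abs(hw - 0.5), 0.1)
  expect_true(as.numeric(hurst_rs(cumsum(rnorm(4096)))) <= 1)  # clipped
  expect_error(hurst_rs(rnorm(100)), "256")
  expect_error(hurst_rs(rep(1, 1000)), "usable|constant")
})

test_that("Hurst broadly agrees with pracma's implementation", {
  skip_if_not_installed("pracma")
  f <- generate_fgn(0.75, 4096, seed = 9)
  ours <- as.numeric(hurst_rs(f))
  theirs <- pracma::hurstexp(f, display = FALSE)$Hs
  expect_lt(abs(ours - theirs), 0.1)
})

test_that("the PCA index measures eigenvalue spread", {
  expect_equal(as.numeric(pcai_from_eigenvalues(c(0.9, 0.1))),
               sd_pop <- sqrt(mean((log10(c(9, 1) / 10) -
                                      mean(log10(c(9, 1) / 10)))^2)),
               tolerance = 1e-12)
  expect_equal(round(as.numeric(pcai_from_eigenvalues(c(0.9, 0.1))), 3),
               0.477)
  expect_equal(as.numeric(pcai_from_eigenvalues(c(2, 2, 2))), 0)
  set.seed(48)
  expect_lt(as.numeric(pcai(rnorm(6000), 3, 500)), 0.05)  # isotropic cloud
  expect_error(pcai(rep(1, 1000), 3, 5), "constant")
  expect_error(pcai(rnorm(100), 1, 5), "m")
})

test_that("features are invariant under affine transforms of the signal", {
  set.seed(49)
  x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 2000))
  y <- -3.7 * x + 11
  expect_equal(approximate_entropy(x), approximate_entropy(y),
               tolerance = 1e-8)
  expect_equal(as.numeric(hurst_rs(x)), as.numeric(hurst_rs(y)),
               tolerance = 1e-8)
  expect_equal(as.numeric(pcai(x, 3, 2)), as.numeric(pcai(y, 3, 2)),
               tolerance = 1e-6)
  d2x <- correlation_dimension(x, 4, 2)$d2
  d2y <- correlation_dimension(y, 4, 2)$d2
  expect_equal(d2x, d2y, tolerance = 0.15)
})

test_that("feature profiles have the right shape and degrade gracefully", {
  set.seed(50)
  w1 <- matrix(rnorm(2 * 750), 2); w2 <- matrix(rnorm(2 * 750), 2)
  w3 <- matrix(rnorm(2 * 750), 2)
  w2[2, ] <- 0                               # constant channel, one window
  ws <- make_window_set(list(w1, w2, w3), labels = c("A", "B"), fs = 250,
                        window_s = 3)
  prof <- feature_profiles(ws, features = c("ApEn", "HE"))
  expect_equal(nrow(prof), 2 * 3 * 2)
  expect_true(is.na(prof$value[prof$channel == "B" & prof$window == 2 &
                                 prof$feature == "HE"]))
  ok <- prof$value[prof$channel == "B" & prof$window != 2 &
                     prof$feature == "HE"]
  expect_true(all(!is.na(ok)))               # other windows intact

  ws2 <- make_window_set(list(rbind(w1[1, ], w1[1, ])), labels = c("A", "B"),
                         fs = 250, window_s = 3)
  p2 <- feature_profiles(ws2, features = "ApEn")
  expect_equal(p2$value[p2$channel == "A"], p2$value[p2$channel == "B"])
})
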