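test_that("chains are bit-reproducible under a fixed seed", {
  des <- testlet_design_blocks(2, 5)
  Y <- tiny_data(40, des, seed = 8)
  f1 <- fit_testlet(Y, des, "n2plt", iter = 400, burnin = 100, seed = 11)
  f2 <- fit_testlet(Y, des, "n2plt", iter = 400, burnin = 100, seed = 11)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_testlet(Y, des, "n2plt", iter = 400, burnin = 100, seed = 12)
  expect_false(identical(f1$draws[[1]], f3$draws[[1]]))
})

test_that("slice indicators hold after every parameter draw on a toy fit", {
  des <- testlet_design_blocks(2, 3)
  Y <- tiny_data(30, des, seed = 14)
  f <- fit_testlet(Y, des, "n2plt", iter = 200, burnin = 50, seed = 15,
                   debug = 2)
  expect_gt(f$slice_checks, 200 * 10)   # at least one audit per item draw
  expect_identical(f$slice_violations, 0)
  # the random-effects testlet model and the 2PL pass the same audit
  f_t <- fit_testlet(Y, des, "t2plt", iter = 150, burnin = 50, seed = 16,
                     debug = 2)
  expect_identical(f_t$slice_violations, 0)
  f_2 <- fit_testlet(Y, des, "2pl", iter = 150, burnin = 50, seed = 17,
                     debug = 2)
  expect_identical(f_2$slice_violations, 0)
})

test_that("identification-fixed parameters never move", {
  des <- testlet_design_blocks(2, 4)
  Y <- tiny_data(35, des, seed = 19)
  f <- fit_testlet(Y, des, "n2plt", iter = 300, burnin = 100, seed = 20,
                   chains = 2)
  for (ch in 1:2) {
    expect_true(all(f$draws[[ch]][, "a[1]"] == 1))
    expect_true(all(f$draws[[ch]][, "b[1]"] == 0))
  }
  # overdispersed secondary chains must not jitter the pinned values,
  # so the PSRF of a constant-equal parameter is 1 by convention
  expect_equal(psrf(cbind(f$draws[[1]][, "a[1]"], f$draws[[2]][, "a[1]"])), 1)
})

test_that("the 2pl fit carries no testlet-effect parameters", {
  des <- testlet_design_blocks(2, 4)
  Y <- tiny_data(30, des, seed = 23)
  f <- fit_testlet(Y, des, "2pl", iter = 200, burnin = 50, seed = 24)
  expect_false(any(grepl("sigma2_eta", colnames(f$draws[[1]]))))
  expect_true(all(f$post_mean$eta == 0))
})

test_that("a single free difficulty matches the analytic posterior (KS)", {
  # 2 persons x 2 items, everything clamped except b_2: the chain's marginal
  # must match the grid-integrated posterior of the joint density
  des <- testlet_design(c(1, 1))
  a <- c(1, 1.2); theta <- c(0.7, -0.6); eta <- matrix(c(0.3, -0.2), 2, 1)
  Y <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  ff <- fit_testlet(Y, des, "n2plt", iter = 12000, burnin = 2000, seed = 31,
                    identify = FALSE,
                    prior = prior_config(sigma2_a = 1, sigma2_b = 1,
                                         update_sigma2 = FALSE),
                    inits = list(a = a, b = c(0, 0), theta = theta,
                                 eta = eta),
                    update = list(a = FALSE, b = c(FALSE, TRUE),
                                  theta = FALSE, eta = FALSE))
  dr <- ff$draws[[1]][, "b[2]"]
  grid <- seq(-9, 9, length.out = 20001)
  lp <- dnorm(grid, 0, 1, log = TRUE)
  alpha <- mean(a)
  for (i in 1:2) {
    p <- plogis(a[2] * (theta[i] - grid) + alpha * eta[i, 1])
    lp <- lp + if (Y[i, 2] == 1) log(p) else log1p(-p)
  }
  w <- exp(lp - max(lp)); cdf <- cumsum(w) / sum(w)
  Fo <- approxfun(grid, cdf, yleft = 0, yright = 1)
  ks <- max(abs(Fo(sort(dr)) - (seq_along(dr) - 0.5) / length(dr)))
  expect_lt(ks, 0.03)
})

test_that("clamped-chain variance draws obey their conjugate law", {
  # with all location parameters clamped the variance draws are iid from
  # the closed-form inverse-gamma full conditionals
  set.seed(71)
  des <- testlet_design_blocks(2, 10)
  n <- 100
  a <- abs(rnorm(20)) + 0.3; b <- rnorm(20)
  eta <- matrix(rnorm(n * 2, 0, 0.6), n, 2)
  tp <- list(a = a, b = b, theta = rnorm(n), eta = eta)
  Y <- sim_responses(tp, des, "n2plt", seed = 72)
  f <- fit_testlet(Y, des, "n2plt", iter = 2300, burnin = 300, seed = 73,
                   identify = FALSE, inits = tp,
                   update = list(a = FALSE, b = FALSE, theta = FALSE,
                                 eta = FALSE))
  M <- 2000
  check_ig <- function(draws, shape, scale) {
    mu <- scale / (shape - 1)
    sdv <- sqrt(scale^2 / ((shape - 1)^2 * (shape - 2)))
    expect_lt(abs(mean(draws) - mu), 3 * sdv / sqrt(M))
  }
  d <- f$draws[[1]]
  check_ig(d[, "sigma2_a"], 10.001, sum(a^2) / 2 + 0.001)
  check_ig(d[, "sigma2_b"], 10.001, sum(b^2) / 2 + 0.001)
  check_ig(d[, "sigma2_eta[1]"], n / 2 + 0.001, sum(eta[, 1]^2) / 2 + 0.001)
  check_ig(d[, "sigma2_eta[2]"], n / 2 + 0.001, sum(eta[, 2]^2) / 2 + 0.001)
})

test_that("input validation catches shape and content errors", {
  des <- testlet_design_blocks(2, 5)
  Y <- tiny_data(20, des, seed = 26)
  expect_error(fit_testlet(Y[, 1:8], des, iter = 10, burnin = 5),
               "J = 10")
  expect_error(fit_testlet(Y, des, iter = 100, burnin = 100), "burnin")
  Ybad <- Y; Ybad[3, 4] <- 2L
  expect_error(fit_testlet(Ybad, des, iter = 10, burnin = 5), "row 3")
  expect_warning(
    fit_testlet(matrix(1L, 10, 10), des, iter = 20, burnin = 10, seed = 1),
    "degenerate")
})
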