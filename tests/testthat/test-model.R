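test_that("testlet discrimination is the within-testlet mean slope", {
  expect_equal(testlet_discrimination(rep(1, 5), testlet_design(rep(1, 5))), 1)
  expect_equal(testlet_discrimination(c(1, 3, 2, 2), des22()), c(2, 2))
  # the published testlet-4 slope EAPs of the reading-test example
  a4 <- c(2.0055, 0.7821, 1.5236, 1.1934, 0.6847)
  expect_equal(testlet_discrimination(a4, testlet_design(rep(1, 5))),
               mean(a4))
  expect_equal(mean(a4), 1.23786, tolerance = 1e-12)
  expect_error(testlet_discrimination(c(1, 2), des22()), "length")
  expect_error(testlet_discrimination(c(1, -1, 1, 1), des22()), "positive")
})

test_that("response probabilities follow the three linear predictors", {
  # theta = b, no testlet term: exactly one half for every model
  for (m in c("2pl", "t2plt", "n2plt"))
    expect_equal(response_probability(m, 0.3, 1.7, 0.3, eta = 0, alpha = 1),
                 0.5)
  expect_equal(response_probability("n2plt", 1, 1, 0, eta = 0, alpha = 2),
               1 / (1 + exp(-1)), tolerance = 1e-6)
  expect_equal(1 / (1 + exp(-1)), 0.731059, tolerance = 1e-6)
  p <- response_probability("n2plt", 0.4, 1.2, -0.3, eta = 0.8, alpha = 1.1)
  expect_equal(p, plogis(1.2 * 0.7 + 1.1 * 0.8))
  expect_error(response_probability("2pl", 0, -1, 0), "positive")
  expect_error(response_probability("n2plt", 0, 1, 0, eta = 1), "alpha")
})

test_that("model reductions hold cellwise", {
  set.seed(3)
  theta <- rnorm(30); b <- rnorm(30); eta <- rnorm(30)
  # equal slopes within the testlet: alpha equals the common slope, so the
  # testlet-discrimination model coincides with the random-effects model
  for (cc in c(0.4, 1, 2.3)) {
    expect_equal(
      response_probability("n2plt", theta, cc, b, eta, alpha = cc),
      response_probability("t2plt", theta, cc, b, eta))
  }
  # zero testlet effects: both testlet models reduce to the 2PL
  a <- abs(rnorm(30)) + 0.1
  expect_equal(response_probability("n2plt", theta, a, b, 0, alpha = 1.4),
               response_probability("2pl", theta, a, b))
  expect_equal(response_probability("t2plt", theta, a, b, 0),
               response_probability("2pl", theta, a, b))
})

test_that("probability is monotone in theta, eta and b", {
  g <- seq(-3, 3, 0.25)
  p_th <- response_probability("n2plt", g, 0.8, 0.2, 0.5, alpha = 1.2)
  expect_true(all(diff(p_th) > 0))
  p_eta <- response_probability("n2plt", 0.3, 0.8, 0.2, g, alpha = 1.2)
  expect_true(all(diff(p_eta) > 0))
  p_b <- response_probability("n2plt", 0.3, 0.8, g, 0.5, alpha = 1.2)
  expect_true(all(diff(p_b) < 0))
  expect_true(all(p_th > 0 & p_th < 1))
})

test_that("forward simulation is reproducible and correctly calibrated", {
  des <- testlet_design_blocks(2, 5)
  tp <- tiny_truth(40, des, seed = 5)
  Y1 <- sim_responses(tp, des, "n2plt", seed = 9)
  Y2 <- sim_responses(tp, des, "n2plt", seed = 9)
  expect_identical(Y1, Y2)
  expect_true(all(Y1 %in% 0:1))

  # degenerate Bernoulli: b -> -50 forces all-correct responses
  tp0 <- list(a = rep(1, 10), b = rep(-50, 10), theta = rep(0, 40),
              eta = matrix(0, 40, 2))
  expect_true(all(sim_responses(tp0, des, "n2plt", seed = 1) == 1L))

  # single item with p = logistic(1): column mean within 3 binomial SEs
  d1 <- testlet_design(1)
  p <- plogis(1)
  tp1 <- list(a = 1, b = 0, theta = rep(1, 2000), eta = matrix(0, 2000, 1))
  Y <- sim_responses(tp1, d1, "n2plt", seed = 11)
  expect_lt(abs(mean(Y) - p), 3 * sqrt(p * (1 - p) / 2000))
})

test_that("log-likelihood matches a brute-force oracle", {
  # single observation at p = 1/2
  d1 <- testlet_design(1)
  tp1 <- list(a = 1, b = 0, theta = 0, eta = matrix(0, 1, 1))
  expect_equal(loglik_testlet(matrix(1L, 1, 1), tp1, d1), log(0.5),
               tolerance = 1e-12)

  set.seed(21)
  des <- testlet_design(c(1, 1, 2))
  tp <- list(a = abs(rnorm(3)) + 0.2, b = rnorm(3), theta = rnorm(3),
             eta = matrix(rnorm(6, 0, 0.5), 3, 2))
  Y <- sim_responses(tp, des, "n2plt", seed = 22)
  alpha <- testlet_discrimination(tp$a, des)
  brute <- 0
  for (i in 1:3) for (j in 1:3) {
    p <- plogis(tp$a[j] * (tp$theta[i] - tp$b[j]) +
                  alpha[des$assignment[j]] * tp$eta[i, des$assignment[j]])
    brute <- brute + log(if (Y[i, j] == 1) p else 1 - p)
  }
  brute <- unname(brute)
  expect_equal(loglik_testlet(Y, tp, des, "n2plt"), brute, tolerance = 1e-10)
  # additivity over independent cells
  half1 <- loglik_testlet(Y[1:2, , drop = FALSE],
                          list(a = tp$a, b = tp$b, theta = tp$theta[1:2],
                               eta = tp$eta[1:2, , drop = FALSE]), des)
  half2 <- loglik_testlet(Y[3, , drop = FALSE],
                          list(a = tp$a, b = tp$b, theta = tp$theta[3],
                               eta = tp$eta[3, , drop = FALSE]), des)
  expect_equal(half1 + half2, brute, tolerance = 1e-10)
})

test_that("log unnormalized posterior matches direct evaluation", {
  set.seed(31)
  des <- des22()
  mk_state <- function() list(
    a = abs(rnorm(4)) + 0.2, b = rnorm(4), theta = rnorm(2),
    eta = matrix(rnorm(4, 0, 0.5), 2, 2),
    sigma2_a = runif(1, 0.5, 2), sigma2_b = runif(1, 0.5, 2),
    sigma2_eta = runif(2, 0.1, 1))
  s1 <- mk_state(); s2 <- mk_state()
  Y <- sim_responses(s1, des, "n2plt", seed = 32)
  pri <- prior_config()
  direct <- function(s) {
    alpha <- testlet_discrimination(s$a, des)
    lp <- 0
    for (i in 1:2) for (j in 1:4) {
      k <- des$assignment[j]
      p <- plogis(s$a[j] * (s$theta[i] - s$b[j]) + alpha[k] * s$eta[i, k])
      lp <- lp + log(if (Y[i, j] == 1) p else 1 - p)
    }
    lp <- unname(lp)
    lp <- lp + sum(dnorm(s$theta, log = TRUE))
    lp <- lp - sum((s$a - 0)^2) / (2 * s$sigma2_a) - 2 * log(s$sigma2_a)
    lp <- lp - sum((s$b - 0)^2) / (2 * s$sigma2_b) - 2 * log(s$sigma2_b)
    lp <- lp - 1.001 * log(s$sigma2_a) - 0.001 / s$sigma2_a
    lp <- lp - 1.001 * log(s$sigma2_b) - 0.001 / s$sigma2_b
    for (k in 1:2) {
      lp <- lp + sum(dnorm(s$eta[, k], 0, sqrt(s$sigma2_eta[k]), log = TRUE))
      lp <- lp - 1.001 * log(s$sigma2_eta[k]) - 0.001 / s$sigma2_eta[k]
    }
    lp
  }
  diff_pkg <- log_unnorm_posterior(s1, Y, des, pri) -
    log_unnorm_posterior(s2, Y, des, pri)
  expect_equal(diff_pkg, direct(s1) - direct(s2), tolerance = 1e-8)
  expect_true(is.finite(log_unnorm_posterior(s1, Y, des, pri)))
  s_bad <- s1; s_bad$a[2] <- -0.5
  expect_identical(log_unnorm_posterior(s_bad, Y, des, pri), -Inf)
})
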