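test_that("auxiliary variables live on the correct uniform supports", {
  d1 <- testlet_design(1)
  tp <- list(a = 1, b = 0, theta = rep(0, 1), eta = matrix(0, 1, 1))
  # p = logistic(a(theta - b)) driven to 0.8 via theta
  tp$theta <- qlogis(0.8)
  set.seed(41)
  lam <- replicate(10000, sample_auxiliary(matrix(1L, 1, 1), tp, d1)$lambda)
  expect_true(all(lam > 0 & lam <= 0.8))
  expect_lt(abs(mean(lam) - 0.4), 3 * 0.8 / sqrt(12 * 10000))
  phi <- replicate(10000, sample_auxiliary(matrix(0L, 1, 1), tp, d1)$phi)
  expect_true(all(phi > 0 & phi <= 0.2))
})

test_that("slope truncation bounds solve the slice inequalities", {
  d1 <- testlet_design(1)
  params <- list(a = 1, b = 0, theta = 1, eta = matrix(0, 1, 1))
  # y = 1, lambda = logistic(1): the constraint is a * 1 >= 1
  aux <- list(threshold = matrix(1, 1, 1))
  b1 <- slice_bounds_a(1, matrix(1L, 1, 1), aux, params, d1)
  expect_equal(unname(b1), c(1, Inf))
  # y = 0, phi = logistic(-1): upper bound a <= 1
  b0 <- slice_bounds_a(1, matrix(0L, 1, 1), aux, params, d1)
  expect_equal(unname(b0), c(0, 1))
  # vacuous constraints (threshold -Inf for y=1) leave (0, Inf)
  aux_v <- list(threshold = matrix(-Inf, 1, 1))
  expect_equal(unname(slice_bounds_a(1, matrix(1L, 1, 1), aux_v, params, d1)),
               c(0, Inf))
})

test_that("difficulty, ability and testlet-effect bounds match hand cases", {
  d1 <- testlet_design(1)
  params <- list(a = 1, b = 0, theta = 0, eta = matrix(0, 1, 1))
  # y = 1 with lambda = 1/2: b <= theta - (logit(1/2) - 0)/a = 0
  aux0 <- list(threshold = matrix(0, 1, 1))
  expect_equal(unname(slice_bounds_b(1, matrix(1L, 1, 1), aux0, params, d1)),
               c(-Inf, 0))
  expect_equal(unname(slice_bounds_b(1, matrix(0L, 1, 1), aux0, params, d1)),
               c(0, Inf))
  # y = 1, lambda = logistic(1): theta >= 1
  aux1 <- list(threshold = matrix(1, 1, 1))
  expect_equal(unname(slice_bounds_theta(1, matrix(1L, 1, 1), aux1, params,
                                         d1)), c(1, Inf))
  # single-item testlet, y = 1: eta lower bound = logit(lambda)
  expect_equal(unname(slice_bounds_eta(1, 1, matrix(1L, 1, 1), aux1, params,
                                       d1)), c(1, Inf))
  # two-item testlet: the binding candidate wins (max over y=1 items)
  d2 <- testlet_design(c(1, 1))
  p2 <- list(a = c(1, 1), b = c(0, 0), theta = 0, eta = matrix(0, 1, 1))
  aux2 <- list(threshold = matrix(c(0.3, 0.7), 1, 2))
  expect_equal(unname(slice_bounds_eta(1, 1, matrix(1L, 1, 2), aux2, p2,
                                       d2)), c(0.7, Inf))
  # all items answered correctly: no upper bound
  expect_equal(slice_bounds_eta(1, 1, matrix(1L, 1, 2), aux2, p2,
                                d2)[["upper"]], Inf)
})

test_that("sibling cells constrain the slope under the n2plt model", {
  # two items in one testlet, nonzero eta: updating a_1 moves alpha and
  # hence the sibling cell's probability; the bound must reflect that
  d2 <- testlet_design(c(1, 1))
  params <- list(a = c(1, 1), b = c(0, 0), theta = 0.5,
                 eta = matrix(1.2, 1, 1))
  Y <- matrix(c(1L, 0L), 1, 2)
  aux <- list(threshold = matrix(c(-2, 1.4), 1, 2))
  with_sib <- slice_bounds_a(1, Y, aux, params, d2, include_siblings = TRUE)
  without <- slice_bounds_a(1, Y, aux, params, d2, include_siblings = FALSE)
  # sibling cell (y=0): a_1 * (eta/2) <= t - a_2(theta - b_2) - a_2 eta/2
  sib_hi <- (1.4 - 1 * 0.5 - 1 * 0.6) / 0.6
  expect_equal(with_sib[["upper"]], min(without[["upper"]], sib_hi))
  expect_true(with_sib[["upper"]] < without[["upper"]])
})

test_that("truncated-normal and truncated-prior draws have the right law", {
  set.seed(51)
  # half-normal mean sqrt(2/pi)
  x <- rtruncnorm(50000, 0, 1, 0, Inf)
  expect_true(all(x > 0))
  expect_lt(abs(mean(x) - sqrt(2 / pi)), 3 * sd(x) / sqrt(50000))
  # degenerate interval
  expect_equal(rtruncnorm(1, 0, 1, 1, 1 + 1e-12), 1, tolerance = 1e-6)
  # deep-tail interval stays inside and does not underflow
  y <- rtruncnorm(2000, 0, 1, 8, 8.5)
  expect_true(all(y >= 8 & y <= 8.5))
  # uniform prior family on intersected bounds
  u <- sample_item_slope(c(2, 3), prior_config("uniform"), n = 20000)
  expect_true(all(u >= 2 & u <= 3))
  expect_lt(abs(mean(u) - 2.5), 3 * sqrt(1 / 12) / sqrt(20000))
})

test_that("conjugate variance updates map to the right inverse-gamma", {
  set.seed(61)
  # J = 2, v = tau = 1, values (mu, mu + 2): IG(2, 3); its variance is
  # infinite, so check the median (= 3 / median of Gamma(2, 1))
  dr <- conj_variance_draw(c(0.5, 2.5), mu = 0.5, v = 1, tau = 1, n = 200000)
  expect_equal(median(dr), 3 / qgamma(0.5, 2), tolerance = 0.02)
  # sum of squares 20 with default hypers: IG(10.001, 10.001),
  # mean 10.001/9.001
  a <- sqrt(rep(1, 20))
  dr2 <- conj_variance_draw(a, mu = 0, n = 100000)
  expect_lt(abs(mean(dr2) - 10.001 / 9.001), 3 * sd(dr2) / sqrt(length(dr2)))
  # all values at the prior mean: IG(J/2 + v, tau)
  dr3 <- conj_variance_draw(rep(1.3, 8), mu = 1.3, v = 2, tau = 0.5,
                            n = 200000)
  expect_lt(abs(mean(dr3) - 0.5 / (4 + 2 - 1)), 4 * sd(dr3) / sqrt(2e5))
})
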