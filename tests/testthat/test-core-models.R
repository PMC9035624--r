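test_that("response probability follows the bi-factor logistic form", {
  # zero linear predictor
  expect_equal(irt_prob(d = 0, a_g = 1, a_s = 1, theta_g = 0, theta_s = 0),
               0.5)
  # independent scalar evaluation of the logistic at 1.3
  lp <- 0.5 + 1.2 * 1.0 + 0.8 * (-0.5)
  expect_equal(irt_prob(d = 0.5, a_g = 1.2, a_s = 0.8, theta_g = 1.0,
                        theta_s = -0.5),
               1 / (1 + exp(-lp)), tolerance = 1e-15)
  # logistic symmetry: P(d, theta) + P(-d, -theta) = 1
  set.seed(1)
  for (i in 1:20) {
    d <- rnorm(1); a <- abs(rnorm(2)); th <- rnorm(2)
    expect_equal(irt_prob(d, a[1], a[2], th[1], th[2]) +
                   irt_prob(-d, a[1], a[2], -th[1], -th[2]), 1,
                 tolerance = 1e-12)
  }
  # numerically stable at extreme linear predictors
  expect_equal(irt_prob(d = 700), 1)
  expect_gt(irt_prob(d = -700), 0)
  # strictly increasing in each ability when its loading is positive
  grid <- seq(-4, 4, length.out = 41)
  expect_true(all(diff(irt_prob(d = 0.3, a_g = 0.9, a_s = 0.5,
                                theta_g = grid, theta_s = 0)) > 0))
  expect_true(all(diff(irt_prob(d = 0.3, a_g = 0.9, a_s = 0.5,
                                theta_g = 0, theta_s = grid)) > 0))
})

test_that("expected log time is linear in speed with negative slopes", {
  expect_equal(log_rt_mean(beta = 4, alpha_g = 0, alpha_s = 0,
                           tau_g = 3, tau_s = -2), 4)
  expect_equal(log_rt_mean(beta = 4, alpha_g = 0.5, alpha_s = 0.3,
                           tau_g = 1, tau_s = 0), 3.5)
  # faster persons have shorter expected log times
  grid <- seq(-3, 3, length.out = 13)
  expect_true(all(diff(log_rt_mean(beta = 4, alpha_g = 0.5, alpha_s = 0.2,
                                   tau_g = grid, tau_s = 0)) < 0))
})

test_that("log-time density matches a normal-density oracle", {
  # standard-normal density at 0 (in log): t = e^4, mean 4, sd 1
  expect_equal(log_rt_logdensity(t = exp(4), beta = 4, sigma = 1),
               log(1 / sqrt(2 * pi)), tolerance = 1e-12)
  # brute-force normal pdf oracle on random parameter draws
  set.seed(42)
  for (i in 1:1000) {
    b <- rnorm(1, 4); s <- runif(1, 0.2, 3); ag <- abs(rnorm(1))
    as_ <- abs(rnorm(1)); tg <- rnorm(1); ts <- rnorm(1)
    t_obs <- exp(rnorm(1, b, s))
    mu <- b - (ag * tg + as_ * ts)
    oracle <- -(log(t_obs) - mu)^2 / (2 * s^2) - log(s) - 0.5 * log(2 * pi)
    expect_equal(log_rt_logdensity(t_obs, b, s, ag, as_, tg, ts), oracle,
                 tolerance = 1e-12)
  }
  # the density integrates to 1 over log time (numerical quadrature)
  f <- function(lt) exp(log_rt_logdensity(exp(lt), beta = 3.5, sigma = 0.8,
                                          alpha_g = 0.4, tau_g = 1.2))
  expect_equal(integrate(f, -20, 20, abs.tol = 1e-8)$value, 1,
               tolerance = 1e-4)
  # domain violations
  expect_error(log_rt_logdensity(0, beta = 4, sigma = 1), "positive")
  expect_error(log_rt_logdensity(-1, beta = 4, sigma = 1), "positive")
  expect_error(log_rt_logdensity(1, beta = 4, sigma = 0), "sigma")
})

test_that("pointwise log-likelihood sums scalar cell contributions", {
  sim <- tiny_sim(N = 12, m = 6, seed = 3)
  tr <- sim$truth
  pw <- pointwise_loglik(sim$U, sim$T, tr$items, tr$persons, sim$pattern,
                         tr$spec)
  # cell-by-cell scalar reconstruction
  grp <- sim$pattern$group_of
  for (i in c(1, 5, 12)) {
    for (j in seq_len(6)) {
      p <- irt_prob(tr$items$d[j], tr$items$a_g[j], tr$items$a_s[j],
                    tr$persons$theta_g[i], tr$persons$theta_s[i, grp[j]])
      expect_equal(pw$ra[i, j],
                   ifelse(sim$U[i, j] == 1, log(p), log(1 - p)),
                   tolerance = 1e-10)
      expect_equal(pw$rt[i, j],
                   log_rt_logdensity(sim$T[i, j], tr$items$beta[j],
                                     tr$items$sigma[j], tr$items$alpha_g[j],
                                     tr$items$alpha_s[j], tr$persons$tau_g[i],
                                     tr$persons$tau_s[i, grp[j]]),
                   tolerance = 1e-10)
    }
  }
})

test_that("uninformative items force probability one half", {
  N <- 9; m <- 6
  items <- flat_items(m, a_g = 1e-300, alpha_g = 1e-300)
  items$a_s <- rep(1e-300, m); items$d <- rep(0, m)
  persons <- person_parameters(theta_s = matrix(rnorm(N * 3), N, 3),
                               tau_s = matrix(rnorm(N * 3), N, 3),
                               theta_g = rnorm(N), tau_g = rnorm(N))
  sim <- tiny_sim(N = N, m = m, seed = 5)
  pw <- pointwise_loglik(sim$U, sim$T, items, persons, sim$pattern,
                         model_spec("bfhm", 3))
  expect_equal(sum(pw$ra), N * m * log(0.5), tolerance = 1e-10)
})

test_that("zero general loadings reduce the bi-factor model to CMHM exactly", {
  sim <- tiny_sim(N = 15, m = 6, seed = 11, variant = "cmhm")
  tr <- sim$truth
  # same data/parameters, viewed as a BFHM with a_g = alpha_g = 0
  items_bf <- tr$items
  items_bf$a_g <- rep(0, 6); items_bf$alpha_g <- rep(0, 6)
  persons_bf <- tr$persons
  persons_bf$theta_g <- rnorm(15); persons_bf$tau_g <- rnorm(15)
  pw_bf <- pointwise_loglik(sim$U, sim$T, items_bf, persons_bf, sim$pattern,
                            model_spec("bfhm", 3))
  pw_cm <- pointwise_loglik(sim$U, sim$T, tr$items, tr$persons, sim$pattern,
                            model_spec("cmhm", 3))
  expect_identical(pw_bf$ra, pw_cm$ra)
  expect_identical(pw_bf$rt, pw_cm$rt)
})

test_that("single-dimension reductions chain down to the unidimensional model", {
  # CMHM with K = 1 equals PMHM with K = 1 equals UNIDIM, as likelihoods
  sim <- tiny_sim(N = 10, m = 6, K = 1, seed = 13, variant = "unidim")
  tr <- sim$truth
  for (v in c("cmhm", "pmhm", "unidim")) {
    pw <- pointwise_loglik(sim$U, sim$T, tr$items, tr$persons, sim$pattern,
                           model_spec(v, 1))
    if (v == "cmhm") ref <- pw
    expect_identical(pw$ra, ref$ra)
    expect_identical(pw$rt, ref$rt)
  }
})

test_that("pointwise log-likelihood is invariant to co-permuted item order", {
  sim <- tiny_sim(N = 10, m = 6, seed = 17)
  tr <- sim$truth
  perm <- c(4, 1, 6, 2, 5, 3)
  items_p <- tr$items
  for (f in c("a_g", "a_s", "d", "alpha_g", "alpha_s", "beta", "sigma"))
    items_p[[f]] <- tr$items[[f]][perm]
  pat_p <- loading_pattern(sim$pattern$group_of[perm], 3)
  pw <- pointwise_loglik(sim$U, sim$T, tr$items, tr$persons, sim$pattern,
                         tr$spec)
  pw_p <- pointwise_loglik(sim$U[, perm], sim$T[, perm], items_p, tr$persons,
                           pat_p, tr$spec)
  expect_equal(unname(pw_p$ra), unname(pw$ra[, perm]))
  expect_equal(unname(pw_p$rt), unname(pw$rt[, perm]))
})

test_that("missing cells contribute zero and are counted", {
  sim <- tiny_sim(N = 8, m = 6, seed = 19)
  U <- sim$U; U[1, 2] <- NA
  T_mat <- sim$T; T_mat[3, 4] <- NA; T_mat[5, 1] <- NA
  tr <- sim$truth
  pw <- pointwise_loglik(U, T_mat, tr$items, tr$persons, sim$pattern,
                         tr$spec)
  expect_equal(pw$n_missing_ra, 1L)
  expect_equal(pw$n_missing_rt, 2L)
  expect_equal(pw$ra[1, 2], 0)
  expect_equal(pw$rt[3, 4], 0)
  # invalid values are rejected with informative errors
  U_bad <- sim$U; U_bad[2, 2] <- 2
  expect_error(pointwise_loglik(U_bad, sim$T, tr$items, tr$persons,
                                sim$pattern, tr$spec), "0, 1 or NA")
  T_bad <- sim$T; T_bad[2, 2] <- -1
  expect_error(pointwise_loglik(sim$U, T_bad, tr$items, tr$persons,
                                sim$pattern, tr$spec), "positive")
})
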