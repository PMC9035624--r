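test_that("WAIC matches hand computation on degenerate and tiny cases", {
  # constant log-likelihood across draws: lppd = c, p_waic = 0, waic = -2c
  c0 <- log(0.37)
  w <- waic(matrix(c0, 50, 1))
  expect_equal(w$lppd, c0)
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * c0)
  # two draws, one observation: brute-force scalar arithmetic
  ll <- matrix(log(c(0.5, 0.25)), 2, 1)
  w2 <- waic(ll)
  expect_equal(w2$lppd, log((0.5 + 0.25) / 2), tolerance = 1e-14)
  expect_equal(w2$p_waic, var(log(c(0.5, 0.25))), tolerance = 1e-14)
  expect_equal(w2$waic, -2 * (w2$lppd - w2$p_waic), tolerance = 1e-14)
  # additivity over observation blocks
  set.seed(83)
  llm <- matrix(rnorm(200 * 30, -1, 0.5), 200, 30)
  expect_equal(waic(llm)$waic,
               waic(llm[, 1:12])$waic + waic(llm[, 13:30])$waic,
               tolerance = 1e-10)
  expect_error(waic(llm[1, , drop = FALSE]), "2 posterior draws")
  expect_error(waic(matrix(c(1, NA), 2, 1)), "finite")
})

test_that("PSIS-LOO equals WAIC when importance weights are constant", {
  ll <- matrix(rep(log(runif(25, 0.2, 0.9)), each = 300), 300, 25)
  l <- psis_loo(ll)
  w <- waic(ll)
  expect_equal(l$loo, w$waic, tolerance = 1e-10)
  expect_equal(l$p_loo, 0, tolerance = 1e-10)
})

test_that("PSIS-LOO agrees with exact leave-one-out on a conjugate model", {
  # normal mean with known unit variance: y_i ~ N(mu, 1), mu ~ N(0, 1).
  # The exact LOO predictive for y_i is available in closed form.
  set.seed(89)
  n <- 30
  y <- rnorm(n, 0.7, 1)
  post_var <- 1 / (n + 1); post_mean <- sum(y) * post_var
  S <- 8000
  mu_draws <- rnorm(S, post_mean, sqrt(post_var))
  ll <- sapply(y, function(yi) dnorm(yi, mu_draws, 1, log = TRUE))
  exact <- sum(sapply(seq_len(n), function(i) {
    v_i <- 1 / (n - 1 + 1); m_i <- sum(y[-i]) * v_i
    dnorm(y[i], m_i, sqrt(v_i + 1), log = TRUE)
  }))
  l <- psis_loo(ll)
  expect_lt(max(l$pareto_k), 0.7)
  expect_equal(l$elpd_loo, exact, tolerance = 0.002)  # relative scale
})

test_that("WAIC and PSIS-LOO reproduce the reference implementation", {
  # cross-validation against arviz on a shared random pointwise matrix
  set.seed(97)
  S <- 500; n <- 40
  ll <- matrix(rnorm(S * n, -1.2, 0.7), S, n)
  dir <- withr::local_tempdir()
  write.table(ll, file.path(dir, "ll.csv"), sep = ",", row.names = FALSE,
              col.names = FALSE)
  py <- c(
    'import numpy as np, json, warnings',
    'warnings.filterwarnings("ignore")',
    'import os; os.chdir(os.path.dirname(os.path.abspath(__file__)))',
    'll = np.loadtxt("ll.csv", delimiter=",")',
    'from arviz.stats.stats import _psislw',
    'S = ll.shape[0]',
    'lppd_i = np.log(np.mean(np.exp(ll), axis=0))',
    'p_i = np.var(ll, axis=0, ddof=1)',
    'waic = -2 * (lppd_i.sum() - p_i.sum())',
    'cutoff_ind = -int(np.ceil(min(S / 5.0, 3 * np.sqrt(S)))) - 1',
    'cutoffmin = np.log(np.finfo(float).tiny)',
    'elpd = np.empty(ll.shape[1]); ks = np.empty(ll.shape[1])',
    'for i in range(ll.shape[1]):',
    '    lw, k = _psislw(-ll[:, i].copy(), cutoff_ind, cutoffmin, True)',
    '    elpd[i] = np.log(np.sum(np.exp(lw + ll[:, i])))',
    '    ks[i] = k',
    'json.dump({"waic": waic, "loo": float(-2 * elpd.sum()),',
    '           "k": ks.tolist()}, open("ref.json", "w"))')
  writeLines(py, file.path(dir, "ref.py"))
  status <- system2("python", file.path(dir, "ref.py"))
  skip_if(status != 0, "python/arviz reference unavailable")
  ref <- jsonlite::read_json(file.path(dir, "ref.json"),
                             simplifyVector = TRUE)
  w <- waic(ll); l <- psis_loo(ll)
  expect_equal(w$waic, ref$waic, tolerance = 1e-6)
  expect_equal(l$loo, ref$loo, tolerance = 1e-6)
  expect_equal(l$pareto_k, ref$k, tolerance = 1e-6)
})

test_that("component indices are additive and ranking is order-invariant", {
  sim <- tiny_sim(N = 25, m = 6, seed = 101)
  f1 <- fit_bfhm(sim$U, sim$T, sim$pattern, model = "bfhm",
                 sampler = quick_sampler(200), seed = 1, quiet = TRUE)
  f2 <- fit_bfhm(sim$U, sim$T, sim$pattern, model = "cmhm",
                 sampler = quick_sampler(200), seed = 1, quiet = TRUE)
  # short chains make some Pareto tails heavy by design; the warning is
  # exercised elsewhere
  fi <- suppressWarnings(fit_indices(f1))
  expect_equal(fi$waic[fi$component == "total"],
               fi$waic[fi$component == "RA"] +
                 fi$waic[fi$component == "RT"], tolerance = 1e-10)
  expect_equal(fi$loo[fi$component == "total"],
               fi$loo[fi$component == "RA"] +
                 fi$loo[fi$component == "RT"], tolerance = 1e-10)
  expect_true(all(fi$p_waic >= 0))

  # single model in, single row out
  tab1 <- compare_fits(list(f1))
  expect_equal(nrow(tab1), 1L)
  # permutation invariance and determinism given fixed draws
  t12 <- compare_fits(list(f1, f2))
  t21 <- compare_fits(list(f2, f1))
  expect_equal(t12, t21, tolerance = 1e-10)
  tdup <- compare_fits(list(f1, f1))
  expect_equal(tdup$waic_total[1], tdup$waic_total[2], tolerance = 1e-10)
  # incompatible data dimensions are rejected
  sim2 <- tiny_sim(N = 10, m = 6, seed = 103)
  f3 <- fit_bfhm(sim2$U, sim2$T, sim2$pattern,
                 sampler = quick_sampler(100), seed = 1, quiet = TRUE)
  expect_error(compare_fits(list(f1, f3)), "incomparable")
})
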