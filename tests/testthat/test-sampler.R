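# Validation of the posterior kernel and the NUTS engine

test_that("analytic gradients match numerical differentiation", {
  skip_if_not_installed("numDeriv")
  for (variant in c("bfhm", "cmhm", "pmhm", "unidim")) {
    K <- if (variant == "unidim") 1 else 3
    sim <- tiny_sim(N = 7, m = 6, K = K, seed = 23, variant = variant)
    sim$U[1, 2] <- NA; sim$T[2, 3] <- NA  # exercise missing-cell handling
    spec <- model_spec(variant, K)
    grp <- if (variant == "unidim") rep(1L, 6) else sim$pattern$group_of
    Ui <- sim$U; Ui[is.na(Ui)] <- -1L; storage.mode(Ui) <- "integer"
    Lt <- log(sim$T); Lt[is.na(Lt)] <- NaN
    D <- cpp_dim(sim, variant)
    set.seed(29)
    x <- rnorm(D, 0, 0.4)
    g <- bfhm:::.bf_grad(x, Ui, Lt, grp - 1L, K, spec$has_general,
                         spec$rt_unidim, prior_vec(), 1, 1)
    gn <- numDeriv::grad(function(z) cpp_logpost(z, sim, variant), x)
    expect_lt(max(abs(g - gn) / (1 + abs(gn))), 1e-6)
  }
})

test_that("the sampler's likelihood equals the pointwise module exactly", {
  sim <- tiny_sim(N = 15, m = 6, seed = 5)
  tr <- sim$truth
  items <- tr$items; pers <- tr$persons; st <- tr$structure
  m <- 6; N <- 15; K <- 3
  # map the generating parameters onto the unconstrained vector
  mu_d <- 0; mu_b <- 4; sd_d <- 1; sd_b <- 0.5; rho_db <- -0.25 / 0.5
  zd <- (items$d - mu_d) / sd_d
  zb <- ((items$beta - mu_b) / sd_b - rho_db * zd) / sqrt(1 - rho_db^2)
  rho_g <- st$rho_general; rho_s <- st$rho_specific
  zg <- (pers$tau_g - rho_g * pers$theta_g) / sqrt(1 - rho_g^2)
  zs <- sapply(1:K, function(k) {
    (pers$tau_s[, k] - rho_s[k] * pers$theta_s[, k]) / sqrt(1 - rho_s[k]^2)
  })
  x <- c(log(items$a_s), log(items$alpha_s), log(1 / items$sigma), zd, zb,
         log(items$a_g), log(items$alpha_g),
         mu_d, mu_b, log(sd_d), log(sd_b), atanh(rho_db),
         atanh(rho_g), atanh(rho_s), as.vector(pers$theta_s), as.vector(zs),
         pers$theta_g, zg)
  ll_cpp <- cpp_logpost(x, sim, "bfhm", lik_weight = 1, prior_weight = 0)
  pw <- pointwise_loglik(sim$U, sim$T, items, pers, sim$pattern, tr$spec)
  expect_equal(ll_cpp, sum(pw$ra) + sum(pw$rt), tolerance = 1e-12)

  # and the reporting transform restores the constrained parameters the
  # names promise
  con <- bfhm:::.bf_transform(matrix(x, 1), N, m, K, TRUE, FALSE)
  nm <- bfhm:::param_names(N, m, K, TRUE, FALSE)
  con <- stats::setNames(as.vector(con), nm)
  expect_equal(unname(con[paste0("a_s[", 1:m, "]")]), items$a_s)
  expect_equal(unname(con[paste0("beta[", 1:m, "]")]), items$beta)
  expect_equal(unname(con[paste0("sigma[", 1:m, "]")]), items$sigma)
  expect_equal(unname(con["rho_g"]), rho_g)
  expect_equal(unname(con[paste0("theta_s[", 1:N, ",2]")]),
               pers$theta_s[, 2])
  expect_equal(unname(con[paste0("tau_g[", 1:N, "]")]), pers$tau_g)
})

test_that("prior-only sampling reproduces the prior moments", {
  sim <- tiny_sim(N = 20, m = 6, seed = 37)
  fit <- fit_bfhm(sim$U, sim$T, sim$pattern, model = "bfhm",
                  sampler = quick_sampler(600), seed = 2, prior_only = TRUE,
                  quiet = TRUE)
  d <- dim(fit$draws)
  flat <- matrix(fit$draws, d[1] * d[2], d[3])
  colnames(flat) <- dimnames(fit$draws)[[3]]
  hn_mean <- sqrt(2 / pi)
  # half-normal(0,1) loadings
  expect_lt(abs(mean(flat[, paste0("a_s[", 1:6, "]")]) - hn_mean), 0.1)
  expect_lt(abs(mean(flat[, paste0("alpha_g[", 1:6, "]")]) - hn_mean), 0.1)
  expect_lt(abs(mean(1 / flat[, paste0("sigma[", 1:6, "]")]) - hn_mean),
            0.1)
  # hyper-priors on the item-side means
  expect_lt(abs(mean(flat[, "mu_beta"]) - 4), 0.15)
  expect_lt(abs(sd(flat[, "mu_beta"]) - 0.5), 0.12)
  expect_lt(abs(mean(flat[, "mu_d"])), 0.15)
  # uniform correlation prior: mean 0, variance 1/3
  expect_lt(abs(mean(flat[, "rho_g"])), 0.15)
  expect_lt(abs(var(flat[, "rho_g"]) - 1 / 3), 0.12)
})

test_that("every retained draw satisfies the positivity identification", {
  sim <- tiny_sim(N = 30, m = 6, seed = 41)
  fit <- fit_bfhm(sim$U, sim$T, sim$pattern, model = "bfhm",
                  sampler = quick_sampler(300), seed = 3, quiet = TRUE)
  d <- dim(fit$draws)
  flat <- matrix(fit$draws, d[1] * d[2], d[3])
  colnames(flat) <- dimnames(fit$draws)[[3]]
  pos <- c(paste0("a_g[", 1:6, "]"), paste0("a_s[", 1:6, "]"),
           paste0("alpha_g[", 1:6, "]"), paste0("alpha_s[", 1:6, "]"),
           paste0("sigma[", 1:6, "]"), "sigma_d", "sigma_beta")
  expect_true(all(flat[, pos] > 0))
  # correlations stay inside (-1, 1)
  expect_true(all(abs(flat[, c("rho_g", paste0("rho_s[", 1:3, "]"),
                               "rho_d_beta")]) < 1))
})

test_that("chains are reproducible from the seed", {
  sim <- tiny_sim(N = 15, m = 6, seed = 43)
  f1 <- fit_bfhm(sim$U, sim$T, sim$pattern, sampler = quick_sampler(120),
                 seed = 9, quiet = TRUE)
  f2 <- fit_bfhm(sim$U, sim$T, sim$pattern, sampler = quick_sampler(120),
                 seed = 9, quiet = TRUE)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_bfhm(sim$U, sim$T, sim$pattern, sampler = quick_sampler(120),
                 seed = 10, quiet = TRUE)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior means agree with an independent Gibbs sampler", {
  # same unidimensional joint model coded in JAGS: two entirely different
  # MCMC engines must land on the same posterior
  skip_if_not_installed("rjags")
  sim <- tiny_sim(N = 120, m = 8, K = 1, seed = 31, variant = "unidim")
  fit <- fit_bfhm(sim$U, sim$T, sim$pattern, model = "unidim",
                  sampler = quick_sampler(800), seed = 41, quiet = TRUE)
  jm <- "
  model {
    for (i in 1:N) {
      theta[i] ~ dnorm(0, 1)
      tau[i] ~ dnorm(rho * theta[i], 1 / (1 - rho^2))
      for (j in 1:m) {
        logit(p[i,j]) <- d[j] + a[j] * theta[i]
        U[i,j] ~ dbern(p[i,j])
        lt[i,j] ~ dnorm(beta[j] - alpha[j] * tau[i], isig[j]^2)
      }
    }
    for (j in 1:m) {
      a[j] ~ dnorm(0, 1) T(0,)
      alpha[j] ~ dnorm(0, 1) T(0,)
      isig[j] ~ dnorm(0, 1) T(0,)
      d[j] ~ dnorm(mu_d, 1 / sd_d^2)
      beta[j] ~ dnorm(mu_b + rho_db * (sd_b / sd_d) * (d[j] - mu_d),
                      1 / (sd_b^2 * (1 - rho_db^2)))
    }
    rho ~ dunif(-1, 1)
    rho_db ~ dunif(-1, 1)
    mu_d ~ dnorm(0, 1 / 0.25)
    mu_b ~ dnorm(4, 1 / 0.25)
    sd_d ~ dnorm(0, 1) T(0,)
    sd_b ~ dnorm(0, 1) T(0,)
  }"
  jags <- rjags::jags.model(
    textConnection(jm),
    data = list(U = sim$U, lt = log(sim$T), N = 120, m = 8),
    n.chains = 2, n.adapt = 500, quiet = TRUE,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 7))
  update(jags, 1000, progress.bar = "none")
  samp <- rjags::coda.samples(jags, c("a", "alpha", "beta", "d", "rho"),
                              2500, progress.bar = "none")
  jm_mean <- colMeans(as.matrix(samp))
  nuts <- eap(fit)
  expect_lt(max(abs(jm_mean[paste0("beta[", 1:8, "]")] -
                      nuts[paste0("beta[", 1:8, "]")])), 0.06)
  expect_lt(max(abs(jm_mean[paste0("d[", 1:8, "]")] -
                      nuts[paste0("d[", 1:8, "]")])), 0.08)
  expect_lt(max(abs(jm_mean[paste0("a[", 1:8, "]")] -
                      nuts[paste0("a_s[", 1:8, "]")])), 0.15)
  expect_lt(max(abs(jm_mean[paste0("alpha[", 1:8, "]")] -
                      nuts[paste0("alpha_s[", 1:8, "]")])), 0.15)
  expect_lt(abs(jm_mean["rho"] - nuts["rho_s[1]"]), 0.08)
})
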