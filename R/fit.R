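#' Prior configuration
#'
#' Priors follow the hierarchical model's standard weakly-informative setup:
#' half-normal(0, 1) on all discriminations/slopes and on the time
#' discrimination `1/sigma`; LKJ(eta) on every 2x2 person correlation block
#' and on the `(d, beta)` correlation (for a 2x2 block, LKJ(eta) is the
#' density proportional to `(1 - rho^2)^(eta - 1)`; eta = 1 is uniform);
#' `mu_d ~ N(0, 0.5)`, `mu_beta ~ N(4, 0.5)` (second argument a standard
#' deviation) and half-normal(0, 1) on `sigma_d`, `sigma_beta`.
#'
#' @param eta LKJ shape for all correlation blocks (> 0, default 1).
#' @param mu_d_mean,mu_d_sd,mu_beta_mean,mu_beta_sd hyperprior moments for
#'   the item-side means.
#' @return an object of class `prior_config`.
#' @export
prior_config <- function(eta = 1, mu_d_mean = 0, mu_d_sd = 0.5,
                         mu_beta_mean = 4, mu_beta_sd = 0.5) {
  if (eta <= 0 || mu_d_sd <= 0 || mu_beta_sd <= 0)
    stop("eta and all prior scales must be positive")
  structure(list(eta = eta, mu_d_mean = mu_d_mean, mu_d_sd = mu_d_sd,
                 mu_beta_mean = mu_beta_mean, mu_beta_sd = mu_beta_sd),
            class = "prior_config")
}

#' Sampler configuration
#'
#' Defaults mirror the estimation protocol the model family is normally run
#' with: two chains of 40,000 iterations each, the first half used for
#' warmup/adaptation, thinning of two, so 10,000 retained draws per chain
#' ("the final 20,000 iterations" across both chains). NUTS typically needs
#' far fewer iterations; short-chain settings are perfectly usable and are
#' what the package's own studies run.
#'
#' @param chains number of chains (>= 2 for PSRF).
#' @param iterations iterations per chain, including warmup.
#' @param warmup warmup iterations per chain (default `iterations / 2`).
#' @param thin thinning interval applied after warmup.
#' @param max_treedepth NUTS maximum tree depth.
#' @param adapt_delta dual-averaging target acceptance statistic.
#' @param psrf_threshold convergence declared when all split-chain PSRF fall
#'   below this value (default 1.1).
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(chains = 2L, iterations = 40000L, warmup = NULL,
                           thin = 2L, max_treedepth = 10L,
                           adapt_delta = 0.8, psrf_threshold = 1.1) {
  if (is.null(warmup)) warmup <- iterations %/% 2L
  chains <- as.integer(chains); iterations <- as.integer(iterations)
  warmup <- as.integer(warmup); thin <- as.integer(thin)
  if (chains < 1L) stop("at least one chain is required")
  if (warmup < 20L || warmup >= iterations)
    stop("warmup must be at least 20 and smaller than iterations")
  if (thin < 1L) stop("thin must be >= 1")
  if (adapt_delta <= 0 || adapt_delta >= 1)
    stop("adapt_delta must be in (0, 1)")
  structure(list(chains = chains, iterations = iterations, warmup = warmup,
                 thin = thin, max_treedepth = as.integer(max_treedepth),
                 adapt_delta = adapt_delta, psrf_threshold = psrf_threshold),
            class = "sampler_config")
}

prior_vector <- function(priors) {
  c(mu_d_mean = priors$mu_d_mean, mu_d_sd = priors$mu_d_sd,
    mu_b_mean = priors$mu_beta_mean, mu_b_sd = priors$mu_beta_sd,
    eta = priors$eta)
}

# constrained parameter names matching the C++ transform column order
param_names <- function(N, m, K, has_general, rt_unidim) {
  idx <- function(stub, n) paste0(stub, "[", seq_len(n), "]")
  pidx <- function(stub) {
    as.vector(outer(seq_len(N), seq_len(K),
                    function(i, k) paste0(stub, "[", i, ",", k, "]")))
  }
  c(idx("a_s", m), idx("alpha_s", m), idx("sigma", m), idx("d", m),
    idx("beta", m),
    if (has_general) c(idx("a_g", m), idx("alpha_g", m)),
    "mu_d", "mu_beta", "sigma_d", "sigma_beta", "rho_d_beta",
    if (has_general) "rho_g",
    idx("rho_s", K),
    pidx("theta_s"),
    if (rt_unidim) idx("tau", N) else pidx("tau_s"),
    if (has_general) c(idx("theta_g", N), idx("tau_g", N)))
}

# random over-dispersed but moderate initial values on the unconstrained
# scale (loadings in (0.2, 1.5), traits in (-1, 1))
random_init <- function(N, m, K, has_general, rt_unidim) {
  la <- function(n) log(runif(n, 0.2, 1.5))
  x <- c(la(m), la(m), la(m), rnorm(m, 0, 0.5), rnorm(m, 0, 0.5))
  if (has_general) x <- c(x, la(m), la(m))
  x <- c(x, rnorm(1, 0, 0.3), rnorm(1, 4, 0.3), log(runif(1, 0.5, 1.2)),
         log(runif(1, 0.3, 0.7)), runif(1, -0.3, 0.3))
  if (has_general) x <- c(x, runif(1, -0.3, 0.3))
  x <- c(x, runif(K, -0.3, 0.3))
  x <- c(x, runif(N * K, -1, 1))
  x <- c(x, runif(if (rt_unidim) N else N * K, -1, 1))
  if (has_general) x <- c(x, runif(N, -1, 1), runif(N, -1, 1))
  x
}

validate_data <- function(U, T_mat, pattern) {
  U <- as.matrix(U); T_mat <- as.matrix(T_mat)
  if (!all(dim(U) == dim(T_mat)))
    stop("response and time matrices must have identical dimensions")
  if (ncol(U) != pattern$n_items)
    stop("number of items disagrees with the loading pattern")
  obs_u <- U[!is.na(U)]
  if (!all(obs_u %in% c(0, 1)))
    stop("responses must be 0, 1 or NA")
  obs_t <- T_mat[!is.na(T_mat)]
  if (any(!is.finite(obs_t)) || any(obs_t <= 0))
    stop("response times must be strictly positive")
  list(U = U, T = T_mat)
}

#' Fit a joint hierarchical model by NUTS
#'
#' Estimates any of the four model variants from a binary response matrix
#' and a positive response-time matrix using the package's No-U-Turn
#' Hamiltonian Monte Carlo sampler. Person factors are identified by fixing
#' their means at 0 and variances at 1 (so person covariances are
#' correlations), and all discriminations/slopes are constrained positive,
#' which pins the factor orientation in every draw. Point estimates are
#' posterior means (EAP). Missing cells (NA) contribute nothing to the
#' likelihood.
#'
#' @param U persons x items 0/1 response matrix (NA allowed).
#' @param T_mat persons x items response-time matrix in seconds (NA
#'   allowed).
#' @param pattern a [loading_pattern()].
#' @param model variant name, see [model_spec()].
#' @param priors a [prior_config()].
#' @param sampler a [sampler_config()].
#' @param seed integer seed controlling initialization and sampling.
#' @param prior_only if `TRUE`, sample from the prior (likelihood switched
#'   off); used for prior-predictive checks.
#' @param quiet suppress per-chain progress messages.
#' @return an object of class `bfhm_fit`: `draws` (iterations x chains x
#'   parameters array on the reporting scale), `summary` (mean, sd,
#'   quantiles, PSRF per parameter), `pointwise` (draw x cell
#'   log-likelihood matrices `ra` and `rt`, pooled across chains),
#'   `diagnostics`, `converged`, and metadata.
#' @export
fit_bfhm <- function(U, T_mat, pattern, model = "bfhm",
                     priors = prior_config(), sampler = sampler_config(),
                     seed = 1L, prior_only = FALSE, quiet = FALSE) {
  stopifnot(inherits(pattern, "loading_pattern"),
            inherits(priors, "prior_config"),
            inherits(sampler, "sampler_config"))
  dat <- validate_data(U, T_mat, pattern)
  spec <- model_spec(model, pattern$n_specific)
  N <- nrow(dat$U); m <- ncol(dat$U)
  K <- spec$n_specific
  grp <- if (spec$variant == "unidim") rep(1L, m) else pattern$group_of

  U_int <- dat$U; U_int[is.na(U_int)] <- -1L
  storage.mode(U_int) <- "integer"
  Lt <- suppressWarnings(log(dat$T))  # NA stays NA
  Lt[is.na(Lt)] <- NaN
  prv <- prior_vector(priors)
  n_keep <- (sampler$iterations - sampler$warmup) %/% sampler$thin
  if (n_keep < 4L) stop("sampler settings retain fewer than 4 draws")

  t0 <- Sys.time()
  chains <- vector("list", sampler$chains)
  diagnostics <- list()
  for (ch in seq_len(sampler$chains)) {
    set.seed(sub_seed(seed, 100L + ch))
    init <- random_init(N, m, K, spec$has_general, spec$rt_unidim)
    res <- .bf_nuts(init, U_int, Lt, grp - 1L, K, spec$has_general,
                    spec$rt_unidim, prv, sampler$warmup,
                    sampler$iterations - sampler$warmup, sampler$thin,
                    sampler$max_treedepth, sampler$adapt_delta,
                    if (prior_only) 0 else 1)
    chains[[ch]] <- res
    if (!quiet)
      message(sprintf(
        "chain %d: %d draws kept, step size %.3g, %d divergence(s)",
        ch, nrow(res$draws), res$step_size, res$n_divergent))
  }

  nm <- param_names(N, m, K, spec$has_general, spec$rt_unidim)
  P <- length(nm)
  draws <- array(NA_real_, c(n_keep, sampler$chains, P),
                 dimnames = list(NULL, paste0("chain", seq_len(sampler$chains)),
                                 nm))
  for (ch in seq_len(sampler$chains)) {
    con <- .bf_transform(chains[[ch]]$draws, N, m, K, spec$has_general,
                         spec$rt_unidim)
    draws[, ch, ] <- con
  }

  flat <- matrix(aperm(draws, c(1, 2, 3)), n_keep * sampler$chains, P)
  colnames(flat) <- nm
  psrf <- apply(draws, 3, function(x) compute_psrf(as.matrix(x)))
  summary_df <- data.frame(
    parameter = nm,
    mean = colMeans(flat),
    sd = apply(flat, 2, sd),
    q2.5 = apply(flat, 2, quantile, 0.025, names = FALSE),
    q97.5 = apply(flat, 2, quantile, 0.975, names = FALSE),
    psrf = psrf,
    row.names = NULL)

  unc <- do.call(rbind, lapply(chains, `[[`, "draws"))
  pw <- .bf_pointwise(unc, U_int, Lt, grp - 1L, K, spec$has_general,
                      spec$rt_unidim)
  cells <- as.vector(outer(rownames(dat$U), colnames(dat$U), paste,
                           sep = ":"))
  colnames(pw$ra) <- colnames(pw$rt) <- cells

  diag_df <- data.frame(
    chain = rep(seq_len(sampler$chains), each = n_keep),
    accept_stat = unlist(lapply(chains, `[[`, "accept_stat")),
    treedepth = unlist(lapply(chains, `[[`, "treedepth")),
    divergent = unlist(lapply(chains, `[[`, "divergent")),
    energy = unlist(lapply(chains, `[[`, "energy")))

  fit <- structure(
    list(draws = draws, summary = summary_df, pointwise = pw,
         diagnostics = diag_df,
         step_size = vapply(chains, `[[`, numeric(1), "step_size"),
         n_divergent = sum(vapply(chains, `[[`, integer(1), "n_divergent")),
         spec = spec, pattern = pattern, priors = priors, sampler = sampler,
         seed = seed, prior_only = prior_only,
         n_persons = N, n_items = m,
         n_missing = sum(is.na(dat$U)) + sum(is.na(dat$T)),
         converged = all(psrf < sampler$psrf_threshold, na.rm = TRUE),
         max_psrf = max(psrf, na.rm = TRUE),
         elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "bfhm_fit")
  fit
}

#' @export
print.bfhm_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d persons, %d items, %d chain(s) x %d draws\n",
              toupper(x$spec$variant), x$n_persons, x$n_items,
              dim(x$draws)[2], dim(x$draws)[1]))
  cat(sprintf("max PSRF %.3f (%s), %d divergence(s), %.1f s\n",
              x$max_psrf,
              if (x$converged) "converged" else "NOT converged",
              x$n_divergent, x$elapsed))
  invisible(x)
}

#' Posterior-mean (EAP) point estimates
#'
#' @param fit a `bfhm_fit`.
#' @return named numeric vector of posterior means on the reporting scale.
#' @export
eap <- function(fit) {
  stopifnot(inherits(fit, "bfhm_fit"))
  stats::setNames(fit$summary$mean, fit$summary$parameter)
}

#' Extract a parameter family from a fit or its EAP vector
#'
#' @param fit a `bfhm_fit`.
#' @param family a family stub such as `"a_s"`, `"beta"`, `"theta_s"`.
#' @return numeric vector (items/persons ordered) of EAP estimates; for
#'   person x dimension families, a matrix.
#' @export
eap_family <- function(fit, family) {
  est <- eap(fit)
  sel <- grepl(paste0("^", family, "\\["), names(est))
  if (!any(sel)) stop(sprintf("no parameters in family '%s'", family))
  v <- est[sel]
  if (grepl(",", names(v)[1], fixed = TRUE)) {
    idx <- do.call(rbind, strsplit(sub("^.*\\[", "", sub("\\]$", "",
                                                         names(v))), ","))
    matrix(v, nrow = max(as.integer(idx[, 1])),
           ncol = max(as.integer(idx[, 2])))
  } else v
}

#' Split-chain potential scale reduction factor
#'
#' Splits each chain in half and computes the classical between/within
#' variance ratio diagnostic on the split halves; splitting detects
#' within-chain drift that the unsplit statistic misses. Chains that are
#' all constant return 1 by convention, with a warning.
#'
#' @param x draws matrix, iterations x chains (>= 2 chains after
#'   splitting, i.e. at least 4 draws in a single chain).
#' @return the PSRF value (>= 1 in expectation; < 1.1 conventionally
#'   declares convergence).
#' @export
compute_psrf <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (ncol(x) < 2L && n < 4L)
    stop("PSRF needs at least 2 chains (or one chain of length >= 4)")
  if (n < 4L) stop("PSRF needs at least 4 draws per chain")
  half <- n %/% 2L
  split_x <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[(n - half + 1):n, j])
  }))
  m_chains <- ncol(split_x)
  n_s <- nrow(split_x)
  means <- colMeans(split_x)
  vars <- apply(split_x, 2, var)
  W <- mean(vars)
  B <- n_s * var(means)
  if (!is.finite(W) || W == 0) {
    if (all(abs(split_x - split_x[1]) < .Machine$double.eps * 100)) {
      warning("constant chains: PSRF defined as 1 by convention")
      return(1)
    }
    return(Inf)
  }
  var_plus <- (n_s - 1) / n_s * W + B / n_s
  sqrt(var_plus / W)
}

#' Population-structure estimates with credible intervals
#'
#' Posterior means and central 95% credible intervals for the level-2
#' quantities: the ability-speed correlations (general and per specific
#' dimension; for identified person factors the covariance equals the
#' correlation), and the item-side moments `mu_d`, `mu_beta`, `sigma_d^2`,
#' `sigma_beta^2`, the covariance `sigma_d_beta` and the correlation
#' `rho_d_beta`.
#'
#' @param fit a converged `bfhm_fit`.
#' @return data.frame with columns `parameter`, `mean`, `q2.5`, `q97.5`.
#' @export
extract_structure <- function(fit) {
  stopifnot(inherits(fit, "bfhm_fit"))
  d <- dim(fit$draws)
  flat <- matrix(fit$draws, d[1] * d[2], d[3])
  colnames(flat) <- dimnames(fit$draws)[[3]]
  col <- function(nm) flat[, nm]
  out <- list()
  add <- function(nm, v) {
    out[[length(out) + 1]] <<- data.frame(
      parameter = nm, mean = mean(v),
      q2.5 = quantile(v, 0.025, names = FALSE),
      q97.5 = quantile(v, 0.975, names = FALSE))
  }
  if (fit$spec$has_general) add("rho_theta_g_tau_g", col("rho_g"))
  for (k in seq_len(fit$spec$n_specific)) {
    nm <- sprintf("rho_s[%d]", k)
    if (nm %in% colnames(flat))
      add(sprintf("rho_theta_s_tau_s[%d]", k), col(nm))
  }
  add("mu_d", col("mu_d"))
  add("mu_beta", col("mu_beta"))
  add("sigma_d2", col("sigma_d")^2)
  add("sigma_beta2", col("sigma_beta")^2)
  add("sigma_d_beta", col("rho_d_beta") * col("sigma_d") * col("sigma_beta"))
  add("rho_d_beta", col("rho_d_beta"))
  do.call(rbind, out)
}
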