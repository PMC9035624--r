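#' Simulation configuration
#'
#' Describes one simulated between-item multidimensional test. Defaults
#' reproduce the generating process of the model's simulation design:
#' \itemize{
#'   \item all discriminations/slopes `a_g`, `a_s`, `alpha_g`, `alpha_s` and
#'     the time discrimination `1/sigma` drawn from the standard normal
#'     truncated to (0, Inf) (the half-normal);
#'   \item `(d, beta)` jointly bivariate normal with means (0, 4), variances
#'     (1, 0.25) and covariance -0.25;
#'   \item for the general and each specific factor, an ability-speed
#'     correlation drawn from Uniform(-1, 1), then standard-bivariate-normal
#'     (ability, speed) pairs with that correlation; factors mutually
#'     independent.
#' }
#'
#' @param N number of examinees.
#' @param m test length.
#' @param n_specific number of specific dimensions (default 3).
#' @param group_sizes items per specific dimension; defaults to an equal
#'   split (requires `m` divisible by `n_specific`).
#' @param seed integer master seed. Item draws, person draws, response noise
#'   and time noise consume separate substreams derived from it, so e.g.
#'   changing `N` does not perturb the item parameters.
#' @param variant generating model (default `"bfhm"`; reductions drop the
#'   general factor and/or collapse the RT side).
#' @param d_beta_mean,d_beta_cov moments of the `(d, beta)` distribution.
#' @param rho_general,rho_specific optional fixed ability-speed
#'   correlations; `NULL` (default) draws them from Uniform(-1, 1).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(N, m, n_specific = 3L, group_sizes = NULL, seed = 1L,
                       variant = c("bfhm", "cmhm", "pmhm", "unidim"),
                       d_beta_mean = c(0, 4),
                       d_beta_cov = matrix(c(1, -0.25, -0.25, 0.25), 2, 2),
                       rho_general = NULL, rho_specific = NULL) {
  variant <- match.arg(variant)
  N <- as.integer(N); m <- as.integer(m)
  if (variant == "unidim") n_specific <- 1L
  n_specific <- as.integer(n_specific)
  if (N < 1L || m < 1L || n_specific < 1L)
    stop("N, m and n_specific must be positive")
  if (is.null(group_sizes)) {
    if (m %% n_specific != 0L)
      stop("m is not divisible by n_specific; supply `group_sizes`")
    group_sizes <- rep(m %/% n_specific, n_specific)
  }
  group_sizes <- as.integer(group_sizes)
  if (length(group_sizes) != n_specific || any(group_sizes < 1L) ||
      sum(group_sizes) != m)
    stop("`group_sizes` must be positive and sum to m")
  if (any(eigen(d_beta_cov, symmetric = TRUE,
                only.values = TRUE)$values <= 0))
    stop("`d_beta_cov` must be positive definite")
  check_rho <- function(r, len, nm) {
    if (is.null(r)) return(NULL)
    r <- as.numeric(r)
    if (length(r) != len || any(abs(r) >= 1))
      stop(sprintf("`%s` must be %d value(s) in (-1, 1)", nm, len))
    r
  }
  structure(
    list(N = N, m = m, n_specific = n_specific, group_sizes = group_sizes,
         seed = as.integer(seed), variant = variant,
         d_beta_mean = as.numeric(d_beta_mean), d_beta_cov = d_beta_cov,
         rho_general = check_rho(rho_general, 1L, "rho_general"),
         rho_specific = check_rho(rho_specific, n_specific, "rho_specific")),
    class = "sim_config")
}

# deterministic substream seeds (Lehmer-style scramble, < 2^31)
sub_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 48271 + idx * 9973) %% 2147483647)
}

#' Loading pattern implied by a simulation configuration
#' @param config a [sim_config()].
#' @return a [loading_pattern()] with contiguous item blocks.
#' @export
sim_pattern <- function(config) {
  loading_pattern(rep(seq_len(config$n_specific), config$group_sizes),
                  config$n_specific)
}

#' Draw item parameters for a simulated test
#'
#' Loadings and the time discrimination are half-normal (standard normal
#' truncated to the positive axis); `(d, beta)` are jointly bivariate
#' normal. The residual SD is `sigma = 1` / the drawn time discrimination.
#'
#' @param config a [sim_config()].
#' @return an [item_parameters()] object.
#' @export
generate_item_params <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 1L))
  m <- config$m
  half_normal <- function(n) abs(rnorm(n))
  has_g <- config$variant == "bfhm"
  a_g <- if (has_g) half_normal(m)
  a_s <- half_normal(m)
  alpha_g <- if (has_g) half_normal(m)
  alpha_s <- half_normal(m)
  isig <- half_normal(m)
  db <- MASS::mvrnorm(m, mu = config$d_beta_mean, Sigma = config$d_beta_cov)
  item_parameters(a_s = a_s, d = db[, 1], alpha_s = alpha_s, beta = db[, 2],
                  sigma = 1 / isig, a_g = a_g, alpha_g = alpha_g)
}

#' Draw person parameters and the population structure
#'
#' For the general pair and each specific pair, an ability-speed correlation
#' is drawn from Uniform(-1, 1) (unless fixed in the configuration), then
#' `N` standard-bivariate-normal (ability, speed) pairs are drawn with that
#' correlation. Pairs are independent across factors (bi-factor
#' orthogonality). A warning is emitted when a drawn |correlation| exceeds
#' 0.99 (near-singular bivariate covariance).
#'
#' @param config a [sim_config()].
#' @return list with `persons` (a [person_parameters()] object) and
#'   `structure` (drawn correlations and the item-side moments).
#' @export
generate_person_params <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 2L))
  N <- config$N; K <- config$n_specific
  has_g <- config$variant == "bfhm"
  rt_uni <- config$variant %in% c("pmhm", "unidim")

  rho_g <- if (has_g) {
    if (is.null(config$rho_general)) runif(1, -1, 1) else config$rho_general
  }
  n_rho_s <- if (rt_uni) K else K  # one speed pairing per ability dimension
  rho_s <- if (is.null(config$rho_specific)) runif(n_rho_s, -1, 1)
           else config$rho_specific
  if (any(abs(c(rho_g, rho_s)) > 0.99))
    warning("drawn ability-speed correlation beyond 0.99 in absolute value; ",
            "the bivariate covariance is nearly singular")

  pair <- function(rho, n) {
    th <- rnorm(n)
    tau <- rho * th + sqrt(1 - rho^2) * rnorm(n)
    cbind(th, tau)
  }
  theta_g <- tau_g <- NULL
  if (has_g) {
    gp <- pair(rho_g, N)
    theta_g <- gp[, 1]; tau_g <- gp[, 2]
  }
  theta_s <- matrix(0, N, K)
  if (rt_uni) {
    # single latent speed: tau = sum_k rho_k theta_k + residual, scaled so
    # Var(tau) = 1 and Cor(tau, theta_k) = rho_k (requires sum rho_k^2 < 1)
    if (sum(rho_s^2) >= 1) {
      rho_s <- rho_s * sqrt(0.99 / sum(rho_s^2))
      warning("specific correlations rescaled so the single-speed ",
              "structure stays positive definite")
    }
    for (k in seq_len(K)) theta_s[, k] <- rnorm(N)
    tau <- theta_s %*% rho_s + sqrt(1 - sum(rho_s^2)) * rnorm(N)
    tau_s <- matrix(tau, N, 1)
  } else {
    tau_s <- matrix(0, N, K)
    for (k in seq_len(K)) {
      sp <- pair(rho_s[k], N)
      theta_s[, k] <- sp[, 1]; tau_s[, k] <- sp[, 2]
    }
  }
  list(persons = person_parameters(theta_s, tau_s, theta_g, tau_g),
       structure = list(rho_general = rho_g, rho_specific = rho_s,
                        mu_J = config$d_beta_mean,
                        Sigma_J = config$d_beta_cov))
}

#' Simulate a joint response-accuracy / response-time dataset
#'
#' Draws item and person parameters, then responses and times:
#' a response is correct when the model probability is greater than or
#' equal to an independent Uniform(0, 1) draw, and log time is normal with
#' mean [log_rt_mean()] and SD `sigma_j`. All randomness derives from
#' `config$seed`; the same configuration reproduces the dataset exactly.
#'
#' @param config a [sim_config()].
#' @return list of class `bfhm_sim` with `U` (0/1 matrix), `T` (seconds),
#'   `pattern`, and `truth` (items, persons, structure, spec, config).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  items <- generate_item_params(config)
  pp <- generate_person_params(config)
  persons <- pp$persons
  pattern <- sim_pattern(config)
  spec <- model_spec(config$variant, config$n_specific)
  N <- config$N; m <- config$m
  grp <- if (spec$variant == "unidim") rep(1L, m) else pattern$group_of

  a_g <- if (spec$has_general) items$a_g else rep(0, m)
  alpha_g <- if (spec$has_general) items$alpha_g else rep(0, m)
  theta_g <- if (spec$has_general) persons$theta_g else rep(0, N)
  tau_g <- if (spec$has_general) persons$tau_g else rep(0, N)
  P <- irt_prob(d = matrix(items$d, N, m, byrow = TRUE),
                a_g = matrix(a_g, N, m, byrow = TRUE),
                a_s = matrix(items$a_s, N, m, byrow = TRUE),
                theta_g = theta_g,
                theta_s = persons$theta_s[, grp, drop = FALSE])
  Tau <- if (spec$rt_unidim) persons$tau_s[, rep(1L, m), drop = FALSE]
         else persons$tau_s[, grp, drop = FALSE]
  mu <- log_rt_mean(beta = matrix(items$beta, N, m, byrow = TRUE),
                    alpha_g = matrix(alpha_g, N, m, byrow = TRUE),
                    alpha_s = matrix(items$alpha_s, N, m, byrow = TRUE),
                    tau_g = tau_g, tau_s = Tau)

  set.seed(sub_seed(config$seed, 3L))
  U <- matrix(as.integer(P >= runif(N * m)), N, m)
  set.seed(sub_seed(config$seed, 4L))
  lnT <- mu + matrix(rnorm(N * m), N, m) *
    matrix(items$sigma, N, m, byrow = TRUE)
  # keep times representable in double precision: a half-normal time
  # discrimination occasionally yields an enormous sigma, and exp() of such
  # log times would under/overflow to 0/Inf
  lnT <- pmin(pmax(lnT, -700), 700)
  T_mat <- exp(lnT)
  dimnames(U) <- dimnames(T_mat) <-
    list(paste0("person", seq_len(N)), pattern$item_ids)
  structure(
    list(U = U, T = T_mat, pattern = pattern,
         truth = list(items = items, persons = persons,
                      structure = pp$structure, spec = spec,
                      config = config, seed = config$seed)),
    class = "bfhm_sim")
}
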