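#' Probability of a correct response under the bi-factor 2PL model
#'
#' The response probability is a logistic function of a weighted sum of the
#' general and the item's assigned specific ability:
#' \deqn{P(u = 1) = 1 / (1 + \exp(-(d + a_g \theta_g + a_s \theta_s)))}
#'
#' For models without a general factor set `a_g = 0` (or leave `a_g`,
#' `theta_g` at their 0 defaults).
#'
#' @param d item location parameter.
#' @param a_g,a_s discriminations of the general and specific ability.
#' @param theta_g,theta_s general and specific ability values.
#' @return probability in (0, 1); vectorized over all arguments.
#' @examples
#' irt_prob(d = 0, a_g = 1, a_s = 1, theta_g = 0, theta_s = 0)  # 0.5
#' @export
irt_prob <- function(d, a_g = 0, a_s = 0, theta_g = 0, theta_s = 0) {
  plogis(d + a_g * theta_g + a_s * theta_s)
}

#' Expected log response time under the bi-factor lognormal RT model
#'
#' \deqn{E[\ln T] = \beta - (\alpha_g \tau_g + \alpha_s \tau_s)}
#' Higher speed (general or specific) shortens the expected log time; the
#' time-intensity `beta` is the expected log time of a person with zero
#' speed on both factors.
#'
#' @param beta item time-intensity (log-seconds).
#' @param alpha_g,alpha_s RT slopes on general and specific speed.
#' @param tau_g,tau_s general and specific speed values.
#' @return expected log time (log-seconds); vectorized.
#' @export
log_rt_mean <- function(beta, alpha_g = 0, alpha_s = 0, tau_g = 0, tau_s = 0) {
  beta - (alpha_g * tau_g + alpha_s * tau_s)
}

#' Log-density of an observed response time
#'
#' The model places a normal distribution on log time: the returned value is
#' the log of the normal density of `log(t)` with mean [log_rt_mean()] and
#' standard deviation `sigma`. All RT fit indices in the package are on this
#' log-time scale (shared by every model variant, so relative comparisons
#' are unaffected).
#'
#' @param t observed response time in seconds, strictly positive.
#' @param beta,alpha_g,alpha_s,tau_g,tau_s see [log_rt_mean()].
#' @param sigma residual standard deviation of log time, strictly positive.
#' @return log-density value; vectorized.
#' @export
log_rt_logdensity <- function(t, beta, sigma, alpha_g = 0, alpha_s = 0,
                              tau_g = 0, tau_s = 0) {
  if (any(!is.finite(t)) || any(t <= 0))
    stop("response times must be finite and strictly positive")
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("`sigma` must be finite and strictly positive")
  dnorm(log(t), mean = log_rt_mean(beta, alpha_g, alpha_s, tau_g, tau_s),
        sd = sigma, log = TRUE)
}

#' Pointwise log-likelihood matrices for a dataset
#'
#' Evaluates the level-1 log-likelihood of every person x item cell under
#' the given parameters, separately for the accuracy (Bernoulli) and the
#' time (normal on log time) component. Missing cells (NA) contribute zero
#' and are counted.
#'
#' @param U binary response matrix (persons x items; 0/1 or NA).
#' @param T_mat response-time matrix (persons x items; positive seconds or
#'   NA).
#' @param items an [item_parameters()] object.
#' @param persons a [person_parameters()] object.
#' @param pattern a [loading_pattern()].
#' @param spec a [model_spec()].
#' @return list with matrices `ra` and `rt` (persons x items, zeros at
#'   missing cells), the logical missingness masks `missing_ra`,
#'   `missing_rt`, and counts `n_missing_ra`, `n_missing_rt`.
#' @export
pointwise_loglik <- function(U, T_mat, items, persons, pattern, spec) {
  stopifnot(inherits(items, "item_parameters"),
            inherits(persons, "person_parameters"),
            inherits(pattern, "loading_pattern"),
            inherits(spec, "model_spec"))
  U <- as.matrix(U); T_mat <- as.matrix(T_mat)
  N <- nrow(U); m <- ncol(U)
  if (!all(dim(T_mat) == c(N, m)))
    stop("response and time matrices must have identical dimensions")
  if (m != pattern$n_items)
    stop("number of items disagrees with the loading pattern")
  if (items$n_items != m)
    stop("item parameters disagree with the number of items")
  if (persons$n_persons != N)
    stop("person parameters disagree with the number of persons")
  obs_u <- U[!is.na(U)]
  if (length(obs_u) && !all(obs_u %in% c(0, 1)))
    stop("responses must be 0, 1 or NA")
  obs_t <- T_mat[!is.na(T_mat)]
  if (length(obs_t) && any(obs_t <= 0))
    stop("response times must be strictly positive")

  grp <- pattern$group_of
  if (spec$variant == "unidim") grp <- rep(1L, m)
  if (persons$n_specific < max(grp))
    stop("person parameters have too few specific dimensions for the pattern")
  a_g <- if (spec$has_general) items$a_g else rep(0, m)
  alpha_g <- if (spec$has_general) items$alpha_g else rep(0, m)
  if (spec$has_general && (is.null(a_g) || is.null(alpha_g)))
    stop("general loadings required for a model with a general factor")
  theta_g <- if (spec$has_general) persons$theta_g else rep(0, N)
  tau_g <- if (spec$has_general) persons$tau_g else rep(0, N)
  if (spec$has_general && (is.null(theta_g) || is.null(tau_g)))
    stop("general traits required for a model with a general factor")

  # linear predictors, persons x items
  Theta <- persons$theta_s[, grp, drop = FALSE]
  eta <- sweep(Theta, 2, items$a_s, `*`) +
    outer(theta_g, a_g) +
    matrix(items$d, N, m, byrow = TRUE)
  Tau <- if (spec$rt_unidim) persons$tau_s[, rep(1L, m), drop = FALSE]
         else persons$tau_s[, grp, drop = FALSE]
  mu <- matrix(items$beta, N, m, byrow = TRUE) -
    sweep(Tau, 2, items$alpha_s, `*`) - outer(tau_g, alpha_g)

  miss_ra <- is.na(U)
  miss_rt <- is.na(T_mat)
  # stable Bernoulli log-likelihood: u*eta - log(1 + exp(eta))
  ll_ra <- ifelse(U == 1, plogis(eta, log.p = TRUE),
                  plogis(-eta, log.p = TRUE))
  ll_ra[miss_ra] <- 0
  sig <- matrix(items$sigma, N, m, byrow = TRUE)
  lt <- suppressWarnings(log(T_mat))
  ll_rt <- dnorm(lt, mean = mu, sd = sig, log = TRUE)
  ll_rt[miss_rt] <- 0
  dimnames(ll_ra) <- dimnames(ll_rt) <- dimnames(U)
  list(ra = ll_ra, rt = ll_rt,
       missing_ra = miss_ra, missing_rt = miss_rt,
       n_missing_ra = sum(miss_ra), n_missing_rt = sum(miss_rt))
}
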