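#' Widely applicable information criterion from pointwise log-likelihood
#'
#' Computes, on the deviance scale, `waic = -2 * (lppd - p_waic)` with
#' `lppd = sum_i log mean_s exp(ll[s, i])` and
#' `p_waic = sum_i var_s(ll[s, i])`.
#'
#' @param ll draws x observations matrix of pointwise log-likelihood values
#'   (at least 2 draws, all finite).
#' @return list with `waic`, `lppd`, `p_waic` and the pointwise vectors
#'   `lppd_i`, `p_i`.
#' @export
waic <- function(ll) {
  ll <- as.matrix(ll)
  if (nrow(ll) < 2L)
    stop("WAIC needs at least 2 posterior draws (variance undefined)")
  if (any(!is.finite(ll))) stop("non-finite pointwise log-likelihoods")
  lppd_i <- apply(ll, 2, logmeanexp)
  p_i <- apply(ll, 2, var)
  lppd <- sum(lppd_i); p_waic <- sum(p_i)
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic,
       lppd_i = lppd_i, p_i = p_i)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logmeanexp <- function(x) logsumexp(x) - log(length(x))

# Empirical-Bayes generalized-Pareto fit (Zhang & Stephens 2009 profile
# estimator with the weak prior regularization used by the reference PSIS
# implementations). `x` must be sorted ascending.
gpd_fit <- function(x) {
  prior_bs <- 3; prior_k <- 10
  n <- length(x)
  m_est <- 30L + floor(sqrt(n))
  b <- 1 - sqrt(m_est / (seq_len(m_est) - 0.5))
  b <- b / (prior_bs * x[floor(n / 4 + 0.5)])
  b <- b + 1 / x[n]
  k_b <- vapply(b, function(bi) mean(log1p(-bi * x)), numeric(1))
  len_scale <- n * (log(-(b / k_b)) - k_b - 1)
  w <- 1 / vapply(len_scale,
                  function(l) sum(exp(len_scale - l)), numeric(1))
  keep <- w >= 10 * .Machine$double.eps
  if (!all(keep)) { w <- w[keep]; b <- b[keep] }
  w <- w / sum(w)
  b_post <- sum(b * w)
  k_post <- mean(log1p(-b_post * x))
  sigma <- -k_post / b_post
  k_post <- (n * k_post + prior_k * 0.5) / (n + prior_k)
  c(k = k_post, sigma = sigma)
}

# Inverse CDF of the generalized Pareto distribution (location 0).
gpd_quantile <- function(p, k, sigma) {
  if (sigma <= 0) return(rep(NaN, length(p)))
  q <- if (abs(k) < .Machine$double.eps) -log1p(-p)
       else expm1(-k * log1p(-p)) / k
  q * sigma
}

# Pareto-smooth one vector of log importance weights; returns normalized
# log weights and the tail-shape estimate.
psis_smooth <- function(lw, tail_len) {
  S <- length(lw)
  x <- lw - max(lw)
  ord <- order(x)
  cutoff <- max(x[ord[S - tail_len]], log(.Machine$double.xmin))
  tail_ids <- which(x > cutoff)
  k <- Inf
  if (length(tail_ids) > 4) {
    xt <- x[tail_ids]
    ti <- order(xt)
    exp_tail <- exp(xt)[ti] - exp(cutoff)
    fit <- gpd_fit(exp_tail)
    k <- fit["k"]
    if (is.finite(k)) {
      sti <- (seq_along(xt) - 0.5) / length(xt)
      smoothed <- log(gpd_quantile(sti, fit["k"], fit["sigma"]) +
                      exp(cutoff))
      x[tail_ids[ti]] <- smoothed
      x[x > 0] <- 0
    }
  }
  list(lw = x - logsumexp(x), k = unname(k))
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' PSIS-LOO on the deviance scale: for each observation the leave-one-out
#' predictive density is approximated by importance sampling with smoothed
#' weights (a generalized Pareto distribution fitted to the weight tail).
#' Warns when any Pareto tail-shape estimate exceeds 0.7 (unreliable
#' importance sampling for that observation).
#'
#' @param ll draws x observations pointwise log-likelihood matrix (100 or
#'   more draws recommended for stable Pareto fits).
#' @param r_eff relative MCMC efficiency of the draws (scales the tail
#'   length used for the Pareto fit; default 1).
#' @return list with `loo` (deviance scale), `elpd_loo`, `p_loo`,
#'   `pareto_k` (one per observation) and pointwise `elpd_i`.
#' @export
psis_loo <- function(ll, r_eff = 1) {
  ll <- as.matrix(ll)
  S <- nrow(ll)
  if (any(!is.finite(ll))) stop("non-finite pointwise log-likelihoods")
  if (S < 2L) stop("PSIS-LOO needs at least 2 posterior draws")
  tail_len <- ceiling(min(S / 5, 3 * sqrt(S / r_eff)))
  n <- ncol(ll)
  elpd_i <- numeric(n); k_i <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i], tail_len)
    elpd_i[i] <- logsumexp(sm$lw + ll[, i])
    k_i[i] <- sm$k
  }
  if (any(is.finite(k_i) & k_i > 0.7))
    warning(sprintf("%d observation(s) with Pareto k > 0.7; ",
                    sum(k_i > 0.7)),
            "PSIS-LOO estimates may be unreliable")
  lppd_i <- apply(ll, 2, logmeanexp)
  elpd <- sum(elpd_i)
  list(loo = -2 * elpd, elpd_loo = elpd, p_loo = sum(lppd_i - elpd_i),
       pareto_k = k_i, elpd_i = elpd_i)
}

#' WAIC and PSIS-LOO of a fitted model, split by component
#'
#' Computes both criteria from the fit's pointwise log-likelihood draws,
#' with the person x item cell as the pointwise unit, separately for the
#' response-accuracy component, the response-time component, and their sum.
#' Because RA and RT cells are conditionally independent given the latent
#' traits, the total equals RA + RT for every index. RT values are
#' densities of log time (the scale shared by all variants).
#'
#' @param fit a `bfhm_fit`.
#' @return data.frame with rows RA, RT, total and columns `waic`, `lppd`,
#'   `p_waic`, `loo`, `p_loo`, `max_pareto_k`.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "bfhm_fit"))
  comp <- function(ll) {
    ll <- ll[, colSums(is.na(ll)) == 0, drop = FALSE]
    w <- waic(ll)
    l <- psis_loo(ll)
    data.frame(waic = w$waic, lppd = w$lppd, p_waic = w$p_waic,
               loo = l$loo, p_loo = l$p_loo,
               max_pareto_k = max(l$pareto_k))
  }
  ra <- comp(fit$pointwise$ra)
  rt <- comp(fit$pointwise$rt)
  total <- ra + rt
  total$max_pareto_k <- max(ra$max_pareto_k, rt$max_pareto_k)
  out <- rbind(RA = ra, RT = rt, total = total)
  out$component <- rownames(out)
  out$model <- toupper(fit$spec$variant)
  rownames(out) <- NULL
  out[, c("model", "component", "waic", "lppd", "p_waic", "loo", "p_loo",
          "max_pareto_k")]
}

#' Compare fitted models by WAIC and LOO
#'
#' All fits must be estimated on the same data cells. Returns one row per
#' model with RA, RT and total columns for each criterion, sorted ascending
#' by total WAIC (smaller is better).
#'
#' @param fits list of `bfhm_fit` objects (optionally named).
#' @return data.frame ranked by total WAIC.
#' @export
compare_fits <- function(fits) {
  if (inherits(fits, "bfhm_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1),
                                          "bfhm_fit")))
  dims <- vapply(fits, function(f) c(f$n_persons, f$n_items), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("fits are incomparable: differing data dimensions")
  rows <- lapply(fits, function(f) {
    fi <- fit_indices(f)
    data.frame(model = fi$model[1],
               waic_ra = fi$waic[fi$component == "RA"],
               waic_rt = fi$waic[fi$component == "RT"],
               waic_total = fi$waic[fi$component == "total"],
               loo_ra = fi$loo[fi$component == "RA"],
               loo_rt = fi$loo[fi$component == "RT"],
               loo_total = fi$loo[fi$component == "total"],
               max_pareto_k = max(fi$max_pareto_k))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$waic_total), , drop = FALSE]
  rownames(out) <- NULL
  out
}
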