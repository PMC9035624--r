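#' Item parameters of the joint hierarchical model
#'
#' Container for the item side of the model: RA discriminations on the
#' general (`a_g`) and assigned specific (`a_s`) ability, the location `d`,
#' RT slopes on general (`alpha_g`) and specific (`alpha_s`) speed, the
#' time-intensity `beta` (expected log-seconds an item demands) and the
#' residual standard deviation `sigma` of log time (its reciprocal is the
#' time-discrimination parameter).
#'
#' `a_g`/`alpha_g` may be `NULL` for models without a general factor.
#'
#' @param a_s,d,alpha_s,beta,sigma numeric vectors of equal length (one per
#'   item); `a_s`, `alpha_s`, `sigma` strictly positive.
#' @param a_g,alpha_g strictly positive vectors, or `NULL` when the model
#'   has no general factor.
#' @return an object of class `item_parameters`.
#' @export
item_parameters <- function(a_s, d, alpha_s, beta, sigma,
                            a_g = NULL, alpha_g = NULL) {
  m <- length(a_s)
  num <- function(v, nm, positive = FALSE, allow_null = FALSE) {
    if (is.null(v)) {
      if (allow_null) return(NULL)
      stop(sprintf("`%s` is required", nm))
    }
    v <- as.numeric(v)
    if (length(v) != m) stop(sprintf("`%s` must have length %d", nm, m))
    if (anyNA(v) || !all(is.finite(v)))
      stop(sprintf("`%s` must be finite", nm))
    if (positive && any(v <= 0))
      stop(sprintf("`%s` must be strictly positive", nm))
    v
  }
  structure(
    list(a_g = num(a_g, "a_g", TRUE, TRUE), a_s = num(a_s, "a_s", TRUE),
         d = num(d, "d"), alpha_g = num(alpha_g, "alpha_g", TRUE, TRUE),
         alpha_s = num(alpha_s, "alpha_s", TRUE), beta = num(beta, "beta"),
         sigma = num(sigma, "sigma", TRUE), n_items = m),
    class = "item_parameters")
}

#' Person parameters of the joint hierarchical model
#'
#' Latent abilities and speeds. `theta_s` and `tau_s` are person x dimension
#' matrices; `tau_s` has a single column when the RT side is unidimensional.
#' `theta_g`/`tau_g` are `NULL` for models without a general factor.
#'
#' @param theta_s,tau_s numeric matrices (persons x dimensions).
#' @param theta_g,tau_g numeric vectors or `NULL`.
#' @return an object of class `person_parameters`.
#' @export
person_parameters <- function(theta_s, tau_s, theta_g = NULL, tau_g = NULL) {
  theta_s <- as.matrix(theta_s)
  tau_s <- as.matrix(tau_s)
  N <- nrow(theta_s)
  if (nrow(tau_s) != N) stop("theta_s and tau_s disagree on person count")
  if (!is.null(theta_g) && length(theta_g) != N)
    stop("theta_g must have one entry per person")
  if (!is.null(tau_g) && length(tau_g) != N)
    stop("tau_g must have one entry per person")
  if (is.null(theta_g) != is.null(tau_g))
    stop("theta_g and tau_g must be supplied together")
  structure(
    list(theta_g = if (!is.null(theta_g)) as.numeric(theta_g),
         theta_s = theta_s,
         tau_g = if (!is.null(tau_g)) as.numeric(tau_g),
         tau_s = tau_s,
         n_persons = N, n_specific = ncol(theta_s)),
    class = "person_parameters")
}

#' Model variant specification
#'
#' The four hierarchical models are constraint cases of one family:
#' \describe{
#'   \item{bfhm}{general + specific factors on both the RA and RT side.}
#'   \item{cmhm}{no general factors (`a_g = alpha_g = 0`); K specific
#'     ability and K specific speed dimensions.}
#'   \item{pmhm}{as cmhm on the RA side, but a single latent speed on the
#'     RT side.}
#'   \item{unidim}{a single ability and a single speed.}
#' }
#'
#' @param variant one of `"bfhm"`, `"cmhm"`, `"pmhm"`, `"unidim"`.
#' @param n_specific number of specific ability dimensions (forced to 1 for
#'   `unidim`).
#' @return an object of class `model_spec` with logical flags `has_general`
#'   (general factors present) and `rt_unidim` (single speed dimension).
#' @export
model_spec <- function(variant = c("bfhm", "cmhm", "pmhm", "unidim"),
                       n_specific) {
  variant <- match.arg(variant)
  if (variant == "unidim") n_specific <- 1L
  n_specific <- as.integer(n_specific)
  if (n_specific < 1L) stop("n_specific must be >= 1")
  structure(
    list(variant = variant,
         n_specific = n_specific,
         has_general = variant == "bfhm",
         rt_unidim = variant %in% c("pmhm", "unidim")),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(toupper(x$variant), "model:", x$n_specific, "specific dimension(s);",
      if (x$has_general) "with" else "no", "general factor;",
      if (x$rt_unidim) "unidimensional" else "multidimensional", "RT side\n")
  invisible(x)
}
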