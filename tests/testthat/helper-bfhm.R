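# shared fixtures: all data is generated in code at test time

# short-chain sampler settings for smoke-level fits
quick_sampler <- function(iterations = 400L, chains = 2L) {
  sampler_config(chains = chains, iterations = iterations,
                 warmup = iterations %/% 2L, thin = 1L)
}

# a small simulated joint dataset
tiny_sim <- function(N = 40, m = 6, K = 3, seed = 7, variant = "bfhm") {
  simulate_dataset(sim_config(N = N, m = m, n_specific = K, seed = seed,
                              variant = variant))
}

# hand-built parameter sets for exact likelihood algebra
flat_items <- function(m, a_g = NULL, alpha_g = NULL, a_s = 0.8, d = 0,
                       alpha_s = 0.5, beta = 4, sigma = 1) {
  item_parameters(a_s = rep(a_s, m), d = rep(d, m),
                  alpha_s = rep(alpha_s, m), beta = rep(beta, m),
                  sigma = rep(sigma, m),
                  a_g = if (!is.null(a_g)) rep(a_g, m),
                  alpha_g = if (!is.null(alpha_g)) rep(alpha_g, m))
}

prior_vec <- function() bfhm:::prior_vector(prior_config())

# evaluate the C++ posterior/likelihood for a variant at a given point
cpp_logpost <- function(x, sim, variant, lik_weight = 1, prior_weight = 1) {
  spec <- model_spec(variant, sim$pattern$n_specific)
  grp <- if (variant == "unidim") rep(1L, ncol(sim$U)) else
    sim$pattern$group_of
  Ui <- sim$U; Ui[is.na(Ui)] <- -1L; storage.mode(Ui) <- "integer"
  Lt <- log(sim$T); Lt[is.na(Lt)] <- NaN
  bfhm:::.bf_logpost(x, Ui, Lt, grp - 1L, spec$n_specific, spec$has_general,
                     spec$rt_unidim, prior_vec(), lik_weight, prior_weight)
}

cpp_dim <- function(sim, variant) {
  spec <- model_spec(variant, sim$pattern$n_specific)
  bfhm:::.bf_dim(nrow(sim$U), ncol(sim$U), spec$n_specific,
                 spec$has_general, spec$rt_unidim)
}
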