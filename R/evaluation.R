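#' Mean squared error of recovered parameters
#'
#' `MSE = sum_r sum_j (est - truth)^2 / (R * K)` where `R` is the number of
#' replications and `K` the number of evaluated units (items for item
#' parameters, examinees for person parameters).
#'
#' @param estimates,truths numeric matrices of identical shape
#'   (replications x units); plain vectors are treated as one replication.
#' @return the mean squared deviation (scalar, >= 0).
#' @export
mse <- function(estimates, truths) {
  estimates <- rbind(estimates); truths <- rbind(truths)
  if (!all(dim(estimates) == dim(truths)))
    stop("estimates and truths must have identical dimensions")
  mean((estimates - truths)^2)
}

#' Average bias of recovered parameters
#'
#' `Bias = sum_r sum_j (est - truth) / (R * K)`: the signed mean deviation.
#'
#' @inheritParams mse
#' @return the signed mean deviation (scalar).
#' @export
bias <- function(estimates, truths) {
  estimates <- rbind(estimates); truths <- rbind(truths)
  if (!all(dim(estimates) == dim(truths)))
    stop("estimates and truths must have identical dimensions")
  mean(estimates - truths)
}

# parameter families evaluated in a recovery study; `truth_fun` pulls the
# generating values, `est_fun` the EAP estimates. Recovery of the residual
# SD is evaluated on the time-discrimination (1/sigma) scale: that is the
# scale the parameter is drawn and assigned its prior on, and it is stable
# where the reciprocal is not (a tiny time discrimination means an
# arbitrarily large, weakly-determined sigma).
recovery_families <- function(K, has_general) {
  fam <- list(
    a_s = list(t = function(tr) tr$items$a_s,
               e = function(f) eap_family(f, "a_s")),
    d = list(t = function(tr) tr$items$d,
             e = function(f) eap_family(f, "d")),
    alpha_s = list(t = function(tr) tr$items$alpha_s,
                   e = function(f) eap_family(f, "alpha_s")),
    sigma = list(t = function(tr) 1 / tr$items$sigma,
                 e = function(f) 1 / eap_family(f, "sigma")),
    beta = list(t = function(tr) tr$items$beta,
                e = function(f) eap_family(f, "beta")))
  if (has_general) {
    fam$a_g <- list(t = function(tr) tr$items$a_g,
                    e = function(f) eap_family(f, "a_g"))
    fam$alpha_g <- list(t = function(tr) tr$items$alpha_g,
                        e = function(f) eap_family(f, "alpha_g"))
    fam$theta_g <- list(t = function(tr) tr$persons$theta_g,
                        e = function(f) eap_family(f, "theta_g"))
    fam$tau_g <- list(t = function(tr) tr$persons$tau_g,
                      e = function(f) eap_family(f, "tau_g"))
  }
  for (k in seq_len(K)) {
    local({
      kk <- k
      fam[[sprintf("theta_s%d", kk)]] <<- list(
        t = function(tr) tr$persons$theta_s[, kk],
        e = function(f) eap_family(f, "theta_s")[, kk])
      fam[[sprintf("tau_s%d", kk)]] <<- list(
        t = function(tr) tr$persons$tau_s[, kk],
        e = function(f) eap_family(f, "tau_s")[, kk])
    })
  }
  fam
}

#' Run a Monte-Carlo parameter-recovery study
#'
#' For each (N, m) condition and replication: simulate a dataset (fresh
#' person correlations each replication), fit the model, take EAP
#' estimates, and accumulate MSE and Bias per parameter family. The
#' replication seed is derived deterministically from the base seed, the
#' condition index and the replication index. Non-converged replications
#' (any PSRF at or above the threshold) are flagged and excluded from the
#' summary table unless `keep_nonconverged = TRUE`.
#'
#' @param conditions data.frame with columns `N` and `m`.
#' @param reps replications per condition.
#' @param n_specific number of specific dimensions (default 3).
#' @param model fitted variant (default `"bfhm"`, which is also the
#'   generating model).
#' @param sampler a [sampler_config()] used for every fit.
#' @param seed base seed.
#' @param keep_nonconverged include non-converged replications in the table.
#' @param quiet suppress progress messages.
#' @return list of class `recovery_report`: `table` (one row per parameter
#'   family x condition with MSE, Bias and a Monte-Carlo standard error of
#'   the MSE across replications), `details` (per-replication rows with
#'   convergence flags and seeds), and the study configuration.
#' @export
run_recovery_study <- function(conditions, reps, n_specific = 3L,
                               model = "bfhm",
                               sampler = sampler_config(),
                               seed = 1L, keep_nonconverged = FALSE,
                               quiet = FALSE) {
  stopifnot(is.data.frame(conditions), all(c("N", "m") %in% names(conditions)),
            reps >= 1)
  details <- list()
  acc <- list()  # acc[[cond]][[family]] = list(est = R x K, truth = R x K)
  for (ci in seq_len(nrow(conditions))) {
    N <- conditions$N[ci]; m <- conditions$m[ci]
    cond_lab <- sprintf("N=%d,m=%d", N, m)
    fams <- NULL
    for (r in seq_len(reps)) {
      rep_seed <- sub_seed(seed, ci * 10000L + r)
      cfg <- sim_config(N = N, m = m, n_specific = n_specific,
                        seed = rep_seed, variant = model)
      sim <- simulate_dataset(cfg)
      fit <- fit_bfhm(sim$U, sim$T, sim$pattern, model = model,
                      sampler = sampler, seed = rep_seed, quiet = TRUE)
      if (!quiet)
        message(sprintf("%s rep %d/%d: max PSRF %.3f (%s)", cond_lab, r,
                        reps, fit$max_psrf,
                        if (fit$converged) "ok" else "non-converged"))
      if (is.null(fams))
        fams <- recovery_families(n_specific, fit$spec$has_general)
      fam_stats <- lapply(fams, function(fm) {
        tr <- fm$t(sim$truth); es <- fm$e(fit)
        list(truth = as.numeric(tr), est = as.numeric(es))
      })
      details[[length(details) + 1]] <- data.frame(
        condition = cond_lab, N = N, m = m, rep = r, seed = rep_seed,
        max_psrf = fit$max_psrf, converged = fit$converged,
        n_divergent = fit$n_divergent)
      use <- fit$converged || keep_nonconverged
      if (use) {
        if (is.null(acc[[cond_lab]])) acc[[cond_lab]] <- list()
        for (fn in names(fam_stats)) {
          a <- acc[[cond_lab]][[fn]]
          acc[[cond_lab]][[fn]] <- list(
            est = rbind(a$est, fam_stats[[fn]]$est),
            truth = rbind(a$truth, fam_stats[[fn]]$truth))
        }
      }
    }
  }
  table_rows <- list()
  for (cond_lab in names(acc)) {
    for (fn in names(acc[[cond_lab]])) {
      a <- acc[[cond_lab]][[fn]]
      per_rep_mse <- rowMeans((a$est - a$truth)^2)
      table_rows[[length(table_rows) + 1]] <- data.frame(
        condition = cond_lab, family = fn,
        mse = mse(a$est, a$truth), bias = bias(a$est, a$truth),
        mse_se = if (nrow(a$est) > 1) sd(per_rep_mse) / sqrt(nrow(a$est))
                 else NA_real_,
        reps_used = nrow(a$est))
    }
  }
  details <- do.call(rbind, details)
  n_dropped <- sum(!details$converged & !keep_nonconverged)
  if (n_dropped > 0 && !quiet)
    message(sprintf("%d non-converged replication(s) excluded", n_dropped))
  structure(list(table = do.call(rbind, table_rows), details = details,
                 conditions = conditions, reps = reps, seed = seed,
                 model = model, n_specific = n_specific,
                 keep_nonconverged = keep_nonconverged),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter-recovery study:", toupper(x$model), "-", x$reps,
      "replication(s) per condition\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' Extract one recovery statistic as a family x condition table
#'
#' @param report a `recovery_report`.
#' @param stat `"mse"` or `"bias"`.
#' @return data.frame, rows = parameter families, one column per condition.
#' @export
recovery_table <- function(report, stat = c("mse", "bias")) {
  stat <- match.arg(stat)
  tb <- report$table
  fams <- unique(tb$family)
  conds <- unique(tb$condition)
  out <- data.frame(family = fams)
  for (cl in conds)
    out[[cl]] <- tb[[stat]][match(
      paste(fams, cl), paste(tb$family, tb$condition))]
  out
}
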