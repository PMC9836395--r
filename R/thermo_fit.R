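#' Fit the thermodynamic enhancer model to rate profiles by MCMC
#'
#' The package's central fitting function: builds a [fit_spec()] from the
#' data and parameter specification, runs the adaptive Metropolis sampler,
#' and returns a fitted-model object with the usual methods (`print`,
#' `summary`, `coef`, `predict`, `logLik`, `residuals`, `plot`).
#'
#' @inheritParams fit_spec
#' @param n_steps,seed,adapt_every,burn_in_frac,init passed to [run_mcmc()].
#' @return object of class `"thermo_fit"` with elements `spec`, `chain`,
#'   `bicoid`, `runt`.
#' @examples
#' \donttest{
#' study <- simulate_study(seed = 7)
#' fit <- thermo_fit(study$profiles[["000_runt_null"]], study$bicoid,
#'                   free = list(Kb = c(1, 1e3), omega_bp = c(1e-3, 1e3),
#'                               p = c(1e-6, 1), R = c(1, 1e5)),
#'                   n_steps = 2000, seed = 1)
#' coef(fit)
#' }
#' @export
thermo_fit <- function(data, bicoid, runt = NULL, free, fixed = numeric(0),
                       activation = list(), sem_floor = NULL,
                       variance_mode = c("fixed", "marginal"),
                       scale_nuisance = FALSE, nu_bounds = c(0.25, 4),
                       nu_prior_sd = NULL, extra_var = NULL,
                       n_steps = 30000, seed, adapt_every = 500,
                       burn_in_frac = 0.2, init = NULL) {
  spec <- fit_spec(data, bicoid, runt, free, fixed, activation, sem_floor,
                   variance_mode, scale_nuisance, nu_bounds, nu_prior_sd,
                   extra_var)
  chain <- run_mcmc(spec, n_steps = n_steps, seed = seed,
                    adapt_every = adapt_every, burn_in_frac = burn_in_frac,
                    init = init)
  structure(list(spec = spec, chain = chain, bicoid = bicoid, runt = runt),
            class = "thermo_fit")
}

#' @export
print.thermo_fit <- function(x, ...) {
  ids <- vapply(x$spec$datasets, function(d)
    paste0("[", d$construct_id, "] ", d$genotype), character(1))
  cat("Thermodynamic enhancer model fit\n")
  cat("  data:", paste(ids, collapse = ", "), "\n")
  cat(sprintf("  %d free parameter(s), %d MCMC steps, acceptance %.1f%%\n",
              ncol(x$chain$samples), nrow(x$chain$samples),
              100 * x$chain$acceptance_rate))
  print(x$chain$summaries$table, digits = 4)
  invisible(x)
}

#' @export
summary.thermo_fit <- function(object, ...) {
  out <- object$chain$summaries
  out$acceptance_rate <- object$chain$acceptance_rate
  out$max_loglik <- max_loglik_chain(object$chain)
  out$aic <- compute_aic(out$max_loglik, ncol(object$chain$samples))
  class(out) <- "summary.thermo_fit"
  out
}

#' @export
print.summary.thermo_fit <- function(x, ...) {
  print(x$table, digits = 4)
  cat(sprintf("acceptance %.1f%%, max logLik %.2f, AIC %.2f\n",
              100 * x$acceptance_rate, x$max_loglik, x$aic))
  if (ncol(x$correlations) > 1L) {
    cat("posterior correlations:\n")
    print(round(x$correlations, 2))
  }
  invisible(x)
}

#' @export
coef.thermo_fit <- function(object, ...) {
  stats::setNames(object$chain$summaries$table$mean,
                  object$chain$summaries$table$parameter)
}

#' @export
logLik.thermo_fit <- function(object, ...) {
  structure(max_loglik_chain(object$chain),
            df = ncol(object$chain$samples), class = "logLik")
}

#' Predicted rate profile from a fitted model
#'
#' Evaluates the model at the maximum-posterior sample (free parameters)
#' combined with the fit's fixed values, for one dataset of the fit.  The
#' MAP sample is used rather than coordinate-wise posterior means because
#' the activation posterior is ridge-shaped and the mean point lies off the
#' ridge (see [chain_estimate()]).
#'
#' @param object a `"thermo_fit"`.
#' @param which index of the dataset within the fit (default 1).
#' @param band also compute a 95% credible band by pushing posterior draws
#'   through the model.
#' @param ... unused.
#' @return a [rate_profile()] (with band attributes if requested).
#' @export
predict.thermo_fit <- function(object, which = 1L, band = FALSE, ...) {
  ds <- object$spec$datasets[[which]]
  pars <- resolve_params(object, ds$construct_id)
  propagate_prediction(ds$arch, pars$act, pars$rep, object$bicoid,
                       object$runt, genotype = ds$genotype,
                       chain = if (band) object$chain else NULL)
}

#' @export
residuals.thermo_fit <- function(object, which = 1L, standardized = TRUE, ...) {
  ds <- object$spec$datasets[[which]]
  pred <- predict.thermo_fit(object, which = which)
  res <- ds$y - pred$mean
  if (standardized) res <- res / pmax(ds$sem, object$spec$sem_floor)
  res
}

#' @export
plot.thermo_fit <- function(x, which = 1L, ...) {
  ds <- x$spec$datasets[[which]]
  pred <- predict.thermo_fit(x, which = which)
  ylim <- range(0, ds$y + ds$sem, pred$mean, na.rm = TRUE)
  plot(pred$ap_fraction, pred$mean, type = "n",
       ylim = ylim, xlab = "AP position (fraction EL)",
       ylab = "initial RNAP loading rate (AU/min)",
       main = paste0("[", ds$construct_id, "] ", ds$genotype), ...)
  graphics::arrows(pred$ap_fraction, ds$y - ds$sem, pred$ap_fraction,
                   ds$y + ds$sem, angle = 90, code = 3, length = 0.02,
                   col = "grey50")
  graphics::points(pred$ap_fraction, ds$y, pch = 16)
  graphics::lines(pred$ap_fraction, pred$mean, col = "firebrick", lwd = 2)
  invisible(x)
}

## Assemble (act, rep) for one construct from a fit's posterior means plus
## its fixed values and inherited activation parameters.
resolve_params <- function(object, construct_id) {
  act <- object$spec$activation[[construct_id]]
  if (is.null(act)) act <- activation_params(1, 1, 1, 1)  # placeholder, overwritten below
  rep_par <- repression_params(Kr = 1)
  theta <- c(object$spec$fixed, chain_estimate(object$chain, "map"))
  apply_theta(theta, act, rep_par)
}
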