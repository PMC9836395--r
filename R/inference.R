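#' Specify a Bayesian fit of the thermodynamic model to rate profiles
#'
#' A fit spec pins down everything the sampler needs: the data (one or more
#' AP rate profiles, each tagged with construct and genotype), the static
#' transcription-factor input profiles, which parameters are free (with
#' prior bounds) and which are fixed, and the likelihood options.
#'
#' Parameter names: activation parameters are `Kb`, `omega_bp`, `p`, `R`
#' (used for constructs without an entry in `activation`); repression
#' parameters are `Kr`, `omega_rp_1/2/3` (site 1 = distal), `omega_rr_12/13/23`,
#' `omega_rrp_12/13/23`, `omega_rrr`, `omega_rrrp`.  Any repression
#' parameter not listed as free or fixed defaults to 1 (no interaction);
#' `Kr` defaults to 1 (irrelevant for runt-null data).
#'
#' Priors are uniform on the sampling scale within the bounds: log-uniform
#' (the default, for strictly positive parameters) or uniform.
#'
#' @param data a [rate_profile()] or list of them.
#' @param bicoid,runt [concentration_profile()]s on the same grid as the
#'   data; `runt` may be `NULL` when all data are runt-null.
#' @param free named list: parameter name to `c(lower, upper)` bounds
#'   (log-uniform prior) or `list(bounds = c(lower, upper),
#'   scale = "log"|"linear")`.
#' @param fixed named numeric of fixed parameter values.
#' @param activation named list (by construct id) of fixed
#'   [activation_params()] inherited from an earlier inference stage.
#' @param sem_floor per-bin SEM floor (AU/min) used in the Gaussian
#'   likelihood; `NULL` (default) uses 2% of the largest data value, which
#'   keeps the likelihood defined for noiseless synthetic data.
#' @param variance_mode `"fixed"` treats `max(SEM_i, floor)` as the exact
#'   per-bin error SD; `"marginal"` multiplies all error SDs by a common
#'   scale factor that is marginalized out under a Jeffreys prior
#'   (MCMCstat-style sampled error variance, integrated analytically).  The
#'   marginal mode lets credible intervals expand with realized misfit,
#'   absorbing embryo-level common-mode noise and upstream point-estimate
#'   error that the per-bin SEMs cannot represent.
#' @param scale_nuisance add one free multiplicative scale parameter
#'   `nu_<construct>` per dataset (log-uniform on `nu_bounds`), multiplying
#'   that dataset's predicted profile.  Embryo-to-embryo variability is
#'   largely a common-mode scale shift of a whole profile; with the scale
#'   profiled out, the repression parameters are inferred from the shape of
#'   the profile along the AP axis and are insensitive both to that
#'   common-mode noise and to the overall-scale error of upstream
#'   point-estimated activation parameters (the fold-change logic of
#'   bacterial gene-regulation dissections).
#' @param nu_bounds bounds for the scale nuisance parameters.
#' @param nu_prior_sd optional SD of a lognormal prior on each scale
#'   nuisance (`log nu ~ N(0, nu_prior_sd^2)`); `NULL` leaves the nuisance
#'   flat within `nu_bounds`.  An informative prior is appropriate when the
#'   overall level is itself the quantity being fit (runt-null activation
#'   fits), where it encodes how well the profile level is known given
#'   embryo-to-embryo variability.
#' @param extra_var optional named list (by construct id) of per-bin
#'   variances (AU^2/min^2) added to the squared error SDs: the propagated
#'   uncertainty of upstream point-fixed parameters, computed by pushing
#'   their posterior draws through the model.
#' @return object of class `"fit_spec"`.
#' @export
fit_spec <- function(data, bicoid, runt = NULL, free, fixed = numeric(0),
                     activation = list(), sem_floor = NULL,
                     variance_mode = c("fixed", "marginal"),
                     scale_nuisance = FALSE, nu_bounds = c(0.25, 4),
                     nu_prior_sd = NULL, extra_var = NULL) {
  variance_mode <- match.arg(variance_mode)
  if (inherits(data, "rate_profile")) data <- list(data)
  stopifnot(length(data) >= 1L)
  if (length(free) == 0L && !scale_nuisance) {
    stop("at least one free parameter is required")
  }
  free <- lapply(free, function(f) {
    if (is.numeric(f)) f <- list(bounds = f, scale = "log")
    stopifnot(length(f$bounds) == 2L, f$bounds[1L] < f$bounds[2L],
              f$scale %in% c("log", "linear"))
    if (f$scale == "log" && f$bounds[1L] <= 0) {
      stop("log-scaled bounds must be strictly positive")
    }
    f
  })
  if (length(free) &&
      (is.null(names(free)) || any(names(free) == ""))) stop("'free' must be named")
  if (length(fixed) && (is.null(names(fixed)) || any(names(fixed) == ""))) {
    stop("'fixed' must be named")
  }
  overlap <- intersect(names(free), names(fixed))
  if (length(overlap)) {
    stop("parameter(s) both free and fixed: ", paste(overlap, collapse = ", "))
  }
  if (is.null(sem_floor)) {
    sem_floor <- 0.02 * max(vapply(data, function(d) max(d$mean, na.rm = TRUE),
                                   numeric(1)))
  }
  datasets <- lapply(data, function(prof) {
    stopifnot(inherits(prof, "rate_profile"))
    ev <- if (is.null(extra_var)) NULL else extra_var[[prof$construct_id[1L]]]
    if (!is.null(ev) && length(ev) != nrow(prof)) {
      stop("extra_var for [", prof$construct_id[1L],
           "] has the wrong length")
    }
    if (nrow(prof) != nrow(bicoid) ||
        any(abs(prof$ap_fraction - bicoid$ap_fraction) > 1e-9)) {
      stop("profile for [", prof$construct_id[1L],
           "] is not on the Bicoid profile's AP grid")
    }
    gt <- prof$genotype[1L]
    if (gt == "runt_wt") {
      if (is.null(runt)) stop("runt_wt data need a Runt concentration profile")
      runt_mean <- runt$mean
    } else {
      runt_mean <- rep(0, nrow(prof))
    }
    list(construct_id = prof$construct_id[1L], genotype = gt,
         arch = enhancer_architecture(prof$construct_id[1L]),
         y = prof$mean, sem = prof$sem, extra_var = ev,
         bicoid_mean = bicoid$mean, runt_mean = runt_mean)
  })
  if (scale_nuisance) {
    for (ds in datasets) {
      nm <- paste0("nu_", ds$construct_id)
      if (!is.null(free[[nm]])) next
      free[[nm]] <- list(bounds = nu_bounds, scale = "log")
    }
  }
  spec <- structure(list(datasets = datasets, free = free, fixed = fixed,
                         activation = activation, sem_floor = sem_floor,
                         variance_mode = variance_mode,
                         scale_nuisance = scale_nuisance,
                         nu_prior_sd = nu_prior_sd),
                    class = "fit_spec")
  ## fail fast on unresolvable parameters
  mid <- vapply(free, function(f) {
    if (f$scale == "log") exp(mean(log(f$bounds))) else mean(f$bounds)
  }, numeric(1))
  invisible(log_likelihood(mid, spec))
  spec
}

#' Gaussian log-likelihood of the thermodynamic model
#'
#' Heteroscedastic Gaussian likelihood over all AP bins of all datasets in
#' the fit spec: `-1/2 * sum_i ((y_i - f_i(theta))^2 / s_i^2 + log(2 pi s_i^2))`
#' with `s_i = max(SEM_i, sem_floor)`; missing bins are skipped.  A `theta`
#' outside the prior bounds returns `-Inf` (rejection), not an error.
#'
#' @param theta named numeric of free-parameter values (natural scale), in
#'   any order covering `names(spec$free)`.
#' @param spec a [fit_spec()].
#' @return log-likelihood (scalar).
#' @export
log_likelihood <- function(theta, spec) {
  f <- make_loglik(spec)
  f(theta[names(spec$free)])
}

## Build a fast closure: theta (numeric, in names(spec$free) order) -> loglik.
## Everything invariant across evaluations is precomputed.
make_loglik <- function(spec) {
  free_names <- names(spec$free)
  lower <- vapply(spec$free, function(f) f$bounds[1L], numeric(1))
  upper <- vapply(spec$free, function(f) f$bounds[2L], numeric(1))
  pool0 <- spec$fixed
  ds_pre <- lapply(spec$datasets, function(ds) {
    keep <- !is.na(ds$y)
    s2 <- pmax(ds$sem[keep], spec$sem_floor)^2
    if (!is.null(ds$extra_var)) s2 <- s2 + ds$extra_var[keep]
    list(ds = ds, keep = keep, y = ds$y[keep], inv_s2 = 1 / s2,
         const = sum(log(2 * pi * s2)),
         nu_name = paste0("nu_", ds$construct_id),
         act_fixed = spec$activation[[ds$construct_id]])
  })
  nu_tau <- spec$nu_prior_sd
  marginal <- identical(spec$variance_mode, "marginal")
  n_obs <- sum(vapply(ds_pre, function(pre) length(pre$y), integer(1)))
  rep_template <- repression_params(Kr = 1)
  omega_slots <- list(
    omega_rp_1 = c("omega_rp", "1"), omega_rp_2 = c("omega_rp", "2"),
    omega_rp_3 = c("omega_rp", "3"),
    omega_rr_12 = c("omega_rr", "12"), omega_rr_13 = c("omega_rr", "13"),
    omega_rr_23 = c("omega_rr", "23"),
    omega_rrp_12 = c("omega_rrp", "12"), omega_rrp_13 = c("omega_rrp", "13"),
    omega_rrp_23 = c("omega_rrp", "23"))
  function(theta) {
    pool <- pool0
    pool[free_names] <- theta
    if (any(theta < lower | theta > upper)) return(-Inf)
    rep_par <- rep_template
    if (!is.na(kr <- pool["Kr"])) rep_par$Kr <- kr
    for (nm in names(pool)) {
      slot <- omega_slots[[nm]]
      if (!is.null(slot)) rep_par[[slot[1L]]][[slot[2L]]] <- pool[[nm]]
    }
    if (!is.na(w <- pool["omega_rrr"])) rep_par$omega_rrr <- w
    if (!is.na(w <- pool["omega_rrrp"])) rep_par$omega_rrrp <- w
    total <- 0
    ssr <- 0
    for (pre in ds_pre) {
      act <- pre$act_fixed
      if (is.null(act)) {
        vals <- pool[c("Kb", "omega_bp", "p", "R")]
        if (anyNA(vals)) {
          stop("activation parameters unresolved for construct [",
               pre$ds$construct_id, "]: supply Kb, omega_bp, p, R as free or ",
               "fixed, or pass fixed activation_params", call. = FALSE)
        }
        act <- structure(list(Kb = vals[[1L]], omega_bp = vals[[2L]],
                              p = vals[[3L]], R = vals[[4L]]),
                         class = "activation_params")
      }
      r <- if (pre$ds$genotype == "runt_wt") pre$ds$runt_mean / rep_par$Kr
           else pre$ds$runt_mean
      pred <- rate_closed_form(
        structure(list(b = pre$ds$bicoid_mean / act$Kb, r = r),
                  class = "dimensionless_inputs"),
        pre$ds$arch, act, rep_par)[pre$keep]
      if (!is.na(nu <- pool[pre$nu_name])) {
        pred <- nu * pred
        if (!is.null(nu_tau)) total <- total - 0.5 * (log(nu) / nu_tau)^2
      }
      resid <- pre$y - pred
      ssr <- ssr + sum(resid * resid * pre$inv_s2)
      total <- total - 0.5 * pre$const
    }
    if (marginal) total - (n_obs / 2) * log(ssr) else total - 0.5 * ssr
  }
}

#' Adaptive random-walk Metropolis sampler
#'
#' Gaussian random-walk Metropolis whose proposal covariance is
#' periodically re-estimated from the chain history (scaled by `2.38^2 / d`
#' with a small diagonal jitter), the standard adaptive scheme for
#' low-dimensional biophysical posteriors.  Fully deterministic given the
#' seed.
#'
#' @param log_post function taking a numeric vector (the sampling-scale
#'   state) and returning a log posterior density (may be `-Inf`).
#' @param init numeric starting state.
#' @param n_steps number of iterations.
#' @param seed integer seed.
#' @param adapt_every adaptation interval (steps).
#' @param prop_sd initial diagonal proposal SD.
#' @return list with `samples` (`n_steps x d` matrix), `log_posterior`,
#'   `acceptance_rate`.
#' @export
adaptive_metropolis <- function(log_post, init, n_steps, seed,
                                adapt_every = 500, prop_sd = 0.1) {
  d <- length(init)
  stopifnot(n_steps >= 2L, d >= 1L)
  set.seed(as.integer(seed))
  samples <- matrix(NA_real_, n_steps, d)
  lp <- numeric(n_steps)
  cur <- init
  cur_lp <- log_post(cur)
  if (!is.finite(cur_lp)) stop("initial state has zero posterior density")
  chol_prop <- diag(prop_sd, d)
  n_acc <- 0L
  for (i in seq_len(n_steps)) {
    prop <- cur + drop(stats::rnorm(d) %*% chol_prop)
    prop_lp <- log_post(prop)
    if (is.finite(prop_lp) &&
        log(stats::runif(1)) < (prop_lp - cur_lp)) {
      cur <- prop
      cur_lp <- prop_lp
      n_acc <- n_acc + 1L
    }
    samples[i, ] <- cur
    lp[i] <- cur_lp
    if (i %% adapt_every == 0L && i < n_steps) {
      if (n_acc == 0L && i >= 2L * adapt_every) {
        stop("no accepted moves after ", i,
             " steps; check bounds, starting point, or proposal scale")
      }
      ## estimate from the most recent half of the history so the poorly
      ## mixed opening phase does not dominate the proposal shape
      win <- seq.int(max(1L, floor(i / 2)), i)
      hist_cov <- stats::cov(samples[win, , drop = FALSE])
      sigma <- (2.38^2 / d) * hist_cov + diag(1e-10, d)
      ch <- tryCatch(chol(sigma), error = function(e) NULL)
      if (!is.null(ch)) chol_prop <- ch
    }
  }
  list(samples = samples, log_posterior = lp,
       acceptance_rate = n_acc / n_steps)
}

#' Run the adaptive MCMC sampler on a fit spec
#'
#' Samples the posterior implied by the fit spec's Gaussian likelihood and
#' its (log-)uniform priors.  Log-scaled parameters are sampled on the log
#' scale; the returned chain is on the natural scale.  The starting point
#' is drawn uniformly on the sampling scale within the bounds.
#'
#' @param spec a [fit_spec()].
#' @param n_steps chain length (default 30000; must be at least 10x the
#'   number of free parameters).
#' @param seed integer seed (mandatory: every chain is reproducible).
#' @param adapt_every adaptation interval.
#' @param burn_in_frac fraction of the chain discarded as burn-in for the
#'   stored summaries (default 0.2).
#' @param init optional named starting values (natural scale).
#' @return object of class `"posterior_chain"`: `samples` (natural-scale
#'   matrix with named columns), `log_posterior`, `acceptance_rate`,
#'   `burn_in`, `seed`, `summaries` (see [summarize_chain()]).
#' @export
run_mcmc <- function(spec, n_steps = 30000, seed, adapt_every = 500,
                     burn_in_frac = 0.2, init = NULL) {
  stopifnot(inherits(spec, "fit_spec"))
  if (missing(seed)) stop("'seed' is mandatory")
  free_names <- names(spec$free)
  d <- length(free_names)
  if (n_steps < 10 * d) stop("'n_steps' must be at least 10x the number of free parameters")
  is_log <- vapply(spec$free, function(f) f$scale == "log", logical(1))
  lo <- vapply(spec$free, function(f) f$bounds[1L], numeric(1))
  hi <- vapply(spec$free, function(f) f$bounds[2L], numeric(1))
  zlo <- ifelse(is_log, log(lo), lo)
  zhi <- ifelse(is_log, log(hi), hi)
  loglik <- make_loglik(spec)
  to_natural <- function(z) ifelse(is_log, exp(z), z)
  log_post <- function(z) {
    if (any(z < zlo | z > zhi)) return(-Inf)
    loglik(to_natural(z))
  }
  set.seed(as.integer(seed))
  z0 <- if (is.null(init)) stats::runif(d, zlo, zhi)
        else { v <- init[free_names]; ifelse(is_log, log(v), v) }
  ## multi-start mode-seeking refinement so the adaptive phase spends its
  ## budget exploring the posterior, not finding it (the likelihood surface
  ## has flat plateaus where a single simplex run can stall)
  starts <- c(list(z0),
              lapply(seq_len(7), function(i) stats::runif(d, zlo, zhi)))
  best_val <- -Inf
  best_par <- z0
  for (zs in starts) {
    opt <- tryCatch(
      if (d == 1L) {
        o <- stats::optimize(function(z) -log_post(z), c(zlo, zhi))
        list(par = o$minimum, value = o$objective)
      } else {
        stats::optim(zs, function(z) -log_post(z), method = "Nelder-Mead",
                     control = list(maxit = 400))
      },
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && -opt$value > best_val) {
      best_val <- -opt$value
      best_par <- opt$par
    }
    if (d == 1L) break
  }
  if (is.finite(best_val)) {
    zc <- pmin(pmax(best_par, zlo), zhi)
    z0 <- if (is.finite(log_post(zc))) zc else best_par
  }
  raw <- adaptive_metropolis(log_post, z0, n_steps,
                             seed = as.integer(seed) + 1L,
                             adapt_every = adapt_every)
  samples <- raw$samples
  for (j in seq_len(d)) if (is_log[j]) samples[, j] <- exp(samples[, j])
  colnames(samples) <- free_names
  burn_in <- floor(burn_in_frac * n_steps)
  chain <- structure(list(samples = samples,
                          log_posterior = raw$log_posterior,
                          acceptance_rate = raw$acceptance_rate,
                          burn_in = burn_in, seed = as.integer(seed)),
                     class = "posterior_chain")
  chain$summaries <- summarize_chain(chain, burn_in)
  chain
}

#' Posterior chain summaries
#'
#' Per-parameter posterior mean, SD and equal-tailed 95% credible interval
#' (2.5 and 97.5 percentiles) over the post-burn-in samples, plus the
#' pairwise sample correlations (the corner-plot statistics).
#'
#' @param chain a `"posterior_chain"`.
#' @param burn_in samples to discard from the front.
#' @return list with `table` (data frame: parameter, mean, sd, q2.5, q97.5)
#'   and `correlations` (matrix).
#' @export
summarize_chain <- function(chain, burn_in = chain$burn_in) {
  s <- chain$samples
  stopifnot(burn_in < nrow(s))
  post <- s[(burn_in + 1L):nrow(s), , drop = FALSE]
  qs <- apply(post, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  tab <- data.frame(parameter = colnames(s),
                    mean = colMeans(post),
                    sd = apply(post, 2L, stats::sd),
                    q2.5 = qs[1L, ], q97.5 = qs[2L, ],
                    row.names = NULL)
  corr <- if (ncol(post) > 1L) suppressWarnings(stats::cor(post)) else
    matrix(1, 1, 1, dimnames = list(colnames(s), colnames(s)))
  list(table = tab, correlations = corr)
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf("Posterior chain: %d steps (%d burn-in), %d parameter(s), acceptance %.1f%%\n",
              nrow(x$samples), x$burn_in, ncol(x$samples),
              100 * x$acceptance_rate))
  print(x$summaries$table, digits = 4)
  invisible(x)
}

#' Coefficient of variation of a parameter across constructs
#'
#' Sample standard deviation divided by the mean; the construct-to-construct
#' variability measure used to decide which activation parameters can be
#' shared across enhancer architectures.
#'
#' @param values numeric vector (>= 2 values) of one parameter's estimates
#'   across constructs.
#' @return dimensionless CV.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is zero")
  stats::sd(values) / m
}

#' Akaike Information Criterion
#'
#' `AIC = 2k - 2 * max_loglik`.  In this package `max_loglik` is the
#' maximum log posterior over the post-burn-in chain, which equals the
#' maximum log likelihood under the flat (log-)uniform priors used here.
#'
#' @param max_loglik maximized log likelihood.
#' @param k number of free parameters (>= 0).
#' @return AIC value.
#' @export
compute_aic <- function(max_loglik, k) {
  stopifnot(k >= 0)
  2 * k - 2 * max_loglik
}

#' Maximum log likelihood of a fitted chain
#'
#' @param chain a `"posterior_chain"`.
#' @return max log posterior over the post-burn-in samples.
#' @export
max_loglik_chain <- function(chain) {
  max(chain$log_posterior[(chain$burn_in + 1L):length(chain$log_posterior)])
}

#' Point estimate from a posterior chain
#'
#' Either the maximum-posterior sample (`"map"`, the best post-burn-in
#' chain sample) or the coordinate-wise posterior mean (`"mean"`).  For
#' weakly identified, ridge-shaped posteriors (the activation block's
#' `omega_bp`-`p`-`R` degeneracy) coordinate-wise means lie off the ridge
#' and misrepresent the fitted curve, so the cascade propagates the MAP
#' sample by default.
#'
#' @param chain a `"posterior_chain"`.
#' @param estimator `"map"` or `"mean"`.
#' @return named numeric of parameter values.
#' @export
chain_estimate <- function(chain, estimator = c("map", "mean")) {
  estimator <- match.arg(estimator)
  idx <- (chain$burn_in + 1L):nrow(chain$samples)
  if (estimator == "mean") return(colMeans(chain$samples[idx, , drop = FALSE]))
  best <- idx[which.max(chain$log_posterior[idx])]
  chain$samples[best, ]
}

#' Push posterior (or point) parameters through the model onto the AP axis
#'
#' Central prediction from the point parameters (typically posterior
#' means); optionally an equal-tailed credible band from pushing thinned
#' posterior draws of the free parameters through the model, per AP bin.
#'
#' @param arch an [enhancer_architecture()].
#' @param act an [activation_params()] (e.g. stage-A posterior means).
#' @param rep a [repression_params()] assembled from inherited posterior
#'   means and/or fixed values.
#' @param bicoid,runt input [concentration_profile()]s.
#' @param genotype `"runt_wt"` or `"runt_null"`.
#' @param chain optional `"posterior_chain"` whose columns name the free
#'   parameters to vary around `act`/`rep` for the band.
#' @param n_draws number of posterior draws pushed through the model.
#' @return a [rate_profile()] for the central curve, with attributes
#'   `"band_lower"` and `"band_upper"` when a chain is supplied.
#' @export
propagate_prediction <- function(arch, act, rep, bicoid, runt = NULL,
                                 genotype = "runt_wt", chain = NULL,
                                 n_draws = 200) {
  central <- predict_profile(bicoid, runt, arch, act, rep, genotype = genotype)
  if (is.null(chain)) return(central)
  post <- chain$samples[(chain$burn_in + 1L):nrow(chain$samples), , drop = FALSE]
  take <- unique(round(seq(1L, nrow(post), length.out = min(n_draws, nrow(post)))))
  preds <- vapply(take, function(i) {
    th <- post[i, ]
    ar <- apply_theta(stats::setNames(as.numeric(th), colnames(post)), act, rep)
    predict_profile(bicoid, runt, arch, ar$act, ar$rep, genotype = genotype)$mean
  }, numeric(nrow(central)))
  attr(central, "band_lower") <- apply(preds, 1L, stats::quantile, probs = 0.025)
  attr(central, "band_upper") <- apply(preds, 1L, stats::quantile, probs = 0.975)
  central
}

## Overlay a named theta vector onto activation/repression parameter objects.
apply_theta <- function(theta, act, rep) {
  for (nm in names(theta)) {
    v <- theta[[nm]]
    if (nm %in% c("Kb", "omega_bp", "p", "R")) act[[nm]] <- v
    else if (nm == "Kr") rep$Kr <- v
    else if (nm %in% c("omega_rrr", "omega_rrrp")) rep[[nm]] <- v
    else if (grepl("^omega_(rp|rr|rrp)_", nm)) {
      parts <- strsplit(sub("^omega_", "", nm), "_")[[1L]]
      rep[[paste0("omega_", parts[1L])]][[parts[2L]]] <- v
    } else if (startsWith(nm, "nu_")) {
      ## per-dataset scale nuisance: not part of the mechanistic model
      next
    } else stop("unknown parameter name: ", nm)
  }
  list(act = act, rep = rep)
}
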