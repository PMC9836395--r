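#' Configuration for the hierarchical inference cascade
#'
#' @param n_steps MCMC chain length per fit.
#' @param n_steps_scenario chain length for the stage-C scenario sweep
#'   (defaults to `n_steps`).
#' @param burn_in_frac,adapt_every passed to [run_mcmc()].
#' @param scenarios run the four-scenario AIC comparison in stage C.
#' @param shared_kr stage B fits one Kr shared across the three one-site
#'   constructs (the default); `FALSE` fits a per-construct Kr as a
#'   robustness check.
#' @param propagate point estimator used to fix parameters for later
#'   stages: `"map"` (maximum-posterior chain sample, the default; stays on
#'   the ridge of weakly identified posteriors) or `"mean"` (coordinate-wise
#'   posterior mean).
#' @param variance_mode likelihood error-scale handling for every fit in
#'   the cascade (see [fit_spec()]).
#' @param scale_nuisance profile out a per-dataset multiplicative scale in
#'   the wild-type stages (B-D), so repression parameters are inferred from
#'   profile shape; see [fit_spec()].  In stage A, where the level is the
#'   quantity being fit, the nuisance instead carries a lognormal prior
#'   whose SD is the profile's own relative level uncertainty, widening the
#'   level-coupled posteriors by the embryo-to-embryo variability.
#' @param propagate_uncertainty add the posterior-predictive variance of
#'   upstream point-fixed parameters (posterior draws pushed through the
#'   model) to the per-bin error budget of later stages.
#' @param bounds named list of prior bounds; entries `Kb`, `omega_bp`, `p`,
#'   `R`, `Kr`, `omega` (the latter applied to every cooperativity).
#' @param sem_floor likelihood SEM floor (AU/min); `NULL` = 2% of the data
#'   maximum per fit.
#' @return list of class `"cascade_config"`.
#' @export
cascade_config <- function(n_steps = 30000, n_steps_scenario = n_steps,
                           burn_in_frac = 0.2, adapt_every = 500,
                           scenarios = TRUE, shared_kr = TRUE,
                           propagate = c("map", "mean"),
                           variance_mode = c("fixed", "marginal"),
                           scale_nuisance = TRUE,
                           propagate_uncertainty = TRUE,
                           bounds = list(Kb = c(1, 1e3),
                                         omega_bp = c(1e-3, 1e3),
                                         p = c(1e-6, 1),
                                         R = c(1, 1e5),
                                         Kr = c(1, 1e4),
                                         omega = c(1e-3, 1e3)),
                           sem_floor = NULL) {
  structure(list(n_steps = n_steps, n_steps_scenario = n_steps_scenario,
                 burn_in_frac = burn_in_frac, adapt_every = adapt_every,
                 scenarios = scenarios, shared_kr = shared_kr,
                 propagate = match.arg(propagate),
                 variance_mode = match.arg(variance_mode),
                 scale_nuisance = scale_nuisance,
                 propagate_uncertainty = propagate_uncertainty,
                 bounds = bounds, sem_floor = sem_floor),
            class = "cascade_config")
}

## Deterministic per-fit seeds keyed to the canonical stage/construct slot,
## so input ordering cannot change any chain.
fit_seed <- function(master, stage, slot) {
  as.integer((as.double(master) * 1009 + stage * 131071 + slot * 127) %%
               2147483629) + 1L
}

## Gaussian log likelihood of a profile against a fixed prediction, in the
## same convention (fixed or marginalized error scale) as the MCMC fits it
## is compared against.
profile_loglik <- function(profile, pred, sem_floor,
                           variance_mode = "fixed") {
  keep <- !is.na(profile$mean)
  s <- pmax(profile$sem[keep], sem_floor)
  resid <- profile$mean[keep] - pred[keep]
  ssr <- sum(resid^2 / s^2)
  base <- -0.5 * sum(log(2 * pi * s^2))
  if (identical(variance_mode, "marginal")) {
    base - (length(resid) / 2) * log(ssr)
  } else {
    base - 0.5 * ssr
  }
}

floor_for <- function(profiles, config) {
  if (!is.null(config$sem_floor)) return(config$sem_floor)
  0.02 * max(vapply(profiles, function(p) max(p$mean, na.rm = TRUE), numeric(1)))
}


## Relative level uncertainty of a profile: the common-mode part of the
## embryo-to-embryo noise is bounded by the per-bin relative SEM in the
## high-signal region.
relative_level_sd <- function(profile) {
  hi <- which(!is.na(profile$mean) & profile$mean >= 0.5 * max(profile$mean, na.rm = TRUE))
  if (length(hi) == 0L) return(0)
  stats::median(profile$sem[hi] / profile$mean[hi])
}

## Per-bin variance of the model prediction induced by upstream posterior
## uncertainty: rows of each chain are pushed through the model around the
## point parameters and the across-draw variance is returned.
prediction_var <- function(arch, act, rep, bicoid, runt, genotype, chains,
                           n_draws = 100) {
  chains <- Filter(Negate(is.null), chains)
  if (length(chains) == 0L) return(NULL)
  idx <- lapply(chains, function(ch) {
    post <- (ch$burn_in + 1L):nrow(ch$samples)
    post[unique(round(seq(1L, length(post), length.out = n_draws)))]
  })
  nd <- min(vapply(idx, length, integer(1)))
  preds <- vapply(seq_len(nd), function(k) {
    a <- act; r <- rep
    for (j in seq_along(chains)) {
      row <- chains[[j]]$samples[idx[[j]][k], ]
      th <- stats::setNames(as.numeric(row), colnames(chains[[j]]$samples))
      ar <- apply_theta(th, a, r)
      a <- ar$act; r <- ar$rep
    }
    predict_profile(bicoid, runt, arch, a, r, genotype = genotype)$mean
  }, numeric(nrow(bicoid)))
  apply(preds, 1L, stats::var)
}

#' Stage A: per-construct activation fits on runt-null profiles
#'
#' Independent four-parameter fits (`Kb`, `omega_bp`, `p`, `R`) of the
#' no-repressor closed form to each construct's runt-null profile, plus the
#' across-construct coefficient-of-variation report used to justify which
#' parameters may be shared downstream.
#'
#' @param null_profiles named list of runt-null [rate_profile()]s (all
#'   eight constructs, or any subset named by construct id).
#' @param bicoid Bicoid [concentration_profile()].
#' @param config a [cascade_config()].
#' @param seed master seed.
#' @param activation_chains optional named list of stage-A posterior chains
#'   used to propagate activation-parameter uncertainty into the error
#'   budget (see `propagate_uncertainty` in [cascade_config()]).
#' @return list with `fits` (named list of `"thermo_fit"`), `activation`
#'   (named list of posterior-mean [activation_params()]) and `cv`
#'   (named numeric, CV of each parameter across constructs).
#' @export
stage_null_fits <- function(null_profiles, bicoid, config = cascade_config(),
                            seed = 1) {
  ids <- intersect(all_construct_ids(), names(null_profiles))
  if (length(ids) == 0L) stop("no runt-null profiles named by construct id")
  missing_ids <- setdiff(names(null_profiles), ids)
  if (length(missing_ids)) stop("unknown construct id(s): ",
                                paste(missing_ids, collapse = ", "))
  b <- config$bounds
  free <- list(Kb = b$Kb, omega_bp = b$omega_bp, p = b$p, R = b$R)
  fits <- list()
  for (k in seq_along(ids)) {
    id <- ids[k]
    tau <- relative_level_sd(null_profiles[[id]])
    fits[[id]] <- thermo_fit(null_profiles[[id]], bicoid, free = free,
                             sem_floor = config$sem_floor,
                             variance_mode = config$variance_mode,
                             scale_nuisance = config$scale_nuisance && tau > 0,
                             nu_prior_sd = if (tau > 0) tau else NULL,
                             n_steps = config$n_steps,
                             seed = fit_seed(seed, 1L, match(id, all_construct_ids())),
                             adapt_every = config$adapt_every,
                             burn_in_frac = config$burn_in_frac)
  }
  activation <- lapply(ids, function(id) {
    m <- chain_estimate(fits[[id]]$chain, config$propagate)
    activation_params(m[["Kb"]], m[["omega_bp"]], m[["p"]], m[["R"]])
  })
  means <- vapply(activation, function(a)
    c(Kb = a$Kb, omega_bp = a$omega_bp, p = a$p, R = a$R), numeric(4))
  names(activation) <- ids
  cv <- if (length(ids) > 1L) apply(means, 1L, coefficient_of_variation)
        else stats::setNames(rep(NA_real_, 4L), rownames(means))
  list(fits = fits, activation = activation, cv = cv)
}

#' Stage B: shared-Kr fit of the one-site constructs
#'
#' Joint fit of the wild-type profiles of the three one-site constructs
#' (\[100\], \[010\], \[001\]) with one shared Runt dissociation constant
#' `Kr` and a construct-specific Runt-RNAP term `omega_rp` per site,
#' holding each construct's activation parameters at the stage-A posterior
#' means.  With `config$shared_kr = FALSE` each construct is fit separately
#' with its own Kr (the robustness variant).
#'
#' @param wt_profiles named list of runt-wt [rate_profile()]s including
#'   `"100"`, `"010"`, `"001"`.
#' @param activation stage-A posterior-mean activation parameters.
#' @param bicoid,runt input concentration profiles.
#' @inheritParams stage_null_fits
#' @return list with `fit` (or `fits` in the per-construct variant) and
#'   `repression`: a [repression_params()] holding the posterior-mean `Kr`
#'   and `omega_rp`, with all higher-order terms still neutral.
#' @export
stage_one_site <- function(wt_profiles, activation, bicoid, runt,
                           config = cascade_config(), seed = 1,
                           activation_chains = NULL) {
  ids <- c("100", "010", "001")
  miss <- setdiff(ids, names(wt_profiles))
  if (length(miss)) stop("missing one-site wt profile(s): ",
                         paste(miss, collapse = ", "))
  miss_act <- setdiff(ids, names(activation))
  if (length(miss_act)) stop("stage A incomplete: no activation parameters for ",
                             paste(miss_act, collapse = ", "))
  b <- config$bounds
  site_of <- c("100" = "1", "010" = "2", "001" = "3")
  extra_var <- NULL
  if (config$propagate_uncertainty && !is.null(activation_chains)) {
    rep0 <- repression_params(Kr = 1)
    extra_var <- lapply(stats::setNames(ids, ids), function(id)
      prediction_var(enhancer_architecture(id), activation[[id]], rep0,
                     bicoid, NULL, "runt_null",
                     chains = activation_chains[id]))
  }
  if (config$shared_kr) {
    free <- c(list(Kr = b$Kr),
              stats::setNames(rep(list(b$omega), 3L),
                              paste0("omega_rp_", site_of[ids])))
    fit <- thermo_fit(wt_profiles[ids], bicoid, runt, free = free,
                      activation = activation[ids],
                      sem_floor = config$sem_floor, extra_var = extra_var,
                      scale_nuisance = config$scale_nuisance,
                      variance_mode = config$variance_mode,
                      n_steps = config$n_steps,
                      seed = fit_seed(seed, 2L, 1L),
                      adapt_every = config$adapt_every,
                      burn_in_frac = config$burn_in_frac)
    cf <- chain_estimate(fit$chain, config$propagate)
    repression <- repression_params(
      Kr = cf[["Kr"]],
      omega_rp = c("1" = cf[["omega_rp_1"]], "2" = cf[["omega_rp_2"]],
                   "3" = cf[["omega_rp_3"]]))
    list(fit = fit, repression = repression)
  } else {
    fits <- list()
    wrp <- c("1" = 1, "2" = 1, "3" = 1)
    kr <- numeric(0)
    for (k in seq_along(ids)) {
      id <- ids[k]
      free <- stats::setNames(list(b$Kr, b$omega),
                              c("Kr", paste0("omega_rp_", site_of[[id]])))
      fits[[id]] <- thermo_fit(wt_profiles[[id]], bicoid, runt, free = free,
                               activation = activation[id],
                               sem_floor = config$sem_floor,
                               extra_var = extra_var,
                               scale_nuisance = config$scale_nuisance,
                               variance_mode = config$variance_mode,
                               n_steps = config$n_steps,
                               seed = fit_seed(seed, 2L, k + 1L),
                               adapt_every = config$adapt_every,
                               burn_in_frac = config$burn_in_frac)
      cf <- chain_estimate(fits[[id]]$chain, config$propagate)
      wrp[[site_of[[id]]]] <- cf[[paste0("omega_rp_", site_of[[id]])]]
      kr[[id]] <- cf[["Kr"]]
    }
    repression <- repression_params(Kr = mean(kr), omega_rp = wrp)
    list(fits = fits, per_construct_Kr = kr, repression = repression)
  }
}

#' Stage C: two-site predictions, scenario comparison, final cooperativities
#'
#' For each two-site construct (\[011\], \[101\], \[110\]): (i) the
#' parameter-free prediction with neutral cooperativities
#' (`omega_rr = omega_rrp = 1`), every other parameter inherited from
#' stages A-B; (ii) optionally, fits under the four nested scenarios
#' (independent, Runt-Runt only, Runt-Runt-RNAP only, both) compared by
#' AIC on that construct's data; (iii) the final inference, in which
#' `omega_rr` is fixed to 1 for \[011\] and \[101\] and only \[110\] frees
#' both `omega_rr` and `omega_rrp`.
#'
#' @param wt_profiles named list of runt-wt [rate_profile()]s including the
#'   two-site constructs.
#' @param activation stage-A activation parameters.
#' @param repression stage-B posterior-mean [repression_params()].
#' @param upstream_chains optional list with elements `activation` (named
#'   list of stage-A chains) and `one_site` (stage-B chain) used for
#'   upstream uncertainty propagation.
#' @inheritParams stage_one_site
#' @return list with per-construct elements: `prediction` (parameter-free
#'   curve), `comparison` (data frame scenario/k/max_loglik/aic, when
#'   enabled), `final_fit`, and the updated `repression` carrying the
#'   posterior-mean pair cooperativities.
#' @export
stage_two_site <- function(wt_profiles, activation, repression, bicoid, runt,
                           config = cascade_config(), seed = 1,
                           upstream_chains = NULL) {
  ids <- c("011", "101", "110")
  miss <- setdiff(ids, names(wt_profiles))
  if (length(miss)) stop("missing two-site wt profile(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(repression)) stop("stage B incomplete: no repression parameters")
  b <- config$bounds
  out <- list()
  rep_final <- repression
  for (k in seq_along(ids)) {
    id <- ids[k]
    arch <- enhancer_architecture(id)
    act <- activation[[id]]
    if (is.null(act)) stop("stage A incomplete: no activation parameters for ", id)
    pk <- construct_pair_key(id)
    sites <- arch$sites
    extra_var <- NULL
    if (config$propagate_uncertainty && !is.null(upstream_chains)) {
      ev <- prediction_var(arch, act, repression, bicoid, runt, "runt_wt",
                           chains = c(upstream_chains$activation[id],
                                      list(upstream_chains$one_site)))
      extra_var <- stats::setNames(list(ev), id)
    }
    inherited <- c(
      Kr = repression$Kr,
      stats::setNames(repression$omega_rp[as.character(sites)],
                      paste0("omega_rp_", sites)))
    prediction <- predict_profile(bicoid, runt, arch, act, repression,
                                  genotype = "runt_wt")
    comparison <- NULL
    if (config$scenarios) {
      scen <- list(
        independent = character(0),
        rr_only = paste0("omega_rr_", pk),
        rrp_only = paste0("omega_rrp_", pk),
        rr_and_rrp = c(paste0("omega_rr_", pk), paste0("omega_rrp_", pk)))
      rows <- lapply(seq_along(scen), function(si) {
        pars <- scen[[si]]
        k_eff <- length(pars) + as.integer(config$scale_nuisance)
        if (length(pars) == 0L && !config$scale_nuisance) {
          ## pure parameter-free curve: likelihood evaluated, nothing fit
          ml <- profile_loglik(wt_profiles[[id]], prediction$mean,
                               floor_for(wt_profiles[id], config),
                               config$variance_mode)
        } else {
          f <- thermo_fit(wt_profiles[[id]], bicoid, runt,
                          free = stats::setNames(rep(list(b$omega), length(pars)), pars),
                          fixed = inherited, activation = activation[id],
                          sem_floor = config$sem_floor,
                          extra_var = extra_var,
                          scale_nuisance = config$scale_nuisance,
                          variance_mode = config$variance_mode,
                          n_steps = config$n_steps_scenario,
                          seed = fit_seed(seed, 3L, (k - 1L) * 10L + si),
                          adapt_every = config$adapt_every,
                          burn_in_frac = config$burn_in_frac)
          ml <- max_loglik_chain(f$chain)
        }
        data.frame(scenario = names(scen)[si], k = k_eff,
                   max_loglik = ml, aic = compute_aic(ml, k_eff))
      })
      comparison <- do.call(rbind, rows)
    }
    final_pars <- if (id == "110")
      c(paste0("omega_rr_", pk), paste0("omega_rrp_", pk))
    else paste0("omega_rrp_", pk)
    final_fit <- thermo_fit(wt_profiles[[id]], bicoid, runt,
                            free = stats::setNames(rep(list(b$omega), length(final_pars)),
                                                   final_pars),
                            fixed = inherited, activation = activation[id],
                            sem_floor = config$sem_floor,
                            extra_var = extra_var,
                            scale_nuisance = config$scale_nuisance,
                            variance_mode = config$variance_mode,
                            n_steps = config$n_steps,
                            seed = fit_seed(seed, 3L, (k - 1L) * 10L + 9L),
                            adapt_every = config$adapt_every,
                            burn_in_frac = config$burn_in_frac)
    cf <- chain_estimate(final_fit$chain, config$propagate)
    rep_final$omega_rrp[[pk]] <- cf[[paste0("omega_rrp_", pk)]]
    if (id == "110") rep_final$omega_rr[[pk]] <- cf[[paste0("omega_rr_", pk)]]
    out[[id]] <- list(prediction = prediction, comparison = comparison,
                      final_fit = final_fit, pair_key = pk)
  }
  out$repression <- rep_final
  out
}

#' Stage D: three-site prediction and the top higher-order cooperativity
#'
#' Parameter-free prediction for \[111\] inheriting every pairwise and
#' higher-order pair term from stages A-C (with `omega_rrr` and
#' `omega_rrrp` neutral), followed by the single-parameter inference of the
#' Runt-Runt-Runt-RNAP cooperativity `omega_rrrp` with `omega_rrr` fixed
#' at 1.
#'
#' @param wt_profile the \[111\] runt-wt [rate_profile()].
#' @param activation stage-A activation parameters (needs `"111"`).
#' @param repression stage-C posterior-mean [repression_params()].
#' @param upstream_chains optional list with elements `activation`,
#'   `one_site` and `two_site` (list of stage-C final chains) for upstream
#'   uncertainty propagation.
#' @inheritParams stage_one_site
#' @return list with `prediction`, `fit`, and `repression` updated with the
#'   posterior-mean `omega_rrrp`.
#' @export
stage_three_site <- function(wt_profile, activation, repression, bicoid, runt,
                             config = cascade_config(), seed = 1,
                             upstream_chains = NULL) {
  act <- activation[["111"]]
  if (is.null(act)) stop("stage A incomplete: no activation parameters for 111")
  if (is.null(repression)) stop("stages B-C incomplete: no repression parameters")
  arch <- enhancer_architecture("111")
  prediction <- predict_profile(bicoid, runt, arch, act, repression,
                                genotype = "runt_wt")
  extra_var <- NULL
  if (config$propagate_uncertainty && !is.null(upstream_chains)) {
    ev <- prediction_var(arch, act, repression, bicoid, runt, "runt_wt",
                         chains = c(upstream_chains$activation["111"],
                                    list(upstream_chains$one_site),
                                    upstream_chains$two_site))
    extra_var <- list("111" = ev)
  }
  inherited <- c(
    Kr = repression$Kr,
    stats::setNames(repression$omega_rp, paste0("omega_rp_", names(repression$omega_rp))),
    stats::setNames(repression$omega_rr, paste0("omega_rr_", names(repression$omega_rr))),
    stats::setNames(repression$omega_rrp, paste0("omega_rrp_", names(repression$omega_rrp))),
    omega_rrr = 1)
  fit <- thermo_fit(wt_profile, bicoid, runt,
                    free = list(omega_rrrp = config$bounds$omega),
                    fixed = inherited, activation = activation["111"],
                    sem_floor = config$sem_floor, extra_var = extra_var,
                    scale_nuisance = config$scale_nuisance,
                    variance_mode = config$variance_mode,
                    n_steps = config$n_steps,
                    seed = fit_seed(seed, 4L, 1L),
                    adapt_every = config$adapt_every,
                    burn_in_frac = config$burn_in_frac)
  rep_final <- repression
  rep_final$omega_rrrp <- chain_estimate(fit$chain, config$propagate)[["omega_rrrp"]]
  list(prediction = prediction, fit = fit, repression = rep_final)
}

#' Run the full hierarchical fix-then-infer cascade
#'
#' Executes the four inference stages in order on a complete study bundle
#' (all eight constructs in both genotypes plus the TF input profiles):
#' activation parameters from runt-null data, then shared `Kr` and per-site
#' `omega_rp` from the one-site constructs, then pairwise and higher-order
#' pair cooperativities (with the scenario AIC sweep) from the two-site
#' constructs, then `omega_rrrp` from \[111\].  Parameters fixed at each
#' stage propagate as posterior means; provenance records which stage fixed
#' every parameter.  Deterministic given `seed`.
#'
#' @param bundle a list as returned by [simulate_study()]: `bicoid`,
#'   `runt`, `profiles` (named `"<construct>_<genotype>"`).
#' @param config a [cascade_config()].
#' @param seed master seed.
#' @return object of class `"thermo_cascade"` with elements `stage_a` ..
#'   `stage_d`, `repression` (final posterior-mean parameters),
#'   `energy_table`, `provenance`, `cv`, `config`, `seed`.
#' @export
run_cascade <- function(bundle, config = cascade_config(), seed = 1) {
  need <- c(paste0(all_construct_ids(), "_runt_null"),
            paste0(all_construct_ids(), "_runt_wt"))
  miss <- setdiff(need, names(bundle$profiles))
  if (length(miss)) stop("incomplete bundle, missing profile(s): ",
                         paste(miss, collapse = ", "))
  nulls <- bundle$profiles[paste0(all_construct_ids(), "_runt_null")]
  names(nulls) <- all_construct_ids()
  wts <- bundle$profiles[paste0(all_construct_ids(), "_runt_wt")]
  names(wts) <- all_construct_ids()

  stage_a <- stage_null_fits(nulls, bundle$bicoid, config, seed)
  a_chains <- lapply(stage_a$fits, `[[`, "chain")
  stage_b <- stage_one_site(wts, stage_a$activation, bundle$bicoid,
                            bundle$runt, config, seed,
                            activation_chains = a_chains)
  b_chain <- if (!is.null(stage_b$fit)) stage_b$fit$chain else NULL
  stage_c <- stage_two_site(wts, stage_a$activation, stage_b$repression,
                            bundle$bicoid, bundle$runt, config, seed,
                            upstream_chains = list(activation = a_chains,
                                                   one_site = b_chain))
  c_chains <- lapply(c("011", "101", "110"), function(id)
    stage_c[[id]]$final_fit$chain)
  stage_d <- stage_three_site(wts[["111"]], stage_a$activation,
                              stage_c$repression, bundle$bicoid,
                              bundle$runt, config, seed,
                              upstream_chains = list(activation = a_chains,
                                                     one_site = b_chain,
                                                     two_site = c_chains))

  provenance <- rbind(
    data.frame(parameter = paste0(rep(c("Kb", "omega_bp", "p", "R"),
                                      each = length(stage_a$activation)),
                                  "[", names(stage_a$activation), "]"),
               stage = "A", how = "inferred"),
    data.frame(parameter = c("Kr", "omega_rp_1", "omega_rp_2", "omega_rp_3"),
               stage = "B", how = "inferred"),
    data.frame(parameter = c("omega_rrp_23", "omega_rrp_13", "omega_rrp_12",
                             "omega_rr_12"),
               stage = "C", how = "inferred"),
    data.frame(parameter = c("omega_rr_23", "omega_rr_13"),
               stage = "C", how = "manual (set to 1)"),
    data.frame(parameter = "omega_rrr", stage = "D", how = "manual (set to 1)"),
    data.frame(parameter = "omega_rrrp", stage = "D", how = "inferred"))

  out <- structure(list(stage_a = stage_a, stage_b = stage_b,
                        stage_c = stage_c, stage_d = stage_d,
                        repression = stage_d$repression,
                        activation = stage_a$activation,
                        cv = stage_a$cv, provenance = provenance,
                        config = config, seed = as.integer(seed)),
                   class = "thermo_cascade")
  out$energy_table <- build_energy_table(out)
  out
}

#' Interaction free-energy table from a fitted cascade
#'
#' Converts every inferred Runt-related cooperativity to an interaction
#' free energy per posterior sample (`E = -ln(omega)`, kBT units) and
#' reports the posterior mean and SD; manually set neutral cooperativities
#' appear as 0 kBT with SD 0 and a `manually_set` flag.
#'
#' @param cascade a `"thermo_cascade"`.
#' @return data frame of class `"energy_table"` with columns `parameter`,
#'   `construct`, `energy_mean_kbt`, `energy_sd_kbt`, `manually_set`.
#' @export
build_energy_table <- function(cascade) {
  post_energy <- function(fit, par) {
    ch <- fit$chain
    e <- -log(ch$samples[(ch$burn_in + 1L):nrow(ch$samples), par])
    c(mean(e), stats::sd(e))
  }
  rows <- list()
  add <- function(parameter, construct, stats_, manual = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, construct = construct,
      energy_mean_kbt = stats_[1L], energy_sd_kbt = stats_[2L],
      manually_set = manual)
  }
  if (!is.null(cascade$stage_b$fit)) {
    for (s in c("3", "2", "1")) {
      cid <- c("3" = "001", "2" = "010", "1" = "100")[[s]]
      add("omega_rp", cid,
          post_energy(cascade$stage_b$fit, paste0("omega_rp_", s)))
    }
  }
  for (id in c("011", "110", "101")) {
    st <- cascade$stage_c[[id]]
    if (id == "110") {
      add("omega_rr", id, post_energy(st$final_fit, paste0("omega_rr_", st$pair_key)))
    } else {
      add("omega_rr", id, c(0, 0), manual = TRUE)
    }
    add("omega_rrp", id, post_energy(st$final_fit, paste0("omega_rrp_", st$pair_key)))
  }
  add("omega_rrr", "111", c(0, 0), manual = TRUE)
  add("omega_rrrp", "111", post_energy(cascade$stage_d$fit, "omega_rrrp"))
  out <- do.call(rbind, rows)
  class(out) <- c("energy_table", "data.frame")
  out
}

#' @export
print.thermo_cascade <- function(x, ...) {
  cat("Hierarchical thermodynamic-model cascade (seed ", x$seed, ")\n", sep = "")
  cat("Stage A coefficient of variation across constructs:\n")
  print(round(x$cv, 3))
  cat("\nFinal repression parameters (posterior means):\n")
  print(x$repression)
  cat("\nInteraction energies (kBT):\n")
  print(x$energy_table, digits = 3)
  invisible(x)
}

#' @export
summary.thermo_cascade <- function(object, ...) {
  comparisons <- lapply(c("011", "101", "110"), function(id)
    object$stage_c[[id]]$comparison)
  names(comparisons) <- c("011", "101", "110")
  list(cv = object$cv, energy_table = object$energy_table,
       comparisons = comparisons, provenance = object$provenance)
}
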