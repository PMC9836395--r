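## a small exact fit problem: noiseless data from known parameters
exact_problem <- function(sem = 1) {
  bic <- simulate_bicoid_profile(scale_sd = 0)
  act <- activation_params(Kb = 30, omega_bp = 100, p = 0.001, R = 3000)
  pred <- predict_profile(bic, NULL, enhancer_architecture("000"), act,
                          genotype = "runt_null")
  prof <- rate_profile(pred$ap_fraction, pred$mean, rep(sem, nrow(pred)),
                       construct_id = "000", genotype = "runt_null")
  list(bicoid = bic, act = act, profile = prof)
}

test_that("the Gaussian log likelihood matches its closed form and an oracle", {
  pb <- exact_problem(sem = 1)
  spec <- fit_spec(pb$profile, pb$bicoid, free = act_bounds, sem_floor = 1)
  n <- nrow(pb$profile)
  truth <- c(Kb = 30, omega_bp = 100, p = 0.001, R = 3000)
  # perfect fit with unit errors: -(n/2) log(2 pi)
  expect_equal(log_likelihood(truth, spec), -n / 2 * log(2 * pi),
               tolerance = 1e-9)
  # independent direct-summation oracle on random parameter draws
  set.seed(21)
  for (k in 1:10) {
    th <- c(Kb = exp(runif(1, 1, 5)), omega_bp = exp(runif(1, -2, 5)),
            p = exp(runif(1, -10, -1)), R = exp(runif(1, 2, 10)))
    act <- activation_params(th[["Kb"]], th[["omega_bp"]], th[["p"]], th[["R"]])
    pred <- predict_profile(pb$bicoid, NULL, enhancer_architecture("000"),
                            act, genotype = "runt_null")$mean
    oracle <- 0
    for (i in seq_len(n)) {
      oracle <- oracle - 0.5 * ((pb$profile$mean[i] - pred[i])^2 / 1 +
                                  log(2 * pi * 1))
    }
    expect_equal(log_likelihood(th, spec), oracle, tolerance = 1e-8)
  }
  # growing residuals always lower the likelihood
  worse <- truth; worse[["R"]] <- 3000 * 2
  worst <- truth; worst[["R"]] <- 3000 * 4
  expect_gt(log_likelihood(truth, spec), log_likelihood(worse, spec))
  expect_gt(log_likelihood(worse, spec), log_likelihood(worst, spec))
  # out-of-bounds parameters are rejected with -Inf, not an error
  oob <- truth; oob[["p"]] <- 2
  expect_identical(log_likelihood(oob, spec), -Inf)
  # dataset order does not change the joint likelihood
  pb2 <- exact_problem(sem = 2)
  prof2 <- pb2$profile; prof2$construct_id <- "100"
  s12 <- fit_spec(list(pb$profile, prof2), pb$bicoid, free = act_bounds,
                  sem_floor = 1)
  s21 <- fit_spec(list(prof2, pb$profile), pb$bicoid, free = act_bounds,
                  sem_floor = 1)
  expect_equal(log_likelihood(truth, s12), log_likelihood(truth, s21))
})

test_that("the adaptive sampler reproduces a known Gaussian target", {
  S <- matrix(c(1, 0.3, 0.3, 0.25), 2, 2)
  Sinv <- solve(S)
  lp <- function(z) -0.5 * drop(t(z - c(1, 2)) %*% Sinv %*% (z - c(1, 2)))
  out <- adaptive_metropolis(lp, init = c(0, 0), n_steps = 1e5, seed = 99)
  post <- out$samples[20001:1e5, ]
  expect_lt(abs(mean(post[, 1]) - 1), 3 * sqrt(1 / 1000))
  expect_lt(abs(mean(post[, 2]) - 2), 3 * sqrt(0.25 / 1000))
  C <- cov(post)
  expect_lt(norm(C - S, "F") / norm(S, "F"), 0.10)
  expect_gt(out$acceptance_rate, 0.05)
  expect_lt(out$acceptance_rate, 0.8)
})

test_that("chains are reproducible from their seed", {
  pb <- exact_problem(sem = 5)
  spec <- fit_spec(pb$profile, pb$bicoid, free = act_bounds)
  a <- run_mcmc(spec, n_steps = 1500, seed = 31)
  b <- run_mcmc(spec, n_steps = 1500, seed = 31)
  expect_identical(a$samples, b$samples)
  expect_identical(a$log_posterior, b$log_posterior)
  c <- run_mcmc(spec, n_steps = 1500, seed = 32)
  expect_false(identical(a$samples, c$samples))
})

test_that("noiseless activation fits recover the identifiable structure", {
  pb <- exact_problem(sem = 1)
  prof <- pb$profile; prof$sem <- rep(0, nrow(prof))
  fit <- thermo_fit(prof, pb$bicoid, free = act_bounds, n_steps = 8000,
                    seed = 12)
  tab <- fit$chain$summaries$table
  # the Bicoid dissociation constant is sharply identified
  expect_lt(abs(tab$mean[tab$parameter == "Kb"] / 30 - 1), 0.05)
  # p and R are identified up to the omega_bp ridge: truth inside the CI
  for (pp in c("p", "R")) {
    row <- tab[tab$parameter == pp, ]
    tv <- c(p = 0.001, R = 3000)[[pp]]
    expect_gte(tv, row$q2.5)
    expect_lte(tv, row$q97.5)
  }
  # the fitted curve reproduces the data profile (deviations small on the
  # scale of the expression amplitude)
  pred <- predict(fit, which = 1)
  expect_lt(max(abs(pred$mean - prof$mean)) / max(prof$mean), 0.02)
})

test_that("chain summaries match direct quantile computations", {
  set.seed(5)
  fake <- structure(list(
    samples = cbind(a = rnorm(4000, 3, 0.5), b = rexp(4000)),
    log_posterior = rnorm(4000), burn_in = 1000L, seed = 1L),
    class = "posterior_chain")
  sm <- summarize_chain(fake, burn_in = 1000L)
  post <- fake$samples[1001:4000, ]
  expect_equal(sm$table$mean, unname(colMeans(post)))
  expect_equal(sm$table$q2.5, unname(apply(post, 2, quantile, 0.025)),
               tolerance = 1e-12)
  expect_equal(sm$table$q97.5, unname(apply(post, 2, quantile, 0.975)),
               tolerance = 1e-12)
  expect_equal(sm$correlations[1, 2], cor(post)[1, 2])
  # a constant chain has zero spread
  const <- structure(list(samples = cbind(a = rep(2, 100)),
                          log_posterior = rep(0, 100), burn_in = 10L,
                          seed = 1L), class = "posterior_chain")
  expect_identical(summarize_chain(const, 10L)$table$sd, 0)
})

test_that("coefficient of variation and AIC follow their definitions", {
  expect_equal(coefficient_of_variation(c(1, 2, 3)), sd(1:3) / 2)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 0.5)
  expect_identical(coefficient_of_variation(rep(4, 6)), 0)
  expect_equal(coefficient_of_variation(5 * c(1, 2, 3)),
               coefficient_of_variation(c(1, 2, 3)))
  expect_error(coefficient_of_variation(c(-1, 1)), "mean")
  expect_error(coefficient_of_variation(3), "2 values")
  expect_identical(compute_aic(0, 0), 0)
  ll <- -12.5
  expect_equal(compute_aic(ll, 3) - compute_aic(ll, 2), 2)
})

test_that("posterior predictions carry credible bands that bracket the center", {
  pb <- exact_problem(sem = 5)
  prof <- pb$profile
  set.seed(8)
  prof$mean <- prof$mean * (1 + rnorm(nrow(prof), 0, 0.03))
  fit <- thermo_fit(prof, pb$bicoid, free = act_bounds, n_steps = 4000,
                    seed = 3)
  pred <- predict(fit, band = TRUE)
  lo <- attr(pred, "band_lower"); hi <- attr(pred, "band_upper")
  expect_true(all(lo <= hi))
  # the band brackets the posterior-median-ish central curve at most bins
  expect_true(mean(pred$mean >= lo & pred$mean <= hi) > 0.8)
  # a degenerate "posterior" yields a zero-width band
  const_chain <- fit$chain
  mid <- fit$chain$samples[nrow(fit$chain$samples), , drop = FALSE]
  const_chain$samples <- mid[rep(1, 500), , drop = FALSE]
  const_chain$burn_in <- 100L
  pars <- runtcoop:::resolve_params(fit, "000")
  pc <- propagate_prediction(enhancer_architecture("000"), pars$act, pars$rep,
                             pb$bicoid, NULL, genotype = "runt_null",
                             chain = const_chain)
  expect_equal(attr(pc, "band_lower"), attr(pc, "band_upper"),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("scale-nuisance fits decouple profile shape from overall level", {
  pb <- exact_problem(sem = 3)
  prof <- pb$profile
  prof$mean <- prof$mean * 1.3  # a pure common-mode level shift
  fit <- thermo_fit(prof, pb$bicoid,
                    free = list(Kb = c(1, 1e3)),
                    fixed = c(omega_bp = 100, p = 0.001, R = 3000),
                    scale_nuisance = TRUE, n_steps = 3000, seed = 7)
  cf <- coef(fit)
  expect_lt(abs(cf[["nu_000"]] / 1.3 - 1), 0.05)
  expect_lt(abs(cf[["Kb"]] / 30 - 1), 0.05)
})
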