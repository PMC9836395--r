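test_that("architectures parse construct bit strings and validate them", {
  a <- enhancer_architecture("011")
  expect_identical(a$sites, c(2L, 3L))
  expect_identical(a$n_bicoid_sites, 6L)
  expect_identical(enhancer_architecture("000")$sites, integer(0))
  expect_error(enhancer_architecture("21"), "3-character")
  expect_error(enhancer_architecture("0111"), "3-character")
  expect_identical(construct_pair_key("011"), "23")
  expect_identical(construct_pair_key("101"), "13")
  expect_identical(construct_pair_key("110"), "12")
  expect_error(construct_pair_key("001"), "two Runt sites")
})

test_that("microstate enumeration has the right size and composition", {
  expect_length(enumerate_states(enhancer_architecture("000")), 4L)
  states1 <- enumerate_states(enhancer_architecture("001"))
  expect_length(states1, 8L)
  # one Runt site adds exactly four Runt-bound states
  expect_identical(sum(vapply(states1, function(s) length(s$runt_bound) > 0,
                              logical(1))), 4L)
  expect_length(enumerate_states(enhancer_architecture("111")), 32L)
  # all states distinct
  keys <- vapply(states1, function(s)
    paste(s$bicoid_bound, paste(s$runt_bound, collapse = ","), s$rnap_bound),
    character(1))
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("statistical weights follow the product rule over interaction terms", {
  act <- activation_params(Kb = 30, omega_bp = 3, p = 0.5, R = 1)
  rp <- repression_params(Kr = 100,
                          omega_rp = c("1" = 0.9, "2" = 0.5, "3" = 0.1),
                          omega_rr = c("12" = 2, "13" = 3, "23" = 4),
                          omega_rrp = c("12" = 5, "13" = 6, "23" = 7),
                          omega_rrr = 8, omega_rrrp = 9)
  inp <- dimensionless_inputs(b = 2, r = 3)
  # reference (empty) state has weight exactly 1
  expect_identical(state_weight(list(bicoid_bound = FALSE, runt_bound = integer(0),
                                     rnap_bound = FALSE), inp, act, rp), 1)
  # fully neutral interactions at unit occupancies give weight 1
  expect_equal(state_weight(list(bicoid_bound = FALSE, runt_bound = 1:3,
                                 rnap_bound = TRUE),
                            dimensionless_inputs(1, 1),
                            activation_params(1, 1, 1, 1),
                            repression_params(Kr = 1)), 1)
  # two Runt sites + Bicoid + RNAP: every pairwise term enters once
  w <- state_weight(list(bicoid_bound = TRUE, runt_bound = c(2L, 3L),
                         rnap_bound = TRUE), inp, act, rp)
  expect_equal(w, 2^6 * 3^2 * 0.5 * 3 * 0.5 * 0.1 * 4 * 7, tolerance = 1e-12)
  # triple adds all three pairs plus the higher-order terms
  w3 <- state_weight(list(bicoid_bound = FALSE, runt_bound = 1:3,
                          rnap_bound = TRUE), inp, act, rp)
  expect_equal(w3, 3^3 * 0.5 * (0.9 * 0.5 * 0.1) * (2 * 3 * 4) *
                 (5 * 6 * 7) * 8 * 9, tolerance = 1e-12)
  expect_error(activation_params(Kb = -1, omega_bp = 1, p = 1, R = 1), "Kb")
  expect_error(repression_params(Kr = 100, omega_rp = c("1" = 0, "2" = 1, "3" = 1)),
               "omega_rp")
})

test_that("p_bound is a normalized probability and obeys analytic limits", {
  set.seed(11)
  for (k in 1:20) {
    pr <- draw_params()
    arch <- enhancer_architecture(sample(all_construct_ids(), 1))
    pb <- pbound_bruteforce(pr$inputs, arch, pr$act, pr$rep)
    expect_true(pb >= 0 && pb <= 1)
    # state probabilities sum to one
    states <- enumerate_states(arch)
    w <- vapply(states, state_weight, numeric(1), inputs = pr$inputs,
                act = pr$act, rep = pr$rep)
    expect_equal(sum(w / sum(w)), 1, tolerance = 1e-12)
  }
  # no RNAP occupancy factor, no bound RNAP
  act0 <- activation_params(Kb = 1, omega_bp = 3, p = 1e-300, R = 1)
  expect_lt(pbound_bruteforce(dimensionless_inputs(1, 0),
                              enhancer_architecture("000"), act0,
                              repression_params(Kr = 1)), 1e-250)
  # saturating Bicoid with no repressor: p*omega_bp / (1 + p*omega_bp)
  act <- activation_params(Kb = 1, omega_bp = 3, p = 0.001, R = 1)
  pb <- pbound_bruteforce(dimensionless_inputs(1e6, 0),
                          enhancer_architecture("000"), act,
                          repression_params(Kr = 1))
  expect_equal(pb, 0.003 / 1.003, tolerance = 1e-8)
})

test_that("closed forms agree with brute-force enumeration over random draws", {
  set.seed(101)
  for (id in all_construct_ids()) {
    arch <- enhancer_architecture(id)
    for (k in 1:200) {
      pr <- draw_params()
      a <- rate_closed_form(pr$inputs, arch, pr$act, pr$rep)
      b <- rate_bruteforce(pr$inputs, arch, pr$act, pr$rep)
      expect_lt(abs(a - b), 1e-10)
    }
  }
})

test_that("limit reductions collapse to the simpler formula exactly", {
  set.seed(7)
  b <- exp(runif(9, -3, 3))
  act <- activation_params(Kb = 30, omega_bp = 100, p = 0.002, R = 240)
  rp <- repression_params(Kr = 100,
                          omega_rp = c("1" = 0.8, "2" = 0.3, "3" = 0.1),
                          omega_rr = c("12" = 2, "13" = 0.5, "23" = 1.5),
                          omega_rrp = c("12" = 0.2, "13" = 4, "23" = 0.7),
                          omega_rrr = 3, omega_rrrp = 0.4)
  base <- rate_closed_form(dimensionless_inputs(b, 0),
                           enhancer_architecture("000"), act, rp)
  # repressor absent: every architecture reduces to the activation-only form
  for (id in all_construct_ids()) {
    expect_equal(rate_closed_form(dimensionless_inputs(b, 0),
                                  enhancer_architecture(id), act, rp),
                 base, tolerance = 1e-12)
  }
  # unsupported site counts are refused at the closed form
  expect_error(rate_closed_form(dimensionless_inputs(1, 1),
                                structure(list(construct_id = "xx",
                                               sites = 1:4,
                                               n_bicoid_sites = 6L),
                                          class = "enhancer_architecture"),
                                act, rp), "site count")
})

test_that("neutral cooperativities factorize into the independent-repression form", {
  b <- c(0.05, 0.4, 2, 9)
  r <- c(0.1, 0.6, 1.3, 3)
  act <- activation_params(Kb = 30, omega_bp = 100, p = 0.002, R = 240)
  w1 <- 0.8; w2 <- 0.3; w3 <- 0.1
  rp_neutral <- repression_params(Kr = 100,
                                  omega_rp = c("1" = w1, "2" = w2, "3" = w3))
  # one site, omega_rp = 1: identical to the zero-site rate
  rp_unit <- repression_params(Kr = 100, omega_rp = c("1" = w1, "2" = 1, "3" = w3))
  expect_equal(rate_closed_form(dimensionless_inputs(b, r),
                                enhancer_architecture("010"), act, rp_unit),
               rate_closed_form(dimensionless_inputs(b, r * 0),
                                enhancer_architecture("000"), act, rp_unit),
               tolerance = 1e-12)
  # two sites, neutral pair terms: product form written out independently
  p <- act$p; wbp <- act$omega_bp; R <- act$R; b6 <- b^6
  num <- p * (1 + b6 * wbp) * (1 + r * w2) * (1 + r * w3)
  den <- (1 + b6) * (1 + r)^2 + num
  expect_equal(rate_closed_form(dimensionless_inputs(b, r),
                                enhancer_architecture("011"), act, rp_neutral),
               R * num / den, tolerance = 1e-12)
  # three sites, all higher-order terms neutral: pairwise-only model built
  # from an explicit subset sum in this test
  rp3 <- repression_params(Kr = 100,
                           omega_rp = c("1" = w1, "2" = w2, "3" = w3),
                           omega_rr = c("12" = 2, "13" = 0.5, "23" = 1.5),
                           omega_rrp = c("12" = 0.2, "13" = 4, "23" = 0.7),
                           omega_rrr = 1, omega_rrrp = 1)
  on3 <- 1 + r * (w1 + w2 + w3) +
    r^2 * (w1 * w2 * 2 * 0.2 + w1 * w3 * 0.5 * 4 + w2 * w3 * 1.5 * 0.7) +
    r^3 * w1 * w2 * w3 * (2 * 0.5 * 1.5) * (0.2 * 4 * 0.7)
  off3 <- 1 + 3 * r + r^2 * (2 + 0.5 + 1.5) + r^3 * 2 * 0.5 * 1.5
  num3 <- p * (1 + b6 * wbp) * on3
  expect_equal(rate_closed_form(dimensionless_inputs(b, r),
                                enhancer_architecture("111"), act, rp3),
               R * num3 / ((1 + b6) * off3 + num3), tolerance = 1e-12)
})

test_that("rate is monotone in the inputs under repressive interactions", {
  act <- activation_params(Kb = 30, omega_bp = 100, p = 0.002, R = 240)
  rp <- repression_params(Kr = 100,
                          omega_rp = c("1" = 0.8, "2" = 0.3, "3" = 0.1),
                          omega_rr = c("12" = 0.9, "13" = 0.5, "23" = 1),
                          omega_rrp = c("12" = 0.2, "13" = 0.7, "23" = 0.6),
                          omega_rrr = 0.8, omega_rrrp = 0.5)
  r_grid <- seq(0, 5, length.out = 40)
  b_grid <- seq(0.01, 5, length.out = 40)
  for (id in c("001", "110", "111")) {
    arch <- enhancer_architecture(id)
    rates_r <- rate_closed_form(dimensionless_inputs(rep(1.5, 40), r_grid),
                                arch, act, rp)
    expect_true(all(diff(rates_r) <= 1e-12))
    rates_b <- rate_closed_form(dimensionless_inputs(b_grid, rep(0.8, 40)),
                                arch, act, rp)
    expect_true(all(diff(rates_b) >= -1e-12))
  }
})

test_that("profile predictions follow the TF inputs and repression strength", {
  bic <- simulate_bicoid_profile()
  run <- simulate_runt_profile()
  act <- activation_params(Kb = 30, omega_bp = 100, p = 0.001, R = 1)
  arch1 <- enhancer_architecture("001")
  # zero Runt input equals the runt-null prediction
  run0 <- simulate_runt_profile(runt_null = TRUE)
  rp <- repression_params(Kr = 100, omega_rp = c("1" = 1, "2" = 1, "3" = 0.1))
  expect_equal(predict_profile(bic, run0, arch1, act, rp)$mean,
               predict_profile(bic, NULL, arch1, act, rp,
                               genotype = "runt_null")$mean,
               tolerance = 1e-12)
  # monotone-decreasing Bicoid with no repressor gives a non-increasing profile
  null_prof <- predict_profile(bic, NULL, arch1, act, rp, genotype = "runt_null")
  expect_true(all(diff(null_prof$mean) <= 1e-12))
  # weakening the Runt-RNAP interaction from 1 down to 0.01 lowers the
  # profile pointwise
  prev <- NULL
  for (w in c(1, 0.3, 0.1, 0.01)) {
    rp_w <- repression_params(Kr = 100, omega_rp = c("1" = 1, "2" = 1, "3" = w))
    cur <- predict_profile(bic, run, arch1, act, rp_w)$mean
    if (!is.null(prev)) expect_true(all(cur <= prev + 1e-12))
    prev <- cur
  }
  # mismatched grids are refused
  bic_short <- simulate_bicoid_profile(grid = seq(0.2, 0.5, by = 0.025))
  expect_error(predict_profile(bic_short, run, arch1, act, rp), "grid")
})

test_that("cooperativities and interaction energies are Boltzmann inverses", {
  expect_identical(energy_from_omega(1), 0)
  expect_equal(abs(energy_from_omega(857)), 6.753, tolerance = 1e-3)
  expect_equal(omega_from_energy(2.34), 0.0963, tolerance = 1e-3)
  # omega < 1 disfavors: positive energy
  expect_gt(energy_from_omega(0.3), 0)
  omegas <- 10^seq(-6, 6, length.out = 25)
  expect_equal(omega_from_energy(energy_from_omega(omegas)), omegas,
               tolerance = 1e-12)
  expect_error(energy_from_omega(0), "positive")
  expect_error(energy_from_omega(-2), "positive")
})

test_that("pairwise cooperativity can phenocopy the higher-order channel", {
  # under the study's input range (r between ~0.15 and ~1.2), the best
  # omega_rr-only curve tracks a pure-omega_rrp curve to within a few
  # percent -- the observational near-degeneracy that limits AIC channel
  # attribution (see the methods vignette)
  truth <- default_ground_truth()
  bic <- simulate_bicoid_profile()
  run <- simulate_runt_profile()
  for (case in list(list(id = "110", wrrp = exp(-4.15)),
                    list(id = "011", wrrp = exp(2.09)))) {
    arch <- enhancer_architecture(case$id)
    act <- truth$activation[[case$id]]
    pk <- construct_pair_key(case$id)
    pure <- truth$repression
    pure$omega_rr[] <- 1
    pure$omega_rrp[] <- 1
    pure$omega_rrp[[pk]] <- case$wrrp
    target <- predict_profile(bic, run, arch, act, pure)$mean
    dev <- function(lw) {
      alt <- pure
      alt$omega_rrp[[pk]] <- 1
      alt$omega_rr[[pk]] <- exp(lw)
      max(abs(predict_profile(bic, run, arch, act, alt)$mean / target - 1))
    }
    best <- optimize(dev, c(-8, 8))
    expect_lt(best$objective, 0.05)
  }
})
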