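## Shared fixtures: everything is generated in code, nothing read from disk.

act_bounds <- list(Kb = c(1, 1e3), omega_bp = c(1e-3, 1e3),
                   p = c(1e-6, 1), R = c(1, 1e5))

## log-uniform random parameter draws for oracle cross-checks
draw_params <- function() {
  lu <- function(n = 1) exp(stats::runif(n, log(1e-3), log(1e3)))
  list(act = activation_params(Kb = lu(), omega_bp = lu(), p = lu(), R = 1),
       rep = repression_params(Kr = lu(),
                               omega_rp = stats::setNames(lu(3), c("1", "2", "3")),
                               omega_rr = stats::setNames(lu(3), c("12", "13", "23")),
                               omega_rrp = stats::setNames(lu(3), c("12", "13", "23")),
                               omega_rrr = lu(), omega_rrrp = lu()),
       inputs = dimensionless_inputs(b = lu(), r = lu()))
}

## noiseless study bundle (exact model curves, sem = 0)
noiseless_truth <- function() {
  tr <- default_ground_truth()
  tr$scale_sd <- 0
  tr$additive_sd <- 0
  tr
}

## ground truth with all cooperativities neutral
neutral_truth <- function() {
  tr <- default_ground_truth()
  tr$repression$omega_rr[] <- 1
  tr$repression$omega_rrp[] <- 1
  tr$repression$omega_rrr <- 1
  tr$repression$omega_rrrp <- 1
  tr
}

quick_config <- function(...) {
  cascade_config(n_steps = 2000, n_steps_scenario = 1000, adapt_every = 250, ...)
}
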