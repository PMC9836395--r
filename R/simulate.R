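#' Ground truth for the synthetic-embryo generator
#'
#' Bundles everything the simulator needs: one set of activation parameters
#' per construct, the shared repression parameters, and the noise model
#' (embryo-level multiplicative scale SD plus position-level additive SD,
#' both Gaussian).  Serialized as a YAML sidecar next to every simulated
#' dataset so a dataset can be regenerated bit-identically.
#'
#' @param activation named list (by construct id) of [activation_params()].
#' @param repression a [repression_params()].
#' @param scale_sd embryo-to-embryo multiplicative noise SD (dimensionless).
#' @param additive_sd position-level additive noise SD (AU/min).
#' @return object of class `"ground_truth"`.
#' @export
ground_truth <- function(activation, repression, scale_sd = 0.15,
                         additive_sd = 5) {
  stopifnot(is.list(activation), inherits(repression, "repression_params"),
            scale_sd >= 0, additive_sd >= 0)
  lapply(activation, function(a) stopifnot(inherits(a, "activation_params")))
  structure(list(activation = activation, repression = repression,
                 scale_sd = scale_sd, additive_sd = additive_sd),
            class = "ground_truth")
}

#' Default synthetic ground truth at literature-like magnitudes
#'
#' Activation base: `Kb = 30` AU, `omega_bp = 100`, `p = 0.001`, with `R`
#' scaled so anterior initial rates are a few hundred AU/min.  The
#' RNAP-dependent parameters `p` and `R` carry fixed per-construct
#' multipliers with a ~40% coefficient of variation (the \[001\] construct
#' runs at roughly twice the unrepressed rate of \[000\]); `Kb` and
#' `omega_bp` are shared exactly.  Repression truths sit at the magnitudes
#' of the inferred interaction-energy table: `Kr = 100` AU,
#' `omega_rp = exp(-(2.34, 1.36, 0.18))` for the proximal/middle/distal
#' sites, `omega_rr = exp(0.95)` for the \{1,2\} pair (neutral otherwise),
#' `omega_rrp = exp(-(-2.09, -1.12, 4.15))` keyed to the \{2,3\}, \{1,3\},
#' \{1,2\} pairs, `omega_rrr = 1`, `omega_rrrp = exp(2.12)`.
#'
#' @return a [ground_truth()].
#' @export
default_ground_truth <- function() {
  ids <- all_construct_ids()
  r_mult <- c("000" = 1.0, "100" = 0.8, "010" = 1.3, "001" = 1.9,
              "011" = 1.1, "101" = 0.7, "110" = 1.5, "111" = 1.2)
  p_mult <- c("000" = 1.0, "100" = 1.4, "010" = 0.75, "001" = 1.2,
              "011" = 0.9, "101" = 1.5, "110" = 0.8, "111" = 1.1)
  activation <- lapply(ids, function(id) {
    activation_params(Kb = 30, omega_bp = 100,
                      p = 0.001 * p_mult[[id]],
                      R = 3000 * r_mult[[id]])
  })
  names(activation) <- ids
  repression <- repression_params(
    Kr = 100,
    omega_rp = c("1" = exp(-0.18), "2" = exp(-1.36), "3" = exp(-2.34)),
    omega_rr = c("12" = exp(0.95), "13" = 1, "23" = 1),
    omega_rrp = c("12" = exp(-4.15), "13" = exp(-1.12), "23" = exp(2.09)),
    omega_rrr = 1,
    omega_rrrp = exp(2.12))
  ground_truth(activation, repression)
}

#' Simulate the Bicoid AP gradient
#'
#' Exponential anterior-posterior gradient
#' `mean(x) = amplitude * exp(-x / length_const)`; the SEM column is the
#' analytic standard error implied by the embryo-level multiplicative noise
#' model, `scale_sd * mean / sqrt(n_embryos)`.
#'
#' @param amplitude concentration at AP = 0 (AU).
#' @param length_const gradient decay length (fraction of embryo length).
#' @param grid AP positions; default [default_ap_grid()].
#' @param n_embryos embryos averaged (for the SEM).
#' @param scale_sd embryo-level multiplicative noise SD.
#' @return a [concentration_profile()], species `"bicoid"`.
#' @export
simulate_bicoid_profile <- function(amplitude = 250, length_const = 0.2,
                                    grid = default_ap_grid(),
                                    n_embryos = 3, scale_sd = 0.15) {
  stopifnot(amplitude > 0, length_const > 0)
  if (length(grid) == 0L) stop("empty AP grid")
  m <- amplitude * exp(-grid / length_const)
  concentration_profile(grid, m, scale_sd * m / sqrt(n_embryos),
                        species = "bicoid", n_embryos = n_embryos)
}

#' Simulate the Runt AP profile
#'
#' Logistic profile
#' `mean(x) = floor + (ceiling - floor) / (1 + exp(-steepness * (x - midpoint)))`
#' emulating the broad nuclear Runt domain over 20-60% embryo length in
#' nc14.  With `runt_null = TRUE` the profile is identically zero (mean and
#' SEM), emulating embryos carrying the protein-null allele.
#'
#' @param floor,ceiling concentration asymptotes (AU).
#' @param midpoint AP position of the half-maximal crossing (fraction EL).
#' @param steepness logistic rate (per fraction EL).
#' @param grid AP positions.
#' @param runt_null produce the null-genotype (all-zero) profile.
#' @inheritParams simulate_bicoid_profile
#' @return a [concentration_profile()], species `"runt"`.
#' @export
simulate_runt_profile <- function(floor = 10, ceiling = 120, midpoint = 0.35,
                                  steepness = 20, grid = default_ap_grid(),
                                  runt_null = FALSE, n_embryos = 3,
                                  scale_sd = 0.15) {
  if (length(grid) == 0L) stop("empty AP grid")
  if (runt_null) {
    return(concentration_profile(grid, rep(0, length(grid)),
                                 rep(0, length(grid)), species = "runt",
                                 n_embryos = n_embryos))
  }
  m <- floor + (ceiling - floor) / (1 + exp(-steepness * (grid - midpoint)))
  concentration_profile(grid, m, scale_sd * m / sqrt(n_embryos),
                        species = "runt", n_embryos = n_embryos)
}

#' Simulate initial-rate profiles for a set of constructs
#'
#' Forward model: the closed-form thermodynamic prediction for each
#' construct and genotype, then per embryo
#' `rate = prediction * (1 + eps_e) + eps_x` with embryo-level
#' `eps_e ~ N(0, scale_sd)` and position-level `eps_x ~ N(0, additive_sd)`,
#' clipped at zero; the returned profile holds the across-embryo mean and
#' SEM.  The runt-null genotype forces the Runt input to zero while reusing
#' the same activation parameters, so the parameter-sharing assumption of
#' the inference cascade holds exactly by construction.
#'
#' @param construct_ids character vector of construct bit strings.
#' @param truth a [ground_truth()].
#' @param bicoid,runt [concentration_profile()]s on a common grid.
#' @param n_embryos embryos per profile (>= 2; the study uses >= 3).
#' @param seed integer seed; the simulation is fully deterministic given it.
#' @param genotypes subset of `c("runt_null", "runt_wt")`.
#' @return named list of [rate_profile()]s, keys `"<construct>_<genotype>"`.
#' @export
simulate_rate_profiles <- function(construct_ids, truth, bicoid, runt,
                                   n_embryos = 3, seed = 1,
                                   genotypes = c("runt_null", "runt_wt")) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_embryos < 2) stop("'n_embryos' must be >= 2 for a defined SEM")
  genotypes <- match.arg(genotypes, several.ok = TRUE)
  out <- list()
  set.seed(as.integer(seed))
  for (id in construct_ids) {
    arch <- enhancer_architecture(id)
    act <- truth$activation[[id]]
    if (is.null(act)) stop("ground truth lacks activation parameters for [", id, "]")
    for (gt in genotypes) {
      pred <- predict_profile(bicoid, runt, arch, act, truth$repression,
                              genotype = gt)$mean
      draws <- vapply(seq_len(n_embryos), function(e) {
        eps_e <- stats::rnorm(1, 0, truth$scale_sd)
        eps_x <- stats::rnorm(length(pred), 0, truth$additive_sd)
        pmax(pred * (1 + eps_e) + eps_x, 0)
      }, numeric(length(pred)))
      out[[paste0(id, "_", gt)]] <- rate_profile(
        ap_fraction = bicoid$ap_fraction,
        mean = rowMeans(draws),
        sem = apply(draws, 1L, stats::sd) / sqrt(n_embryos),
        construct_id = id, genotype = gt, n_embryos = n_embryos)
    }
  }
  out
}

#' Simulate MS2 fluorescence traces
#'
#' Each trace rises linearly from the transcription onset time,
#' `F(t) = rate * (t - t_on)` for `t_on <= t <= plateau_time`, is held at
#' its plateau value afterwards, and carries additive Gaussian noise.
#' Before onset (and wherever the noiseless signal is zero) the locus is
#' off and fluorescence is the missing marker `NA`.
#'
#' @param rate initial RNAP loading rate (AU/min), >= 0.
#' @param t_on onset of transcription (min from the 13th anaphase), >= 0.
#' @param plateau_time time at which the rise saturates (min).
#' @param noise_sd additive fluorescence noise SD (AU).
#' @param seed integer seed.
#' @param n_nuclei number of traces.
#' @param ap_position AP fraction tag for the traces.
#' @param times sampling times (min), strictly increasing.
#' @param embryo_id embryo tag.
#' @return list of `"ms2_trace"` data frames with columns `embryo_id`,
#'   `nucleus_id`, `ap_fraction`, `time_min`, `fluorescence`.
#' @export
simulate_ms2_traces <- function(rate, t_on = 2, plateau_time = 12,
                                noise_sd = 0, seed = 1, n_nuclei = 1,
                                ap_position = 0.3,
                                times = seq(0, 20, by = 0.5),
                                embryo_id = 1L) {
  stopifnot(rate >= 0, t_on >= 0, all(diff(times) > 0))
  set.seed(as.integer(seed))
  signal <- pmax(0, rate * (pmin(times, plateau_time) - t_on))
  lapply(seq_len(n_nuclei), function(k) {
    f <- signal + stats::rnorm(length(times), 0, noise_sd)
    f <- pmax(f, 0)
    f[signal <= 0] <- NA_real_  # locus not yet (or never) detected
    out <- data.frame(embryo_id = embryo_id, nucleus_id = k,
                      ap_fraction = ap_position, time_min = times,
                      fluorescence = f)
    class(out) <- c("ms2_trace", "data.frame")
    out
  })
}

#' Simulate a complete study bundle
#'
#' Generates the full input set the hierarchical cascade consumes: Bicoid
#' and Runt concentration profiles and initial-rate profiles for all eight
#' constructs in both genotypes, with the ground truth attached.
#'
#' @param seed integer master seed.
#' @param truth a [ground_truth()]; default [default_ground_truth()].
#' @param n_embryos embryos per profile.
#' @param grid AP grid.
#' @return list with elements `bicoid`, `runt`, `profiles` (named list of
#'   [rate_profile()]s), `truth`, `seed`.
#' @export
simulate_study <- function(seed = 1, truth = default_ground_truth(),
                           n_embryos = 3, grid = default_ap_grid()) {
  bicoid <- simulate_bicoid_profile(grid = grid, n_embryos = n_embryos,
                                    scale_sd = truth$scale_sd)
  runt <- simulate_runt_profile(grid = grid, n_embryos = n_embryos,
                                scale_sd = truth$scale_sd)
  profiles <- simulate_rate_profiles(all_construct_ids(), truth, bicoid,
                                     runt, n_embryos = n_embryos, seed = seed)
  list(bicoid = bicoid, runt = runt, profiles = profiles, truth = truth,
       seed = as.integer(seed))
}
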