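#' Closed-form predicted transcription rate
#'
#' Evaluates the explicit closed-form rate expression for an architecture
#' with 0-3 Runt sites.  For zero sites this is the Bicoid-activation Hill
#' form; one site adds the Runt occupancy and the `omega_rp` term; two sites
#' add the pairwise `omega_rr` / `omega_rrp` cooperativities; three sites
#' additionally multiply in every pairwise term plus the `omega_rrr` and
#' `omega_rrrp` higher-order terms.  Semantically identical to
#' `R * pbound_bruteforce()`; the two are independent code paths
#' (polynomial expansion here, per-microstate log-weight summation there)
#' and are cross-checked in the test suite.
#'
#' @param inputs a [dimensionless_inputs()] (vectors allowed).
#' @param arch an [enhancer_architecture()].
#' @param act an [activation_params()].
#' @param rep a [repression_params()]; may be `NULL` for the zero-site
#'   architecture.
#' @return predicted rate, AU/min, in `[0, R]`; vectorized over positions.
#' @export
rate_closed_form <- function(inputs, arch, act, rep = NULL) {
  stopifnot(inherits(arch, "enhancer_architecture"))
  n <- length(arch$sites)
  if (n > 0L && is.null(rep)) {
    stop("architecture [", arch$construct_id, "] needs repression parameters")
  }
  b6 <- inputs$b^6
  r <- rep_len(inputs$r, length(b6))
  p <- act$p; wbp <- act$omega_bp
  ## Factored form: weights split into a Runt polynomial without RNAP
  ## (sum_S r^|S| Omega(S)) and one with RNAP (sum_S r^|S| Omega(S) Gamma(S)),
  ## where Omega collects Runt-only terms and Gamma the RNAP-coupled ones.
  poly <- switch(as.character(n),
    "0" = list(off = 1, on = 1),
    "1" = {
      wrp <- rep$omega_rp[[as.character(arch$sites)]]
      list(off = 1 + r, on = 1 + r * wrp)
    },
    "2" = {
      i <- arch$sites[1L]; j <- arch$sites[2L]
      wrpi <- rep$omega_rp[[as.character(i)]]
      wrpj <- rep$omega_rp[[as.character(j)]]
      pk <- pair_key(i, j)
      wrr <- rep$omega_rr[[pk]]; wrrp <- rep$omega_rrp[[pk]]
      list(off = 1 + 2 * r + r^2 * wrr,
           on  = 1 + r * (wrpi + wrpj) + r^2 * wrpi * wrpj * wrr * wrrp)
    },
    "3" = {
      wrp <- rep$omega_rp
      wrr <- rep$omega_rr; wrrp <- rep$omega_rrp
      off <- 1 + 3 * r +
        r^2 * (wrr[["12"]] + wrr[["13"]] + wrr[["23"]]) +
        r^3 * wrr[["12"]] * wrr[["13"]] * wrr[["23"]] * rep$omega_rrr
      on <- 1 + r * (wrp[["1"]] + wrp[["2"]] + wrp[["3"]]) +
        r^2 * (wrp[["1"]] * wrp[["2"]] * wrr[["12"]] * wrrp[["12"]] +
               wrp[["1"]] * wrp[["3"]] * wrr[["13"]] * wrrp[["13"]] +
               wrp[["2"]] * wrp[["3"]] * wrr[["23"]] * wrrp[["23"]]) +
        r^3 * wrp[["1"]] * wrp[["2"]] * wrp[["3"]] *
              wrr[["12"]] * wrr[["13"]] * wrr[["23"]] *
              wrrp[["12"]] * wrrp[["13"]] * wrrp[["23"]] *
              rep$omega_rrr * rep$omega_rrrp
      list(off = off, on = on)
    },
    stop("unsupported Runt site count: ", n)
  )
  num <- p * (1 + b6 * wbp) * poly$on
  den <- (1 + b6) * poly$off + num
  act$R * num / den
}

#' Predicted transcription rate (brute-force route)
#'
#' `R * p_bound` via the microstate enumerator.  Slow but definitionally
#' transparent; [rate_closed_form()] is the production path.
#' @inheritParams rate_closed_form
#' @return rate in AU/min.
#' @export
rate_bruteforce <- function(inputs, arch, act, rep = NULL) {
  if (is.null(rep)) rep <- repression_params(Kr = 1)
  act$R * pbound_bruteforce(inputs, arch, act, rep)
}

#' Predict a rate profile along the AP axis from TF concentration profiles
#'
#' Converts the Bicoid and Runt concentration profiles to dimensionless
#' occupancies using the current `Kb`, `Kr` and evaluates the closed-form
#' rate at every AP position.  For `genotype = "runt_null"` the Runt input is
#' forced to zero regardless of the supplied profile.
#'
#' @param bicoid,runt [concentration_profile()]s on the same AP grid; `runt`
#'   may be `NULL` when `genotype = "runt_null"`.
#' @param arch an [enhancer_architecture()].
#' @param act,rep parameter objects.
#' @param genotype `"runt_wt"` or `"runt_null"`.
#' @return a [rate_profile()] with the model prediction in `mean` and
#'   `sem = 0` (a noiseless model curve).
#' @export
predict_profile <- function(bicoid, runt = NULL, arch, act, rep = NULL,
                            genotype = c("runt_wt", "runt_null")) {
  genotype <- match.arg(genotype)
  if (genotype == "runt_null" || is.null(runt)) {
    rvals <- rep(0, nrow(bicoid))
  } else {
    if (nrow(runt) != nrow(bicoid) ||
        any(abs(runt$ap_fraction - bicoid$ap_fraction) > 1e-9)) {
      stop("Bicoid and Runt profiles must share the same AP position grid")
    }
    if (is.null(rep)) stop("runt_wt prediction needs repression parameters")
    rvals <- runt$mean / rep$Kr
  }
  inputs <- dimensionless_inputs(b = bicoid$mean / act$Kb, r = rvals)
  rate <- rate_closed_form(inputs, arch, act, rep)
  rate_profile(ap_fraction = bicoid$ap_fraction, mean = rate,
               sem = rep(0, length(rate)), construct_id = arch$construct_id,
               genotype = genotype, n_embryos = NA_integer_)
}

#' Convert a cooperativity to an interaction free energy (and back)
#'
#' Boltzmann relation `omega = exp(-E / kBT)`, i.e. `E = -ln(omega)` in kBT
#' units: `omega = 1` is a neutral interaction (0 kBT), `omega < 1`
#' (disfavoring) gives positive energy, `omega > 1` (favoring) negative.
#'
#' @param omega dimensionless cooperativity, > 0 (vectorized).
#' @return energy in kBT.
#' @examples
#' energy_from_omega(1)            # 0
#' omega_from_energy(2.34)         # ~0.096, i.e. ~0.1 repression
#' @export
energy_from_omega <- function(omega) {
  if (any(!is.finite(omega) | omega <= 0)) {
    stop("'omega' must be strictly positive and finite")
  }
  -log(omega)
}

#' @rdname energy_from_omega
#' @param energy interaction energy in kBT (vectorized).
#' @export
omega_from_energy <- function(energy) exp(-energy)
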