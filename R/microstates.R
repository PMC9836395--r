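#' Enumerate the binding microstates of an enhancer architecture
#'
#' In the strong Bicoid-Bicoid cooperativity limit the six Bicoid sites act
#' as a single all-or-none block, so each microstate is (Bicoid block bound
#' or not) x (any subset of the architecture's Runt sites bound) x (RNAP
#' bound or not): `2 * 2^n * 2` states for `n` Runt sites.  Order is
#' deterministic: Bicoid-major, then Runt subset by bitmask (site 1 = lowest
#' bit), then RNAP.
#'
#' @param arch an [enhancer_architecture()].
#' @return list of microstates; each is a list with `bicoid_bound` (logical),
#'   `runt_bound` (integer subset of `arch$sites`) and `rnap_bound` (logical).
#' @examples
#' length(enumerate_states(enhancer_architecture("000")))  # 4
#' length(enumerate_states(enhancer_architecture("111")))  # 32
#' @export
enumerate_states <- function(arch) {
  stopifnot(inherits(arch, "enhancer_architecture"))
  n <- length(arch$sites)
  states <- vector("list", 2L * 2L^n * 2L)
  k <- 0L
  for (B in c(FALSE, TRUE)) {
    for (mask in 0L:(2L^n - 1L)) {
      subset <- arch$sites[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L]
      for (P in c(FALSE, TRUE)) {
        k <- k + 1L
        states[[k]] <- list(bicoid_bound = B, runt_bound = subset,
                            rnap_bound = P)
      }
    }
  }
  states
}

#' Statistical weight of one microstate
#'
#' The unnormalized Boltzmann weight of a microstate is the product of the
#' occupancy factors (`b^6` for the Bicoid block, `r` per bound Runt, `p` for
#' RNAP) and every interaction term active in that state: `omega_bp` when
#' Bicoid and RNAP co-occur, the per-site `omega_rp` for each bound Runt when
#' RNAP is present, every pairwise `omega_rr` among bound Runts, every
#' pairwise `omega_rrp` among bound Runts when RNAP is present, and, when all
#' three Runts are bound, `omega_rrr` (and `omega_rrrp` with RNAP).  The
#' empty state has weight exactly 1.  Computed in log space internally so
#' extreme occupancies do not overflow.
#'
#' @param state one element of [enumerate_states()].
#' @param inputs a [dimensionless_inputs()] with scalar `b`, `r`.
#' @param act an [activation_params()].
#' @param rep a [repression_params()].
#' @param log return the log weight instead of the weight.
#' @return positive statistical weight (or its log).
#' @export
state_weight <- function(state, inputs, act, rep, log = FALSE) {
  stopifnot(inherits(act, "activation_params"),
            inherits(rep, "repression_params"))
  lw <- state_log_weight(state, inputs$b, inputs$r, act, rep)
  if (log) lw else exp(lw)
}

## log-weight kernel; b, r scalars. log(0) terms are only added when the
## corresponding occupancy indicator is active, so b = 0 or r = 0 give -Inf
## exactly for the states that require the missing species.
state_log_weight <- function(state, b, r, act, rep) {
  B <- isTRUE(state$bicoid_bound)
  P <- isTRUE(state$rnap_bound)
  S <- state$runt_bound
  ns <- length(S)
  lw <- 0
  if (B) lw <- lw + 6 * log(b)
  if (ns > 0L) lw <- lw + ns * log(r)
  if (P) lw <- lw + log(act$p)
  if (B && P) lw <- lw + log(act$omega_bp)
  if (ns > 0L && P) lw <- lw + sum(log(rep$omega_rp[as.character(S)]))
  if (ns >= 2L) {
    pk <- site_pairs(S)
    lw <- lw + sum(log(rep$omega_rr[pk]))
    if (P) lw <- lw + sum(log(rep$omega_rrp[pk]))
  }
  if (ns == 3L) {
    lw <- lw + log(rep$omega_rrr)
    if (P) lw <- lw + log(rep$omega_rrrp)
  }
  lw
}

#' Promoter occupancy probability by brute-force state enumeration
#'
#' `p_bound` is the sum of the statistical weights of all RNAP-containing
#' microstates divided by the sum over all microstates (the partition
#' function).  This enumerator is the oracle against which the closed-form
#' expressions are checked; the ratio is evaluated with log-sum-exp.
#'
#' @inheritParams state_weight
#' @param arch an [enhancer_architecture()].
#' @return probability in \[0, 1\]; vectorized over positions when
#'   `inputs$b`/`inputs$r` are vectors.
#' @export
pbound_bruteforce <- function(inputs, arch, act, rep) {
  states <- enumerate_states(arch)
  rnap_on <- vapply(states, function(s) s$rnap_bound, logical(1))
  b <- inputs$b
  r <- rep_len(inputs$r, length(b))
  vapply(seq_along(b), function(i) {
    lw <- vapply(states, state_log_weight, numeric(1),
                 b = b[i], r = r[i], act = act, rep = rep)
    exp(logsumexp(lw[rnap_on]) - logsumexp(lw))
  }, numeric(1))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
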