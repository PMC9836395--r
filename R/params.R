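#' Activation (Runt-independent) parameters
#'
#' The four parameters governing Bicoid activation and RNAP recruitment at
#' the promoter.  Each construct carries its own instance: the construct
#' sequence context measurably shifts the RNAP-dependent parameters even in
#' the absence of repressor.
#'
#' @param Kb Bicoid dissociation constant (concentration, AU).
#' @param omega_bp Bicoid-RNAP interaction term (dimensionless, > 0).
#' @param p lumped RNAP occupancy factor \[RNAP\]/Kp (dimensionless, > 0).
#'   RNAP concentration and the promoter dissociation constant are never
#'   separable from rate data; only their ratio is identifiable and stored.
#' @param R transcription rate when RNAP is bound (AU/min).
#' @return object of class `"activation_params"`.
#' @export
activation_params <- function(Kb, omega_bp, p, R) {
  check_positive(c(Kb = Kb, omega_bp = omega_bp, p = p, R = R))
  structure(list(Kb = Kb, omega_bp = omega_bp, p = p, R = R),
            class = "activation_params")
}

#' Repression (Runt-dependent) parameters
#'
#' Runt-dependent parameters shared across constructs: a single dissociation
#' constant `Kr` for every Runt site, per-site Runt-RNAP terms, pairwise
#' Runt-Runt and Runt-Runt-RNAP cooperativities keyed by unordered site pair
#' (`"23"` from construct \[011\], `"13"` from \[101\], `"12"` from \[110\]),
#' and the three-site higher-order terms.  A value of 1 encodes "no
#' interaction".
#'
#' @param Kr Runt dissociation constant (AU), shared across constructs.
#' @param omega_rp named numeric, Runt-RNAP interaction per site
#'   (names `"1"`, `"2"`, `"3"`; 1 = distal).
#' @param omega_rr named numeric, Runt-Runt pair terms (names `"12"`, `"13"`,
#'   `"23"`).
#' @param omega_rrp named numeric, Runt-Runt-RNAP pair terms (same keys).
#' @param omega_rrr three-Runt cooperativity (scalar).
#' @param omega_rrrp three-Runt-RNAP higher-order cooperativity (scalar).
#' @return object of class `"repression_params"`.
#' @export
repression_params <- function(Kr,
                              omega_rp = c("1" = 1, "2" = 1, "3" = 1),
                              omega_rr = c("12" = 1, "13" = 1, "23" = 1),
                              omega_rrp = c("12" = 1, "13" = 1, "23" = 1),
                              omega_rrr = 1,
                              omega_rrrp = 1) {
  omega_rp <- fill_named(omega_rp, c("1", "2", "3"))
  omega_rr <- fill_named(omega_rr, c("12", "13", "23"))
  omega_rrp <- fill_named(omega_rrp, c("12", "13", "23"))
  check_positive(c(Kr = Kr, omega_rrr = omega_rrr, omega_rrrp = omega_rrrp))
  check_positive(stats::setNames(omega_rp, paste0("omega_rp[", names(omega_rp), "]")))
  check_positive(stats::setNames(omega_rr, paste0("omega_rr[", names(omega_rr), "]")))
  check_positive(stats::setNames(omega_rrp, paste0("omega_rrp[", names(omega_rrp), "]")))
  structure(list(Kr = Kr, omega_rp = omega_rp, omega_rr = omega_rr,
                 omega_rrp = omega_rrp, omega_rrr = omega_rrr,
                 omega_rrrp = omega_rrrp),
            class = "repression_params")
}

#' Dimensionless occupancy inputs
#'
#' @param b \[Bicoid\]/Kb, dimensionless, may be a vector (one value per AP
#'   position).
#' @param r \[Runt\]/Kr, dimensionless, same length as `b` (or scalar).
#' @return object of class `"dimensionless_inputs"`.
#' @export
dimensionless_inputs <- function(b, r) {
  if (any(!is.finite(b)) || any(!is.finite(r)) || any(b < 0) || any(r < 0)) {
    stop("dimensionless inputs 'b' and 'r' must be finite and non-negative")
  }
  structure(list(b = b, r = r), class = "dimensionless_inputs")
}

check_positive <- function(x) {
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    stop("parameter must be strictly positive and finite: ",
         paste(names(x)[bad], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

fill_named <- function(x, keys) {
  if (is.null(names(x))) {
    if (length(x) == length(keys)) names(x) <- keys
    else stop("expected names ", paste(keys, collapse = ", "))
  }
  out <- stats::setNames(rep(1, length(keys)), keys)
  if (!all(names(x) %in% keys)) {
    stop("unknown key(s): ", paste(setdiff(names(x), keys), collapse = ", "))
  }
  out[names(x)] <- x
  out
}

#' @export
print.activation_params <- function(x, ...) {
  cat(sprintf("Activation parameters: Kb = %.4g AU, omega_bp = %.4g, p = %.4g, R = %.4g AU/min\n",
              x$Kb, x$omega_bp, x$p, x$R))
  invisible(x)
}

#' @export
print.repression_params <- function(x, ...) {
  cat(sprintf("Repression parameters (shared): Kr = %.4g AU\n", x$Kr))
  cat("  omega_rp  :", paste(sprintf("[%s] %.4g", names(x$omega_rp), x$omega_rp), collapse = "  "), "\n")
  cat("  omega_rr  :", paste(sprintf("{%s} %.4g", names(x$omega_rr), x$omega_rr), collapse = "  "), "\n")
  cat("  omega_rrp :", paste(sprintf("{%s} %.4g", names(x$omega_rrp), x$omega_rrp), collapse = "  "), "\n")
  cat(sprintf("  omega_rrr = %.4g, omega_rrrp = %.4g\n", x$omega_rrr, x$omega_rrrp))
  invisible(x)
}
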