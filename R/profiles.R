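#' AP-binned transcription-factor concentration profile
#'
#' A data frame with one row per anterior-posterior (AP) bin: position as
#' fraction of embryo length, mean nuclear concentration (AU) and the
#' standard error of that mean over embryos.  The measurement window (minutes
#' into nuclear cycle 14) and the species are carried as columns so profiles
#' round-trip losslessly through the CSV schema.
#'
#' @param ap_fraction strictly increasing AP positions in \[0, 1\].
#' @param mean,sem non-negative concentration mean and SEM (AU).
#' @param species `"bicoid"` or `"runt"`.
#' @param n_embryos number of embryos averaged.
#' @param window_start_min,window_end_min averaging window, minutes into nc14.
#' @return data frame of class `"concentration_profile"`.
#' @export
concentration_profile <- function(ap_fraction, mean, sem,
                                  species = c("bicoid", "runt"),
                                  n_embryos = NA_integer_,
                                  window_start_min = 5,
                                  window_end_min = 10) {
  species <- match.arg(species)
  check_profile_vectors(ap_fraction, mean, sem)
  out <- data.frame(species = species, ap_fraction = ap_fraction,
                    mean = mean, sem = sem, n_embryos = n_embryos,
                    window_start_min = window_start_min,
                    window_end_min = window_end_min)
  class(out) <- c("concentration_profile", "data.frame")
  out
}

#' AP-binned initial transcription-rate profile
#'
#' One row per AP bin: mean initial RNAP loading rate (AU/min) and SEM over
#' embryos, tagged with the construct and genotype it was measured (or
#' simulated) from.
#'
#' @inheritParams concentration_profile
#' @param mean,sem non-negative rate mean and SEM (AU/min).
#' @param construct_id 3-bit construct identifier, e.g. `"011"`.
#' @param genotype `"runt_null"` or `"runt_wt"`.
#' @return data frame of class `"rate_profile"`.
#' @export
rate_profile <- function(ap_fraction, mean, sem, construct_id,
                         genotype = c("runt_wt", "runt_null"),
                         n_embryos = NA_integer_,
                         window_start_min = 5, window_end_min = 10) {
  genotype <- match.arg(genotype)
  check_profile_vectors(ap_fraction, mean, sem)
  enhancer_architecture(construct_id)  # validates the id
  out <- data.frame(construct_id = construct_id, genotype = genotype,
                    ap_fraction = ap_fraction, mean = mean, sem = sem,
                    n_embryos = n_embryos,
                    window_start_min = window_start_min,
                    window_end_min = window_end_min)
  class(out) <- c("rate_profile", "data.frame")
  out
}

check_profile_vectors <- function(ap_fraction, mean, sem) {
  if (length(ap_fraction) == 0L) stop("profile grid is empty")
  if (length(mean) != length(ap_fraction) || length(sem) != length(ap_fraction)) {
    stop("'ap_fraction', 'mean' and 'sem' must have equal length")
  }
  if (any(diff(ap_fraction) <= 0)) stop("'ap_fraction' must be strictly increasing")
  if (any(ap_fraction < 0 | ap_fraction > 1)) stop("'ap_fraction' must lie in [0, 1]")
  if (any(stats::na.omit(mean) < 0)) stop("'mean' must be non-negative")
  if (any(stats::na.omit(sem) < 0)) stop("'sem' must be non-negative")
  invisible(TRUE)
}

#' Default AP grid: 20-60% embryo length in 2.5% bins
#'
#' The imaging field of view spans 20-60% of the embryo length and
#' quantities are averaged in spatial bins of 2.5% EL, giving 17 bin
#' centers.
#' @return numeric vector of AP fractions.
#' @export
default_ap_grid <- function() seq(0.20, 0.60, by = 0.025)
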