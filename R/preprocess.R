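#' Time window anchored to the 13th anaphase
#'
#' The analysis window spans 5 to 10 minutes after the 13th anaphase (early
#' nuclear cycle 14): transcription-factor inputs are time-averaged over it
#' and the initial-rate line is fit over the same window.
#'
#' @param start,end window bounds in minutes, `0 <= start < end`.
#' @return object of class `"time_window"`.
#' @export
time_window <- function(start = 5, end = 10) {
  if (!(is.numeric(start) && is.numeric(end) && start >= 0 && start < end)) {
    stop("need 0 <= start < end")
  }
  structure(list(start = start, end = end), class = "time_window")
}

#' Time-average a transcription-factor time series into a static profile
#'
#' For every AP position, the arithmetic mean of all samples inside the
#' window is taken per embryo; the returned profile is the across-embryo
#' mean with its SEM.  This is the reduction from concentration dynamics to
#' the static input profiles the thermodynamic model consumes.
#'
#' @param series data frame with columns `embryo_id`, `ap_fraction`,
#'   `time_min`, `value` (nuclear concentration, AU).
#' @param window a [time_window()].
#' @param species label for the output profile.
#' @return a [concentration_profile()].
#' @export
time_average_concentration <- function(series, window = time_window(),
                                       species = c("bicoid", "runt")) {
  species <- match.arg(species)
  need <- c("embryo_id", "ap_fraction", "time_min", "value")
  if (!all(need %in% names(series))) {
    stop("series needs columns: ", paste(need, collapse = ", "))
  }
  inside <- series$time_min >= window$start & series$time_min <= window$end
  positions <- sort(unique(series$ap_fraction))
  per_pos <- lapply(positions, function(x) {
    sel <- series[inside & series$ap_fraction == x, , drop = FALSE]
    if (nrow(sel) == 0L) {
      stop("time window [", window$start, ", ", window$end,
           "] does not overlap the series at AP position ", x)
    }
    embryo_means <- tapply(sel$value, sel$embryo_id, mean)
    c(mean = mean(embryo_means),
      sem = if (length(embryo_means) > 1L)
        stats::sd(embryo_means) / sqrt(length(embryo_means)) else 0,
      n = length(embryo_means))
  })
  m <- vapply(per_pos, `[[`, numeric(1), "mean")
  s <- vapply(per_pos, `[[`, numeric(1), "sem")
  n <- vapply(per_pos, `[[`, numeric(1), "n")
  concentration_profile(positions, m, s, species = species,
                        n_embryos = as.integer(max(n)),
                        window_start_min = window$start,
                        window_end_min = window$end)
}

#' Fit the initial rise of an MS2 trace
#'
#' Ordinary least squares on all non-missing points inside the window.  The
#' slope is the initial RNAP loading rate; the onset of transcription `t_on`
#' is the x-intercept of the fitted line (`-intercept / slope`), defined
#' only when the slope is positive.
#'
#' @param trace an `"ms2_trace"` data frame (or any data frame with
#'   `time_min` and `fluorescence` columns).
#' @param window a [time_window()]; default the 5-10 min analysis window.
#' @return object of class `"initial_rate_fit"` with fields `slope`
#'   (AU/min), `t_on` (min, `NA` when undefined), `fit_window`,
#'   `residual_sd`, `n_points`.
#' @export
fit_initial_rate <- function(trace, window = time_window()) {
  keep <- !is.na(trace$fluorescence) &
    trace$time_min >= window$start & trace$time_min <= window$end
  tt <- trace$time_min[keep]
  ff <- trace$fluorescence[keep]
  if (length(tt) < 2L) {
    stop("need at least 2 non-missing points inside the fit window, got ",
         length(tt))
  }
  fit <- stats::lm(ff ~ tt)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  structure(list(
    slope = slope,
    t_on = if (is.finite(slope) && slope > 0) -intercept / slope else NA_real_,
    fit_window = window,
    residual_sd = if (length(tt) > 2L)
      suppressWarnings(summary(fit)$sigma) else 0,
    n_points = length(tt)),
    class = "initial_rate_fit")
}

#' @export
print.initial_rate_fit <- function(x, ...) {
  cat(sprintf("Initial-rate fit: slope = %.4g AU/min, t_on = %s min (%d points, window [%g, %g] min)\n",
              x$slope, if (is.na(x$t_on)) "undefined" else sprintf("%.4g", x$t_on),
              x$n_points, x$fit_window$start, x$fit_window$end))
  invisible(x)
}

#' Bin per-nucleus values along the AP axis and aggregate across embryos
#'
#' Values are assigned to half-open bins `[left, right)` of width
#' `bin_width` on the AP fraction.  Within each bin, nuclei are first
#' averaged within embryo, then the across-embryo mean and SEM are
#' reported.  Empty bins carry the missing marker rather than an error.
#'
#' @param values data frame with columns `embryo_id`, `ap_fraction`,
#'   `value` (e.g. per-nucleus initial-rate fits).
#' @param bin_width bin width in AP fraction; default 0.025 (2.5% EL).
#' @param construct_id,genotype tags for the output profile.
#' @param range AP range covered by the bins; default `c(0.2, 0.6)`.
#' @return a [rate_profile()] whose positions are the left bin edges; bins
#'   with a single embryo report `sem = 0`, empty bins `NA`.
#' @export
bin_and_aggregate <- function(values, bin_width = 0.025,
                              construct_id = "000",
                              genotype = "runt_wt",
                              range = c(0.2, 0.6)) {
  stopifnot(bin_width > 0)
  edges <- round(seq(range[1L], range[2L] + bin_width, by = bin_width), 12)
  centers <- utils::head(edges, -1L)
  idx <- findInterval(values$ap_fraction, edges, rightmost.closed = FALSE)
  m <- s <- rep(NA_real_, length(centers))
  nmax <- 1L
  for (k in seq_along(centers)) {
    sel <- values[idx == k, , drop = FALSE]
    if (nrow(sel) == 0L) next
    embryo_means <- tapply(sel$value, sel$embryo_id, mean)
    m[k] <- mean(embryo_means)
    s[k] <- if (length(embryo_means) > 1L)
      stats::sd(embryo_means) / sqrt(length(embryo_means)) else 0
    nmax <- max(nmax, length(embryo_means))
  }
  rate_profile(centers, m, s, construct_id = construct_id,
               genotype = genotype, n_embryos = as.integer(nmax))
}
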