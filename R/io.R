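#' Read and write the AP profile CSV schema
#'
#' The tabular interchange format for rate and concentration profiles:
#' columns `construct_id`, `genotype`, `ap_fraction`, `mean`, `sem`,
#' `n_embryos`, `units`, `window_start_min`, `window_end_min`.  UTF-8,
#' header mandatory, `.` decimal.  Reading validates the schema and reports
#' offending row numbers; writing then reading is lossless.
#'
#' @param path CSV file path.
#' @return `read_profile_table()`: a data frame (the raw table);
#'   `profile_table_to_rates()` splits it into [rate_profile()]s.
#' @export
read_profile_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(construct_id = "character"))
  need <- c("construct_id", "genotype", "ap_fraction", "mean", "sem",
            "n_embryos", "units", "window_start_min", "window_end_min")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("profile table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) return(tab)
  for (col in c("ap_fraction", "mean", "sem")) {
    bad <- which(!is.na(tab[[col]]) & !is.finite(suppressWarnings(as.numeric(tab[[col]]))))
    if (length(bad)) stop("non-numeric '", col, "' at row(s): ",
                          paste(bad, collapse = ", "))
  }
  bad <- which(tab$ap_fraction < 0 | tab$ap_fraction > 1)
  if (length(bad)) stop("ap_fraction outside [0, 1] at row(s): ",
                        paste(bad, collapse = ", "))
  bad <- which(!tab$units %in% c("AU", "AU/min"))
  if (length(bad)) stop("units must be 'AU' or 'AU/min' at row(s): ",
                        paste(bad, collapse = ", "))
  tab
}

#' @rdname read_profile_table
#' @param profiles list of [rate_profile()]s (or a single one).
#' @export
write_profile_table <- function(profiles, path) {
  if (inherits(profiles, "rate_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(construct_id = p$construct_id, genotype = p$genotype,
               ap_fraction = p$ap_fraction, mean = p$mean, sem = p$sem,
               n_embryos = p$n_embryos, units = "AU/min",
               window_start_min = p$window_start_min,
               window_end_min = p$window_end_min)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_profile_table
#' @param tab a validated profile table.
#' @export
profile_table_to_rates <- function(tab) {
  keys <- unique(tab[, c("construct_id", "genotype")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- tab[tab$construct_id == keys$construct_id[i] &
                 tab$genotype == keys$genotype[i], , drop = FALSE]
    sel <- sel[order(sel$ap_fraction), , drop = FALSE]
    rate_profile(sel$ap_fraction, sel$mean, sel$sem,
                 construct_id = keys$construct_id[i],
                 genotype = keys$genotype[i],
                 n_embryos = sel$n_embryos[1L],
                 window_start_min = sel$window_start_min[1L],
                 window_end_min = sel$window_end_min[1L])
  })
  names(out) <- paste0(keys$construct_id, "_", keys$genotype)
  out
}

#' Read and write the MS2 trace CSV schema
#'
#' Columns `embryo_id`, `nucleus_id`, `ap_fraction`, `time_min`,
#' `fluorescence`; an empty fluorescence cell is the locus-off missing
#' marker.  Time must be strictly increasing within each
#' (embryo, nucleus) trace.
#'
#' @param path CSV file path.
#' @return data frame with the trace columns.
#' @export
read_trace_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("embryo_id", "nucleus_id", "ap_fraction", "time_min", "fluorescence")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("trace table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(stats::na.omit(tab$fluorescence) < 0)) {
    stop("negative fluorescence values present")
  }
  by_trace <- split(tab$time_min, paste(tab$embryo_id, tab$nucleus_id))
  bad <- names(by_trace)[vapply(by_trace, function(t) any(diff(t) <= 0), logical(1))]
  if (length(bad)) stop("time_min not strictly increasing for trace(s): ",
                        paste(bad, collapse = ", "))
  tab
}

#' @rdname read_trace_table
#' @param traces list of `"ms2_trace"` data frames.
#' @export
write_trace_table <- function(traces, path) {
  if (is.data.frame(traces)) traces <- list(traces)
  utils::write.csv(do.call(rbind, traces), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Serialize and reload the simulator ground truth
#'
#' YAML sidecar holding the per-construct activation parameters, shared
#' repression parameters and the noise model; reloading reproduces the
#' [ground_truth()] object exactly (round-trip identity).
#'
#' @param truth a [ground_truth()].
#' @param path YAML file path.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(
    activation = lapply(truth$activation, function(a)
      list(Kb = a$Kb, omega_bp = a$omega_bp, p = a$p, R = a$R)),
    repression = list(Kr = truth$repression$Kr,
                      omega_rp = as.list(truth$repression$omega_rp),
                      omega_rr = as.list(truth$repression$omega_rr),
                      omega_rrp = as.list(truth$repression$omega_rrp),
                      omega_rrr = truth$repression$omega_rrr,
                      omega_rrrp = truth$repression$omega_rrrp),
    noise = list(scale_sd = truth$scale_sd, additive_sd = truth$additive_sd))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  activation <- lapply(obj$activation, function(a)
    activation_params(a$Kb, a$omega_bp, a$p, a$R))
  repression <- repression_params(
    Kr = obj$repression$Kr,
    omega_rp = unlist(obj$repression$omega_rp),
    omega_rr = unlist(obj$repression$omega_rr),
    omega_rrp = unlist(obj$repression$omega_rrp),
    omega_rrr = obj$repression$omega_rrr,
    omega_rrrp = obj$repression$omega_rrrp)
  ground_truth(activation, repression, obj$noise$scale_sd, obj$noise$additive_sd)
}

#' Persist a posterior chain as CSV
#'
#' One column per parameter plus `log_posterior`; the seed and burn-in are
#' recorded in a YAML sidecar of the same basename.
#'
#' @param chain a `"posterior_chain"`.
#' @param path CSV path (sidecar written with extension `.meta.yaml`).
#' @export
write_chain <- function(chain, path) {
  tab <- as.data.frame(chain$samples)
  tab$log_posterior <- chain$log_posterior
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(seed = chain$seed, burn_in = chain$burn_in,
                        acceptance_rate = chain$acceptance_rate),
                   paste0(sub("\\.csv$", "", path), ".meta.yaml"))
  invisible(path)
}

#' Write a plain-text + CSV report of a fitted cascade
#'
#' Persists, under `outdir`: every stage's chains (CSV), the energy table,
#' the stage-A CV report, the stage-C AIC comparisons, a JSON-lines summary
#' of all posterior means/SDs, and the configuration echo (YAML).  Content
#' is fully determined by the cascade object, so identical config + seed
#' reproduce byte-identical files.
#'
#' @param cascade a `"thermo_cascade"`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cascade_report <- function(cascade, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  for (id in names(cascade$stage_a$fits)) {
    write_chain(cascade$stage_a$fits[[id]]$chain,
                fp(paste0("chain_stageA_", id, ".csv")))
  }
  if (!is.null(cascade$stage_b$fit)) {
    write_chain(cascade$stage_b$fit$chain, fp("chain_stageB_one_site.csv"))
  }
  for (id in c("011", "101", "110")) {
    write_chain(cascade$stage_c[[id]]$final_fit$chain,
                fp(paste0("chain_stageC_", id, ".csv")))
    cmp <- cascade$stage_c[[id]]$comparison
    if (!is.null(cmp)) {
      utils::write.csv(cmp, fp(paste0("aic_", id, ".csv")), row.names = FALSE,
                       quote = FALSE)
    }
  }
  write_chain(cascade$stage_d$fit$chain, fp("chain_stageD_111.csv"))
  utils::write.csv(cascade$energy_table, fp("energy_table.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(parameter = names(cascade$cv), cv = cascade$cv),
                   fp("stageA_cv.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(cascade$provenance, fp("provenance.csv"),
                   row.names = FALSE, quote = FALSE)
  ## JSON-lines summary of every posterior mean/SD
  lines <- character(0)
  emit <- function(stage, label, tab) {
    for (i in seq_len(nrow(tab))) {
      lines[[length(lines) + 1L]] <<- sprintf(
        '{"stage":"%s","fit":"%s","parameter":"%s","mean":%.10g,"sd":%.10g}',
        stage, label, tab$parameter[i], tab$mean[i], tab$sd[i])
    }
  }
  for (id in names(cascade$stage_a$fits)) {
    emit("A", id, cascade$stage_a$fits[[id]]$chain$summaries$table)
  }
  if (!is.null(cascade$stage_b$fit)) {
    emit("B", "one_site_joint", cascade$stage_b$fit$chain$summaries$table)
  }
  for (id in c("011", "101", "110")) {
    emit("C", id, cascade$stage_c[[id]]$final_fit$chain$summaries$table)
  }
  emit("D", "111", cascade$stage_d$fit$chain$summaries$table)
  writeLines(lines, fp("posterior_summaries.jsonl"))
  cfg <- cascade$config
  yaml::write_yaml(c(unclass(cfg), list(seed = cascade$seed)),
                   fp("config_echo.yaml"))
  invisible(outdir)
}
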