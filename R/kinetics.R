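# Aggregation and binding kinetics: logistic fits of thioflavin-T traces
# (lag time, t50), lag-time ratios between conditions, and one-site
# saturation-binding fits.
#
# Lag time uses the tangent-at-midpoint convention: lag = t50 - 2/rate.

#' Construct a kinetic trace
#'
#' @param time Hours, strictly increasing, >= 8 points.
#' @param signal Fluorescence (a.u.), finite.
#' @param replicate_id Replicate label.
#' @return A `kinetic_trace` data frame.
#' @export
kinetic_trace <- function(time, signal, replicate_id = 1) {
  stopifnot(length(time) == length(signal), length(time) >= 8,
            all(diff(time) > 0), all(is.finite(signal)))
  structure(data.frame(time = time, signal = signal,
                       replicate_id = replicate_id),
            class = c("kinetic_trace", "data.frame"))
}

logistic4 <- function(t, baseline, amplitude, t50, rate) {
  baseline + amplitude / (1 + exp(-rate * (t - t50)))
}

## Robust noise estimate: MAD of the fit residuals over the first
## quartile of points (raw-signal MAD would misfire when the transition
## starts inside the first quartile).
baseline_noise <- function(trace, fitted_vals) {
  n <- nrow(trace)
  idx <- seq_len(max(3, floor(n / 4)))
  stats::mad(trace$signal[idx] - fitted_vals[idx])
}

#' Fit a thioflavin-T aggregation trace
#'
#' Least-squares fit of the 4-parameter logistic
#' `signal(t) = baseline + amplitude / (1 + exp(-rate (t - t50)))`, with
#' multi-start initialization (5 seeded starts) to avoid local minima.
#' The trace counts as aggregated when the fitted amplitude exceeds three
#' times the baseline noise (MAD of the fit residuals over the first
#' quartile of points); flat traces get `aggregated_flag = FALSE` and an
#' undefined lag time.
#' Lag time = t50 - 2/rate (tangent at the midpoint).
#'
#' @param trace A [kinetic_trace()] (or data frame with `time`, `signal`).
#' @return A `kinetic_fit`: baseline, amplitude, t50 (h), rate (1/h),
#'   lag_time (h or NA), aggregated_flag, converged, residual_sse.
#' @export
fit_tht_curve <- function(trace) {
  stopifnot(all(c("time", "signal") %in% names(trace)), nrow(trace) >= 8)
  t <- trace$time; y <- trace$signal
  span <- max(y) - min(y)
  starts <- list()
  qs <- stats::quantile(t, c(0.25, 0.4, 0.5, 0.6, 0.75))
  for (k in seq_len(5)) {
    starts[[k]] <- c(baseline = min(y), amplitude = max(span, 1e-6),
                     t50 = unname(qs[k]),
                     rate = 4 / max(diff(range(t)) / 4, 1e-6) * k / 3)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        signal ~ baseline + amplitude / (1 + exp(-rate * (time - t50))),
        data = trace, start = as.list(st),
        lower = c(baseline = -Inf, amplitude = 0, t50 = min(t) - diff(range(t)),
                  rate = 1e-6),
        upper = c(baseline = Inf, amplitude = Inf, t50 = max(t) + diff(range(t)),
                  rate = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    return(structure(list(baseline = NA_real_, amplitude = NA_real_,
                          t50 = NA_real_, rate = NA_real_, lag_time = NA_real_,
                          aggregated_flag = FALSE, converged = FALSE,
                          residual_sse = NA_real_),
                     class = "kinetic_fit"))
  }
  p <- as.list(stats::coef(best$fit))
  noise <- baseline_noise(trace, stats::fitted(best$fit))
  noise_floor <- max(noise, 1e-6 * max(1, abs(stats::median(y))))
  aggregated <- p$amplitude >= 3 * noise_floor
  lag <- if (aggregated) p$t50 - 2 / p$rate else NA_real_
  structure(list(baseline = p$baseline, amplitude = p$amplitude,
                 t50 = p$t50, rate = p$rate, lag_time = lag,
                 aggregated_flag = aggregated, converged = TRUE,
                 residual_sse = best$sse),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (!x$converged) {
    cat("kinetic_fit: fit failure\n")
  } else if (!x$aggregated_flag) {
    cat("kinetic_fit: no aggregation detected (flat trace)\n")
  } else {
    cat(sprintf("kinetic_fit: t50 %.2f h, rate %.3f /h, lag %.2f h, amplitude %.3g\n",
                x$t50, x$rate, x$lag_time, x$amplitude))
  }
  invisible(x)
}

#' Lag-time ratio between a treated and a control condition
#'
#' Returns `treated$lag_time / control$lag_time`. When either condition
#' never aggregates, returns `Inf` (the "no-aggregation" sentinel, stronger
#' than any finite ratio).
#'
#' @param treated,control `kinetic_fit` objects.
#' @export
lag_ratio <- function(treated, control) {
  if (!treated$aggregated_flag || !control$aggregated_flag) return(Inf)
  if (!is.finite(control$lag_time) || control$lag_time <= 0) {
    stop("control lag time must be positive")
  }
  treated$lag_time / control$lag_time
}

#' Fit replicate ThT traces and summarize
#'
#' Each replicate is fitted independently; the summary reports mean and SD
#' across replicates of t50, rate and lag time.
#'
#' @param traces List of [kinetic_trace()] objects.
#' @return List with `fits` and `summary` (data frame).
#' @export
fit_tht_replicates <- function(traces) {
  fits <- lapply(traces, fit_tht_curve)
  agg <- vapply(fits, function(f) isTRUE(f$aggregated_flag), TRUE)
  grab <- function(field) vapply(fits[agg], function(f) f[[field]], 0)
  summary <- if (any(agg)) {
    data.frame(n = sum(agg),
               t50_mean = mean(grab("t50")), t50_sd = stats::sd(grab("t50")),
               rate_mean = mean(grab("rate")), rate_sd = stats::sd(grab("rate")),
               lag_mean = mean(grab("lag_time")), lag_sd = stats::sd(grab("lag_time")))
  } else {
    data.frame(n = 0, t50_mean = NA, t50_sd = NA, rate_mean = NA,
               rate_sd = NA, lag_mean = NA, lag_sd = NA)
  }
  list(fits = fits, summary = summary)
}

#' Fit a one-site saturation binding curve
#'
#' Least-squares fit of `signal = bmax * c / (half_saturation + c)` with
#' positivity constraints. Requires at least 5 concentration points; a
#' concentration range narrower than one order of magnitude sets
#' `wide_ci_flag` (with a warning).
#'
#' @param conc Concentrations (nM).
#' @param signal Measured signal.
#' @return A `binding_fit`: bmax, half_saturation (nM), residual_sse,
#'   converged, wide_ci_flag.
#' @export
fit_saturation_binding <- function(conc, signal) {
  stopifnot(length(conc) == length(signal), all(conc >= 0))
  if (length(conc) < 5) stop("need at least 5 concentration points")
  wide_ci <- FALSE
  pos <- conc[conc > 0]
  if (max(pos) / min(pos) < 10) {
    warning("concentrations span less than one order of magnitude; ",
            "half-saturation is poorly constrained")
    wide_ci <- TRUE
  }
  df <- data.frame(conc = conc, signal = signal)
  fit <- tryCatch(
    minpack.lm::nlsLM(signal ~ bmax * conc / (kd + conc), data = df,
                      start = list(bmax = max(signal), kd = stats::median(conc)),
                      lower = c(bmax = 1e-12, kd = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  ok <- !is.null(fit) && all(stats::coef(fit) > 1e-9) &&
    max(signal) > 0 && stats::coef(fit)[["bmax"]] > 10 * .Machine$double.eps
  if (!ok || max(abs(signal)) < 1e-12) {
    return(structure(list(bmax = NA_real_, half_saturation = NA_real_,
                          residual_sse = NA_real_, converged = FALSE,
                          wide_ci_flag = wide_ci),
                     class = "binding_fit"))
  }
  p <- stats::coef(fit)
  structure(list(bmax = p[["bmax"]], half_saturation = p[["kd"]],
                 residual_sse = sum(stats::residuals(fit)^2),
                 converged = TRUE, wide_ci_flag = wide_ci),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$converged) {
    cat("binding_fit: fit failure\n")
  } else {
    cat(sprintf("binding_fit: bmax %.3g, half-saturation %.1f nM%s\n",
                x$bmax, x$half_saturation,
                if (x$wide_ci_flag) " [wide CI]" else ""))
  }
  invisible(x)
}

#' Read kinetic traces from a delimited file
#'
#' Expects a `time` column plus one column per replicate.
#'
#' @param path CSV/TSV file.
#' @param sep Field separator (default: guessed from extension).
#' @return List of [kinetic_trace()] objects.
#' @export
read_tht_traces <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  stopifnot("time" %in% names(df), ncol(df) >= 2)
  reps <- setdiff(names(df), "time")
  lapply(seq_along(reps), function(i) {
    kinetic_trace(df$time, df[[reps[i]]], replicate_id = reps[i])
  })
}
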