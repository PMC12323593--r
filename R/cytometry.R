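# Control-calibrated flow-cytometry gating of FLAPS-positive events.

#' Fluorescence threshold from a control community
#'
#' Applies the instrument's electric threshold (events with forward scatter
#' below `fsc_threshold` are discarded) and returns the nearest-rank
#' `quantile` of FL1-H among the surviving control events. The control is an
#' unamended community, or a fixed-and-inactivated sample with FLAPS added
#' (accounting for unspecific binding); the calculation is agnostic to which
#' is supplied.
#'
#' @param control an [event_table()] with at least 100 events surviving the
#'   forward-scatter threshold.
#' @param quantile proportion in `(0, 1]`; default 0.999, so gating the
#'   control against its own threshold scores ~0.1% of events positive.
#' @param fsc_threshold forward-scatter electric threshold (default 17000).
#' @return FL1-H threshold (numeric scalar).
#' @export
control_threshold <- function(control, quantile = 0.999, fsc_threshold = 17000) {
  stopifnot(inherits(control, "event_table"))
  if (quantile <= 0 || quantile > 1)
    stopf("quantile must lie in (0, 1]", class = "flaps_config_error")
  fl1 <- control[["FL1-H"]][control[["FSC-H"]] >= fsc_threshold]
  if (length(fl1) < 100)
    stopf("only %d control events survive FSC-H >= %g; need >= 100 to place a threshold",
          length(fl1), fsc_threshold, class = "flaps_control_insufficiency_error")
  sort(fl1)[max(1L, ceiling(quantile * length(fl1)))]
}

#' Gate FLAPS-positive events in a sample
#'
#' Events surviving the forward-scatter threshold are scored positive when
#' FL1-H strictly exceeds `fl1_threshold` (strict, so a control gated
#' against its own quantile yields ~`1 - quantile` positives). The positive
#' fraction is reported over retained events with a Wilson 95% interval.
#'
#' @param sample an [event_table()].
#' @param fl1_threshold FL1-H threshold, typically from [control_threshold()].
#' @param fsc_threshold forward-scatter electric threshold (default 17000).
#' @return object of class `gate_result`.
#' @export
gate_flaps_positive <- function(sample, fl1_threshold, fsc_threshold = 17000) {
  stopifnot(inherits(sample, "event_table"))
  if (nrow(sample) == 0)
    stopf("sample event table is empty", class = "flaps_gating_error")
  keep <- sample[["FSC-H"]] >= fsc_threshold
  n_after <- sum(keep)
  if (n_after == 0)
    stopf("no events survive FSC-H >= %g", fsc_threshold,
          class = "flaps_gating_error")
  pos <- sample[["FL1-H"]][keep] > fl1_threshold
  n_pos <- sum(pos)
  structure(list(fsc_threshold = fsc_threshold, fl1_threshold = fl1_threshold,
                 n_events_total = nrow(sample), n_after_fsc = n_after,
                 n_positive = n_pos, frac_positive = n_pos / n_after,
                 ci95 = wilson_ci(n_pos, n_after),
                 positive = which(keep)[pos]),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("gate_result: %d events, %d after FSC >= %g, %d positive (%.2f%%, 95%% CI %.2f-%.2f%%)\n",
              x$n_events_total, x$n_after_fsc, x$fsc_threshold, x$n_positive,
              100 * x$frac_positive, 100 * x$ci95[1], 100 * x$ci95[2]))
  cat(sprintf("  FL1-H threshold: %.4g\n", x$fl1_threshold))
  invisible(x)
}

#' @export
as.data.frame.gate_result <- function(x, ...) {
  data.frame(fsc_threshold = x$fsc_threshold, fl1_threshold = x$fl1_threshold,
             n_events_total = x$n_events_total, n_after_fsc = x$n_after_fsc,
             n_positive = x$n_positive, frac_positive = x$frac_positive,
             ci95_lower = x$ci95[1], ci95_upper = x$ci95[2])
}

#' Plot the FL1-H distribution with the control threshold
#'
#' Histogram of log10 FL1-H among events surviving the forward-scatter
#' threshold, with the fluorescence gate drawn as a dashed line.
#'
#' @param x a `gate_result`.
#' @param sample the [event_table()] that was gated.
#' @param ... passed to [graphics::hist()].
#' @export
plot.gate_result <- function(x, sample, ...) {
  fl1 <- sample[["FL1-H"]][sample[["FSC-H"]] >= x$fsc_threshold]
  graphics::hist(log10(pmax(fl1, 1e-6)), breaks = 60,
                 xlab = "log10 FL1-H", main = "FLAPS gate", ...)
  graphics::abline(v = log10(x$fl1_threshold), lty = 2, col = "red")
  invisible(x)
}
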