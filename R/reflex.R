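#' Peak-to-peak reflex amplitude
#'
#' Computes the peak-to-peak amplitude (max minus min, mV) of an EMG trace
#' inside a latency window after the stimulus. The default window of
#' 25-50 ms after the stimulus covers the typical lower-limb H-reflex
#' latency; the bounds are configurable. The measure is invariant to a
#' baseline shift of the trace.
#'
#' @param trace data frame with columns `time_s` (uniform, >= 1000 Hz) and
#'   `emg_mv`.
#' @param stimulus_time_s stimulus time (s), inside the trace.
#' @param window latency window `c(lo, hi)` in seconds after the stimulus.
#' @return amplitude in mV (scalar, >= 0).
#' @export
peak_to_peak <- function(trace, stimulus_time_s, window = c(0.025, 0.050)) {
  stopifnot(all(c("time_s", "emg_mv") %in% names(trace)))
  uniform_dt(trace$time_s, what = "trace time")
  stop_not_finite(trace$emg_mv, "emg_mv")
  stop_not_finite(stimulus_time_s, "stimulus_time_s")
  lo <- stimulus_time_s + window[1L]
  hi <- stimulus_time_s + window[2L]
  if (lo < min(trace$time_s) || hi > max(trace$time_s)) {
    abort(sprintf("scoring window [%.3f, %.3f] s exceeds trace extent", lo, hi))
  }
  sel <- trace$time_s >= lo & trace$time_s <= hi
  seg <- trace$emg_mv[sel]
  max(seg) - min(seg)
}

#' Score all trials of a reflex trial set
#'
#' Applies [peak_to_peak()] to every trial of a trial set (as produced by
#' [generate_reflex_trials()] or read from disk) and appends an
#' `amplitude_mv` column.
#'
#' @param trials tibble with columns `trial`, `stimulus_time_s`, `cycle_pct`
#'   and a list-column `trace` of per-trial EMG traces.
#' @param window latency window passed to [peak_to_peak()].
#' @return the input tibble with an `amplitude_mv` column.
#' @export
reflex_amplitudes <- function(trials, window = c(0.025, 0.050)) {
  stopifnot(all(c("stimulus_time_s", "trace") %in% names(trials)))
  dplyr::mutate(trials, amplitude_mv = purrr::map2_dbl(
    .data$trace, .data$stimulus_time_s,
    function(tr, ts) peak_to_peak(tr, ts, window = window)))
}

#' Bin reflex amplitudes over the gait cycle
#'
#' Assigns each trial to one of `n_bins` equal bins over the gait cycle by
#' its stimulus position (bin index `floor(pct / (100 / n_bins))`) and
#' averages the amplitudes within each bin. Bins with fewer than
#' `min_trials` trials are flagged (the measurement protocol aims for at
#' least ten reflexes per bin).
#'
#' @param trials tibble with columns `cycle_pct` and `amplitude_mv` (run
#'   [reflex_amplitudes()] first if amplitudes are missing).
#' @param n_bins number of bins (default 16).
#' @param min_trials minimum trials per bin before a bin is trusted.
#' @return tibble of class `binned_reflexes` with one row per bin: `bin`
#'   (1-based), `bin_center_pct`, `n`, `mean_amplitude_mv` (NA when empty),
#'   `flagged`.
#' @export
bin_and_average <- function(trials, n_bins = 16, min_trials = 10) {
  width <- 100 / n_bins
  centers <- width / 2 + width * (seq_len(n_bins) - 1L)
  if (nrow(trials) == 0L) {
    out <- tibble(bin = seq_len(n_bins), bin_center_pct = centers,
                  n = 0L, mean_amplitude_mv = NA_real_, flagged = TRUE)
  } else {
    stopifnot(all(c("cycle_pct", "amplitude_mv") %in% names(trials)))
    idx <- pmin(n_bins, floor(wrap_pct(trials$cycle_pct) / width) + 1L)
    agg <- dplyr::summarise(
      dplyr::group_by(tibble(bin = idx, amplitude = trials$amplitude_mv),
                      .data$bin),
      n = dplyr::n(), mean_amplitude_mv = mean(.data$amplitude),
      .groups = "drop")
    out <- dplyr::left_join(tibble(bin = seq_len(n_bins),
                                   bin_center_pct = centers),
                            agg, by = "bin")
    out$n[is.na(out$n)] <- 0L
    out$flagged <- out$n < min_trials
  }
  class(out) <- c("binned_reflexes", class(out))
  out
}

#' Build a modulation curve from binned reflex amplitudes
#'
#' Normalizes the per-bin mean amplitudes by their maximum (so the largest
#' bin maps to 1; absent swing-phase suppression therefore shows up as
#' values near 1 rather than being rescaled away) and interpolates the
#' normalized values into a continuous periodic curve via
#' [modulation_curve()]. Empty bins are filled by periodic linear
#' interpolation from their neighbours before splining. If all bins carry
#' the same amplitude the curve is the constant 1.
#'
#' @param binned a [bin_and_average()] result with at least 2 non-empty bins.
#' @return a [modulation_curve()].
#' @export
normalize_and_interpolate <- function(binned) {
  stopifnot(inherits(binned, "binned_reflexes"))
  vals <- binned$mean_amplitude_mv
  have <- which(!is.na(vals))
  if (length(have) < 2L) abort("need at least 2 non-empty bins")
  if (length(have) < length(vals)) {
    vals <- periodic_approx(binned$bin_center_pct[have], vals[have],
                            binned$bin_center_pct)
  }
  if (any(vals < 0)) abort("negative mean amplitudes are not meaningful")
  mx <- max(vals)
  norm <- if (mx > 0) vals / mx else rep(1, length(vals))
  # guard against round-off pushing a ratio above 1
  modulation_curve(pmin(1, norm), binned$bin_center_pct)
}

#' Full reflex-processing pipeline
#'
#' Convenience wrapper: scores amplitudes, bins them over the cycle and
#' returns the normalized continuous modulation curve.
#'
#' @inheritParams reflex_amplitudes
#' @inheritParams bin_and_average
#' @return a [modulation_curve()].
#' @export
reflex_modulation_curve <- function(trials, window = c(0.025, 0.050),
                                    n_bins = 16, min_trials = 10) {
  trials |>
    reflex_amplitudes(window = window) |>
    bin_and_average(n_bins = n_bins, min_trials = min_trials) |>
    normalize_and_interpolate()
}
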