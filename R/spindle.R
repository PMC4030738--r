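#' Muscle-spindle feedback parameters
#'
#' Per-muscle-group feedback gains and time constants of the spindle model.
#' The length pathway is a first-order filter with time constant `tau_l` and
#' gain `g_l` driven by normalized fiber length; the velocity pathway has time
#' constant `tau_v` and gain `g_v` and is driven by the positive part of the
#' normalized lengthening velocity. Feedback of either kind is only present
#' while the muscle is lengthening.
#'
#' @param muscle_group one of `"soleus"`, `"gastrocnemius"`, `"vasti"`,
#'   `"rectus_femoris"`.
#' @param tau_l,tau_v time constants in seconds (> 0).
#' @param g_l,g_v dimensionless feedback gains (>= 0).
#' @return an object of class `spindle_params`.
#' @examples
#' p <- spindle_params("soleus", tau_l = 0.075, tau_v = 0.040,
#'                     g_l = 0.1, g_v = 0.59)
#' @export
spindle_params <- function(muscle_group, tau_l, tau_v, g_l, g_v) {
  muscle_group <- match.arg(muscle_group, spindle_muscle_groups())
  stop_not_finite(tau_l, "tau_l"); stop_not_finite(tau_v, "tau_v")
  stop_not_finite(g_l, "g_l"); stop_not_finite(g_v, "g_v")
  if (tau_l <= 0 || tau_v <= 0) abort("time constants must be positive")
  if (g_l < 0 || g_v < 0) abort("feedback gains must be non-negative")
  structure(list(muscle_group = muscle_group, tau_l = tau_l, tau_v = tau_v,
                 g_l = g_l, g_v = g_v),
            class = "spindle_params")
}

#' @export
print.spindle_params <- function(x, ...) {
  cat(sprintf("<spindle_params> %s: tau_l=%g s, tau_v=%g s, g_l=%g, g_v=%g\n",
              x$muscle_group, x$tau_l, x$tau_v, x$g_l, x$g_v))
  invisible(x)
}

#' Muscle groups with modeled spindle feedback
#' @return character vector of the four feedback muscle groups.
#' @export
spindle_muscle_groups <- function() {
  c("soleus", "gastrocnemius", "vasti", "rectus_femoris")
}

#' Default spindle parameter table
#'
#' Reads the parameter file shipped with the package: time constants and
#' length/velocity gains per feedback muscle group, in a reference profile
#' and a stroke profile (gains three times the reference values). The stroke
#' profile corresponds to one of the hyperexcitability multipliers studied;
#' [scale_gains()] applies arbitrary multipliers.
#'
#' @param profile `"reference"` or `"stroke"`.
#' @return a tibble with columns `muscle_group`, `tau_l_s`, `tau_v_s`,
#'   `g_l`, `g_v`.
#' @export
default_spindle_params <- function(profile = c("reference", "stroke")) {
  profile <- match.arg(profile)
  tab <- utils::read.csv(pkg_extdata("spindle_params.csv"),
                         stringsAsFactors = FALSE)
  out <- tab[tab$profile == profile,
             c("muscle_group", "tau_l_s", "tau_v_s", "g_l", "g_v")]
  as_tibble(out)
}

# internal: one row of the default table -> spindle_params
spindle_params_for <- function(muscle_group,
                               profile = "reference",
                               factor_l = 1, factor_v = 1) {
  tab <- default_spindle_params(profile)
  row <- tab[tab$muscle_group == muscle_group, ]
  if (nrow(row) != 1L) abort(sprintf("unknown muscle group '%s'", muscle_group))
  scale_gains(spindle_params(muscle_group, row$tau_l_s, row$tau_v_s,
                             row$g_l, row$g_v),
              factor_l, factor_v)
}

#' Scale spindle feedback gains
#'
#' Multiplies the length and velocity gains by independent factors (the
#' hyperexcitability manipulation); time constants are unchanged.
#'
#' @param params a [spindle_params()] object.
#' @param factor_l,factor_v non-negative multipliers for `g_l` and `g_v`.
#' @return a new `spindle_params` object.
#' @export
scale_gains <- function(params, factor_l = 1, factor_v = 1) {
  stopifnot(inherits(params, "spindle_params"))
  stop_not_finite(factor_l, "factor_l"); stop_not_finite(factor_v, "factor_v")
  if (factor_l < 0 || factor_v < 0) abort("gain factors must be non-negative")
  spindle_params(params$muscle_group, params$tau_l, params$tau_v,
                 params$g_l * factor_l, params$g_v * factor_v)
}

#' Time derivatives of the spindle feedback states
#'
#' Right-hand side of the two first-order feedback filters. The length
#' pathway is driven by `k * g_l * l_norm` while the muscle lengthens
#' (`v_norm > 0`) and decays otherwise; the velocity pathway is driven by
#' `k * g_v * max(0, v_norm)`.
#'
#' @param state list or named vector with elements `u_l`, `u_v` (>= 0).
#' @param fiber list or named vector with `l_norm` (> 0) and `v_norm`
#'   (positive while lengthening).
#' @param k reflex modulation factor in `[0, 1]`.
#' @param params a [spindle_params()] object.
#' @return named list with `du_l`, `du_v` (1/s).
#' @examples
#' p <- spindle_params_for("soleus")
#' spindle_derivatives(list(u_l = 0, u_v = 0),
#'                     list(l_norm = 1, v_norm = 1), k = 1, params = p)
#' @export
spindle_derivatives <- function(state, fiber, k, params) {
  stopifnot(inherits(params, "spindle_params"))
  u_l <- state[["u_l"]]; u_v <- state[["u_v"]]
  l_norm <- fiber[["l_norm"]]; v_norm <- fiber[["v_norm"]]
  stop_not_finite(u_l, "u_l"); stop_not_finite(u_v, "u_v")
  stop_not_finite(l_norm, "l_norm"); stop_not_finite(v_norm, "v_norm")
  stop_not_finite(k, "k")
  if (any(k < 0 | k > 1)) abort("modulation factor k must lie in [0, 1]")
  if (any(l_norm <= 0)) abort("l_norm must be positive")
  drive_l <- ifelse(v_norm > 0, k * params$g_l * l_norm, 0)
  drive_v <- k * params$g_v * pmax(0, v_norm)
  list(du_l = (-u_l + drive_l) / params$tau_l,
       du_v = (-u_v + drive_v) / params$tau_v)
}

#' Integrate the spindle feedback filters over a sampled drive
#'
#' Integrates both feedback filters along a time-indexed fiber and modulation
#' series. Because the filters are linear first-order systems given sampled
#' drives, each step uses the exact exponential update with sample-and-hold
#' drives, which is unconditionally stable and independent of the multibody
#' integrator. `dt` must still resolve the filter dynamics (`dt <=
#' min(tau_l, tau_v) / 2`) so that the held drive is an adequate model of the
#' continuous signal.
#'
#' @param data data frame with columns `time` (s, uniform grid), `l_norm`,
#'   `v_norm` and `k` (modulation factor in `[0, 1]`).
#' @param params a [spindle_params()] object.
#' @param initial named vector `c(u_l = , u_v = )` of initial feedback
#'   excitations (default zero).
#' @return a tibble with columns `time`, `u_l`, `u_v`.
#' @examples
#' p <- spindle_params_for("soleus")
#' d <- tibble::tibble(time = seq(0, 1, by = 0.001), l_norm = 1,
#'                     v_norm = 1, k = 1)
#' tail(integrate_spindle(d, p), 1)  # u_v ~ g_v = 0.59
#' @export
integrate_spindle <- function(data, params, initial = c(u_l = 0, u_v = 0)) {
  stopifnot(inherits(params, "spindle_params"))
  need <- c("time", "l_norm", "v_norm", "k")
  if (!all(need %in% names(data))) {
    abort(sprintf("data must have columns %s", paste(need, collapse = ", ")))
  }
  dt <- uniform_dt(data$time)
  if (dt > min(params$tau_l, params$tau_v) / 2) {
    abort(sprintf(
      "dt = %g s too large for time constants (must be <= min(tau)/2 = %g s)",
      dt, min(params$tau_l, params$tau_v) / 2))
  }
  for (col in c("l_norm", "v_norm", "k")) stop_not_finite(data[[col]], col)
  if (any(data$k < 0 | data$k > 1)) abort("modulation factor k must lie in [0, 1]")
  n <- nrow(data)
  drive_l <- ifelse(data$v_norm > 0, data$k * params$g_l * data$l_norm, 0)
  drive_v <- data$k * params$g_v * pmax(0, data$v_norm)
  el <- exp(-dt / params$tau_l); ev <- exp(-dt / params$tau_v)
  u_l <- numeric(n); u_v <- numeric(n)
  u_l[1L] <- initial[["u_l"]]; u_v[1L] <- initial[["u_v"]]
  for (i in seq_len(n - 1L)) {
    u_l[i + 1L] <- u_l[i] * el + drive_l[i] * (1 - el)
    u_v[i + 1L] <- u_v[i] * ev + drive_v[i] * (1 - ev)
  }
  tibble(time = data$time, u_l = u_l, u_v = u_v)
}

#' Total motoneuron drive
#'
#' Sum of the base excitation and the two spindle feedback excitations.
#' Saturation to the physiological range is applied separately by
#' [saturate_excitation()].
#'
#' @param u_b,u_l,u_v base, length-feedback and velocity-feedback excitations.
#' @return the unsaturated total excitation.
#' @export
total_excitation <- function(u_b, u_l, u_v) {
  stop_not_finite(u_b, "u_b"); stop_not_finite(u_l, "u_l")
  stop_not_finite(u_v, "u_v")
  u_b + u_l + u_v
}

#' Saturate a total excitation into the neural output range
#'
#' Clips the total excitation to `[0, 1]`: values above 1 saturate at 1.
#' Negative totals (possible when a negative base excitation outweighs the
#' feedback) are clamped to 0, since physiological excitations are
#' non-negative.
#'
#' @param u_tot total excitation (any finite value).
#' @return excitation in `[0, 1]`.
#' @export
saturate_excitation <- function(u_tot) {
  stop_not_finite(u_tot, "u_tot")
  pmin(1, pmax(0, u_tot))
}

#' Decompose a tracking excitation into base and feedback parts
#'
#' Given the total tracking excitation `u_cmc` of a muscle over the reference
#' gait cycle, integrates the spindle filters along the reference fiber and
#' modulation series and subtracts, point-wise, the feedback excitations:
#' `u_b = u_cmc - u_l - u_v`. The base excitation is kept even where it is
#' negative (so that reassembling the three parts reconstructs `u_cmc`
#' exactly); any negative samples are reported through the `n_negative_u_b`
#' attribute and a diagnostic warning.
#'
#' @param data data frame with columns `time` (s, uniform), `u_cmc` in
#'   `[0, 1]`, `l_norm`, `v_norm`, `k`.
#' @param params a [spindle_params()] object (the fixed reference gains).
#' @param initial initial spindle state as in [integrate_spindle()].
#' @param quiet suppress the negative-base-excitation warning.
#' @return a tibble of class `excitation_decomposition` with columns `time`,
#'   `u_cmc`, `u_b`, `u_l`, `u_v`; attributes `params` and `n_negative_u_b`.
#' @export
fit_reference_gains <- function(data, params, initial = c(u_l = 0, u_v = 0),
                                quiet = FALSE) {
  if (!"u_cmc" %in% names(data)) abort("data must have a column 'u_cmc'")
  stop_not_finite(data$u_cmc, "u_cmc")
  if (any(data$u_cmc < -1e-12 | data$u_cmc > 1 + 1e-12)) {
    abort("u_cmc must lie in [0, 1]")
  }
  fb <- integrate_spindle(data, params, initial = initial)
  u_b <- data$u_cmc - fb$u_l - fb$u_v
  n_neg <- sum(u_b < 0)
  if (n_neg > 0 && !quiet) {
    warn(sprintf(
      "feedback exceeds u_cmc at %d of %d samples; u_b kept negative there so the decomposition stays exact",
      n_neg, length(u_b)))
  }
  out <- tibble(time = data$time, u_cmc = data$u_cmc,
                u_b = u_b, u_l = fb$u_l, u_v = fb$u_v)
  attr(out, "params") <- params
  attr(out, "n_negative_u_b") <- n_neg
  class(out) <- c("excitation_decomposition", class(out))
  out
}

#' @rdname fit_reference_gains
#' @param x an `excitation_decomposition`.
#' @param ... unused.
#' @method glance excitation_decomposition
#' @export
glance.excitation_decomposition <- function(x, ...) {
  recon <- x$u_b + x$u_l + x$u_v
  tibble(
    n = nrow(x),
    max_reconstruction_error = max(abs(recon - x$u_cmc)),
    n_negative_u_b = attr(x, "n_negative_u_b"),
    mean_feedback_fraction = mean((x$u_l + x$u_v) / pmax(x$u_cmc, 1e-9))
  )
}
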