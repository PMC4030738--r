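# Synthetic reference gait, modulation presets and reflex-trial generator.
# Everything here is deterministic for a fixed spec/seed so the rest of the
# package is testable without measured data.

# --- truncated Fourier series over the gait cycle ---------------------------

fit_fourier <- function(pct, values, n_harmonics = 6) {
  stopifnot(length(pct) == length(values))
  sp <- stats::splinefun(c(pct, pct[1L] + 100), c(values, values[1L]),
                         method = "periodic")
  m <- 512L
  xs <- seq(0, 100, length.out = m + 1L)[-(m + 1L)]
  ys <- sp(ifelse(xs >= pct[1L], xs, xs + 100))
  cf <- stats::fft(ys) / m
  k <- seq_len(n_harmonics)
  list(a0 = Re(cf[1L]), a = 2 * Re(cf[k + 1L]), b = -2 * Im(cf[k + 1L]))
}

eval_fourier <- function(cf, pct, cycle_s = 1, deriv = 0) {
  k <- seq_along(cf$a)
  phi <- outer(2 * pi * pct / 100, k)   # n x K
  w <- 2 * pi / cycle_s                 # rad per s for harmonic 1
  if (deriv == 0) {
    cf$a0 + as.vector(cos(phi) %*% cf$a + sin(phi) %*% cf$b)
  } else if (deriv == 1) {
    as.vector((-sin(phi) %*% (cf$a * k) + cos(phi) %*% (cf$b * k))) * w
  } else if (deriv == 2) {
    as.vector((-cos(phi) %*% (cf$a * k^2) - sin(phi) %*% (cf$b * k^2))) * w^2
  } else {
    abort("deriv must be 0, 1 or 2")
  }
}

# --- fixture specification ---------------------------------------------------

#' Specification of the synthetic reference gait
#'
#' Parameters of the synthetic slow-treadmill-walking fixture: cycle
#' duration (2.2 s by default, matching walking at 1 km/h), Fourier order of
#' the joint-angle series, the target quasi-static penetration of the
#' lowest contact sphere (which sets the scale of the simulated ground
#' reaction force), and an optional seeded jitter applied to the joint-angle
#' template knots.
#'
#' @param cycle_s gait cycle duration in s.
#' @param seed integer seed (used when `jitter_deg > 0`).
#' @param n_harmonics Fourier order for the joint-angle series.
#' @param jitter_deg s.d. of seeded random jitter on the angle knots (deg).
#' @param penetration_m target stance penetration of the lowest sphere (m).
#' @param grid_pct sampling step of the stored tables (% of cycle).
#' @export
gait_fixture_spec <- function(cycle_s = 2.2, seed = 1L, n_harmonics = 6,
                              jitter_deg = 0, penetration_m = 0.003,
                              grid_pct = 0.5) {
  stopifnot(cycle_s > 0, n_harmonics >= 1, penetration_m > 0)
  structure(list(cycle_s = cycle_s, seed = as.integer(seed),
                 n_harmonics = n_harmonics, jitter_deg = jitter_deg,
                 penetration_m = penetration_m, grid_pct = grid_pct),
            class = "gait_fixture_spec")
}

# joint-angle template knots (deg); right side, cycle starts at right heel
# strike; the left side is the same template shifted by half a cycle
gait_angle_knots <- function() {
  list(
    hip = list(pct = c(0, 10, 30, 50, 60, 75, 90),
               deg = c(25, 22, 8, -8, -5, 15, 25)),
    knee = list(pct = c(0, 10, 20, 40, 50, 62, 75, 85, 95),
                deg = c(5, 12, 10, 5, 8, 35, 60, 35, 10)),
    ankle = list(pct = c(0, 8, 30, 45, 55, 62, 70, 80, 90),
                 deg = c(0, -8, 5, 10, 0, -18, -12, -5, 0)),
    pelvis_tilt = list(pct = c(0, 25, 50, 75), deg = c(2, 0, 2, 0)),
    pelvis_tx = list(pct = c(0, 30, 50, 80), m = c(0, 0.012, 0, 0.012)))
}

#' Generate the synthetic reference gait trajectory
#'
#' Builds smooth periodic sagittal joint-angle trajectories (truncated
#' Fourier series through physiological template knots for slow treadmill
#' walking; right heel strike at 0% of the cycle, left side shifted by
#' half a cycle), then derives the pelvis vertical trajectory so the lowest
#' foot contact sphere maintains a small stance penetration — which makes
#' the kinematics compatible with the elastic-foundation contact model.
#' Also returns plausible base excitation bursts per muscle and a
#' double-bump vertical GRF trace per leg whose impulse over the cycle
#' equals body weight times cycle duration.
#'
#' @param spec a [gait_fixture_spec()].
#' @param model a [skeleton_model()] (used for foot geometry).
#' @return object of class `gait_trajectory` with elements `kinematics`
#'   (tibble; angles in deg, translations in m), `excitations` (tibble in
#'   `[0, 1]`), `grf` (tibble, N), `basis` (Fourier coefficients, SI
#'   units), `cycle_s`, `body_mass`.
#' @export
generate_reference_gait <- function(spec = gait_fixture_spec(),
                                    model = skeleton_model()) {
  kn <- gait_angle_knots()
  if (spec$jitter_deg > 0) {
    set.seed(spec$seed)
    for (j in c("hip", "knee", "ankle")) {
      kn[[j]]$deg <- kn[[j]]$deg + stats::rnorm(length(kn[[j]]$deg),
                                                sd = spec$jitter_deg)
    }
  }
  K <- spec$n_harmonics
  cf_hip <- fit_fourier(kn$hip$pct, deg2rad(kn$hip$deg), K)
  cf_knee <- fit_fourier(kn$knee$pct, deg2rad(kn$knee$deg), K)
  cf_ankle <- fit_fourier(kn$ankle$pct, deg2rad(kn$ankle$deg), K)
  cf_tilt <- fit_fourier(kn$pelvis_tilt$pct, deg2rad(kn$pelvis_tilt$deg), K)
  cf_tx <- fit_fourier(kn$pelvis_tx$pct, kn$pelvis_tx$m, K)
  shift50 <- function(cf) {
    # phase-shift a Fourier series by half a cycle: odd harmonics flip sign
    k <- seq_along(cf$a); s <- cos(pi * k)
    list(a0 = cf$a0, a = cf$a * s, b = cf$b * s)
  }
  basis <- list(
    pelvis_tx = cf_tx, pelvis_ty = NULL, pelvis_tilt = cf_tilt,
    hip_r = cf_hip, knee_r = cf_knee, ankle_r = cf_ankle,
    hip_l = shift50(cf_hip), knee_l = shift50(cf_knee),
    ankle_l = shift50(cf_ankle))

  # pelvis height: softmin of the sphere-bottom heights at pelvis_ty = 0,
  # offset so the lowest sphere penetrates by ~penetration_m, then smoothed
  # by a higher-order Fourier fit
  pg <- seq(0, 100, by = 0.25); pg <- pg[-length(pg)]
  bmin <- vapply(pg, function(p) {
    q <- numeric(9)
    for (j in setdiff(coord_names(), c("pelvis_ty"))) {
      q[match(j, coord_names())] <- eval_fourier(basis[[j]], p)
    }
    sk <- sphere_kinematics(model, q, numeric(9))
    b <- sk$pos[, 2L] - model$spheres$radius
    -log(sum(exp(-600 * b))) / 600
  }, numeric(1))
  cf_ty <- fit_fourier(pg, -spec$penetration_m - bmin, 12)
  basis$pelvis_ty <- cf_ty

  grid <- seq(0, 100, by = spec$grid_pct)
  tgrid <- grid * spec$cycle_s / 100
  kin <- tibble(time = tgrid, cycle_pct = grid)
  for (j in coord_names()) {
    v <- eval_fourier(basis[[j]], grid)
    kin[[j]] <- if (j %in% angle_coords()) rad2deg(v) else v
  }

  exc <- excitation_bursts(grid)
  exc <- dplyr::bind_cols(tibble(time = tgrid, cycle_pct = grid), exc)

  bw <- model$body_mass * model$gravity
  shape <- function(p) cos_bump(p, 15, 15) + cos_bump(p, 47, 15) +
    0.55 * cos_bump(p, 31, 18)
  fr <- shape(grid); flft <- shape(wrap_pct(grid - 50))
  scale <- bw / mean(fr + flft)
  grf <- tibble(time = tgrid, cycle_pct = grid,
                vgrf_r_n = scale * fr, vgrf_l_n = scale * flft,
                vgrf_n = scale * (fr + flft))

  structure(list(kinematics = kin, excitations = exc, grf = grf,
                 basis = basis, cycle_s = spec$cycle_s,
                 body_mass = model$body_mass, spec = spec),
            class = "gait_trajectory")
}

# base excitation bursts (raised-cosine bumps on the cycle), right-side
# template; left shifted by half a cycle
excitation_bursts <- function(pct) {
  tmpl <- list(
    soleus = cbind(c(35, 22, 0.40)),
    gastrocnemius = cbind(c(45, 15, 0.35)),
    vasti = cbind(c(12, 14, 0.35)),
    rectus_femoris = cbind(c(60, 10, 0.20), c(5, 8, 0.15)),
    tibialis_anterior = cbind(c(85, 20, 0.30), c(3, 8, 0.25)),
    hamstrings = cbind(c(95, 12, 0.35), c(8, 10, 0.25)),
    iliopsoas = cbind(c(65, 12, 0.30)),
    gluteals = cbind(c(10, 15, 0.30)))
  ev <- function(bumps, p) {
    out <- rep(0.02, length(p))  # small tonic background
    for (i in seq_len(ncol(bumps))) {
      out <- out + cos_bump(p, bumps[1, i], bumps[2, i], bumps[3, i])
    }
    pmin(out, 1)
  }
  out <- list()
  for (g in names(tmpl)) {
    out[[paste0(g, "_r")]] <- ev(tmpl[[g]], pct)
    out[[paste0(g, "_l")]] <- ev(tmpl[[g]], wrap_pct(pct - 50))
  }
  as_tibble(out)
}

#' @export
print.gait_trajectory <- function(x, ...) {
  cat(sprintf("<gait_trajectory> cycle %.2f s, %d samples, body mass %.1f kg\n",
              x$cycle_s, nrow(x$kinematics), x$body_mass))
  invisible(x)
}

#' @rdname generate_reference_gait
#' @param x a `gait_trajectory`.
#' @param ... unused.
#' @method tidy gait_trajectory
#' @export
tidy.gait_trajectory <- function(x, ...) {
  tidyr::pivot_longer(x$kinematics, cols = -c("time", "cycle_pct"),
                      names_to = "coordinate", values_to = "value")
}

#' @rdname generate_reference_gait
#' @param object a `gait_trajectory`.
#' @method autoplot gait_trajectory
#' @export
autoplot.gait_trajectory <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$coordinate %in% c("hip_r", "knee_r", "ankle_r"), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle_pct, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~coordinate, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "gait cycle (%)", y = "joint angle (deg)")
}

# evaluate the trajectory's coordinates (SI units, rad) at arbitrary times;
# deriv 0/1/2 gives q, qdot, qddot
eval_gait_coords <- function(traj, t, deriv = 0) {
  pct <- wrap_pct(100 * t / traj$cycle_s)
  out <- matrix(0, length(t), 9, dimnames = list(NULL, coord_names()))
  for (j in coord_names()) {
    out[, j] <- eval_fourier(traj$basis[[j]], pct, traj$cycle_s, deriv)
  }
  out
}

#' Normalized fiber states along a trajectory
#'
#' Evaluates, for every muscle with spindle feedback (the four groups on
#' each side), the rigid-tendon normalized fiber length and velocity along
#' the reference trajectory.
#'
#' @param model a [skeleton_model()].
#' @param traj a [generate_reference_gait()] trajectory.
#' @param at gait-cycle positions (% of cycle) at which to evaluate.
#' @return long tibble with `time`, `cycle_pct`, `muscle`, `group`, `side`,
#'   `l_norm`, `v_norm`.
#' @export
fiber_state_series <- function(model, traj, at = seq(0, 99.5, by = 0.5)) {
  t <- at * traj$cycle_s / 100
  q <- eval_gait_coords(traj, t, 0)
  qd <- eval_gait_coords(traj, t, 1)
  fb <- which(model$muscles$group %in% spindle_muscle_groups())
  res <- list()
  for (i in fb) {
    L <- model$muscles$l_ref_m[i] - as.vector(q %*% model$Rm[i, ])
    v <- -as.vector(qd %*% model$Rm[i, ])
    ns <- normalized_fiber_state(model$muscles[i, ], L, v)
    res[[length(res) + 1L]] <- tibble(
      time = t, cycle_pct = at, muscle = model$muscles$muscle[i],
      group = model$muscles$group[i], side = model$muscles$side[i],
      l_norm = ns$l_norm, v_norm = ns$v_norm)
  }
  dplyr::bind_rows(res)
}

#' Reflex modulation presets
#'
#' Hand-specified 16-bin modulation patterns shaped like published
#' gait-phase reflex modulation: plantarflexor curves (shared by soleus and
#' gastrocnemius, H-reflex-like) peak during stance and are suppressed to
#' near zero during swing in the reference condition, while the stroke
#' preset lacks the swing-phase suppression; quadriceps curves (vasti and
#' rectus femoris, tendon-jerk-like) behave analogously. These presets are
#' shaped after the literature, not digitized data.
#'
#' @return nested list: `presets[[muscle_group]][[condition]]` is a
#'   [modulation_curve()], with conditions `reference` and `stroke`.
#' @export
generate_modulation_presets <- function() {
  pf_ref <- c(0.35, 0.55, 0.75, 0.90, 1.00, 1.00, 0.90, 0.75,
              0.50, 0.25, 0.08, 0.03, 0.02, 0.02, 0.05, 0.15)
  pf_str <- c(0.55, 0.70, 0.85, 0.95, 1.00, 1.00, 0.95, 0.90,
              0.80, 0.75, 0.70, 0.65, 0.60, 0.60, 0.60, 0.60)
  qd_ref <- c(0.90, 1.00, 0.85, 0.60, 0.45, 0.40, 0.45, 0.50,
              0.45, 0.30, 0.15, 0.08, 0.05, 0.05, 0.10, 0.40)
  qd_str <- c(0.85, 1.00, 0.90, 0.80, 0.70, 0.65, 0.65, 0.70,
              0.70, 0.65, 0.60, 0.55, 0.50, 0.50, 0.55, 0.70)
  mk <- function(ref, str) list(reference = modulation_curve(ref),
                                stroke = modulation_curve(str))
  list(soleus = mk(pf_ref, pf_str),
       gastrocnemius = mk(pf_ref, pf_str),
       vasti = mk(qd_ref, qd_str),
       rectus_femoris = mk(qd_ref, qd_str))
}

#' Generate synthetic stimulus-locked reflex trials
#'
#' Inverse of the reflex-processing chain, for round-trip testing: for each
#' of `n_bins` gait-cycle bins, `n_per_bin` trials are created with the
#' stimulus placed at the bin center and a clean biphasic reflex wave of
#' peak-to-peak amplitude `amplitude_mv * curve(bin center)` (plus optional
#' Gaussian amplitude noise) inserted 27.5-37.5 ms after the stimulus —
#' inside the default 25-50 ms scoring window.
#'
#' @param curve a [modulation_curve()] giving the shape to encode.
#' @param n_per_bin trials per bin (the protocol records at least ten).
#' @param noise_sd s.d. of Gaussian amplitude noise (mV).
#' @param seed integer seed.
#' @param n_bins number of gait-cycle bins.
#' @param amplitude_mv amplitude scale (mV) of a bin at modulation 1.
#' @param fs trace sampling rate (Hz, >= 1000).
#' @return tibble with `trial`, `bin`, `cycle_pct`, `stimulus_time_s`,
#'   `amplitude_true_mv` and list-column `trace`.
#' @export
generate_reflex_trials <- function(curve, n_per_bin = 10, noise_sd = 0,
                                   seed = 1L, n_bins = 16,
                                   amplitude_mv = 1, fs = 2000) {
  stopifnot(inherits(curve, "modulation_curve"), n_per_bin >= 1, fs >= 1000)
  set.seed(seed)
  width <- 100 / n_bins
  centers <- width / 2 + width * (seq_len(n_bins) - 1L)
  tt <- seq(0, 0.2, by = 1 / fs)
  ts <- 0.1
  rows <- list()
  id <- 0L
  for (b in seq_len(n_bins)) {
    base_amp <- amplitude_mv * predict(curve, centers[b])
    for (r in seq_len(n_per_bin)) {
      id <- id + 1L
      amp <- max(0, base_amp + if (noise_sd > 0) stats::rnorm(1, sd = noise_sd) else 0)
      emg <- numeric(length(tt))
      in_wave <- tt >= ts + 0.0275 & tt <= ts + 0.0375 + 1e-12
      emg[in_wave] <- amp / 2 * sin(2 * pi * 100 * (tt[in_wave] - ts - 0.0275))
      rows[[id]] <- tibble(
        trial = id, bin = b, cycle_pct = centers[b], stimulus_time_s = ts,
        amplitude_true_mv = amp,
        trace = list(tibble(time_s = tt, emg_mv = emg)))
    }
  }
  dplyr::bind_rows(rows)
}
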