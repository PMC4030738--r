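#' Gait-phase partition of the cycle
#'
#' The eight named gait phases partition `[0, 100)` % of the gait cycle
#' exactly: Initial Contact 0-5, Loading Response 5-20, Mid Stance 20-35,
#' Terminal Stance 35-50, Pre-Swing 50-70, Initial Swing 70-80, Mid Swing
#' 80-95, Terminal Swing 95-100.
#'
#' @return tibble with `phase`, `start_pct`, `end_pct`.
#' @export
gait_phases <- function() {
  tibble(phase = c("Initial Contact", "Loading Response", "Mid Stance",
                   "Terminal Stance", "Pre-Swing", "Initial Swing",
                   "Mid Swing", "Terminal Swing"),
         start_pct = c(0, 5, 20, 35, 50, 70, 80, 95),
         end_pct = c(5, 20, 35, 50, 70, 80, 95, 100))
}

#' Interval specification of the segmented protocol
#'
#' The open-loop forward simulation is run in short intervals (5% of the
#' cycle by default, about 0.11 s) to limit integration-error growth, each
#' preceded by a discarded lead-in (1% by default) during which the
#' feedback excitations adapt to the interval's kinematics.
#'
#' @param length_pct interval length in % of the cycle.
#' @param overlap_pct lead-in overlap in % of the cycle.
#' @param dt integration step in s.
#' @export
interval_spec <- function(length_pct = 5, overlap_pct = 1, dt = 5e-4) {
  if (!(overlap_pct > 0 && overlap_pct < length_pct && length_pct <= 100)) {
    abort("need 0 < overlap < length <= 100")
  }
  if (100 %% length_pct != 0) abort("length_pct must divide 100")
  structure(list(length_pct = length_pct, overlap_pct = overlap_pct, dt = dt),
            class = "interval_spec")
}

#' A feedback manipulation condition
#'
#' One hemiparetic simulation condition: the spindle gains of one muscle
#' group are multiplied by `factor_l` (length) and `factor_v` (velocity),
#' and that group's reflex-modulation pattern is switched to the given
#' preset, on the affected side. All other muscles keep reference
#' parameters.
#'
#' @param muscle_group one of [spindle_muscle_groups()].
#' @param factor_l,factor_v non-negative gain multipliers.
#' @param modulation `"reference"` or `"stroke"` preset (or a
#'   [modulation_curve()]).
#' @param side `"right"`, `"left"` or `"both"` (the affected side).
#' @param label optional condition label.
#' @export
feedback_condition <- function(muscle_group, factor_l = 3, factor_v = 3,
                               modulation = "stroke", side = "right",
                               label = NULL) {
  muscle_group <- match.arg(muscle_group, spindle_muscle_groups())
  side <- match.arg(side, c("right", "left", "both"))
  if (factor_l < 0 || factor_v < 0) abort("gain factors must be non-negative")
  if (is.null(label)) {
    mod_lab <- if (is.character(modulation)) modulation else "custom"
    label <- sprintf("%s l%g v%g %s", muscle_group, factor_l, factor_v, mod_lab)
  }
  structure(list(muscle_group = muscle_group, factor_l = factor_l,
                 factor_v = factor_v, modulation = modulation,
                 side = side, label = label),
            class = "feedback_condition")
}

#' Prepare the reference simulation setup
#'
#' Bundles everything the segmented protocol needs: the model, the
#' reference trajectory, the tracking excitations and reserves, the
#' modulation presets, the spindle parameters, and the decomposition of
#' each feedback muscle's tracking excitation into base and feedback parts
#' (the base excitations are what all conditions share).
#'
#' @param model a [skeleton_model()].
#' @param traj a [generate_reference_gait()] trajectory.
#' @param tracking optional precomputed [compute_tracking_excitations()]
#'   result.
#' @param presets modulation presets as from [generate_modulation_presets()].
#' @param spindle_table reference spindle parameters
#'   ([default_spindle_params()]).
#' @param config a [tracking_config()] (used if `tracking` is NULL).
#' @param dt protocol integration step in s (the control series are
#'   resampled and made dynamically consistent on this grid).
#' @return object of class `reference_setup`.
#' @details After the excitation solve on the control grid, all control
#'   series are resampled to the protocol's integration grid and the
#'   reserve forces are recomputed by *discrete* inverse dynamics of the
#'   integrator itself (the torque each step needs, beyond what the
#'   replayed activations produce, so that the stepping scheme lands on
#'   the next reference state). This residual-reduction pass is what makes
#'   a segmented open-loop replay reproduce the reference kinematics to a
#'   fraction of a degree.
#' @export
reference_setup <- function(model, traj, tracking = NULL,
                            presets = generate_modulation_presets(),
                            spindle_table = default_spindle_params(),
                            config = tracking_config(), dt = 5e-4) {
  if (is.null(tracking)) {
    tracking <- compute_tracking_excitations(model, traj, config)
  }
  mus <- model$muscles
  n_m <- nrow(mus)
  cpct <- tracking$controls$cycle_pct
  y_ctrl <- as.matrix(tracking$controls[, paste0("u_", mus$muscle)])
  fb_idx <- which(mus$group %in% spindle_muscle_groups())
  fb <- tibble(idx = fb_idx, muscle = mus$muscle[fb_idx],
               group = mus$group[fb_idx], side = mus$side[fb_idx])
  prm <- spindle_table[match(fb$group, spindle_table$muscle_group), ]
  fb$tau_l <- prm$tau_l_s; fb$tau_v <- prm$tau_v_s
  fb$g_l <- prm$g_l; fb$g_v <- prm$g_v

  # fine (integration) grid over one cycle
  nf <- round(traj$cycle_s / dt)
  tf <- dt * (0:(nf - 1L))
  pf <- wrap_pct(100 * tf / traj$cycle_s)
  y_fine <- matrix(0, nf, n_m)
  for (j in seq_len(n_m)) y_fine[, j] <- periodic_approx(cpct, y_ctrl[, j], pf)

  # replayed activations: filter the excitations at replay resolution
  # (two cycles, second kept as the periodic solution)
  a_fine <- matrix(0, nf, n_m)
  a_cur <- y_fine[1L, ]
  for (rep in 1:2) {
    for (i in seq_len(nf)) {
      a_fine[i, ] <- a_cur
      a_cur <- activation_step(a_cur, y_fine[i, ], dt,
                               model$tau_act, model$tau_deact)
    }
  }

  # reference fiber states of the feedback muscles on the fine grid
  fiber <- fiber_reference_matrices(model, traj, pf, fb)

  # decomposition on the fine grid with the same exponential recursion the
  # replay uses: u_b = u_cmc - u_l - u_v, periodic steady state
  n_fb <- nrow(fb)
  u_l_f <- matrix(0, nf, n_fb); u_v_f <- matrix(0, nf, n_fb)
  el <- exp(-dt / fb$tau_l); ev <- exp(-dt / fb$tau_v)
  k_ref <- vapply(seq_len(n_fb),
                  function(m) predict(presets[[fb$group[m]]]$reference, pf),
                  numeric(nf))
  ul <- numeric(n_fb); uv <- numeric(n_fb)
  for (rep in 1:2) {
    for (i in seq_len(nf)) {
      if (rep == 2L) { u_l_f[i, ] <- ul; u_v_f[i, ] <- uv }
      dl <- ifelse(fiber$v[i, ] > 0, k_ref[i, ] * fb$g_l * fiber$l[i, ], 0)
      dv <- k_ref[i, ] * fb$g_v * pmax(0, fiber$v[i, ])
      ul <- ul * el + dl * (1 - el)
      uv <- uv * ev + dv * (1 - ev)
    }
  }
  u_b <- y_fine[, fb$idx, drop = FALSE] - u_l_f - u_v_f

  # discrete inverse dynamics of the integrator along the reference: the
  # reserve at step k is the generalized force that makes the semi-implicit
  # step starting from the reference state at t_k land on the reference
  # velocity at t_{k+1}
  Qr <- eval_gait_coords(traj, tf, 0)
  Qdr <- eval_gait_coords(traj, tf, 1)
  res_fine <- matrix(0, nf, 9)
  for (i in seq_len(nf)) {
    q <- Qr[i, ]; qd <- Qdr[i, ]
    qd_next <- Qdr[if (i == nf) 1L else i + 1L, ]
    dt_ <- dyn_terms(model, q, qd)
    L <- mtu_lengths(model, q); vL <- mtu_velocities(model, qd)
    l_norm <- pmax((L - mus$tendon_slack_m) / mus$l_opt_m, 0.01)
    v_norm <- vL / (mus$vmax_lopt_per_s * mus$l_opt_m)
    mt <- muscle_terms(model, a_fine[i, ], l_norm, v_norm)
    jp <- joint_passive_torques(model, q, qd)
    sk <- sphere_kinematics(model, q, qd)
    ct <- contact_terms(model, sk)
    Q0 <- mt$Q + jp$tau + dt_$Qgrav + dt_$Qcor + ct$Q
    S <- mt$S + diag(jp$damp) + ct$S
    res_fine[i, ] <- as.vector((dt_$M + dt * S) %*% (qd_next - qd)) / dt - Q0
  }

  structure(list(model = model, traj = traj, tracking = tracking,
                 presets = presets, fb = fb,
                 dt_fine = dt, nf = nf, pf = pf,
                 y_mat = y_fine, a_mat = a_fine,
                 res_mat = res_fine, u_b = u_b,
                 u_l_ref = u_l_f, u_v_ref = u_v_f),
            class = "reference_setup")
}

#' @export
print.reference_setup <- function(x, ...) {
  cat(sprintf("<reference_setup> %d muscles (%d with spindle feedback), cycle %.2f s\n",
              nrow(x$model$muscles), nrow(x$fb), x$traj$cycle_s))
  invisible(x)
}

# normalized fiber length/velocity of the feedback muscles along the
# reference, as nq x n_fb matrices
fiber_reference_matrices <- function(model, traj, cpct, fb) {
  tt <- cpct * traj$cycle_s / 100
  q <- eval_gait_coords(traj, tt, 0)
  qd <- eval_gait_coords(traj, tt, 1)
  l <- matrix(0, length(tt), nrow(fb)); v <- l
  for (m in seq_len(nrow(fb))) {
    i <- fb$idx[m]
    L <- model$muscles$l_ref_m[i] - as.vector(q %*% model$Rm[i, ])
    vv <- -as.vector(qd %*% model$Rm[i, ])
    l[, m] <- (L - model$muscles$tendon_slack_m[i]) / model$muscles$l_opt_m[i]
    v[, m] <- vv / (model$muscles$vmax_lopt_per_s[i] * model$muscles$l_opt_m[i])
  }
  list(l = l, v = v)
}

# per-run gain/modulation tables: reference values, with the condition's
# group (on the affected side) scaled and its modulation switched
run_parameters <- function(setup, condition) {
  fb <- setup$fb
  g_l <- fb$g_l; g_v <- fb$g_v
  curves <- lapply(seq_len(nrow(fb)),
                   function(m) setup$presets[[fb$group[m]]]$reference)
  if (!is.null(condition)) {
    sd <- switch(condition$side, right = "r", left = "l", both = c("r", "l"))
    hit <- fb$group == condition$muscle_group & fb$side %in% sd
    g_l[hit] <- g_l[hit] * condition$factor_l
    g_v[hit] <- g_v[hit] * condition$factor_v
    mod <- condition$modulation
    crv <- if (inherits(mod, "modulation_curve")) mod
           else setup$presets[[condition$muscle_group]][[mod]]
    for (m in which(hit)) curves[[m]] <- crv
  }
  list(g_l = g_l, g_v = g_v, curves = curves)
}

# core segmented-interval simulator: integrates n_steps starting at fine-
# grid index i0 (1-based; the grid is periodic), with spindle feedback
# computed online from the simulated fiber states
simulate_controlled <- function(setup, pars, i0, n_steps, q0, qd0, a0, spl0) {
  model <- setup$model
  mus <- model$muscles
  n_m <- nrow(mus)
  fbi <- setup$fb$idx
  dt <- setup$dt_fine
  idx <- ((i0 - 1L) + 0:(n_steps - 1L)) %% setup$nf + 1L
  pct_k <- setup$pf[idx]
  u_b_fb <- setup$u_b[idx, , drop = FALSE]
  y_base <- setup$y_mat[idx, , drop = FALSE]
  reserves <- setup$res_mat[idx, , drop = FALSE]
  k_mat <- vapply(seq_along(fbi),
                  function(m) predict(pars$curves[[m]], pct_k),
                  numeric(n_steps))
  k_mat <- matrix(k_mat, nrow = n_steps)
  el <- exp(-dt / setup$fb$tau_l); ev <- exp(-dt / setup$fb$tau_v)
  slack <- mus$tendon_slack_m; lopt <- mus$l_opt_m
  vmax_abs <- mus$vmax_lopt_per_s * lopt
  q <- q0; qd <- qd0; a <- a0
  u_l <- spl0[, 1L]; u_v <- spl0[, 2L]
  q_hist <- matrix(0, n_steps, 9)
  y_hist <- matrix(0, n_steps, n_m)
  grf_hist <- numeric(n_steps)
  for (s in seq_len(n_steps)) {
    L <- mtu_lengths(model, q); vL <- mtu_velocities(model, qd)
    l_norm <- pmax((L - slack) / lopt, 0.01)
    v_norm <- vL / vmax_abs
    lf <- l_norm[fbi]; vf <- v_norm[fbi]; km <- k_mat[s, ]
    drive_l <- ifelse(vf > 0, km * pars$g_l * lf, 0)
    drive_v <- km * pars$g_v * pmax(0, vf)
    u_l <- u_l * el + drive_l * (1 - el)
    u_v <- u_v * ev + drive_v * (1 - ev)
    y <- y_base[s, ]
    y[fbi] <- u_b_fb[s, ] + u_l + u_v
    y <- pmin(1, pmax(0, y))
    # dynamics step (semi-implicit with linearized velocity damping)
    dt_ <- dyn_terms(model, q, qd)
    mt <- muscle_terms(model, a, l_norm, v_norm)
    jp <- joint_passive_torques(model, q, qd)
    sk <- sphere_kinematics(model, q, qd)
    ct <- contact_terms(model, sk)
    Q <- mt$Q + jp$tau + dt_$Qgrav + dt_$Qcor + ct$Q + reserves[s, ]
    S <- mt$S + diag(jp$damp) + ct$S
    qd_new <- qd + solve(dt_$M + dt * S, dt * Q)
    if (!all(is.finite(qd_new))) {
      abort(sprintf("integration failure at cycle position %.2f%%", pct_k[s]),
            class = "reflexgait_sim_failure")
    }
    q_hist[s, ] <- q
    y_hist[s, ] <- y
    grf_hist[s] <- sum(ct$forces[, 2L])
    q <- q + dt * qd_new
    qd <- qd_new
    a <- activation_step(a, y, dt, model$tau_act, model$tau_deact)
  }
  list(pct = pct_k, q = q_hist, y = y_hist, grf = grf_hist,
       q_end = q, qd_end = qd, a_end = a,
       spindle_end = cbind(u_l = u_l, u_v = u_v))
}

#' Simulate one protocol interval
#'
#' Runs one open-loop interval of the segmented protocol: the simulation
#' starts one overlap before the interval at the reference kinematic state,
#' with activations from the reference solution and spindle feedback states
#' carried over from the previous interval; only the portion from
#' `start_pct` to `start_pct + length` is returned, the lead-in is
#' simulated but discarded.
#'
#' @param setup a [reference_setup()].
#' @param condition a [feedback_condition()] or NULL for the reference run.
#' @param start_pct interval start in % of the cycle.
#' @param spindle_init n_fb x 2 matrix of initial `u_l`, `u_v` (defaults to
#'   the steady-state spin-up for the condition).
#' @param spec an [interval_spec()].
#' @return list with `kinematics` (tibble, angles in deg), `excitations`
#'   (tibble), and `spindle_end` (terminal feedback state).
#' @export
run_interval <- function(setup, condition = NULL, start_pct = 0,
                         spindle_init = NULL, spec = interval_spec()) {
  pars <- run_parameters(setup, condition)
  T <- setup$traj$cycle_s
  if (abs(spec$dt - setup$dt_fine) > 1e-12) {
    abort("interval_spec dt must match the reference_setup dt")
  }
  N <- setup$nf
  n_keep <- round(spec$length_pct / 100 * N)
  n_lead <- round(spec$overlap_pct / 100 * N)
  i0 <- (round(start_pct / 100 * N) - n_lead) %% N + 1L
  if (is.null(spindle_init)) {
    spindle_init <- spindle_spinup(setup, pars, end_idx = i0)
  }
  t0 <- (start_pct - spec$overlap_pct) / 100 * T
  q0 <- as.vector(eval_gait_coords(setup$traj, t0, 0))
  qd0 <- as.vector(eval_gait_coords(setup$traj, t0, 1))
  a0 <- setup$a_mat[i0, ]
  sim <- simulate_controlled(setup, pars, i0, n_lead + n_keep,
                             q0, qd0, a0, spindle_init)
  keep <- (n_lead + 1L):(n_lead + n_keep)
  kin <- tibble(cycle_pct = sim$pct[keep])
  for (j in seq_len(9)) {
    v <- sim$q[keep, j]
    nm <- coord_names()[j]
    kin[[nm]] <- if (nm %in% angle_coords()) rad2deg(v) else v
  }
  exc <- as_tibble(as.data.frame(sim$y[keep, , drop = FALSE]))
  names(exc) <- setup$model$muscles$muscle
  exc <- dplyr::bind_cols(tibble(cycle_pct = sim$pct[keep]), exc)
  list(kinematics = kin, excitations = exc, spindle_end = sim$spindle_end,
       grf_n = sim$grf[keep])
}

# periodic-steady-state spindle spin-up: integrate the filters along the
# reference fiber states with the run's gains/modulation for two cycles,
# continuing to fine-grid index end_idx (so the returned state is the
# steady state "just before" that index)
spindle_spinup <- function(setup, pars, end_idx = 1L) {
  fb <- setup$fb
  fiber <- fiber_reference_matrices(setup$model, setup$traj, setup$pf, fb)
  dt <- setup$dt_fine
  nf <- setup$nf
  n_fb <- nrow(fb)
  el <- exp(-dt / fb$tau_l); ev <- exp(-dt / fb$tau_v)
  k_mat <- vapply(seq_len(n_fb),
                  function(m) predict(pars$curves[[m]], setup$pf),
                  numeric(nf))
  ul <- numeric(n_fb); uv <- numeric(n_fb)
  steps <- c(rep(seq_len(nf), 2), seq_len(end_idx - 1L))
  for (i in steps) {
    dl <- ifelse(fiber$v[i, ] > 0, k_mat[i, ] * pars$g_l * fiber$l[i, ], 0)
    dv <- k_mat[i, ] * pars$g_v * pmax(0, fiber$v[i, ])
    ul <- ul * el + dl * (1 - el)
    uv <- uv * ev + dv * (1 - ev)
  }
  cbind(u_l = ul, u_v = uv)
}

# run all intervals of the protocol for one condition, chaining spindle
# states; returns concatenated per-step series covering the full cycle
run_protocol <- function(setup, condition = NULL, spec = interval_spec()) {
  n_int <- round(100 / spec$length_pct)
  starts <- spec$length_pct * (0:(n_int - 1L))
  spl <- NULL  # first interval: periodic steady-state spin-up
  kin <- list(); exc <- list()
  failed <- character(0)
  for (i in seq_len(n_int)) {
    res <- tryCatch(
      run_interval(setup, condition, starts[i], spindle_init = spl,
                   spec = spec),
      reflexgait_sim_failure = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("interval %d (%g%%): %s", i, starts[i],
                                  conditionMessage(res)))
      next
    }
    spl <- res$spindle_end
    kin[[i]] <- res$kinematics
    exc[[i]] <- res$excitations
  }
  list(kinematics = dplyr::bind_rows(kin), excitations = dplyr::bind_rows(exc),
       failed = failed)
}

#' Run the hemiparetic simulation experiment
#'
#' Simulates the full segmented protocol once with reference parameters
#' and once per condition, and summarizes per interval and per gait phase
#' the mean differences (condition minus reference run) in the sagittal
#' joint angles of both legs and in the muscle excitations. Differences are
#' taken against the re-simulated reference run of the same protocol, not
#' against the raw reference trajectory, so they isolate the feedback
#' manipulation.
#'
#' @param setup a [reference_setup()].
#' @param conditions list of [feedback_condition()] objects (possibly
#'   empty, in which case only the reference run is performed).
#' @param spec an [interval_spec()].
#' @param threshold_deg sign-classification threshold in degrees.
#' @return object of class `effect_summary`.
#' @export
run_experiment <- function(setup, conditions = list(),
                           spec = interval_spec(), threshold_deg = 1) {
  if (inherits(conditions, "feedback_condition")) conditions <- list(conditions)
  ref <- run_protocol(setup, NULL, spec)
  if (length(ref$failed)) {
    abort(paste("reference run failed:", paste(ref$failed, collapse = "; ")))
  }
  n_int <- round(100 / spec$length_pct)
  interval_of <- function(pct) pmin(n_int, floor(pct / spec$length_pct) + 1L)
  phases <- gait_phases()
  phase_of <- function(pct) phases$phase[findInterval(pct, phases$start_pct)]
  joints <- c("hip_r", "knee_r", "ankle_r", "hip_l", "knee_l", "ankle_l")
  muscles <- setup$model$muscles$muscle
  rows_int <- list(); rows_ph <- list(); series <- list()
  incomplete <- character(0)
  for (cd in conditions) {
    run <- run_protocol(setup, cd, spec)
    if (length(run$failed)) {
      incomplete <- c(incomplete,
                      sprintf("%s: %s", cd$label,
                              paste(run$failed, collapse = "; ")))
      next
    }
    pct <- ref$kinematics$cycle_pct
    dk <- as.matrix(run$kinematics[joints]) - as.matrix(ref$kinematics[joints])
    de <- as.matrix(run$excitations[muscles]) -
      as.matrix(ref$excitations[muscles])
    iv <- interval_of(pct); ph <- phase_of(pct)
    long <- dplyr::bind_rows(
      tidyr::pivot_longer(
        dplyr::bind_cols(tibble(cycle_pct = pct, interval = iv, phase = ph),
                         as_tibble(as.data.frame(dk))),
        cols = dplyr::all_of(joints), names_to = "name",
        values_to = "diff") |> dplyr::mutate(quantity = "angle_deg"),
      tidyr::pivot_longer(
        dplyr::bind_cols(tibble(cycle_pct = pct, interval = iv, phase = ph),
                         as_tibble(as.data.frame(de))),
        cols = dplyr::all_of(muscles), names_to = "name",
        values_to = "diff") |> dplyr::mutate(quantity = "excitation"))
    long$condition <- cd$label
    series[[cd$label]] <- long
    rows_int[[cd$label]] <- long |>
      dplyr::group_by(.data$condition, .data$interval, .data$quantity,
                      .data$name) |>
      dplyr::summarise(mean_diff = mean(.data$diff), .groups = "drop") |>
      dplyr::mutate(start_pct = (.data$interval - 1L) * spec$length_pct,
                    end_pct = .data$interval * spec$length_pct)
    rows_ph[[cd$label]] <- long |>
      dplyr::group_by(.data$condition, .data$phase, .data$quantity,
                      .data$name) |>
      dplyr::summarise(mean_diff = mean(.data$diff), .groups = "drop")
  }
  structure(list(
    intervals = dplyr::bind_rows(rows_int),
    phases = dplyr::bind_rows(rows_ph),
    series = dplyr::bind_rows(series),
    conditions = tibble(
      label = vapply(conditions, function(c) c$label, character(1)),
      muscle_group = vapply(conditions, function(c) c$muscle_group, character(1)),
      factor_l = vapply(conditions, function(c) c$factor_l, numeric(1)),
      factor_v = vapply(conditions, function(c) c$factor_v, numeric(1)),
      side = vapply(conditions, function(c) c$side, character(1))),
    reference = ref, spec = spec, threshold_deg = threshold_deg,
    incomplete = incomplete),
    class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("<effect_summary> %d condition(s), %d intervals of %g%%\n",
              nrow(x$conditions), round(100 / x$spec$length_pct),
              x$spec$length_pct))
  if (length(x$incomplete)) {
    cat("incomplete conditions:\n")
    for (s in x$incomplete) cat(" -", s, "\n")
  }
  invisible(x)
}

#' @rdname run_experiment
#' @param x an `effect_summary`.
#' @param ... unused.
#' @method tidy effect_summary
#' @export
tidy.effect_summary <- function(x, ...) x$intervals

#' @rdname run_experiment
#' @method glance effect_summary
#' @export
glance.effect_summary <- function(x, ...) {
  ang <- x$phases[x$phases$quantity == "angle_deg", ]
  ang |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(max_abs_angle_diff_deg = max(abs(.data$mean_diff)),
                     n_phases_classified = sum(abs(.data$mean_diff) >
                                                 x$threshold_deg),
                     .groups = "drop")
}

#' @rdname run_experiment
#' @param object an `effect_summary`.
#' @method autoplot effect_summary
#' @export
autoplot.effect_summary <- function(object, ...) {
  df <- object$series[object$series$quantity == "angle_deg" &
                        object$series$name %in%
                          c("hip_r", "knee_r", "ankle_r"), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle_pct, y = .data$diff,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~name, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "gait cycle (%)",
                  y = "angle difference vs reference run (deg)")
}

#' Directional effect table
#'
#' Classifies the per-phase mean joint-angle differences of an experiment
#' into directional arrows: an effect larger than the threshold in
#' magnitude gets a single arrow, larger than three thresholds a double
#' arrow, smaller effects stay blank.
#'
#' @param summary an [run_experiment()] `effect_summary`.
#' @param threshold_deg threshold in degrees (single arrow; double at 3x).
#' @param joints joints to tabulate (default the right-side sagittal
#'   angles).
#' @return tibble with `phase`, `condition`, `joint`, `mean_diff_deg`,
#'   `sign` (one of "", "up", "up2", "down", "down2") and `arrow`.
#' @export
directional_effect_table <- function(summary,
                                     threshold_deg = summary$threshold_deg,
                                     joints = c("hip_r", "knee_r", "ankle_r")) {
  stopifnot(inherits(summary, "effect_summary"))
  ph <- summary$phases
  ph <- ph[ph$quantity == "angle_deg" & ph$name %in% joints, ]
  cls <- function(d) {
    ifelse(d > 3 * threshold_deg, "up2",
           ifelse(d > threshold_deg, "up",
                  ifelse(d < -3 * threshold_deg, "down2",
                         ifelse(d < -threshold_deg, "down", ""))))
  }
  arrows <- c(up = "↑", up2 = "↑↑",
              down = "↓", down2 = "↓↓")
  out <- ph |>
    dplyr::transmute(phase = .data$phase, condition = .data$condition,
                     joint = .data$name, mean_diff_deg = .data$mean_diff,
                     sign = cls(.data$mean_diff))
  out$arrow <- ifelse(out$sign == "", "", arrows[out$sign])
  phases <- gait_phases()$phase
  out$phase <- factor(out$phase, levels = phases)
  dplyr::arrange(out, .data$condition, .data$phase, .data$joint)
}
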