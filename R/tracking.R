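#' Tracking-controller configuration
#'
#' Parameters of the excitation computation that stands in for a full
#' computed-muscle-control stage: PD gains shaping the target acceleration
#' (they contribute nothing when evaluating along the reference trajectory
#' itself), the excitation bounds, the strictly convex effort weight of the
#' per-sample excitation solve, and the control-grid resolution.
#'
#' @param kp,kd PD gains on joint angle / velocity error (1/s^2, 1/s).
#' @param effort_weight ridge weight on the squared excitations (> 0 so the
#'   per-sample solution is unique).
#' @param bounds excitation bounds (always `[0, 1]` physiologically).
#' @param control_pct control-grid step in % of the gait cycle.
#' @export
tracking_config <- function(kp = 400, kd = 40, effort_weight = 1e-3,
                            bounds = c(0, 1), control_pct = 0.25) {
  stopifnot(kp > 0, kd > 0, effort_weight > 0)
  structure(list(kp = kp, kd = kd, effort_weight = effort_weight,
                 bounds = bounds, control_pct = control_pct),
            class = "tracking_config")
}

# bounded ridge least squares:  min ||A u - b||^2 + lambda ||u||^2,
# lo <= u <= hi, solved with L-BFGS-B and an analytic gradient
solve_excitations <- function(A, b, lambda, lo = 0, hi = 1) {
  n <- ncol(A)
  AtA <- crossprod(A); Atb <- crossprod(A, b)
  fn <- function(u) {
    r <- A %*% u - b
    sum(r * r) + lambda * sum(u * u)
  }
  gr <- function(u) 2 * as.vector(AtA %*% u - Atb) + 2 * lambda * u
  res <- stats::optim(rep(0.1, n), fn, gr, method = "L-BFGS-B",
                      lower = lo, upper = hi,
                      control = list(maxit = 200, factr = 1e4))
  res$par
}

#' Compute tracking excitations for the reference gait
#'
#' Computes, at every control-grid sample of the reference cycle, the
#' muscle excitations that realize the trajectory's accelerations through
#' the model's equations of motion: inverse dynamics at the reference state
#' (including foot-ground contact evaluated on the reference kinematics)
#' gives the required generalized forces; a bounded, strictly convex
#' effort-minimizing solve distributes the hip/knee/ankle torques over the
#' muscles of each leg. Whatever the muscles cannot produce — the three
#' pelvis degrees of freedom, which no muscle spans, and any joint-torque
#' shortfall — is recorded as reserve generalized forces that are replayed
#' together with the excitations. The stored excitation series is
#' compensated for the activation filter lag (first-order inverse filter,
#' clipped to the bounds), so an open-loop replay through the activation
#' dynamics reproduces the solved activations.
#'
#' @param model a [skeleton_model()].
#' @param traj a [generate_reference_gait()] trajectory.
#' @param config a [tracking_config()].
#' @return object of class `tracking_result`: tibble `controls` with the
#'   excitation (`u_*`), solved activation (`a_*`) and reserve (`res_*`)
#'   series on the control grid; `infeasible` tibble reporting samples
#'   where the torque demand could not be met (joint, time, shortfall in
#'   N m); `config`.
#' @export
compute_tracking_excitations <- function(model, traj,
                                         config = tracking_config()) {
  pct <- seq(0, 100 - config$control_pct, by = config$control_pct)
  tt <- pct * traj$cycle_s / 100
  nq <- length(pct)
  mus <- model$muscles
  n_m <- nrow(mus)
  jidx <- match(joint_coords(), coord_names())
  ridx <- list(r = which(mus$side == "r"), l = which(mus$side == "l"))
  jleg <- list(r = match(c("hip_r", "knee_r", "ankle_r"), coord_names()),
               l = match(c("hip_l", "knee_l", "ankle_l"), coord_names()))
  Q_all <- eval_gait_coords(traj, tt, 0)
  Qd_all <- eval_gait_coords(traj, tt, 1)
  Qdd_all <- eval_gait_coords(traj, tt, 2)
  u_mat <- matrix(0, nq, n_m)
  qreq_mat <- matrix(0, nq, 9)
  fact_mat <- matrix(0, nq, n_m)
  infeas <- list()
  for (i in seq_len(nq)) {
    q <- Q_all[i, ]; qd <- Qd_all[i, ]
    # target acceleration: reference + PD correction (zero along reference)
    qdd <- Qdd_all[i, ] + config$kp * (Q_all[i, ] - q) +
      config$kd * (Qd_all[i, ] - qd)
    dt_ <- dyn_terms(model, q, qd)
    sk <- sphere_kinematics(model, q, qd)
    ct <- contact_terms(model, sk)
    jp <- joint_passive_torques(model, q, qd)
    L <- mtu_lengths(model, q); v <- mtu_velocities(model, qd)
    l_norm <- pmax((L - mus$tendon_slack_m) / mus$l_opt_m, 0.01)
    v_norm <- v / (mus$vmax_lopt_per_s * mus$l_opt_m)
    Fpas <- mus$fmax_n * fp_passive(l_norm)
    Q_pas <- as.vector(crossprod(model$Rm, Fpas))
    Q_req <- as.vector(dt_$M %*% qdd) - dt_$Qcor - dt_$Qgrav -
      ct$Q - jp$tau - Q_pas
    Fact <- mus$fmax_n * fl_active(l_norm) * fv_curve(v_norm)
    qreq_mat[i, ] <- Q_req
    fact_mat[i, ] <- Fact
    for (s in c("r", "l")) {
      mi <- ridx[[s]]; jc <- jleg[[s]]
      A <- t(model$Rm[mi, jc, drop = FALSE] * Fact[mi])
      b <- Q_req[jc]
      u <- solve_excitations(A, b, config$effort_weight,
                             config$bounds[1L], config$bounds[2L])
      u_mat[i, mi] <- u
      short <- b - as.vector(A %*% u)
      bad <- abs(short) > 5
      if (any(bad)) {
        infeas[[length(infeas) + 1L]] <- tibble(
          time = tt[i], joint = coord_names()[jc][bad],
          shortfall_nm = short[bad])
      }
    }
  }
  # activation-lag compensation: y = a* + tau * da*/dt on the periodic grid
  dtc <- traj$cycle_s * config$control_pct / 100
  adot <- (u_mat[c(2:nq, 1L), ] - u_mat[c(nq, 1:(nq - 1L)), ]) / (2 * dtc)
  tau <- ifelse(adot > 0, model$tau_act, model$tau_deact)
  y_mat <- u_mat + tau * adot
  y_mat[y_mat < 0] <- 0; y_mat[y_mat > 1] <- 1
  # the replay filters y through the activation dynamics; simulate that
  # filter at replay resolution (two cycles, second kept periodic) and book
  # whatever torque the replayed activations do NOT produce into the
  # reserves, so the stored controls are dynamically consistent with an
  # open-loop replay
  dtf <- 5e-4
  nf <- round(traj$cycle_s / dtf)
  tf <- dtf * (0:(nf - 1L))
  y_fine <- matrix(0, nf, n_m)
  for (j in seq_len(n_m)) {
    y_fine[, j] <- periodic_approx(pct, y_mat[, j], wrap_pct(100 * tf / traj$cycle_s))
  }
  a_fine <- y_fine * 0
  a_cur <- u_mat[1L, ]
  for (rep in 1:2) {
    for (i in seq_len(nf)) {
      a_fine[i, ] <- a_cur
      a_cur <- activation_step(a_cur, y_fine[i, ], dtf,
                               model$tau_act, model$tau_deact)
    }
  }
  a_rep <- matrix(0, nq, n_m)
  for (j in seq_len(n_m)) {
    a_rep[, j] <- stats::approx(tf, a_fine[, j], xout = tt, rule = 2)$y
  }
  res_mat <- qreq_mat - (fact_mat * a_rep) %*% model$Rm
  u_mat <- a_rep
  controls <- tibble(time = tt, cycle_pct = pct)
  for (j in seq_len(n_m)) controls[[paste0("u_", mus$muscle[j])]] <- y_mat[, j]
  for (j in seq_len(n_m)) controls[[paste0("a_", mus$muscle[j])]] <- u_mat[, j]
  for (j in seq_len(9)) controls[[paste0("res_", coord_names()[j])]] <- res_mat[, j]
  structure(list(controls = controls,
                 infeasible = if (length(infeas)) dplyr::bind_rows(infeas)
                              else tibble(time = numeric(0),
                                          joint = character(0),
                                          shortfall_nm = numeric(0)),
                 config = config, cycle_s = traj$cycle_s,
                 muscles = mus$muscle),
            class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  cat(sprintf("<tracking_result> %d control samples, %d muscles, %d infeasible samples\n",
              nrow(x$controls), length(x$muscles), nrow(x$infeasible)))
  invisible(x)
}

#' @rdname compute_tracking_excitations
#' @param x a `tracking_result`.
#' @param ... unused.
#' @method glance tracking_result
#' @export
glance.tracking_result <- function(x, ...) {
  u <- as.matrix(x$controls[, paste0("u_", x$muscles)])
  tibble(n_samples = nrow(x$controls),
         n_infeasible = nrow(x$infeasible),
         max_excitation = max(u), mean_excitation = mean(u))
}
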