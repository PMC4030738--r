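# Planar multibody dynamics of the 9-DOF skeleton.
#
# Every body-fixed point (segment COM, contact sphere center) is written as
#   p(q) = pelvis + sum_t R(theta_{a_t}) b_t
# with absolute segment angles theta = W q (W constant).  COM Jacobians are
# therefore analytic, the mass matrix is M = sum_s m_s J_s' J_s + W' I W,
# and the velocity-product terms come from the point accelerations at zero
# generalized acceleration: pdd|qdd=0 = -sum_t thetadot_{a_t}^2 R b_t.

rot2 <- function(theta) {
  c(cos(theta), sin(theta))  # returns (cos, sin) pair for reuse
}

# kinematics of one composite point: position, 2x9 Jacobian, and the
# zero-acceleration point acceleration term
point_kinematics <- function(W, theta, thetadot, q, angles, offsets) {
  pos <- c(q[1L], q[2L])
  J <- matrix(0, 2, 9)
  J[1L, 1L] <- 1; J[2L, 2L] <- 1
  alpha <- c(0, 0)
  for (i in seq_along(angles)) {
    a <- angles[i]
    ct <- cos(theta[a]); st <- sin(theta[a])
    b <- offsets[, i]
    r <- c(ct * b[1L] - st * b[2L], st * b[1L] + ct * b[2L])
    pos <- pos + r
    perp <- c(-r[2L], r[1L])
    dep <- which(W[a, ] != 0)
    for (j in dep) {
      J[, j] <- J[, j] + W[a, j] * perp
    }
    alpha <- alpha - thetadot[a]^2 * r
  }
  list(pos = pos, J = J, alpha = alpha)
}

# mass matrix, Coriolis/centrifugal generalized force (moved to the RHS),
# gravity generalized force and COM positions at (q, qd)
dyn_terms <- function(model, q, qd) {
  dyn <- model$dyn
  theta <- as.vector(dyn$W %*% q)
  thetadot <- as.vector(dyn$W %*% qd)
  M <- dyn$Iang
  Qcor <- numeric(9)
  Qgrav <- numeric(9)
  com <- matrix(0, length(dyn$points), 2)
  Js <- vector("list", length(dyn$points))
  for (s in seq_along(dyn$points)) {
    pk <- point_kinematics(dyn$W, theta, thetadot, q,
                           dyn$points[[s]]$angles, dyn$points[[s]]$offsets)
    m <- dyn$m[s]
    M <- M + m * crossprod(pk$J)
    Qcor <- Qcor - m * as.vector(crossprod(pk$J, pk$alpha))
    Qgrav <- Qgrav - m * model$gravity * pk$J[2L, ]
    com[s, ] <- pk$pos
    Js[[s]] <- pk$J
  }
  list(M = M, Qcor = Qcor, Qgrav = Qgrav, com = com, J = Js,
       theta = theta, thetadot = thetadot)
}

# kinematics of all contact sphere centers: positions (n x 2), velocities
# (n x 2), Jacobians (list of 2x9)
sphere_kinematics <- function(model, q, qd) {
  dyn <- model$dyn
  theta <- as.vector(dyn$W %*% q)
  thetadot <- as.vector(dyn$W %*% qd)
  n <- length(model$spheres$radius)
  pos <- matrix(0, n, 2); vel <- matrix(0, n, 2)
  Js <- vector("list", n)
  for (i in seq_len(n)) {
    aid <- model$spheres$angle_id[i]
    foot <- if (aid == 4L) "foot_r" else "foot_l"
    base <- dyn$points[[foot]]
    angles <- c(base$angles[1:2], aid)
    offsets <- cbind(base$offsets[, 1:2], model$spheres$local[, i])
    pk <- point_kinematics(dyn$W, theta, thetadot, q, angles, offsets)
    pos[i, ] <- pk$pos
    vel[i, ] <- as.vector(pk$J %*% qd)
    Js[[i]] <- pk$J
  }
  list(pos = pos, vel = vel, J = Js)
}

# soft joint-range limit torques plus viscous joint damping
joint_passive_torques <- function(model, q, qd) {
  lo <- model$limits$lower; up <- model$limits$upper
  tau <- numeric(9); damp <- numeric(9)
  over <- q > up; under <- q < lo
  tau[over] <- -model$limit_stiffness * (q[over] - up[over])
  tau[under] <- model$limit_stiffness * (lo[under] - q[under])
  damp[over | under] <- model$limit_damping
  jidx <- 4:9
  damp[jidx] <- damp[jidx] + model$joint_damping
  tau <- tau - damp * qd
  list(tau = tau, damp = damp)
}

# potential energy stored in the soft joint limits
limit_energy <- function(model, q) {
  lo <- model$limits$lower; up <- model$limits$upper
  e <- 0
  over <- q > up; under <- q < lo
  e <- e + sum(0.5 * model$limit_stiffness * (q[over] - up[over])^2)
  e + sum(0.5 * model$limit_stiffness * (lo[under] - q[under])^2)
}

# contact forces at the current state plus linearized velocity-damping
# coefficients for the implicit step.  Returns the generalized force and the
# 9x9 damping contribution, plus per-sphere diagnostics.
contact_terms <- function(model, sk) {
  n <- length(model$spheres$radius)
  Q <- numeric(9)
  S <- matrix(0, 9, 9)
  forces <- matrix(0, n, 2)
  pen <- numeric(n)
  for (i in seq_len(n)) {
    r <- model$spheres$radius[i]
    fl <- ef_force_law(sk$pos[i, 2L], sk$vel[i, 1L], sk$vel[i, 2L], r,
                       model$ground, model$contact)
    if (fl$delta <= 0) next
    pen[i] <- fl$delta
    f <- c(fl$ft, fl$fn)
    forces[i, ] <- f
    J <- sk$J[[i]]
    Q <- Q + as.vector(crossprod(J, f))
    # tangential force acts at the sphere bottom: moment r*ft about the
    # center maps through the foot segment's angle rows
    aid <- model$spheres$angle_id[i]
    Q <- Q + (r * fl$ft) * model$dyn$W[aid, ]
    S <- S + fl$Dn * tcrossprod(J[2L, ]) + fl$Dt * tcrossprod(J[1L, ])
  }
  list(Q = Q, S = S, forces = forces, penetration = pen)
}

# generalized force of all muscles at given activations and fiber state,
# plus the linearized force-velocity damping matrix
muscle_terms <- function(model, a, l_norm, v_norm) {
  mus <- model$muscles
  Fm <- mus$fmax_n * (a * fl_active(l_norm) * fv_curve(v_norm) +
                        fp_passive(l_norm))
  Q <- as.vector(crossprod(model$Rm, Fm))
  dFdv <- mus$fmax_n * a * fl_active(l_norm) * fv_slope(v_norm) /
    (mus$vmax_lopt_per_s * mus$l_opt_m)
  S <- crossprod(model$Rm * dFdv, model$Rm)
  list(Q = Q, F = Fm, S = S)
}

#' Mechanical energy of the skeleton
#'
#' Kinetic plus gravitational potential energy (potential reference at
#' ground height), plus the elastic energy stored in the soft joint limits.
#' Used by the energy-balance checks of the passive dynamics.
#'
#' @param model a [skeleton_model()].
#' @param q,qd generalized coordinates and velocities.
#' @param include_limits include soft-joint-limit elastic energy.
#' @param include_muscle_passive include the elastic energy of the passive
#'   muscle element (the active and damping parts are non-conservative).
#' @return energy in J.
#' @export
mech_energy <- function(model, q, qd, include_limits = TRUE,
                        include_muscle_passive = TRUE) {
  q <- as_coord_vector(q); qd <- as_coord_vector(qd)
  dt <- dyn_terms(model, q, qd)
  ke <- 0.5 * sum(qd * (dt$M %*% qd))
  pe <- model$gravity * sum(model$dyn$m * dt$com[, 2L])
  if (include_limits) pe <- pe + limit_energy(model, q)
  if (include_muscle_passive) {
    l_norm <- (mtu_lengths(model, q) - model$muscles$tendon_slack_m) /
      model$muscles$l_opt_m
    pe <- pe + sum(model$muscles$fmax_n * model$muscles$l_opt_m *
                     fp_energy(l_norm))
  }
  ke + pe
}

# antiderivative of the passive force-length curve wrt normalized length
# (zero below optimal length; matches the capped curve up to l_norm = 2)
fp_energy <- function(l_norm) {
  l <- pmin(pmax(l_norm, 1), 2)
  (0.15 * (exp(4 * (l - 1) / 0.6) - 1) - (l - 1)) / (exp(4) - 1)
}

#' Dynamic state of the model
#'
#' Container for the simulator state: coordinates, velocities and muscle
#' activations (spindle feedback states are carried separately by the
#' protocol layer, which owns their chaining rule).
#'
#' @param q,qd numeric vectors of the 9 coordinates / velocities.
#' @param a activations in `[0, 1]`, one per muscle (default 0).
#' @param n_muscles number of muscles (used when `a` is omitted).
#' @return a list of class `dynamic_state`.
#' @export
dynamic_state <- function(q, qd = rep(0, 9), a = NULL, n_muscles = 16) {
  q <- as_coord_vector(q); qd <- as_coord_vector(qd)
  if (is.null(a)) a <- rep(0, n_muscles)
  stop_not_finite(a, "a")
  if (any(a < 0 | a > 1)) abort("activations must lie in [0, 1]")
  structure(list(q = q, qd = qd, a = a), class = "dynamic_state")
}

# acceleration at a state for explicit (RK4) integration; controls fixed
explicit_qdd <- function(model, q, qd, a, y, reserves, use_contact) {
  dt_ <- dyn_terms(model, q, qd)
  L <- mtu_lengths(model, q); v <- mtu_velocities(model, qd)
  l_norm <- (L - model$muscles$tendon_slack_m) / model$muscles$l_opt_m
  v_norm <- v / (model$muscles$vmax_lopt_per_s * model$muscles$l_opt_m)
  mt <- muscle_terms(model, a, pmax(l_norm, 0.01), v_norm)
  jp <- joint_passive_torques(model, q, qd)
  Q <- mt$Q + jp$tau + dt_$Qgrav + dt_$Qcor + reserves
  if (use_contact) {
    sk <- sphere_kinematics(model, q, qd)
    ct <- contact_terms(model, sk)
    Q <- Q + ct$Q
  }
  solve(dt_$M, Q)
}

#' Advance the model state by one time step
#'
#' One fixed step of the forward dynamics under given neural excitations.
#' The default scheme is semi-implicit (symplectic) Euler in which all
#' velocity-dependent forces with stiff slopes — contact damping and
#' friction, muscle force-velocity damping, joint damping — are treated
#' implicitly through a linearized velocity solve, so the step is stable at
#' the millisecond scale despite the stiff contact dissipation. An explicit
#' `"rk4"` scheme is available for high-accuracy checks without contact.
#' Activations advance by the exact exponential update of the first-order
#' activation filter.
#'
#' @param model a [skeleton_model()].
#' @param state a [dynamic_state()].
#' @param y neural excitations in `[0, 1]`, one per muscle.
#' @param dt time step in s (must be <= 1 ms; contract with the contact
#'   stiffness).
#' @param reserves optional 9-vector of generalized reserve/residual forces.
#' @param use_contact evaluate foot-ground contact (default TRUE).
#' @param method `"semi_implicit"` (default) or `"rk4"`.
#' @return a new `dynamic_state`; attribute `contact` carries the per-sphere
#'   contact forces of the step (semi-implicit scheme only).
#' @export
forward_step <- function(model, state, y, dt, reserves = rep(0, 9),
                         use_contact = TRUE,
                         method = c("semi_implicit", "rk4")) {
  method <- match.arg(method)
  if (dt <= 0 || dt > 1e-3 + 1e-12) abort("dt must be in (0, 1 ms]")
  stop_not_finite(y, "y")
  if (any(y < 0 | y > 1)) abort("excitations must lie in [0, 1]")
  q <- state$q; qd <- state$qd; a <- state$a
  if (method == "rk4") {
    f <- function(q, qd) explicit_qdd(model, q, qd, a, y, reserves, use_contact)
    k1v <- f(q, qd);                       k1q <- qd
    k2v <- f(q + dt / 2 * k1q, qd + dt / 2 * k1v); k2q <- qd + dt / 2 * k1v
    k3v <- f(q + dt / 2 * k2q, qd + dt / 2 * k2v); k3q <- qd + dt / 2 * k2v
    k4v <- f(q + dt * k3q, qd + dt * k3v);         k4q <- qd + dt * k3v
    qd_new <- qd + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    q_new <- q + dt / 6 * (k1q + 2 * k2q + 2 * k3q + k4q)
    ct <- NULL
  } else {
    dt_ <- dyn_terms(model, q, qd)
    L <- mtu_lengths(model, q); v <- mtu_velocities(model, qd)
    l_norm <- pmax((L - model$muscles$tendon_slack_m) / model$muscles$l_opt_m,
                   0.01)
    v_norm <- v / (model$muscles$vmax_lopt_per_s * model$muscles$l_opt_m)
    mt <- muscle_terms(model, a, l_norm, v_norm)
    jp <- joint_passive_torques(model, q, qd)
    Q <- mt$Q + jp$tau + dt_$Qgrav + dt_$Qcor + reserves
    S <- mt$S + diag(jp$damp)
    ct <- NULL
    if (use_contact) {
      sk <- sphere_kinematics(model, q, qd)
      ct <- contact_terms(model, sk)
      Q <- Q + ct$Q
      S <- S + ct$S
    }
    qd_new <- qd + solve(dt_$M + dt * S, dt * Q)
    q_new <- q + dt * qd_new
  }
  if (!all(is.finite(qd_new))) {
    abort("non-finite accelerations: simulation aborted",
          class = "reflexgait_sim_failure",
          state = list(q = q, qd = qd, a = a, y = y))
  }
  a_new <- activation_step(a, y, dt, model$tau_act, model$tau_deact)
  out <- dynamic_state(q_new, qd_new, a_new)
  if (!is.null(ct)) attr(out, "contact") <- ct$forces
  out
}
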