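#' Generalized coordinates of the sagittal skeleton
#'
#' The model has 9 degrees of freedom: pelvis translation (m), pelvis tilt
#' and bilateral hip, knee and ankle flexion (rad internally, degrees in
#' user-facing tables). Sign conventions: hip flexion, knee flexion and
#' ankle dorsiflexion are positive; pelvis tilt is positive
#' counter-clockwise with the subject walking towards +x.
#'
#' @return character vector of coordinate names.
#' @export
coord_names <- function() {
  c("pelvis_tx", "pelvis_ty", "pelvis_tilt",
    "hip_r", "knee_r", "ankle_r", "hip_l", "knee_l", "ankle_l")
}

# coordinates that are angles (all but the two translations)
angle_coords <- function() coord_names()[-(1:2)]
joint_coords <- function() coord_names()[4:9]

#' Default muscle parameter table
#'
#' Muscle-tendon parameters of the eight modeled muscle groups per leg:
#' maximal isometric force, optimal fiber length, tendon slack length, the
#' fiber length (as a fraction of optimal) taken at the neutral standing
#' pose, maximal contraction velocity, and constant sagittal moment arms
#' about hip, knee and ankle. Positive moment arms produce flexion
#' (dorsiflexion) torque; a bi-articular muscle has two non-zero arms.
#' Values are adapted from standard gait-model tables.
#'
#' @return tibble, one row per muscle group.
#' @export
default_muscles <- function() {
  as_tibble(utils::read.csv(pkg_extdata("muscles.csv"),
                            stringsAsFactors = FALSE))
}

#' Build the sagittal-plane skeleton model
#'
#' Constructs a 9-DOF planar lower-limb model: HAT segment (head, arms,
#' trunk and pelvis), bilateral thigh, shank and foot, actuated by
#' Hill-type muscle-tendon units with constant moment arms and a rigid
#' tendon, plus sphere-on-plane foot-ground contact. Segment masses, lengths
#' and inertias follow standard anthropometric fractions of total body mass
#' and stature.
#'
#' @param body_mass total mass in kg (default 54.4, the reference subject).
#' @param height stature in m.
#' @param gravity gravitational acceleration, m/s^2 (acting along -y).
#' @param muscles muscle parameter table as from [default_muscles()].
#' @param spheres contact sphere table as from [default_contact_spheres()].
#' @param contact contact parameters as from [default_contact_params()].
#' @param ground a [ground_plane()].
#' @param joint_damping viscous damping at hip/knee/ankle, N m s/rad.
#' @param limit_stiffness soft joint-range limit stiffness, N m/rad.
#' @param limit_damping extra damping applied beyond a joint limit.
#' @param joint_limits optional override of the soft joint ranges: a list
#'   with `lower` and `upper`, 9 values each (rad; translations may be
#'   infinite).
#' @param tau_act,tau_deact activation / deactivation time constants, s.
#' @return object of class `skeleton_model`.
#' @export
skeleton_model <- function(body_mass = 54.4, height = 1.68, gravity = 9.81,
                           muscles = default_muscles(),
                           spheres = default_contact_spheres(),
                           contact = default_contact_params(),
                           ground = ground_plane(),
                           joint_damping = 0.5,
                           limit_stiffness = 200,
                           limit_damping = 5,
                           joint_limits = NULL,
                           tau_act = 0.010, tau_deact = 0.040) {
  stopifnot(body_mass > 0, height > 0)
  s <- height / 1.68  # geometric scale relative to the nominal stature
  l_th <- 0.245 * height; l_sh <- 0.246 * height; l_ft <- 0.152 * height
  m_hat <- 0.678 * body_mass
  m_th <- 0.100 * body_mass; m_sh <- 0.0465 * body_mass
  m_ft <- 0.0145 * body_mass
  hat_com <- c(0, 0.18 * height)
  ft_com <- c(0.06, -0.03) * s
  calcn <- c(-0.049, -0.042) * s
  segments <- tibble(
    name = c("HAT", "thigh_r", "shank_r", "foot_r",
             "thigh_l", "shank_l", "foot_l"),
    mass_kg = c(m_hat, m_th, m_sh, m_ft, m_th, m_sh, m_ft),
    length_m = c(NA, l_th, l_sh, l_ft, l_th, l_sh, l_ft),
    inertia_kgm2 = c(m_hat * (0.35 * s)^2,
                     m_th * (0.323 * l_th)^2, m_sh * (0.302 * l_sh)^2,
                     m_ft * (0.475 * l_ft)^2,
                     m_th * (0.323 * l_th)^2, m_sh * (0.302 * l_sh)^2,
                     m_ft * (0.475 * l_ft)^2))

  # absolute segment angles as fixed linear combinations of the coordinates:
  # rows HAT, thigh_r, shank_r, foot_r, thigh_l, shank_l, foot_l
  W <- matrix(0, 7, 9, dimnames = list(segments$name, coord_names()))
  W["HAT", "pelvis_tilt"] <- 1
  W["thigh_r", c("pelvis_tilt", "hip_r")] <- 1
  W["shank_r", c("pelvis_tilt", "hip_r")] <- 1; W["shank_r", "knee_r"] <- -1
  W["foot_r", c("pelvis_tilt", "hip_r", "ankle_r")] <- 1
  W["foot_r", "knee_r"] <- -1
  W["thigh_l", c("pelvis_tilt", "hip_l")] <- 1
  W["shank_l", c("pelvis_tilt", "hip_l")] <- 1; W["shank_l", "knee_l"] <- -1
  W["foot_l", c("pelvis_tilt", "hip_l", "ankle_l")] <- 1
  W["foot_l", "knee_l"] <- -1

  # COM of each segment = pelvis point + sum of rotated offsets; `angles`
  # indexes rows of W, `offsets` are the body-fixed vectors (m)
  c_th <- 0.433 * l_th; c_sh <- 0.433 * l_sh
  points <- list(
    HAT = list(angles = 1L, offsets = matrix(hat_com, 2)),
    thigh_r = list(angles = 2L, offsets = matrix(c(0, -c_th), 2)),
    shank_r = list(angles = c(2L, 3L),
                   offsets = cbind(c(0, -l_th), c(0, -c_sh))),
    foot_r = list(angles = c(2L, 3L, 4L),
                  offsets = cbind(c(0, -l_th), c(0, -l_sh), ft_com)),
    thigh_l = list(angles = 5L, offsets = matrix(c(0, -c_th), 2)),
    shank_l = list(angles = c(5L, 6L),
                   offsets = cbind(c(0, -l_th), c(0, -c_sh))),
    foot_l = list(angles = c(5L, 6L, 7L),
                  offsets = cbind(c(0, -l_th), c(0, -l_sh), ft_com)))

  dyn <- list(W = W, m = segments$mass_kg, I = segments$inertia_kgm2,
              points = points,
              Iang = t(W) %*% diag(segments$inertia_kgm2) %*% W,
              l_th = l_th, l_sh = l_sh)

  # muscles expanded to both sides; constant moment-arm matrix (n x 9),
  # entries r_mj = -dL_m/dq_j so generalized force = t(Rm) %*% F
  mt <- muscles
  n_g <- nrow(mt)
  side <- rep(c("r", "l"), each = n_g)
  mfull <- tibble(
    muscle = paste(rep(mt$muscle, 2), side, sep = "_"),
    group = rep(mt$muscle, 2), side = side,
    fmax_n = rep(mt$fmax_n, 2), l_opt_m = rep(mt$l_opt_m, 2),
    tendon_slack_m = rep(mt$tendon_slack_m, 2),
    fiber_ref_frac = rep(mt$fiber_ref_frac, 2),
    vmax_lopt_per_s = rep(mt$vmax_lopt_per_s, 2))
  Rm <- matrix(0, nrow(mfull), 9,
               dimnames = list(mfull$muscle, coord_names()))
  for (i in seq_len(n_g)) {
    Rm[i, c("hip_r", "knee_r", "ankle_r")] <-
      c(mt$r_hip_m[i], mt$r_knee_m[i], mt$r_ankle_m[i])
    Rm[n_g + i, c("hip_l", "knee_l", "ankle_l")] <-
      c(mt$r_hip_m[i], mt$r_knee_m[i], mt$r_ankle_m[i])
  }
  mfull$l_ref_m <- mfull$tendon_slack_m + mfull$fiber_ref_frac * mfull$l_opt_m

  # contact spheres in the foot frame: calcaneus-frame locations shifted by
  # the ankle-to-calcaneus offset (sagittal x-y; the mediolateral z
  # coordinate is carried in the table but unused by the planar mechanics)
  sph <- list(side = spheres$side,
              angle_id = ifelse(spheres$side == "right", 4L, 7L),
              local = t(cbind(spheres$x_mm, spheres$y_mm) / 1000) + calcn,
              radius = spheres$radius_mm / 1000,
              table = spheres)

  limits <- joint_limits %||% list(
    lower = deg2rad(c(-Inf, -Inf, -20, -25, -2, -45, -25, -2, -45)),
    upper = deg2rad(c(Inf, Inf, 20, 70, 140, 35, 70, 140, 35)))
  stopifnot(length(limits$lower) == 9, length(limits$upper) == 9)

  structure(list(
    body_mass = body_mass, height = height, gravity = gravity,
    segments = segments, dyn = dyn,
    muscles = mfull, Rm = Rm,
    spheres = sph, contact = contact, ground = ground,
    joint_damping = joint_damping, limit_stiffness = limit_stiffness,
    limit_damping = limit_damping, limits = limits,
    tau_act = tau_act, tau_deact = tau_deact,
    calcn_offset = calcn),
    class = "skeleton_model")
}

#' @export
print.skeleton_model <- function(x, ...) {
  cat(sprintf(
    "<skeleton_model> 9-DOF sagittal model, %.1f kg, %.2f m, %d muscles, %d contact spheres\n",
    x$body_mass, x$height, nrow(x$muscles), length(x$spheres$radius)))
  invisible(x)
}

#' Muscle-tendon lengths and moment arms at a pose
#'
#' Evaluates every muscle-tendon unit's length and its moment arms about the
#' spanned joints at the generalized coordinates `q`. With the constant
#' moment-arm path model, `L(q) = L_ref - sum_j r_j q_j`, so the moment arm
#' equals `-dL/dq_j` exactly.
#'
#' @param model a [skeleton_model()].
#' @param q named or ordered numeric vector of the 9 coordinates (rad, m).
#' @return tibble with columns `muscle`, `side`, `mtu_length_m` and one
#'   moment-arm column per joint coordinate (`r_<coord>_m`).
#' @export
mtu_geometry <- function(model, q) {
  q <- as_coord_vector(q)
  L <- mtu_lengths(model, q)
  out <- tibble(muscle = model$muscles$muscle, side = model$muscles$side,
                mtu_length_m = L)
  for (j in joint_coords()) out[[paste0("r_", j, "_m")]] <- model$Rm[, j]
  out
}

# internal vectorized forms used by the simulator
mtu_lengths <- function(model, q) {
  as.vector(model$muscles$l_ref_m - model$Rm %*% q)
}
mtu_velocities <- function(model, qd) {
  as.vector(-model$Rm %*% qd)
}

as_coord_vector <- function(q) {
  if (!is.null(names(q))) q <- q[coord_names()]
  q <- as.numeric(q)
  if (length(q) != 9L) abort("q must have 9 coordinates")
  stop_not_finite(q, "q")
  q
}

#' Normalized fiber state of a muscle-tendon unit
#'
#' Applies the rigid-tendon convention: fiber length = MTU length minus
#' tendon slack length (pennation ignored), normalized by optimal fiber
#' length; fiber velocity equals MTU velocity, normalized by ten optimal
#' fiber lengths per second (the maximal contraction velocity), positive
#' while lengthening.
#'
#' @param mtu one row of [default_muscles()] (or of `model$muscles`), i.e. a
#'   list with `l_opt_m`, `tendon_slack_m` and `vmax_lopt_per_s`.
#' @param mtu_length_m,mtu_velocity_m_s muscle-tendon length (m) and
#'   lengthening velocity (m/s); vectors allowed.
#' @return tibble with columns `l_norm`, `v_norm`.
#' @export
normalized_fiber_state <- function(mtu, mtu_length_m, mtu_velocity_m_s = 0) {
  fiber <- mtu_length_m - mtu$tendon_slack_m
  if (any(fiber <= 0)) {
    abort("fiber length <= 0: pose outside the muscle path model's domain")
  }
  tibble(l_norm = fiber / mtu$l_opt_m,
         v_norm = mtu_velocity_m_s / (mtu$vmax_lopt_per_s * mtu$l_opt_m))
}

# force-length, force-velocity and passive curves (dimensionless)
fl_active <- function(l_norm) exp(-((l_norm - 1) / 0.45)^2)
fv_curve <- function(v_norm) {
  ifelse(v_norm <= 0,
         pmax(0, (1 + v_norm) / (1 - 4 * v_norm)),
         1 + 0.5 * v_norm / (v_norm + 0.1))
}
# derivative of fv wrt v_norm (for implicit muscle damping); >= 0
fv_slope <- function(v_norm) {
  ifelse(v_norm <= 0,
         ifelse(v_norm <= -1, 0, 5 / (1 - 4 * v_norm)^2),
         0.05 / (v_norm + 0.1)^2)
}
fp_passive <- function(l_norm) {
  l <- pmin(l_norm, 2)  # cap to keep the exponential bounded
  ifelse(l > 1, (exp(4 * (l - 1) / 0.6) - 1) / (exp(4) - 1), 0)
}

#' Hill-type muscle fiber force
#'
#' Standard Hill model with a Gaussian active force-length curve, hyperbolic
#' force-velocity relation (zero force at maximal shortening, 1.5 times
#' isometric on the lengthening asymptote) and an exponential passive
#' element engaging beyond optimal fiber length. With a rigid tendon the
#' fiber force is also the tendon force.
#'
#' @param mtu a list/row with `fmax_n` (and the fields used by
#'   [normalized_fiber_state()] if you start from MTU kinematics).
#' @param a activation in `[0, 1]`.
#' @param l_norm,v_norm normalized fiber length and velocity.
#' @return force in N (>= 0), vectorized.
#' @export
hill_force <- function(mtu, a, l_norm, v_norm) {
  stop_not_finite(a, "a"); stop_not_finite(l_norm, "l_norm")
  stop_not_finite(v_norm, "v_norm")
  if (any(a < 0 | a > 1)) abort("activation must lie in [0, 1]")
  mtu$fmax_n * (a * fl_active(l_norm) * fv_curve(v_norm) + fp_passive(l_norm))
}

#' First-order activation dynamics
#'
#' Excitation-to-activation lag with separate activation and deactivation
#' time constants. Returns the derivative `da/dt`; for fixed excitation the
#' activation converges exponentially to it.
#'
#' @param a current activation in `[0, 1]`.
#' @param y_neural neural excitation in `[0, 1]`.
#' @param tau_act,tau_deact time constants in s.
#' @return `da/dt` (1/s), vectorized.
#' @export
activation_dynamics <- function(a, y_neural, tau_act = 0.015,
                                tau_deact = 0.060) {
  stop_not_finite(a, "a"); stop_not_finite(y_neural, "y_neural")
  if (any(y_neural < 0 | y_neural > 1)) abort("y_neural must lie in [0, 1]")
  tau <- ifelse(y_neural > a, tau_act, tau_deact)
  (y_neural - a) / tau
}

# exact exponential update of the activation filter over one step
activation_step <- function(a, y, dt, tau_act, tau_deact) {
  tau <- ifelse(y > a, tau_act, tau_deact)
  e <- exp(-dt / tau)
  pmin(1, pmax(0, a * e + y * (1 - e)))
}
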