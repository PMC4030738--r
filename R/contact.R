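#' Default foot contact spheres
#'
#' Sphere locations (calcaneus frame, mm) and radii of the foot-ground
#' contact geometry: one heel sphere (30 mm) and two forefoot spheres
#' (15 mm) per foot. The mediolateral `z` coordinate is carried for
#' completeness but unused by the sagittal mechanics.
#'
#' @return tibble with columns `side`, `sphere`, `x_mm`, `y_mm`, `z_mm`,
#'   `radius_mm`.
#' @export
default_contact_spheres <- function() {
  as_tibble(utils::read.csv(pkg_extdata("contact_spheres.csv"),
                            stringsAsFactors = FALSE))
}

#' Default elastic-foundation contact parameters
#'
#' Stiffness, dissipation and friction coefficients of the foot-ground
#' contact model, shipped verbatim as defaults (note the unusual printed
#' units of stiffness and dissipation; both can be overridden).
#'
#' @return a list of class `contact_params`.
#' @export
default_contact_params <- function() {
  tab <- utils::read.csv(pkg_extdata("contact_params.csv"))
  contact_params(tab$stiffness_mpa_m, tab$dissipation_s_m,
                 tab$static_friction, tab$dynamic_friction,
                 tab$viscous_friction_s_m)
}

#' Contact parameter set
#'
#' @param stiffness_mpa_m elastic-foundation stiffness (MPa/m, > 0).
#' @param dissipation_s_m normal dissipation coefficient (s/m, >= 0).
#' @param static_friction,dynamic_friction friction coefficients (>= 0).
#' @param viscous_friction_s_m viscous friction coefficient (s/m, >= 0).
#' @export
contact_params <- function(stiffness_mpa_m = 1.86, dissipation_s_m = 1000,
                           static_friction = 0.101, dynamic_friction = 0.2,
                           viscous_friction_s_m = 0.01) {
  if (stiffness_mpa_m <= 0) abort("stiffness must be positive")
  if (dissipation_s_m < 0) abort("dissipation must be non-negative")
  if (static_friction < 0 || dynamic_friction < 0 || viscous_friction_s_m < 0) {
    abort("friction coefficients must be non-negative")
  }
  structure(list(stiffness_mpa_m = stiffness_mpa_m,
                 dissipation_s_m = dissipation_s_m,
                 static_friction = static_friction,
                 dynamic_friction = dynamic_friction,
                 viscous_friction_s_m = viscous_friction_s_m),
            class = "contact_params")
}

#' Ground plane (treadmill surface)
#'
#' Horizontal contact plane attached to the treadmill, with the belt moving
#' towards -x at `belt_speed_m_s` (1 km/h by default, the reference walking
#' speed).
#'
#' @param height_m plane height (m).
#' @param belt_speed_m_s belt speed (m/s, surface moves towards -x).
#' @export
ground_plane <- function(height_m = 0, belt_speed_m_s = 1 / 3.6) {
  structure(list(height_m = height_m, belt_speed_m_s = belt_speed_m_s,
                 normal = c(0, 1)),
            class = "ground_plane")
}

# Elastic-foundation sphere-plane force law.  Normal force
#   f_n = stiffness * pi * radius * delta * max(0, 1 + c * ddot)
# (linear in penetration, Hunt-Crossley-style velocity factor, clipped at
# zero).  The tabulated dissipation coefficient is read on a mm/s
# penetration-rate scale (c = dissipation/1000 per m/s): taken literally in
# SI it would amplify gait-scale penetration rates into two-orders-of-
# magnitude force spikes.  Tangential force is a tanh-regularized Coulomb
# law with a stiction/dynamic transition at a 1 mm/s reference slip speed
# plus a viscous term, always opposing slip relative to the belt.  Also
# returns the linearized velocity-damping slopes used by the implicit
# integrator.
ef_force_law <- function(pos_y, vel_x, vel_y, radius, plane, params) {
  k_eff <- params$stiffness_mpa_m * 1e6 * pi * radius
  delta <- plane$height_m - (pos_y - radius)
  if (delta <= 0) {
    return(list(fn = 0, ft = 0, Dn = 0, Dt = 0, delta = 0))
  }
  ddot <- -vel_y
  cdis <- params$dissipation_s_m / 1000
  fac <- 1 + cdis * ddot
  fn <- k_eff * delta * max(0, fac)
  Dn <- if (fac > 0) k_eff * delta * cdis else 0
  vslip <- vel_x + plane$belt_speed_m_s
  sig <- vslip / 0.001
  mu <- (params$dynamic_friction +
           (params$static_friction - params$dynamic_friction) / cosh(sig)) *
    tanh(sig)
  ft <- -fn * (mu + params$viscous_friction_s_m * vslip)
  Dt <- fn * (max(params$static_friction, params$dynamic_friction) / 0.001 +
                params$viscous_friction_s_m)
  list(fn = fn, ft = ft, Dn = Dn, Dt = Dt, delta = delta)
}

#' Sphere-on-plane contact force
#'
#' Evaluates the elastic-foundation contact law for a single sphere: zero
#' force without penetration, a normal force linear in penetration with a
#' Hunt-Crossley-style dissipation factor (clipped so the normal force never
#' pulls), and regularized Coulomb-plus-viscous friction opposing slip
#' relative to the belt. The force is a continuous function of the sphere
#' state.
#'
#' @param position sphere center `c(x, y)` or `c(x, y, z)` in m.
#' @param velocity sphere center velocity, same layout.
#' @param radius_m sphere radius (m).
#' @param plane a [ground_plane()].
#' @param params a [contact_params()].
#' @return list with `force` (3-component, N; z = 0 in the sagittal model)
#'   and `point` (application point on the plane).
#' @export
sphere_plane_force <- function(position, velocity, radius_m,
                               plane = ground_plane(),
                               params = default_contact_params()) {
  stop_not_finite(position, "position"); stop_not_finite(velocity, "velocity")
  if (radius_m <= 0) abort("radius must be positive")
  f <- ef_force_law(position[2L], velocity[1L], velocity[2L], radius_m,
                    plane, params)
  list(force = c(f$ft, f$fn, 0),
       point = c(position[1L], position[2L] - radius_m, 0),
       penetration_m = f$delta)
}

#' Detect heel-contact events from vertical ground reaction force
#'
#' A gait event is registered at every upward crossing of 10% of body
#' weight (threshold configurable); crossings closer together than the
#' debounce interval are merged (first one kept).
#'
#' @param grf data frame with columns `time` (s, uniform) and `vgrf_n`
#'   (vertical GRF, N).
#' @param body_weight_n body weight in N (> 0).
#' @param threshold_frac threshold as a fraction of body weight.
#' @param debounce_s merge window in s.
#' @return tibble with column `time` of event times (linearly interpolated
#'   at the crossing).
#' @export
detect_heel_contact <- function(grf, body_weight_n, threshold_frac = 0.10,
                                debounce_s = 0.100) {
  stopifnot(all(c("time", "vgrf_n") %in% names(grf)))
  if (!is.finite(body_weight_n) || body_weight_n <= 0) {
    abort("body_weight_n must be positive")
  }
  uniform_dt(grf$time)
  f <- grf$vgrf_n
  thr <- threshold_frac * body_weight_n
  n <- length(f)
  below <- f[-n] < thr
  above <- f[-1L] >= thr
  idx <- which(below & above)
  if (length(idx) == 0L) return(tibble(time = numeric(0)))
  frac <- (thr - f[idx]) / (f[idx + 1L] - f[idx])
  times <- grf$time[idx] + frac * (grf$time[idx + 1L] - grf$time[idx])
  keep <- c(TRUE, diff(times) >= debounce_s)
  # merge chains: keep an event only if far enough from the last kept one
  kept <- times[1L]
  for (t in times[-1L]) if (t - kept[length(kept)] >= debounce_s) kept <- c(kept, t)
  tibble(time = kept)
}

#' Replace the contact spheres of a model
#'
#' @param model a [skeleton_model()].
#' @param spheres sphere table in the layout of [default_contact_spheres()].
#' @return the model with updated contact geometry.
#' @export
set_contact_spheres <- function(model, spheres) {
  model$spheres <- list(
    side = spheres$side,
    angle_id = ifelse(spheres$side == "right", 4L, 7L),
    local = t(cbind(spheres$x_mm, spheres$y_mm) / 1000) + model$calcn_offset,
    radius = spheres$radius_mm / 1000,
    table = spheres)
  model
}

#' Optimize contact-sphere locations against the kinematic tracking error
#'
#' Tunes the in-plane (x, y) sphere locations in the calcaneus frame by
#' minimizing the RMS joint-angle deviation (deg, over hip/knee/ankle of
#' both legs) of open-loop protocol intervals replayed with the trial
#' geometry, while the excitations and reserves of the reference setup stay
#' fixed — the analogue of tuning the contact model so a forward simulation
#' with computed excitations best tracks the reference. The same offsets
#' are applied to the corresponding sphere of both feet. A derivative-free
#' simplex search with box-clamped coordinates (+/- `bounds_mm`) is used;
#' the best point ever visited (including the start) is returned, so the
#' objective never increases.
#'
#' @param setup a [reference_setup()] (its model holds the initial spheres).
#' @param spheres initial sphere table (defaults to the setup's model's).
#' @param intervals protocol interval start positions (% of cycle) used in
#'   the objective.
#' @param bounds_mm box half-width around the initial locations (mm).
#' @param maxit maximum objective evaluations.
#' @param spec an [interval_spec()].
#' @return list with `spheres` (optimized table), `objective_deg`
#'   (best objective), `initial_objective_deg`, and `trace` (objective per
#'   evaluation).
#' @export
optimize_sphere_locations <- function(setup, spheres = NULL,
                                      intervals = c(0, 15, 30, 45),
                                      bounds_mm = 50, maxit = 40,
                                      spec = interval_spec()) {
  if (is.null(spheres)) spheres <- setup$model$spheres$table
  joints <- c("hip_r", "knee_r", "ankle_r", "hip_l", "knee_l", "ankle_l")
  pars <- run_parameters(setup, NULL)
  n_sp <- 3L  # per-foot spheres share offsets across sides
  trace <- numeric(0)
  qref_cache <- new.env()
  objective <- function(offset_mm) {
    offset_mm <- pmin(bounds_mm, pmax(-bounds_mm, offset_mm))
    sph <- spheres
    for (i in seq_len(n_sp)) {
      rows <- which(ave(seq_len(nrow(sph)), sph$side, FUN = seq_along) == i)
      sph$x_mm[rows] <- spheres$x_mm[rows] + offset_mm[2 * i - 1L]
      sph$y_mm[rows] <- spheres$y_mm[rows] + offset_mm[2 * i]
    }
    trial <- setup
    trial$model <- set_contact_spheres(setup$model, sph)
    err2 <- 0; n <- 0
    for (s in intervals) {
      res <- tryCatch(
        run_interval(trial, NULL, start_pct = s, spec = spec),
        reflexgait_sim_failure = function(e) NULL,
        error = function(e) NULL)
      if (is.null(res)) return(1e3)  # failed trial point: large finite score
      key <- sprintf("s%g", s)
      if (is.null(qref_cache[[key]])) {
        qref_cache[[key]] <- rad2deg(eval_gait_coords(
          setup$traj, res$kinematics$cycle_pct * setup$traj$cycle_s / 100, 0))
      }
      qref <- qref_cache[[key]]
      for (j in joints) {
        d <- res$kinematics[[j]] - qref[, match(j, coord_names())]
        err2 <- err2 + sum(d^2); n <- n + length(d)
      }
    }
    val <- sqrt(err2 / n)
    trace[length(trace) + 1L] <<- val
    val
  }
  x0 <- rep(0, 2L * n_sp)
  f0 <- objective(x0)
  best <- list(par = x0, value = f0)
  opt <- stats::optim(x0, function(x) {
    v <- objective(x)
    if (v < best$value) best <<- list(par = pmin(bounds_mm, pmax(-bounds_mm, x)),
                                      value = v)
    v
  }, method = "Nelder-Mead", control = list(maxit = maxit))
  off <- best$par
  out <- spheres
  for (i in seq_len(n_sp)) {
    rows <- which(ave(seq_len(nrow(out)), out$side, FUN = seq_along) == i)
    out$x_mm[rows] <- spheres$x_mm[rows] + off[2 * i - 1L]
    out$y_mm[rows] <- spheres$y_mm[rows] + off[2 * i]
  }
  list(spheres = out, objective_deg = best$value,
       initial_objective_deg = f0, trace = trace)
}
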