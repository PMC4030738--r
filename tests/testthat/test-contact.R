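still_plane <- function() ground_plane(belt_speed_m_s = 0)

test_that("sphere-plane force vanishes without penetration and is continuous", {
  prm <- default_contact_params()
  f0 <- sphere_plane_force(c(0, 0.05), c(0, 0), 0.03, still_plane(), prm)
  expect_equal(f0$force, c(0, 0, 0))
  # just touching
  f1 <- sphere_plane_force(c(0, 0.03), c(0, 0), 0.03, still_plane(), prm)
  expect_equal(f1$force, c(0, 0, 0))
  # continuity: tiny penetration gives tiny force
  f2 <- sphere_plane_force(c(0, 0.03 - 1e-8), c(0, 0), 0.03, still_plane(), prm)
  expect_lt(abs(f2$force[2]), 1e-2)
})

test_that("static penetration gives the closed-form elastic-foundation force", {
  prm <- default_contact_params()
  delta <- 0.004; r <- 0.03
  f <- sphere_plane_force(c(0.1, r - delta), c(0, 0), r, still_plane(), prm)
  expect_equal(f$force[2], prm$stiffness_mpa_m * 1e6 * pi * r * delta,
               tolerance = 1e-12)
  expect_equal(f$force[1], 0)
  expect_equal(f$point, c(0.1, -delta, 0))
})

test_that("fast sliding approaches the dynamic-plus-viscous friction ratio", {
  prm <- default_contact_params()
  delta <- 0.003; r <- 0.03
  v <- 0.5
  f <- sphere_plane_force(c(0, r - delta), c(v, 0), r, still_plane(), prm)
  ratio <- -f$force[1] / f$force[2]
  expect_equal(ratio, prm$dynamic_friction + prm$viscous_friction_s_m * v,
               tolerance = 1e-3)
  # friction opposes slip and dissipates over a range of speeds
  for (v in c(-0.3, -0.01, -1e-4, 1e-4, 0.01, 0.3)) {
    f <- sphere_plane_force(c(0, r - delta), c(v, 0), r, still_plane(), prm)
    expect_lt(f$force[1] * v, 0)
    bound <- (max(prm$static_friction, prm$dynamic_friction) +
                prm$viscous_friction_s_m * abs(v)) * f$force[2]
    expect_lte(abs(f$force[1]), bound + 1e-9)
  }
})

test_that("the normal force never pulls", {
  prm <- default_contact_params()
  # rapidly separating contact: dissipation factor clips at zero
  f <- sphere_plane_force(c(0, 0.028), c(0, 5), 0.03, still_plane(), prm)
  expect_gte(f$force[2], 0)
})

test_that("heel contact fires at 10% body weight", {
  bw <- 534
  # monotone ramp 0 -> 1.2 BW over 1 s: single event where f = 0.1 BW
  tt <- seq(0, 1, by = 1e-3)
  ev <- detect_heel_contact(tibble::tibble(time = tt, vgrf_n = 1.2 * bw * tt),
                            bw)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$time, 0.1 / 1.2, tolerance = 1e-6)
  # all-zero trace: nothing fires
  ev0 <- detect_heel_contact(tibble::tibble(time = tt, vgrf_n = 0), bw)
  expect_equal(nrow(ev0), 0L)
  # two gait cycles of a stance-shaped trace (loaded 0-60%, unloaded in
  # swing): exactly two events, one per cycle
  tt2 <- seq(0, 4.4, by = 1e-3)
  pct <- (tt2 / 2.2 * 100) %% 100
  shape <- exp(-((pct - 30) / 14)^2)
  ev2 <- detect_heel_contact(tibble::tibble(time = tt2, vgrf_n = bw * shape),
                             bw)
  expect_equal(nrow(ev2), 2L)
  expect_equal(diff(ev2$time), 2.2, tolerance = 0.01)
  expect_error(detect_heel_contact(tibble::tibble(time = tt, vgrf_n = 0), -5),
               "positive")
})

test_that("chattering crossings are debounced", {
  bw <- 534
  tt <- seq(0, 1, by = 1e-3)
  f <- 0.1 * bw + 0.02 * bw * sin(2 * pi * 50 * tt)  # 50 Hz chatter
  ev <- detect_heel_contact(tibble::tibble(time = tt, vgrf_n = f), bw)
  expect_true(all(diff(ev$time) >= 0.1))
})

test_that("standing on both feet settles to body weight within 1%", {
  # braced joints (tight soft limits) so the check isolates the contact
  # model's static equilibrium from postural control, which the passive
  # skeleton does not have; the belt is stationary
  brace <- pi / 180
  model <- skeleton_model(
    joint_damping = 30,
    limit_stiffness = 2000,
    joint_limits = list(lower = c(-Inf, -Inf, rep(-brace, 7)),
                        upper = c(Inf, Inf, rep(brace, 7))),
    ground = ground_plane(belt_speed_m_s = 0))
  bw <- model$body_mass * model$gravity
  # static penetration so the heel spheres carry the weight; pelvis centred
  # over the support
  k_heel <- model$contact$stiffness_mpa_m * 1e6 * pi * 0.03
  delta <- bw / (2 * k_heel)
  l_leg <- model$dyn$l_th + model$dyn$l_sh
  heel_drop <- -(model$spheres$local[2, 1] - model$spheres$radius[1])
  q <- rep(0, 9)
  q[2] <- l_leg + heel_drop - delta
  q[1] <- -model$spheres$local[1, 1]  # pelvis roughly over the heel sphere
  st <- dynamic_state(q, rep(0, 9))
  grf <- numeric(0)
  for (i in 1:3000) {
    st <- forward_step(model, st, rep(0, 16), 5e-4)
    if (i > 2400) grf <- c(grf, sum(attr(st, "contact")[, 2]))
  }
  expect_lt(max(abs(st$qd)), 0.05)  # effectively static
  expect_equal(mean(grf), bw, tolerance = 0.01)
})

test_that("sphere-location optimization improves a perturbed geometry", {
  setup <- rg_setup()
  spec <- interval_spec()
  # perturb the heel spheres 20 mm downward-out of place
  sph <- setup$model$spheres$table
  heel <- sph$radius_mm == 30
  sph$y_mm[heel] <- sph$y_mm[heel] + 20
  pert <- optimize_sphere_locations(setup, spheres = sph,
                                    intervals = c(0, 15), maxit = 25)
  expect_lte(pert$objective_deg, pert$initial_objective_deg)
  expect_lt(pert$objective_deg, pert$initial_objective_deg - 1e-3)
  # box constraint respected
  expect_true(all(abs(pert$spheres$x_mm - sph$x_mm) <= 50 + 1e-9))
  expect_true(all(abs(pert$spheres$y_mm - sph$y_mm) <= 50 + 1e-9))
  # starting from the true geometry the objective does not increase
  base <- optimize_sphere_locations(setup, intervals = c(0, 15), maxit = 5)
  expect_lte(base$objective_deg, base$initial_objective_deg)
})
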