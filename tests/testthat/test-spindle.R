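test_that("spindle derivative branches follow the lengthening gate", {
  p <- ref_params("soleus")
  # zero state, zero drive
  d0 <- spindle_derivatives(list(u_l = 0, u_v = 0),
                            list(l_norm = 1, v_norm = 0), k = 1, p)
  expect_equal(d0$du_l, 0)
  expect_equal(d0$du_v, 0)
  # shortening muscle: pure decay of the length pathway
  d1 <- spindle_derivatives(list(u_l = 0.2, u_v = 0.2),
                            list(l_norm = 1, v_norm = -0.5), k = 1, p)
  expect_equal(d1$du_l, -0.2 / 0.075)
  expect_equal(d1$du_v, -0.2 / 0.040)
  # lengthening at unit length: drive g_l * l / tau_l
  d2 <- spindle_derivatives(list(u_l = 0, u_v = 0),
                            list(l_norm = 1, v_norm = 1), k = 1, p)
  expect_equal(d2$du_l, 0.1 / 0.075)
  expect_equal(d2$du_v, 0.59 / 0.040)
})

test_that("non-finite inputs are rejected naming the offending field", {
  p <- ref_params()
  expect_error(spindle_derivatives(list(u_l = NaN, u_v = 0),
                                   list(l_norm = 1, v_norm = 0), 1, p),
               "u_l")
  expect_error(spindle_derivatives(list(u_l = 0, u_v = 0),
                                   list(l_norm = Inf, v_norm = 0), 1, p),
               "l_norm")
})

test_that("integration reaches the analytic steady states", {
  grid <- tibble::tibble(time = seq(0, 1, by = 0.001),
                         l_norm = 1, v_norm = 1, k = 1)
  for (g in spindle_muscle_groups()) {
    p <- ref_params(g)
    out <- integrate_spindle(grid, p)
    expect_equal(tail(out$u_v, 1), p$g_v, tolerance = 1e-3)
    expect_equal(tail(out$u_l, 1), p$g_l, tolerance = 1e-3)
  }
  # full suppression: k = 0 kills both pathways
  out0 <- integrate_spindle(dplyr::mutate(grid, k = 0), ref_params())
  expect_equal(tail(out0$u_l, 1), 0)
  expect_equal(tail(out0$u_v, 1), 0)
})

test_that("step response recovers the printed time constant", {
  p <- ref_params("soleus")
  grid <- tibble::tibble(time = seq(0, 0.5, by = 1e-4),
                         l_norm = 1, v_norm = 1, k = 1)
  out <- integrate_spindle(grid, p)
  asym <- p$g_l
  t63 <- out$time[which(out$u_l >= (1 - exp(-1)) * asym)[1L]]
  expect_equal(t63 * 1000, 75, tolerance = 1 / 75)  # 75 ms within 1 ms
})

test_that("integration matches the closed-form solution for piecewise-constant drives", {
  p <- ref_params("gastrocnemius")
  set.seed(42)
  dt <- 1e-3
  segs <- 5
  n_per <- 200
  l <- rep(runif(segs, 0.8, 1.2), each = n_per)
  v <- rep(runif(segs, -1, 1), each = n_per)
  k <- rep(runif(segs), each = n_per)
  grid <- tibble::tibble(time = dt * (seq_len(segs * n_per) - 1),
                         l_norm = l, v_norm = v, k = k)
  out <- integrate_spindle(grid, p)
  # independent oracle: per-segment exponential relaxation to the drive
  ul <- 0; uv <- 0
  for (s in seq_len(segs)) {
    i <- (s - 1) * n_per + 1
    Dl <- if (v[i] > 0) k[i] * p$g_l * l[i] else 0
    Dv <- k[i] * p$g_v * max(0, v[i])
    t_end <- n_per * dt
    idx_end <- s * n_per
    ul_end <- Dl + (ul - Dl) * exp(-t_end / p$tau_l)
    uv_end <- Dv + (uv - Dv) * exp(-t_end / p$tau_v)
    # compare one step into the next segment (state at segment boundary)
    if (s < segs) {
      expect_equal(out$u_l[idx_end + 1], ul_end, tolerance = 1e-6)
      expect_equal(out$u_v[idx_end + 1], uv_end, tolerance = 1e-6)
    }
    ul <- ul_end; uv <- uv_end
  }
})

test_that("feedback states stay non-negative and monotone in the gains", {
  set.seed(7)
  grid <- tibble::tibble(time = seq(0, 2, by = 1e-3))
  grid$l_norm <- 1 + 0.2 * sin(2 * pi * grid$time)
  grid$v_norm <- 0.3 * sin(4 * pi * grid$time)
  grid$k <- 0.5 + 0.5 * cos(2 * pi * grid$time)^2
  p1 <- ref_params("soleus")
  out1 <- integrate_spindle(grid, p1)
  expect_true(all(out1$u_l >= 0) && all(out1$u_v >= 0))
  p2 <- scale_gains(p1, factor_l = 1, factor_v = 2.5)
  out2 <- integrate_spindle(grid, p2)
  expect_true(all(out2$u_v >= out1$u_v - 1e-12))
})

test_that("suppressed modulation makes feedback decay exponentially", {
  p <- ref_params("soleus")
  n <- 301
  grid <- tibble::tibble(time = seq(0, 0.3, length.out = n),
                         l_norm = 1.1, v_norm = 0.5, k = 0)
  out <- integrate_spindle(grid, p, initial = c(u_l = 0.4, u_v = 0.3))
  expect_equal(out$u_l, 0.4 * exp(-out$time / p$tau_l), tolerance = 1e-9)
  expect_equal(out$u_v, 0.3 * exp(-out$time / p$tau_v), tolerance = 1e-9)
})

test_that("too-coarse sampling is rejected by the stability contract", {
  p <- ref_params("soleus")  # min tau = 40 ms
  grid <- tibble::tibble(time = seq(0, 1, by = 0.05), l_norm = 1,
                         v_norm = 1, k = 1)
  expect_error(integrate_spindle(grid, p), "too large")
})

test_that("excitation assembly sums and saturates as specified", {
  expect_equal(total_excitation(0.3, 0.1, 0.2), 0.6)
  expect_identical(total_excitation(0, 0, 0), 0)
  expect_equal(total_excitation(0.9, 0.4, 0.3), 1.6)
  expect_identical(saturate_excitation(0.5), 0.5)
  expect_identical(saturate_excitation(1.5), 1)
  expect_identical(saturate_excitation(-0.1), 0)
})

test_that("gain scaling reproduces the stroke parameter column", {
  # the stroke column prints 3x the reference gains at two decimals
  # (2.31 -> 2.30, 2.46 -> 2.45), so agreement is at printed precision
  for (g in spindle_muscle_groups()) {
    scaled <- scale_gains(ref_params(g), 3, 3)
    strk <- stroke_params(g)
    expect_equal(scaled$g_l, strk$g_l)
    expect_equal(scaled$g_v, strk$g_v, tolerance = 0.005)
    expect_equal(scaled$tau_l, strk$tau_l)
  }
  p <- ref_params("soleus")
  expect_equal(scale_gains(p, 1, 1), p)
  expect_error(scale_gains(p, -1, 1), "non-negative")
})

test_that("excitation decomposition is exact and round-trips known gains", {
  # zero tracking excitation with shortening muscle: u_b identically zero
  grid <- tibble::tibble(time = seq(0, 1, by = 1e-3), l_norm = 1,
                         v_norm = -0.1, k = 1, u_cmc = 0)
  dec0 <- fit_reference_gains(grid, ref_params(), quiet = TRUE)
  expect_true(all(dec0$u_b == 0))
  # zero gains: the base excitation is the whole signal
  gridc <- dplyr::mutate(grid, v_norm = 0.5,
                         u_cmc = 0.3 + 0.2 * sin(2 * pi * time))
  p0 <- spindle_params("soleus", 0.075, 0.04, 0, 0)
  decg <- fit_reference_gains(gridc, p0, quiet = TRUE)
  expect_equal(decg$u_b, gridc$u_cmc, tolerance = 1e-12)
  # round trip: forward-generate u_cmc from known base + gains, recover base
  p <- ref_params("gastrocnemius")
  drv <- tibble::tibble(time = seq(0, 2, by = 1e-3))
  drv$l_norm <- 1 + 0.15 * sin(pi * drv$time)
  drv$v_norm <- 0.4 * sin(3 * drv$time)
  drv$k <- 0.5 + 0.5 * sin(drv$time)^2
  fb <- integrate_spindle(drv, p)
  u_b_true <- 0.2 + 0.1 * cos(2 * pi * drv$time)
  drv$u_cmc <- pmin(1, u_b_true + fb$u_l + fb$u_v)
  dec <- fit_reference_gains(drv, p, quiet = TRUE)
  keep <- drv$u_cmc < 1
  expect_lt(max(abs(dec$u_b[keep] - u_b_true[keep])), 1e-9)
  # reassembly reconstructs u_cmc everywhere
  expect_lt(max(abs(total_excitation(dec$u_b, dec$u_l, dec$u_v) - drv$u_cmc)),
            1e-9)
})

test_that("negative base excitation is kept but reported", {
  p <- scale_gains(ref_params("soleus"), 6, 6)
  grid <- tibble::tibble(time = seq(0, 1, by = 1e-3), l_norm = 1.2,
                         v_norm = 0.5, k = 1, u_cmc = 0.05)
  expect_warning(dec <- fit_reference_gains(grid, p), "negative")
  expect_gt(attr(dec, "n_negative_u_b"), 0)
  expect_lt(max(abs(dec$u_b + dec$u_l + dec$u_v - grid$u_cmc)), 1e-12)
})

test_that("modulation curves interpolate their bins, stay periodic and clipped", {
  vals <- c(0.35, 0.55, 0.75, 0.9, 1, 1, 0.9, 0.75,
            0.5, 0.25, 0.08, 0.03, 0.02, 0.02, 0.05, 0.15)
  mc <- modulation_curve(vals)
  expect_lt(max(abs(predict(mc, mc$bin_centers) - vals)), 1e-9)
  pct <- seq(-50, 250, by = 0.37)
  expect_equal(predict(mc, pct), predict(mc, pct + 100), tolerance = 1e-12)
  dense <- predict(mc, seq(0, 100, by = 0.01))
  expect_true(all(dense >= 0 & dense <= 1))
  expect_error(modulation_curve(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(predict(constant_modulation(0.7), c(0, 33, 87)),
               rep(0.7, 3))
})
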