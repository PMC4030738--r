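#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
NULL

# internal: degrees <-> radians (user-facing tables are in degrees, all
# mechanics are in radians; conversion happens at the interface boundary only)
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @keywords internal
stop_not_finite <- function(value, field) {
  if (!all(is.finite(value))) {
    abort(sprintf("non-finite value in field '%s'", field),
          class = "reflexgait_nonfinite", field = field)
  }
  invisible(value)
}

# wrap a gait-cycle position into [0, 100)
wrap_pct <- function(pct) pct %% 100

# circular distance on the gait cycle (always in [-50, 50])
circ_dist_pct <- function(a, b) {
  d <- (a - b) %% 100
  ifelse(d > 50, d - 100, d)
}

# raised-cosine bump centred at `center` (% cycle) with half-width `width`,
# periodic over the cycle
cos_bump <- function(pct, center, width, height = 1) {
  d <- abs(circ_dist_pct(pct, center))
  ifelse(d < width, height * 0.5 * (1 + cos(pi * d / width)), 0)
}

# check a numeric time grid is uniform; returns dt
uniform_dt <- function(time, tol = 1e-9, what = "time") {
  if (length(time) < 2L) abort(sprintf("%s series needs at least 2 samples", what))
  dts <- diff(time)
  dt <- dts[1L]
  if (dt <= 0 || any(abs(dts - dt) > tol * max(1, abs(dt)))) {
    abort(sprintf("%s grid must be uniform and increasing", what))
  }
  dt
}

# linear interpolation that treats the series as periodic over one gait cycle
periodic_approx <- function(pct_grid, values, pct_query) {
  n <- length(pct_grid)
  stopifnot(length(values) == n)
  x <- c(pct_grid, pct_grid[1L] + 100)
  y <- c(values, values[1L])
  stats::approx(x, y, xout = pct_grid[1L] + (pct_query - pct_grid[1L]) %% 100,
                rule = 2)$y
}

pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "reflexgait", mustWork = FALSE)
  if (!nzchar(path)) {
    # during development (pkgload) fall back to the source tree
    path <- file.path("inst", "extdata", file)
  }
  path
}
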