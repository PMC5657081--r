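# Independent oracles and small fixtures shared across the test files.

# Brute-force terminal fit: evaluate every contiguous point set ending at the
# torque extremum and keep the largest one whose torque-on-angle regression
# reaches r2_min. Independent of the iterative implementation.
exhaustive_terminal_fit <- function(trace, window, branch, r2_min = 0.995) {
  idx <- seq.int(window$start[1], window$end[1] - 1L)
  tq <- trace$torque[idx]
  anchor <- idx[if (branch == "external") which.max(tq) else which.min(tq)]
  navail <- anchor - idx[1] + 1L
  r2s <- vapply(3:navail, function(n) {
    sel <- (anchor - n + 1L):anchor
    x <- trace$angle[sel]; y <- trace$torque[sel]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)^2
  }, numeric(1))
  pass <- which(!is.na(r2s) & r2s >= r2_min)
  if (!length(pass)) return(NULL)
  n <- max(pass) + 2L
  sel <- (anchor - n + 1L):anchor
  ft <- stats::lm(trace$torque[sel] ~ trace$angle[sel])
  list(n_points = n, slope = unname(stats::coef(ft)[2]))
}

# Rodrigues rotation of point p about the axis (point + unit direction).
rotate_about_axis <- function(p, phi_deg, point = c(0, 0, 0), dir = c(0, 0, 1)) {
  dir <- dir / sqrt(sum(dir^2))
  v <- p - point
  phi <- phi_deg * pi / 180
  vpar <- sum(v * dir) * dir
  vperp <- v - vpar
  w <- c(dir[2] * vperp[3] - dir[3] * vperp[2],
         dir[3] * vperp[1] - dir[1] * vperp[3],
         dir[1] * vperp[2] - dir[2] * vperp[1])
  point + vpar + vperp * cos(phi) + w * sin(phi)
}

# Small, fast synthetic fixtures.
small_protocol <- function(n_cycles = 3, sample_rate = 100)
  load_protocol(n_cycles = n_cycles, sample_rate = sample_rate)

make_trace <- function(k = 1.10, tau = 5.08, noise = 0, n_cycles = 3,
                       sample_rate = 100, transition = 0.2, seed = 1,
                       pin_group = "two") {
  generate_trace(small_protocol(n_cycles, sample_rate),
                 construct_params(k, tau, transition_torque = transition,
                                  angle_noise_sd = noise, pin_group = pin_group),
                 seed = seed)
}
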