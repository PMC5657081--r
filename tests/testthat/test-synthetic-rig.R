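test_that("backbone angle matches closed-form values and is odd", {
  # tanh saturates: 2/1 + 2 with a near-instant transition
  p_sat <- construct_params(1, 4, transition_torque = 1e-9)
  expect_equal(backbone_angle(2, p_sat), 4.0, tolerance = 1e-12)
  expect_equal(backbone_angle(0, p_sat), 0)

  # direct evaluation oracle: 1/2 + 3 * tanh(1/0.5)
  p <- construct_params(2, 6, transition_torque = 0.5)
  expect_equal(backbone_angle(1, p), 0.5 + 3 * tanh(2), tolerance = 1e-12)
  expect_equal(backbone_angle(1, p), 3.3920827, tolerance = 1e-6)

  # odd function for a grid of parameters and torques
  for (k in c(0.5, 1.18, 2)) for (tau in c(0, 4.25, 6.41)) {
    pp <- construct_params(k, tau, transition_torque = 0.3)
    tq <- seq(-2, 2, by = 0.25)
    expect_equal(backbone_angle(-tq, pp), -backbone_angle(tq, pp))
  }
})

test_that("generated traces follow the protocol and are seed-deterministic", {
  tr <- generate_trace(load_protocol(), construct_params(1.18, 4.25), seed = 5)
  expect_length(tr$time, 500000L)          # 250 cycles / 0.5 Hz * 1000 Hz
  expect_equal(max(tr$torque), 2.0, tolerance = 1e-4)

  # identical seed => identical trace; different seed => different noise
  a <- make_trace(noise = 0.05, seed = 11)
  b <- make_trace(noise = 0.05, seed = 11)
  c <- make_trace(noise = 0.05, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$angle, c$angle))

  # linear backbone: zero toggle, zero noise => T = k * theta exactly
  lin <- make_trace(k = 1.18, tau = 0, noise = 0)
  expect_equal(lin$torque, 1.18 * lin$angle, tolerance = 1e-10)

  # non-integer samples per cycle is a configuration error
  expect_error(generate_trace(load_protocol(frequency = 0.3, sample_rate = 100),
                              construct_params(1, 4)),
               class = "torsionrig_config_error")
})

test_that("sigmoid degenerates to two parallel lines separated by the toggle", {
  tr <- make_trace(k = 1.1, tau = 5, transition = 1e-9, noise = 0)
  up <- tr$torque > 0.01
  dn <- tr$torque < -0.01
  expect_equal(tr$torque[up], 1.1 * (tr$angle[up] - 2.5), tolerance = 1e-6)
  expect_equal(tr$torque[dn], 1.1 * (tr$angle[dn] + 2.5), tolerance = 1e-6)
})

test_that("marker generation obeys geometry, slippage and noise settings", {
  geo0 <- rig_geometry(position_noise_sd = 0,
                       rotation_share = c(cranial = 1, lateral = 1,
                                          caudal = 1, medial = 1))
  tr <- make_trace(noise = 0)
  mk <- generate_markers(tr, geo0, construct_params(1.1, 5.08), seed = 1)
  expect_length(mk, 16L)
  expect_s3_class(mk[["epi_cranial"]], "marker_trajectory")

  # static segments do not move at zero noise
  expect_equal(max(abs(apply(mk[["dia_lateral"]]$position, 2, sd))), 0)
  expect_equal(max(abs(apply(mk[["pot_top_cranial"]]$position, 2, sd))), 0)

  # chord between extreme positions of a share-1 marker: 2 r sin(phi/2)
  # with bone rotation 10 deg at radius 30 mm the chord is 2*30*sin(5 deg)
  geo_chord <- rig_geometry(position_noise_sd = 0, slippage_factor = 1,
                            rotation_share = c(cranial = 1, lateral = 1,
                                               caudal = 1, medial = 1))
  pr <- small_protocol()
  # amplitude/stiffness chosen so peak backbone angle is exactly +/-5 deg
  par <- construct_params(0.4, 0, angle_noise_sd = 0)
  tr5 <- generate_trace(pr, par, seed = 1)
  expect_equal(max(tr5$angle), 5, tolerance = 1e-9)
  mk5 <- generate_markers(tr5, geo_chord, par, seed = 1)
  pos <- mk5[["epi_cranial"]]$position
  d <- as.matrix(dist(pos[, 1:2]))
  expect_equal(max(d), 2 * 30 * sin(5 * pi / 180), tolerance = 1e-6)

  # slippage: actuator gross displacement / marker-derived gross = factor
  geo_slip <- rig_geometry(position_noise_sd = 0, slippage_factor = 2.6,
                           rotation_share = c(cranial = 1, lateral = 1,
                                              caudal = 1, medial = 1))
  mk_s <- generate_markers(tr, geo_slip, construct_params(1.1, 5.08), seed = 1)
  w <- segment_cycles(tr)[2, ]
  actuator <- gross_cycle_displacement(tr, w)
  marker <- marker_cycle_displacement(mk_s[["epi_medial"]], 2, 4,
                                      estimate_axis(mk_s))
  expect_equal(actuator / marker, 2.6, tolerance = 1e-3)

  # zero rotation => every trajectory constant
  tr0 <- generate_trace(pr, construct_params(1, 0, angle_noise_sd = 0), seed = 1)
  tr0$angle[] <- 0
  mk0 <- generate_markers(tr0, geo0, construct_params(1, 0), seed = 1)
  expect_true(all(vapply(mk0, function(m) max(apply(m$position, 2, sd)), 1) == 0))

  expect_error(marker_trajectory("m", "dorsal", "epiphysis", 1:3,
                                 matrix(0, 3, 3)),
               class = "torsionrig_data_error")
})

test_that("marker chords are invariant to rigid translation of the set", {
  geo0 <- rig_geometry(position_noise_sd = 0)
  tr <- make_trace(noise = 0, n_cycles = 1)
  mk <- generate_markers(tr, geo0, construct_params(1.1, 5.08), seed = 1)
  m <- mk[["epi_caudal"]]
  chord <- function(pos) sqrt(sum((pos[1, ] - pos[nrow(pos) %/% 4, ])^2))
  shifted <- sweep(m$position, 2, c(12.3, -4.5, 6.7), "+")
  expect_equal(chord(m$position), chord(shifted), tolerance = 1e-12)
})

test_that("a simulated study has repeated-measures structure and group levels", {
  pr <- small_protocol(n_cycles = 1, sample_rate = 50)
  st <- generate_study(study_design(n_specimens = 12, seed = 4), pr)
  expect_length(st$runs, 36L)            # 12 specimens x 3 groups
  expect_equal(nrow(st$true_params), 36L)
  expect_setequal(unique(st$true_params$pin_group), c("three", "two", "one"))

  # determinism: same design seed reproduces the same parameter draws
  st2 <- generate_study(study_design(n_specimens = 12, seed = 4), pr)
  expect_identical(st$true_params, st2$true_params)

  expect_error(generate_study(study_design(n_specimens = 1)),
               class = "torsionrig_config_error")
  expect_error(study_design(groups = c("one", "two", "three")),
               class = "torsionrig_config_error")
})

test_that("group means approach the reference levels and specimens induce correlation", {
  # empirical toggle means over many specimens approach the group table
  pr <- small_protocol(n_cycles = 1, sample_rate = 50)
  st <- generate_study(study_design(n_specimens = 200, seed = 9), pr)
  tp <- st$true_params
  ref <- default_group_params()
  for (g in c("three", "two", "one")) {
    m <- mean(tp$toggle_true[tp$pin_group == g])
    expect_equal(m, ref$toggle_mean[ref$pin_group == g], tolerance = 0.1)
    mk <- mean(tp$stiffness_true[tp$pin_group == g])
    expect_equal(mk, ref$stiffness_mean[ref$pin_group == g], tolerance = 0.1)
  }

  # Monte-Carlo oracle: positive within-specimen toggle correlation
  cors <- vapply(1:60, function(i) {
    s <- generate_study(study_design(n_specimens = 8, seed = 1000 + i), pr)
    wide <- matrix(s$true_params$toggle_true, nrow = 8, byrow = TRUE)
    cor(wide[, 1], wide[, 3])
  }, numeric(1))
  expect_gt(mean(cors), 0.2)
  expect_gt(mean(cors > 0), 0.8)
})
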