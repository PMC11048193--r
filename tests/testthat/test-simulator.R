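test_that("noise-free pulse round-trips its normalized Stokes components", {
  a <- const_archetype(quv = c(0.5, 0, 0))
  p <- simulate_pulse(a, A_true = identity_A(), noise_level = 0, seed = 1)
  tr <- to_stokes_trace(p, identity_A())
  expect_true(all(abs(tr$q_trace - 0.5) < 1e-12))
  expect_true(all(abs(tr$u_trace) < 1e-12))
  expect_equal(tr$q_mean, 0.5, tolerance = 1e-12)
})

test_that("value statistics of a pulse are invariant under time reversal", {
  # amplitude-occupation moments cannot see the direction of time, so a
  # mirrored pulse must give identical features
  a <- species_archetype("skewed", c(2, 0.3, 0, 0),
                         stokes_dispersion = rep(0, 4),
                         shape = list(width_mean = 80, width_sd = 0,
                                      asymmetry = 1.2, flatness = 2))
  p <- simulate_pulse(a, identity_A(), noise_level = 0, seed = 3)
  rev_p <- p[rev(seq_len(nrow(p))), ]
  s_fwd <- pulse_statistics(to_stokes_trace(p, identity_A())$I_trace)
  s_rev <- pulse_statistics(to_stokes_trace(rev_p, identity_A())$I_trace)
  expect_equal(as.list(s_fwd), as.list(s_rev), tolerance = 1e-12)
})

test_that("envelope flatness drives the sign and size of value skewness", {
  spiky <- gg_envelope(501, flatness = 0.8)
  flat <- gg_envelope(501, flatness = 8)
  expect_gt(pulse_statistics(spiky)$sk, 0.5)
  expect_lt(pulse_statistics(flat)$sk, -0.5)
})

test_that("streams are seed-deterministic and honour degenerate settings", {
  panel <- demo_panel()
  s1 <- simulate_stream(panel, duration = 3000, arrival_rate = 0.003,
                        seed = 42)
  s2 <- simulate_stream(panel, duration = 3000, arrival_rate = 0.003,
                        seed = 42)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_identical(stream_truth(s1), stream_truth(s2))

  s0 <- simulate_stream(panel, duration = 2000, arrival_rate = 0,
                        noise_level = 0, baseline_level = 0.4, seed = 1)
  expect_equal(nrow(stream_truth(s0)), 0)
  expect_true(all(abs(s0$I1 - 0.4) < 1e-12))

  one <- simulate_stream(panel[1:2], mixture = c(1, 0), duration = 30000,
                         arrival_rate = 0.003, seed = 2)
  expect_true(all(stream_truth(one)$label == names(panel)[1]))
})

test_that("particle counts concentrate around the Poisson mean", {
  panel <- demo_panel()[1]
  lambda_T <- 0.002 * 20000
  counts <- vapply(1:20, function(k) {
    nrow(stream_truth(simulate_stream(panel, duration = 20000,
                                      arrival_rate = 0.002, seed = 100 + k)))
  }, 0L)
  expect_true(all(abs(counts - lambda_T) <= 4 * sqrt(lambda_T)))
})

test_that("stream argument errors are raised", {
  panel <- demo_panel()
  expect_error(simulate_stream(panel, mixture = c(1, 1, 1, 1),
                               duration = 100), "sum to 1")
  expect_error(simulate_stream(panel, duration = -5), "positive")
  expect_error(simulate_stream(panel, duration = 1000, arrival_rate = 0.5),
               "occupancy")
  expect_error(simulate_pulse(demo_panel()[[1]], noise_level = -1), ">= 0")
  expect_error(simulate_pulse(demo_panel()[[1]],
                              A_true = matrix(0, 4, 4)), "singular")
})

test_that("calibration sets reproduce references exactly without noise", {
  cal <- simulate_calibration_set(identity_A(), n_states = 6,
                                  noise_level = 0, seed = 1)
  expect_equal(as.matrix(cal[, c("I1", "I2", "I3", "I4")]),
               as.matrix(cal[, c("S_I", "S_Q", "S_U", "S_V")]),
               ignore_attr = TRUE, tolerance = 1e-15)
  expect_error(simulate_calibration_set(n_states = 3), "at least 4")
})

test_that("zero-noise calibration round trip recovers A to machine precision", {
  for (s in 1:5) {
    A <- random_instrument_matrix(max_condition = 50, seed = s)
    cal <- simulate_calibration_set(A, n_states = 8, noise_level = 0,
                                    seed = s)
    A_hat <- estimate_instrument_matrix(cal)
    relerr <- norm(unclass(A_hat) - unclass(A), "F") / norm(unclass(A), "F")
    expect_lt(relerr, 1e-9)
  }
})

test_that("in-pulse DOP never exceeds 1 before noise injection", {
  a <- species_archetype("dispersed", c(3, 0.6, 0.5, 0.3),
                         stokes_dispersion = c(0.3, 0.3, 0.3, 0.3))
  for (s in 1:50) {
    p <- simulate_pulse(a, identity_A(), noise_level = 0, seed = s)
    tr <- to_stokes_trace(p, identity_A())
    expect_lte(tr$dop, 1 + 1e-12)
  }
})

test_that("archetype panels round-trip through YAML", {
  panel <- demo_panel()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_archetype_panel(panel, path)
  back <- read_archetype_panel(path)
  expect_identical(names(back), names(panel))
  expect_equal(back$Cyanophyta$mean_stokes, panel$Cyanophyta$mean_stokes)
  expect_equal(back$other_SPM$shape, panel$other_SPM$shape)

  shipped <- read_archetype_panel(system.file("extdata", "demo_panel.yaml",
                                              package = "pfec"))
  expect_equal(shipped$Chlorophyta$mean_stokes, panel$Chlorophyta$mean_stokes)
})

test_that("archetype validation rejects unphysical parameters", {
  expect_error(species_archetype("x", c(1, 0.9, 0.9, 0.9)), "unit ball")
  expect_error(species_archetype("x", c(-1, 0, 0, 0)), "> 0")
  expect_error(species_archetype("x", c(1, 0, 0, 0),
                                 stokes_dispersion = c(-0.1, 0, 0, 0)),
               "nonnegative")
  expect_error(species_archetype("x", c(1, 0, 0, 0),
                                 shape = list(width_mean = 2)), ">= 3")
})

test_that("stream CSV round trip preserves data and truth sidecar", {
  s <- simulate_stream(demo_panel(), duration = 2000, arrival_rate = 0.003,
                       seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stream_csv(s, path)
  back <- read_stream_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(s), tolerance = 1e-12)
  expect_equal(as.data.frame(stream_truth(back)),
               as.data.frame(stream_truth(s)))
})
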