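test_that("jitter is seeded, exact at sigma zero, and chi-distributed", {
  cr <- cached("cr4430", build_cnc(4, 4, 30))
  expect_identical(jitter_crystal(cr, 0), cr)
  j1 <- jitter_crystal(cr, 0.02, seed = 9)
  j2 <- jitter_crystal(cr, 0.02, seed = 9)
  expect_identical(j1$atoms, j2$atoms)
  j3 <- jitter_crystal(cr, 0.02, seed = 10)
  expect_false(identical(j1$atoms, j3$atoms))
  expect_error(jitter_crystal(cr, -0.1), "non-negative")

  # RMSD of >= 1e4 atoms approaches sigma * sqrt(3)
  expect_gt(nrow(cr$atoms), 1e4)
  d <- as.matrix(j1$atoms[, c("x", "y", "z")]) -
       as.matrix(cr$atoms[, c("x", "y", "z")])
  rmsd <- sqrt(mean(rowSums(d^2)))
  expect_equal(rmsd, 0.02 * sqrt(3), tolerance = 0.05)
})

test_that("modified units receive the larger disorder scale", {
  m <- apply_dialcohol_modification(build_cnc(2, 2, 6), 0:1, "B")
  j <- jitter_crystal(m, 0.02, seed = 2)
  d <- sqrt(rowSums((as.matrix(j$atoms[, c("x", "y", "z")]) -
                     as.matrix(m$atoms[, c("x", "y", "z")]))^2))
  mod <- m$atoms$resname == "DAG"
  expect_gt(mean(d[mod]), 4 * mean(d[!mod]))
})

test_that("water placement is seeded, respects exclusions, and tracks density", {
  cr <- cached("cr2x2x6", build_cnc(2, 2, 6))
  w0 <- place_water_shell(cr, thickness = 0, seed = 1)
  expect_equal(attr(w0, "n_water"), 0L)

  w1 <- place_water_shell(cr, thickness = 0.5, density = 15, seed = 21)
  w1b <- place_water_shell(cr, thickness = 0.5, density = 15, seed = 21)
  expect_identical(w1$atoms, w1b$atoms)
  n1 <- attr(w1, "n_water")
  expect_gt(n1, 0)

  # every water oxygen at least 0.25 nm from any solute heavy atom
  a <- w1$atoms
  iw <- which(a$name == "OW")
  heavy <- which(a$resname != "SOL" & a$element != "H")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  dmin <- min(vapply(iw, function(i)
    min(sqrt(colSums((t(xyz[heavy, ]) - xyz[i, ])^2))), numeric(1)))
  expect_gte(dmin, 0.25)

  # count tracks density x accessible volume
  expect_equal(n1, 15 * attr(w1, "shell_volume"), tolerance = 0.1)
  w2 <- place_water_shell(cr, thickness = 0.5, density = 30, seed = 22)
  expect_equal(attr(w2, "n_water") / n1, 2, tolerance = 0.2)

  # infeasible density errors out after the attempt budget
  expect_error(place_water_shell(cr, thickness = 0.4, density = 500,
                                 seed = 1, max_attempts_factor = 3),
               "density too high")
})

test_that("synthetic traces reproduce their programmed ground truth exactly", {
  p <- synth_trace_params(noise_sd = 0)
  tr <- synth_force_trace(p)
  sc <- stress_curve(tr$curve)
  expect_equal(tau_max(sc)$tau_max, 120)
  expect_equal(tau_max(sc)$d_at_max, tr$truth$d_at_max)
  expect_equal(interfacial_stiffness(sc), 150, tolerance = 1e-9)
  expect_equal(nrow(stick_slip_events(sc)), 4)
  expect_equal(interaction_energy(tr$curve), tr$truth$energy,
               tolerance = 1e-9)

  # programmed decreasing peaks come out strictly decreasing
  ev <- stick_slip_events(sc)
  expect_true(all(diff(ev$tau_peak) < 0))
})

test_that("a zero-event trace is a ramp whose stiffness is the slope", {
  tr <- synth_force_trace(synth_trace_params(n_events = 0, peak_heights = NULL,
                                             noise_sd = 0, ramp_height = 80,
                                             slope = 120))
  sc <- stress_curve(tr$curve)
  expect_equal(nrow(stick_slip_events(sc)), 0)
  expect_message(st <- interfacial_stiffness(sc), "first 10%")
  expect_equal(st, 120, tolerance = 1e-9)
})

test_that("noisy traces are bitwise reproducible per seed", {
  t1 <- synth_force_trace(synth_trace_params(seed = 33))
  t2 <- synth_force_trace(synth_trace_params(seed = 33))
  expect_identical(t1$curve$force, t2$curve$force)
  t3 <- synth_force_trace(synth_trace_params(seed = 34))
  expect_false(identical(t1$curve$force, t3$curve$force))
})

test_that("trace parameters are validated", {
  expect_error(synth_trace_params(n_events = -1), "non-negative")
  expect_error(synth_trace_params(n_events = 2, peak_heights = c(10, 20, 30)),
               "length")
  expect_error(synth_trace_params(slope = 0), "positive")
  expect_error(synth_trace_params(spacing = -1), "increasing")
  expect_error(synth_trace_params(noise_sd = -1), "non-negative")
})
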