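test_that("XVG and CSV pull traces are parsed, converted and validated", {
  f <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("# comment", "@ title \"pull\"", "@ xaxis label \"t\"",
               "0.0 1.0", "0.5 2.0", "1.0 3.0", "1.5 2.5", "2.0 4.0"), f)
  fc <- read_pull_curve(f)
  expect_length(fc$d, 5)
  expect_equal(fc$force, c(1, 2, 3, 2.5, 4))

  # force-vs-time at 1 nm/ns: displacement equals time numerically
  ft <- read_pull_curve(f, abscissa = "time")
  expect_equal(ft$d, c(0, 0.5, 1, 1.5, 2))
  # ps time base scales by 1000
  fp <- read_pull_curve(f, abscissa = "time", time_unit = "ps")
  expect_equal(fp$d, c(0, 0.5, 1, 1.5, 2) / 1000)

  # duplicate abscissae collapse by averaging
  g <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("0 1", "0 3", "1 5"), g)
  fg <- read_pull_curve(g)
  expect_equal(fg$d, c(0, 1))
  expect_equal(fg$force, c(2, 5))

  # CSV round trip
  cs <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(d = fc$d, force = fc$force), cs, row.names = FALSE)
  fc2 <- read_pull_curve(cs)
  expect_equal(fc2$d, fc$d)
  expect_equal(fc2$force, fc$force)

  bad <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("@ legend", "0 1", "oops 2"), bad)
  expect_error(read_pull_curve(bad), "line 3")
  empty <- withr::local_tempfile(fileext = ".xvg")
  writeLines("# only comments", empty)
  expect_error(read_pull_curve(empty), "no data")
})

test_that("stress conversion divides by the contact area with exact units", {
  # 655 pN over the default 65.5 nm^2 is exactly 10 MPa
  fc <- force_curve(c(0, 1), c(655, 655),
                    shear_metadata(force_unit = "pN"))
  sc <- stress_curve(fc)
  expect_equal(sc$metadata$area, 65.5)
  expect_equal(sc$tau, c(10, 10))

  # zero force gives zero stress; scaling force scales stress linearly
  f0 <- force_curve(c(0, 1, 2), c(0, 0, 0))
  expect_equal(stress_curve(f0)$tau, c(0, 0, 0))
  f1 <- force_curve(c(0, 1, 2), c(10, 20, 30))
  f3 <- force_curve(c(0, 1, 2), 3 * c(10, 20, 30))
  expect_equal(stress_curve(f3)$tau, 3 * stress_curve(f1)$tau)

  md <- shear_metadata()
  md$area <- NA
  expect_error(stress_curve(force_curve(0:1, c(1, 2), md)), "area")
})

test_that("tau_max takes the global maximum with smallest-d tie-breaking", {
  ramp <- stress_curve(force_curve(0:10, 0:10))
  expect_equal(tau_max(ramp)$d_at_max, 10)
  zero <- stress_curve(force_curve(0:5, rep(0, 6)))
  expect_equal(tau_max(zero)$tau_max, 0)
  expect_equal(tau_max(zero)$d_at_max, 0)
  ties <- stress_curve(force_curve(0:4, c(1, 5, 2, 5, 1)))
  expect_equal(tau_max(ties)$d_at_max, 1)
})

test_that("stiffness fits the pre-peak window and degenerates gracefully", {
  d <- seq(0, 2, by = 0.01)
  line <- stress_curve(force_curve(d, 50 * d, shear_metadata(area = 1,
                                                             force_unit = "pN")))
  expect_message(st <- interfacial_stiffness(line), "first 10%")
  expect_equal(st, 50, tolerance = 1e-9)

  const <- stress_curve(force_curve(d, rep(2, length(d)),
                                    shear_metadata(force_unit = "pN")))
  expect_message(sc <- interfacial_stiffness(const), "first 10%")
  expect_equal(sc, 0, tolerance = 1e-9)
})

test_that("stick-slip detection counts programmed teeth and ignores ramps", {
  tr <- synth_force_trace(synth_trace_params(noise_sd = 0))
  sc <- stress_curve(tr$curve)
  ev <- stick_slip_events(sc)
  expect_equal(nrow(ev), 4)
  expect_equal(ev$tau_peak, c(120, 100, 90, 80))
  expect_equal(ev$drop, c(120, 100, 90, 80), tolerance = 1e-9)

  ramp <- stress_curve(force_curve(0:100, 0:100))
  expect_equal(nrow(stick_slip_events(ramp)), 0)

  # event count invariant to a uniform displacement offset
  sh <- sc
  sh$d <- sh$d + 5
  expect_equal(nrow(stick_slip_events(sh)), 4)
})

test_that("interaction energy integrates force with additive ranges", {
  z <- force_curve(seq(0, 1, 0.1), rep(0, 11))
  expect_equal(interaction_energy(z), 0)

  # triangular pulse of height h over width w integrates to h*w/2
  d <- seq(0, 2, by = 0.001)
  h <- 40
  f <- ifelse(d < 0.5 | d > 1.5, 0, h * (1 - abs(d - 1) / 0.5))
  fc <- force_curve(d, f)
  expect_equal(interaction_energy(fc), h * 1 / 2, tolerance = 1e-6)

  # additivity at an arbitrary interior split
  for (s in c(0.3, 1.0, 1.27)) {
    e1 <- interaction_energy(fc, c(0, s))
    e2 <- interaction_energy(fc, c(s, 2))
    expect_equal(e1 + e2, interaction_energy(fc), tolerance = 1e-9)
  }
  expect_error(interaction_energy(fc, c(1, 0.5)), "inverted")
  expect_error(interaction_energy(fc, c(-1, 1)), "span")

  # resampling on a 2x finer grid changes the integral by < 1%
  d2 <- seq(0, 2, by = 0.0005)
  fc2 <- force_curve(d2, stats::approx(d, f, d2)$y)
  expect_equal(interaction_energy(fc2), interaction_energy(fc),
               tolerance = 0.01)
})

test_that("the pipeline is linear in the input force", {
  tr <- synth_force_trace(synth_trace_params(noise_sd = 0))
  fc <- tr$curve
  fc3 <- force_curve(fc$d, 3 * fc$force, fc$metadata)
  s1 <- stress_curve(fc); s3 <- stress_curve(fc3)
  expect_equal(tau_max(s3)$tau_max, 3 * tau_max(s1)$tau_max)
  expect_equal(interfacial_stiffness(s3), 3 * interfacial_stiffness(s1),
               tolerance = 1e-9)
  expect_equal(interaction_energy(fc3), 3 * interaction_energy(fc),
               tolerance = 1e-9)
})

test_that("run labels parse into metadata", {
  md <- parse_run_label("Ax_3@25")
  expect_equal(md$direction, "axial")
  expect_equal(md$separation, 3)
  expect_equal(md$temperature, 25)
  md2 <- parse_run_label("Tr_8@100")
  expect_equal(md2$direction, "transverse")
  expect_equal(md2$separation, 8)
  expect_error(parse_run_label("Zz_1@5"), "cannot parse")
})
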