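test_that("interchain RDF equals a brute-force all-pairs oracle", {
  cr <- cached("cr334", build_cnc(3, 3, 4))
  for (pc in c("C-O", "C-H", "O-H")) {
    prof <- interchain_rdf(cr, pc, r_max = 2, bin_width = 0.01)
    counts <- brute_rdf_counts(cr, pc, r_max = 2, bin_width = 0.01)
    g_ref <- counts / (prof$n_ref * 4 * pi * prof$r^2 * 0.01 * prof$rho)
    expect_equal(prof$g, g_ref, tolerance = 1e-10)
  }
})

test_that("a single isolated chain has identically zero interchain RDF", {
  cr <- build_cnc(1, 1, 4)
  prof <- interchain_rdf(cr, "C-O", r_max = 2, bin_width = 0.01)
  expect_true(all(prof$g == 0))
})

test_that("a single interchain pair occupies one analytically normalized bin", {
  d <- 0.299  # bin center for bin_width 0.002
  fr <- make_frame(c("C1", "O1"), c("C", "O"), "GLC", c(0, 1), c(0, 0),
                   rbind(c(0, 0, 0), c(d, 0, 0)))
  V <- 50
  prof <- interchain_rdf(fr, "C-O", r_max = 1, bin_width = 0.002, volume = V)
  occ <- which(prof$g > 0)
  expect_length(occ, 1)
  expect_equal(prof$r[occ], d, tolerance = 1e-9)
  # one pair: g = V / (4 pi d^2 dr)
  expect_equal(prof$g[occ], V / (4 * pi * d^2 * 0.002), tolerance = 1e-9)
})

test_that("RDF inputs are validated", {
  cr <- build_cnc(1, 1, 2)
  expect_error(interchain_rdf(cr, "N-O"), "unknown pair_class")
  expect_error(interchain_rdf(cr, "C-O", bin_width = 0), "bin_width")
})

test_that("two-atom S(q) matches the Debye closed form", {
  d <- 0.299
  fr <- make_frame(c("C1", "O1"), c("C", "O"), "GLC", c(0, 1), c(0, 0),
                   rbind(c(0, 0, 0), c(d, 0, 0)))
  prof <- interchain_rdf(fr, "C-O", r_max = 1, bin_width = 0.002,
                         volume = 1e5)
  sq <- structure_factor(prof, window = "none")
  expect_equal(sq$S, 1 + sin(sq$q * d) / (sq$q * d), tolerance = 1e-3)
})

test_that("an ideal-gas RDF gives S(q) identically one", {
  prof <- structure(list(pair_class = "C-O",
                         r = seq(0.001, 2.999, by = 0.002), g = 1,
                         rho = 30, r_max = 3, bin_width = 0.002),
                    class = "rdf_profile")
  prof$g <- rep(1, length(prof$r))
  sq <- structure_factor(prof)
  expect_equal(sq$S, rep(1, length(sq$q)), tolerance = 1e-12)
})

test_that("structure_factor rejects mismatched r grids", {
  cr <- build_cnc(2, 1, 2)
  p1 <- interchain_rdf(cr, "C-O", r_max = 2, bin_width = 0.01)
  p2 <- interchain_rdf(cr, "O-H", r_max = 2, bin_width = 0.02)
  expect_error(structure_factor(list(p1, p2)), "mismatched r grids")
  expect_error(structure_factor(list(p1, p1), weights = 1), "one weight")
})

test_that("find_peaks recovers programmed Gaussian centers and refines positions", {
  q <- seq(0, 30, by = 0.05)
  y <- exp(-(q - 10.02)^2 / (2 * 0.5^2)) + 0.6 * exp(-(q - 20.51)^2 / (2 * 2))
  pk <- find_peaks(list(x = q, y = y), min_prominence = 0.1)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$position, c(10.02, 20.51), tolerance = 0.05)
  expect_true(all(diff(pk$height) <= 0))  # sorted by descending height

  flat <- find_peaks(list(x = q, y = rep(1, length(q))), min_prominence = 0.01)
  expect_equal(nrow(flat), 0)
})

test_that("S(q) is invariant under rigid motion and insensitive to class weights", {
  cr <- cached("cr338", build_cnc(3, 3, 8))
  jf <- jitter_crystal(cr, 0.02, seed = 4)
  rot <- rigid_motion(jf)
  sq_of <- function(fr, w = NULL) {
    rdfs <- lapply(c("C-O", "C-H", "O-H"), function(pc)
      interchain_rdf(fr, pc, volume = 100))
    structure_factor(rdfs, weights = w)
  }
  s1 <- sq_of(jf)
  s2 <- sq_of(rot)
  expect_equal(s1$S, s2$S, tolerance = 1e-9)

  # the (200) peak position is insensitive to the component weighting
  # (checked on the full crystal, whose reflection is sharp)
  rdfs <- full_crystal_rdfs()
  peak200 <- function(sq) {
    win <- sq_window(sq, 14.5, 18)
    find_peaks(win, min_prominence = 0)$position[1]
  }
  p_equal <- peak200(structure_factor(rdfs))
  p_xray <- peak200(structure_factor(rdfs, weights = c(2, 1, 0.5)))
  expect_lt(abs(p_equal - p_xray), 0.3)
})

test_that("built-crystal peak positions shift little under coordinate jitter", {
  cr <- cached("cr338", build_cnc(3, 3, 8))
  pos <- vapply(c(5, 6), function(s) {
    jf <- jitter_crystal(cr, 0.02, seed = s)
    rdfs <- lapply(c("C-O", "C-H", "O-H"), function(pc) interchain_rdf(jf, pc))
    sq <- structure_factor(rdfs)
    find_peaks(sq_window(sq, 14.5, 18), min_prominence = 0)$position[1]
  }, numeric(1))
  expect_lt(abs(pos[1] - pos[2]), 0.3)
  # and the unjittered crystal agrees too
  rdfs <- lapply(c("C-O", "C-H", "O-H"), function(pc) interchain_rdf(cr, pc))
  p0 <- find_peaks(sq_window(structure_factor(rdfs), 14.5, 18),
                   min_prominence = 0)$position[1]
  expect_lt(abs(p0 - pos[1]), 0.3)
})
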