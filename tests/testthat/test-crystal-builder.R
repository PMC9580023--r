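test_that("build_cnc validates its arguments and counts atoms correctly", {
  expect_error(build_cnc(1, 1, 3), "cellobiose")
  expect_error(build_cnc(1, 1, 0), "even")
  expect_error(build_cnc(0, 1, 2), "positive")
  expect_error(build_cnc(-2, 3, 4), "positive")

  cr <- build_cnc(1, 1, 2)
  # 21 atoms per glucose unit plus 3 cap atoms (HO4, O1, HO1)
  expect_equal(nrow(cr$atoms), 2 * 21 + 3)
  expect_equal(nrow(cr$chains), 1)
  expect_setequal(unique(cr$atoms$element), c("C", "O", "H"))

  cr2 <- build_cnc(3, 2, 4)
  expect_equal(nrow(cr2$chains), 6)
  expect_equal(nrow(cr2$units), 6 * 4)
  expect_equal(nrow(cr2$atoms), 6 * (4 * 21 + 3))
  expect_false(any(cr2$units$modified))
  # every atom belongs to exactly one (chain, unit)
  expect_equal(nrow(unique(cr2$atoms[, c("chain_id", "unit")])), 24)
})

test_that("chain geometry carries the two-fold screw and the I-beta lattice", {
  cr <- build_cnc(1, 1, 4)
  a <- cr$atoms
  get <- function(u, nm) unlist(a[a$unit == u & a$name == nm, c("x", "y", "z")])
  # consecutive glucose O4 atoms are c/2 apart along the chain axis
  dz <- unname(get(1, "O4")[3] - get(0, "O4")[3])
  expect_equal(dz, 1.038 / 2, tolerance = 1e-6)
  # glycosidic bond C1(k)-O4(k+1) has a covalent length
  d <- sqrt(sum((get(0, "C1") - get(1, "O4"))^2))
  expect_gt(d, 0.13)
  expect_lt(d, 0.15)
  # screw symmetry: unit 2 is unit 0 translated by c
  expect_equal(unname(get(2, "C1") - get(0, "C1")), c(0, 0, 1.038),
               tolerance = 1e-6)
})

test_that("chain classification labels layers and side vs top/bottom roles", {
  c1 <- classify_chains(build_cnc(1, 1, 2))
  expect_equal(c1$layer, 1L)

  c5 <- classify_chains(build_cnc(5, 5, 2))
  expect_equal(sum(c5$layer == 1), 16)  # perimeter of a 5x5 grid

  c7 <- classify_chains(full_crystal())
  expect_equal(sum(c7$layer == 1), 24)
  expect_equal(sum(c7$layer == 1 & c7$position == "side"), 22)
  expect_equal(sum(c7$layer == 1 & c7$position == "top/bottom"), 2)
  expect_equal(sum(c7$layer == 2), 16)
  expect_equal(sum(c7$layer == 2 & c7$position == "top/bottom"), 2)
  expect_true(all(c7$role[c7$layer > 1] == "core"))
})

test_that("dialcohol modification keeps exact atom and bond bookkeeping", {
  cr <- build_cnc(2, 2, 4)
  n0 <- nrow(cr$atoms)
  b0 <- nrow(cr$bonds)
  el0 <- table(cr$atoms$element)

  m <- apply_dialcohol_modification(cr, 0, "A", phase = 0)
  expect_equal(sum(m$units$modified), 2)            # units 0 and 2
  expect_equal(nrow(m$atoms), n0 + 2 * 2)           # +2 H per modified unit
  expect_equal(nrow(m$bonds), b0 - 2 + 4)           # -1 bond, +2 bonds per unit
  el1 <- table(m$atoms$element)
  expect_equal(el1[["H"]], el0[["H"]] + 4)
  expect_equal(el1[["C"]], el0[["C"]])
  expect_equal(el1[["O"]], el0[["O"]])

  # modified units have no C2-C3 bond, unmodified keep theirs
  has_c2c3 <- function(cr, ch, un) {
    a <- cr$atoms
    i2 <- which(a$chain_id == ch & a$unit == un & a$name == "C2")
    i3 <- which(a$chain_id == ch & a$unit == un & a$name == "C3")
    any((cr$bonds[, 1] == i2 & cr$bonds[, 2] == i3) |
        (cr$bonds[, 1] == i3 & cr$bonds[, 2] == i2))
  }
  expect_false(has_c2c3(m, 0, 0))
  expect_true(has_c2c3(m, 0, 1))
  expect_true(has_c2c3(m, 1, 0))
  expect_equal(unique(m$atoms$resname[m$atoms$chain_id == 0 & m$atoms$unit == 0]),
               "DAG")

  # idempotence: re-application is a no-op
  m2 <- apply_dialcohol_modification(m, 0, "A", phase = 0)
  expect_identical(m2$atoms, m$atoms)
  expect_equal(compute_dom(m2), compute_dom(m))

  # phase selects the complementary alternate units
  mp <- apply_dialcohol_modification(cr, 0, "A", phase = 1)
  expect_equal(mp$units$unit[mp$units$modified], c(1, 3))

  expect_warning(apply_dialcohol_modification(cr, integer()), "empty")
  expect_error(apply_dialcohol_modification(cr, 99), "unknown chain")
})

test_that("compute_dom is monotone under additional modification", {
  cr <- build_cnc(2, 2, 4)
  expect_equal(compute_dom(cr), 0)
  d <- compute_dom(cr)
  for (ch in 0:3) {
    cr <- apply_dialcohol_modification(cr, ch, "A")
    expect_gte(compute_dom(cr), d)
    d <- compute_dom(cr)
  }
  cr <- apply_dialcohol_modification(cr, 0:3, "B")
  expect_equal(compute_dom(cr), 1)
})

test_that("standard DoM recipes flag the documented unit counts", {
  expect_error(make_standard_dom(2, 2, 4, 50), "supported labels")

  m0 <- make_standard_dom(7, 7, 40, 0)
  expect_equal(compute_dom(m0), 0)
  expect_identical(m0$atoms, full_crystal()$atoms)

  m25 <- cached("dom25", make_standard_dom(7, 7, 40, 25))
  expect_equal(sum(m25$units$modified), 520)  # 22 x 20 + 2 x 40
  expect_equal(compute_dom(m25), 520 / 1960)
  # only layer-1 chains touched
  cls <- classify_chains(m25)
  touched <- unique(m25$units$chain_id[m25$units$modified])
  expect_setequal(touched, cls$chain_id[cls$layer == 1])

  m40 <- cached("dom40", make_standard_dom(7, 7, 40, 40))
  expect_equal(sum(m40$units$modified), 520 + 14 * 20 + 2 * 40)

  mB <- make_standard_dom(7, 7, 40, 40, variant = "surface_B")
  expect_equal(sum(mB$units$modified), 24 * 40)

  m100 <- cached("dom100", make_standard_dom(7, 7, 40, 100))
  expect_equal(compute_dom(m100), 1)
})

test_that("measured dimensions are invariant under rigid motion", {
  cr <- build_cnc(2, 2, 6)
  d_nom <- measure_dimensions(cr)
  d_ext <- measure_dimensions(cr, "extent")
  moved <- cr
  rot <- rigid_motion(cr)
  moved$atoms <- rot$atoms
  expect_identical(measure_dimensions(moved), d_nom)
  expect_equal(measure_dimensions(moved, "extent"), d_ext, tolerance = 1e-6)
})
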