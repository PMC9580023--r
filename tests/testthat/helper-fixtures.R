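# Shared fixtures. Heavy objects (full-size crystals) are cached per test
# session so several test files can reuse one build.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

full_crystal <- function() cached("cr7740", build_cnc(7, 7, 40))

# A minimal hand-made frame from raw atom records.
make_frame <- function(name, element, resname, chain_id, unit, xyz,
                       bonds = NULL) {
  fr <- structure(list(
    atoms = data.frame(name = name, element = element, resname = resname,
                       chain_id = chain_id, unit = unit,
                       ord = seq_along(name),
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       stringsAsFactors = FALSE),
    bonds = bonds), class = "cnc_frame")
  fr$box <- apply(as.matrix(fr$atoms[, c("x", "y", "z")]), 2,
                  function(v) diff(range(v)))
  fr
}

# Two water molecules: the first donates an aligned O-H...O bond to the
# second when d_oo is within the cutoff.
two_waters <- function(d_oo = 0.28) {
  xyz <- rbind(
    c(0, 0, 0),                    # OW  (donor)
    c(0.0957, 0, 0),               # HW1 aimed at the acceptor
    c(-0.024, 0.093, 0),           # HW2
    c(d_oo, 0, 0),                 # OW' (acceptor)
    c(d_oo + 0.024, 0.093, 0),     # HW1'
    c(d_oo + 0.024, -0.093, 0))    # HW2'
  make_frame(rep(c("OW", "HW1", "HW2"), 2), rep(c("O", "H", "H"), 2),
             "SOL", c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 1, 1, 1), xyz)
}

# Rigidly rotate + translate every atom of a frame.
rigid_motion <- function(frame, axis = c(1, 2, 3), angle = 0.7,
                         shift = c(1, -2, 3)) {
  R <- dacnc:::.rotmat(axis / sqrt(sum(axis^2)) * angle)
  xyz <- as.matrix(frame$atoms[, c("x", "y", "z")])
  frame$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, shift, `+`)
  frame$box <- apply(as.matrix(frame$atoms[, c("x", "y", "z")]), 2,
                     function(v) diff(range(v)))
  frame
}

# Brute-force interchain pair histogram (O(N^2) oracle).
brute_rdf_counts <- function(frame, pair_class, r_max, bin_width) {
  el <- list("C-O" = c("C", "O"), "C-H" = c("C", "H"),
             "O-H" = c("O", "H"))[[pair_class]]
  a <- frame$atoms
  ia <- which(a$element == el[1])
  ib <- which(a$element == el[2])
  xyz <- as.matrix(a[, c("x", "y", "z")])
  nb <- ceiling(r_max / bin_width)
  counts <- numeric(nb)
  for (i in ia) {
    d <- sqrt(colSums((t(xyz[ib, , drop = FALSE]) - xyz[i, ])^2))
    ok <- a$chain_id[ib] != a$chain_id[i] & d > 1e-6 & d < r_max
    if (any(ok))
      counts <- counts + tabulate(pmin(floor(d[ok] / bin_width) + 1, nb),
                                  nbins = nb)
  }
  counts
}

sq_window <- function(sq, lo = 8, hi = 25) {
  sel <- sq$q >= lo & sq$q <= hi
  list(q = sq$q[sel], S = sq$S[sel])
}

# Full three-class interchain RDFs / S(q) of a crystal jittered at the
# default scales.
crystal_rdfs <- function(crystal, seed = 11, sigma = 0.02) {
  jf <- jitter_crystal(crystal, sigma, seed = seed)
  lapply(c("C-O", "C-H", "O-H"), function(pc) interchain_rdf(jf, pc))
}

crystal_sq <- function(crystal, seed = 11, sigma = 0.02) {
  structure_factor(crystal_rdfs(crystal, seed, sigma))
}

full_crystal_rdfs <- function() {
  cached("rdfs_dom0", crystal_rdfs(full_crystal()))
}
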