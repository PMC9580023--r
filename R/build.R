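# Nanocrystal construction and dialcohol modification.
#
# A crystal is a `cnc_crystal` (which is also a `cnc_frame`): a list with
#   atoms   data.frame(name, element, resname, chain_id, unit, ord, x, y, z)
#           coordinates in nm; chain_id and unit are 0-based
#   bonds   2-column integer matrix of row indices into atoms
#   units   data.frame(chain_id, unit, modified)
#   chains  data.frame(chain_id, i, j)  grid position of each chain
#   nx, ny, n_units, lattice, box
# Atom order within a glucose unit is stable (`ord`); writers sort on
# (chain_id, unit, ord) so residue blocks stay contiguous in files.

.ATOM_ORDER <- c("C1", "C2", "C3", "C4", "C5", "C6", "O2", "O3", "O4", "O5",
                 "O6", "H1", "H2", "H3", "H4", "H5", "H61", "H62",
                 "HO2", "HO3", "HO6", "HO4", "O1", "HO1", "H2B", "H3B")

.element_of <- function(name) substr(sub("^([A-Za-z]).*", "\\1", name), 1, 1)

# Single chain at the lattice origin, Angstrom coordinates.
# Returns atoms (data.frame with local row order) and local bond list.
.build_chain <- function(n_units) {
  tmpl <- .chain_template()$xyz
  tn <- rownames(tmpl)
  per <- lapply(0:(n_units - 1), function(k) .screw(tmpl, k))
  virt_prev <- .screw(tmpl, -1)        # residue -1 (for the HO4 cap)
  virt_next <- .screw(tmpl, n_units)   # residue n (for the reducing-end cap)

  rows <- vector("list", n_units)
  for (k in seq_len(n_units) - 1) {
    x <- per[[k + 1]]
    # hydroxyl hydrogens: O3-H donates to O5 of the previous residue
    # (canonical intrachain bond); O2-H is left at a trans torsion
    # (the O2/O6 network is orientationally disordered in I-beta);
    # O6-H gets a placeholder here and is re-aimed in crystal context.
    acc3 <- if (k > 0) per[[k]]["O5", ] else NULL
    HO3 <- if (is.null(acc3))
      .place_atom(x["C2", ], x["C3", ], x["O3", ], 0.97, 108, 180)
    else
      as.numeric(.place_h_toward(x["O3", ], x["C3", ], acc3, bond = 0.97))
    HO2 <- .place_atom(x["C1", ], x["C2", ], x["O2", ], 0.97, 108, 180)
    HO6 <- .place_atom(x["C5", ], x["C6", ], x["O6", ], 0.97, 108, 180)
    xx <- rbind(x, HO2 = HO2, HO3 = HO3, HO6 = HO6)
    if (k == 0) {
      # non-reducing end: the free O4 is capped where C1 of residue -1 sat
      HO4 <- as.numeric(.place_h_toward(x["O4", ], x["C4", ],
                                        virt_prev["C1", ], bond = 0.97))
      xx <- rbind(xx, HO4 = HO4)
    }
    if (k == n_units - 1) {
      # reducing end: O1 takes the crystallographic position of O4 of the
      # (absent) next residue, so the cap stays inside the chain envelope
      O1 <- virt_next["O4", ]
      HO1 <- as.numeric(.place_h_toward(O1, x["C1", ], virt_next["C4", ],
                                        bond = 0.97))
      xx <- rbind(xx, O1 = O1, HO1 = HO1)
    }
    nm <- rownames(xx)
    o <- match(nm, .ATOM_ORDER)
    xx <- xx[order(o), , drop = FALSE]
    rows[[k + 1]] <- data.frame(name = rownames(xx), unit = k,
                                x = xx[, 1], y = xx[, 2], z = xx[, 3],
                                stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  atoms$ord <- match(atoms$name, .ATOM_ORDER)

  key <- paste(atoms$unit, atoms$name)
  aidx <- function(u, nm) match(paste(u, nm), key)
  rb <- .residue_bonds()
  bl <- list()
  for (k in 0:(n_units - 1)) {
    b <- cbind(aidx(k, rb[, 1]), aidx(k, rb[, 2]))
    bl[[length(bl) + 1]] <- b
    if (k < n_units - 1)
      bl[[length(bl) + 1]] <- cbind(aidx(k, "C1"), aidx(k + 1, "O4"))
  }
  bl[[length(bl) + 1]] <- rbind(
    c(aidx(0, "O4"), aidx(0, "HO4")),
    c(aidx(n_units - 1, "C1"), aidx(n_units - 1, "O1")),
    c(aidx(n_units - 1, "O1"), aidx(n_units - 1, "HO1")))
  bonds <- do.call(rbind, bl)
  stopifnot(!anyNA(bonds))
  list(atoms = atoms, bonds = bonds)
}

#' Build an unmodified cellulose I-beta nanocrystal
#'
#' Constructs an `nx` x `ny` grid of parallel cellulose chains on the
#' I-beta chain lattice (grid vectors `u = (a+b)/2`, `v = (a-b)/2` of the
#' monoclinic cell), each chain `n_units` glucose units long with the
#' two-fold screw symmetry of the chain axis. Chain ends are capped with
#' hydroxyls (O4-H at the non-reducing end, O1-H at the reducing end).
#' Chains on alternating grid diagonals are staggered by c/4 along the
#' chain axis, reproducing the inter-sheet stagger of I-beta.
#'
#' @param nx,ny Chains per cross-section axis (positive integers).
#' @param n_units Glucose units per chain; must be even, because the
#'   crystallographic repeat along the chain is one cellobiose (two units).
#' @return A `cnc_crystal` object (also a `cnc_frame`).
#' @examples
#' cr <- build_cnc(2, 2, 4)
#' compute_dom(cr)
#' @export
build_cnc <- function(nx, ny, n_units) {
  if (length(nx) != 1 || length(ny) != 1 || nx < 1 || ny < 1 ||
      nx != round(nx) || ny != round(ny))
    stop("nx and ny must be positive integers")
  if (length(n_units) != 1 || n_units < 2 || n_units != round(n_units))
    stop("n_units must be a positive even integer")
  if (n_units %% 2 != 0)
    stop("n_units must be even: the chain repeat is one cellobiose ",
         "(two glucose units), so chains are built in whole cellobiose repeats")

  ch <- .build_chain(n_units)
  vecs <- .ibeta_vectors()
  nat <- nrow(ch$atoms)
  n_chain <- nx * ny

  grid <- expand.grid(j = 0:(ny - 1), i = 0:(nx - 1))[, c("i", "j")]
  grid <- grid[order(grid$i, grid$j), ]
  chains <- data.frame(chain_id = 0:(n_chain - 1), i = grid$i, j = grid$j)

  xyz1 <- as.matrix(ch$atoms[, c("x", "y", "z")])
  off <- t(vapply(seq_len(n_chain), function(r) {
    i <- chains$i[r]; j <- chains$j[r]
    i * vecs$u + j * vecs$v +
      c(0, 0, if ((i + j) %% 2 == 1) .ibeta$stagger_frac * .ibeta$c else 0)
  }, numeric(3)))
  xyz <- matrix(0, nat * n_chain, 3)
  for (r in seq_len(n_chain))
    xyz[((r - 1) * nat + 1):(r * nat), ] <- sweep(xyz1, 2, off[r, ], `+`)

  atoms <- data.frame(
    name = rep(ch$atoms$name, n_chain),
    element = rep(.element_of(ch$atoms$name), n_chain),
    resname = "GLC",
    chain_id = rep(0:(n_chain - 1), each = nat),
    unit = rep(ch$atoms$unit, n_chain),
    ord = rep(ch$atoms$ord, n_chain),
    x = xyz[, 1] / 10, y = xyz[, 2] / 10, z = xyz[, 3] / 10,
    stringsAsFactors = FALSE)

  bonds <- do.call(rbind, lapply(seq_len(n_chain) - 1L,
                                 function(r) ch$bonds + r * nat))

  cr <- structure(
    list(atoms = atoms, bonds = bonds,
         units = data.frame(chain_id = rep(0:(n_chain - 1), each = n_units),
                            unit = rep(0:(n_units - 1), n_chain),
                            modified = FALSE),
         chains = chains, nx = nx, ny = ny, n_units = n_units,
         lattice = list(a = .ibeta$a / 10, b = .ibeta$b / 10,
                        c = .ibeta$c / 10, gamma = .ibeta$gamma,
                        u = vecs$u / 10, v = vecs$v / 10,
                        stagger = .ibeta$stagger_frac * .ibeta$c / 10)),
    class = c("cnc_crystal", "cnc_frame"))
  cr <- .aim_surface_hydroxyls(cr)
  cr$box <- .frame_box(cr)
  cr
}

# Re-aim every O6-H at its nearest interchain O3 (the canonical intrasheet
# acceptor) where one exists within 0.36 nm; chains without a neighbour on
# that side keep the trans default.
.aim_surface_hydroxyls <- function(cr) {
  a <- cr$atoms
  io6 <- which(a$name == "O6")
  io3 <- which(a$name == "O3")
  ic6 <- which(a$name == "C6")
  ih6 <- which(a$name == "HO6")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  np <- neighbor_pairs_cpp(xyz[io6, , drop = FALSE], xyz[io3, , drop = FALSE], 0.36)
  if (length(np$i)) {
    keep <- a$chain_id[io6[np$i]] != a$chain_id[io3[np$j]]
    if (any(keep)) {
      np <- lapply(np, `[`, keep)
      best <- tapply(seq_along(np$i), np$i, function(s) s[which.min(np$d[s])])
      sel <- as.integer(names(best))   # index into io6
      acc <- io3[np$j[unlist(best)]]
      newH <- .place_h_toward(xyz[io6[sel], , drop = FALSE],
                              xyz[ic6[sel], , drop = FALSE],
                              xyz[acc, , drop = FALSE], bond = 0.097)
      cr$atoms[ih6[sel], c("x", "y", "z")] <- newH
    }
  }
  cr
}

.frame_box <- function(frame) {
  xyz <- as.matrix(frame$atoms[, c("x", "y", "z")])
  apply(xyz, 2, function(v) diff(range(v)))
}

#' Classify chains into surface layers and side/top-bottom roles
#'
#' Layers are concentric rings of the chain grid (layer 1 = perimeter).
#' Within each layer, the two chains at the extremes of the sheet-stacking
#' diagonal (the (200) normal) are labelled `"top/bottom"`; the rest are
#' `"side"`. For the 7x7 crystal this reproduces the 22 side + 2 top/bottom
#' split of the outermost layer. The `role` column reports
#' `"side-surface"`/`"top/bottom-surface"` for layer-1 chains and `"core"`
#' for interior chains.
#'
#' @param crystal A `cnc_crystal`.
#' @return data.frame with columns chain_id, i, j, layer, position, role.
#' @export
classify_chains <- function(crystal) {
  stopifnot(inherits(crystal, "cnc_crystal"))
  ch <- crystal$chains
  nx <- crystal$nx; ny <- crystal$ny
  ring <- pmin(ch$i, ch$j, nx - 1 - ch$i, ny - 1 - ch$j)
  s <- ch$i + ch$j
  position <- rep("side", nrow(ch))
  for (r in unique(ring)) {
    in_r <- which(ring == r)
    if (length(in_r) < 3) next
    lo <- in_r[which(s[in_r] == min(s[in_r]))]
    hi <- in_r[which(s[in_r] == max(s[in_r]))]
    if (length(lo) == 1 && length(hi) == 1) position[c(lo, hi)] <- "top/bottom"
  }
  layer <- ring + 1L
  data.frame(chain_id = ch$chain_id, i = ch$i, j = ch$j,
             layer = layer, position = position,
             role = ifelse(layer == 1L, paste0(position, "-surface"), "core"),
             stringsAsFactors = FALSE)
}

#' Apply dialcohol (C2-C3 cleavage) modification to selected chains
#'
#' In each selected chain, glucose units matching the pattern have their
#' C2-C3 bond removed and one hydrogen added to each of C2 and C3 at the
#' ideal tetrahedral completion of the remaining substituents (no geometry
#' relaxation is performed; ring re-opening is left to a simulation
#' engine). Modified units are renamed `DAG`; re-application is a no-op.
#'
#' @param crystal A `cnc_crystal`.
#' @param chain_ids Integer chain ids (0-based) to modify.
#' @param pattern `"A"` (every second unit along the chain) or `"B"` (all
#'   units).
#' @param phase For pattern A, which alternate set reacts: units with
#'   `unit %% 2 == phase` (default 0).
#' @return The modified `cnc_crystal`.
#' @export
apply_dialcohol_modification <- function(crystal, chain_ids,
                                         pattern = c("A", "B"), phase = 0) {
  stopifnot(inherits(crystal, "cnc_crystal"))
  pattern <- match.arg(pattern)
  if (!phase %in% c(0, 1)) stop("phase must be 0 or 1")
  if (length(chain_ids) == 0) {
    warning("empty chain selection: crystal returned unchanged")
    return(crystal)
  }
  unknown <- setdiff(chain_ids, crystal$chains$chain_id)
  if (length(unknown))
    stop("unknown chain id(s): ", paste(unknown, collapse = ", "))

  u <- crystal$units
  sel <- u$chain_id %in% chain_ids
  if (pattern == "A") sel <- sel & (u$unit %% 2 == phase)
  todo <- which(sel & !u$modified)
  if (!length(todo)) return(crystal)

  a <- crystal$atoms
  key <- paste(a$chain_id, a$unit, a$name)
  gidx <- function(ch, un, nm) match(paste(ch, un, nm), key)
  tc <- u$chain_id[todo]; tu <- u$unit[todo]
  iC1 <- gidx(tc, tu, "C1"); iC2 <- gidx(tc, tu, "C2")
  iC3 <- gidx(tc, tu, "C3"); iC4 <- gidx(tc, tu, "C4")
  iO2 <- gidx(tc, tu, "O2"); iO3 <- gidx(tc, tu, "O3")
  iH2 <- gidx(tc, tu, "H2"); iH3 <- gidx(tc, tu, "H3")
  xyz <- as.matrix(a[, c("x", "y", "z")])

  tet_dir <- function(center, n1, n2, n3) {
    s <- .vunit(xyz[n1, , drop = FALSE] - xyz[center, , drop = FALSE]) +
         .vunit(xyz[n2, , drop = FALSE] - xyz[center, , drop = FALSE]) +
         .vunit(xyz[n3, , drop = FALSE] - xyz[center, , drop = FALSE])
    -.vunit(s)
  }
  H2B <- xyz[iC2, , drop = FALSE] + 0.110 * tet_dir(iC2, iC1, iO2, iH2)
  H3B <- xyz[iC3, , drop = FALSE] + 0.110 * tet_dir(iC3, iC4, iO3, iH3)

  new_atoms <- data.frame(
    name = rep(c("H2B", "H3B"), each = length(todo)),
    element = "H", resname = "DAG",
    chain_id = rep(tc, 2), unit = rep(tu, 2),
    ord = rep(match(c("H2B", "H3B"), .ATOM_ORDER), each = length(todo)),
    x = c(H2B[, 1], H3B[, 1]), y = c(H2B[, 2], H3B[, 2]),
    z = c(H2B[, 3], H3B[, 3]), stringsAsFactors = FALSE)

  # drop the C2-C3 bond of each newly modified unit
  b <- crystal$bonds
  drop <- (b[, 1] %in% iC2 & b[, 2] %in% iC3) |
          (b[, 1] %in% iC3 & b[, 2] %in% iC2)
  # restrict to same-unit pairs (C2/C3 indices are unit-specific already)
  b <- b[!drop, , drop = FALSE]
  n0 <- nrow(a)
  add <- rbind(cbind(iC2, n0 + seq_along(todo)),
               cbind(iC3, n0 + length(todo) + seq_along(todo)))
  crystal$atoms <- rbind(a, new_atoms)
  mod_sel <- paste(crystal$atoms$chain_id, crystal$atoms$unit) %in% paste(tc, tu)
  crystal$atoms$resname[mod_sel] <- "DAG"
  crystal$bonds <- rbind(b, add)
  dimnames(crystal$bonds) <- NULL
  crystal$units$modified[todo] <- TRUE
  crystal$box <- .frame_box(crystal)
  crystal
}

#' Build a nanocrystal with one of the standard modification recipes
#'
#' Recipe labels follow the source modification series: `0` (native), `25`
#' (outermost layer: side chains pattern A, top/bottom chains pattern B),
#' `40` (same recipe applied to layers 1 and 2), and `100` (pattern B
#' everywhere). `variant = "surface_B"` gives the control recipe in which
#' every C2-C3 bond of the outermost layer is modified (pattern B) and
#' layer 2 is untouched. Labels are recipe names; the exact modified
#' fraction is reported by [compute_dom()] (e.g. the `25` recipe flags
#' 520/1960 units = 26.5% on the 7x7x40 crystal).
#'
#' @param nx,ny,n_units Grid and chain-length parameters, see [build_cnc()].
#' @param label One of 0, 25, 40, 100.
#' @param phase Pattern-A phase, see [apply_dialcohol_modification()].
#' @param variant `"layers"` (default) or `"surface_B"` (only meaningful
#'   for label 40).
#' @return A `cnc_crystal`.
#' @export
make_standard_dom <- function(nx, ny, n_units, label, phase = 0,
                              variant = c("layers", "surface_B")) {
  variant <- match.arg(variant)
  if (!length(label) == 1 || !label %in% c(0, 25, 40, 100))
    stop("unsupported DoM label '", label, "': supported labels are 0, 25, 40, 100")
  cr <- build_cnc(nx, ny, n_units)
  if (label == 0) return(cr)
  cls <- classify_chains(cr)
  if (label == 100)
    return(apply_dialcohol_modification(cr, cls$chain_id, "B"))
  layers <- if (label == 25) 1L else c(1L, 2L)
  if (label == 40 && variant == "surface_B") {
    sel <- cls$chain_id[cls$layer == 1L]
    return(apply_dialcohol_modification(cr, sel, "B"))
  }
  for (ly in layers) {
    side <- cls$chain_id[cls$layer == ly & cls$position == "side"]
    tb <- cls$chain_id[cls$layer == ly & cls$position == "top/bottom"]
    if (length(side)) cr <- apply_dialcohol_modification(cr, side, "A", phase)
    if (length(tb)) cr <- apply_dialcohol_modification(cr, tb, "B")
  }
  cr
}

#' Degree of modification
#'
#' Fraction of glucose units carrying the dialcohol modification.
#'
#' @param crystal A `cnc_crystal`.
#' @return Numeric fraction in \[0, 1\].
#' @export
compute_dom <- function(crystal) {
  stopifnot(inherits(crystal, "cnc_crystal"))
  if (nrow(crystal$units) == 0) stop("empty crystal")
  mean(crystal$units$modified)
}

#' Nanocrystal dimensions
#'
#' `method = "nominal"` (default) reports the crystallographic dimensions
#' conventionally quoted for nanocrystals: length = `n_units` x c/2, and
#' cross-section = span of the outermost chain axes plus one carbon van
#' der Waals diameter (0.40 nm) along each of the two chain-lattice
#' directions. `method = "extent"` reports raw atomic-center extents along
#' the principal axes of the coordinates. Both are invariant under rigid
#' motion of the crystal; values are reported to 0.1 nm.
#'
#' @param crystal A `cnc_crystal`.
#' @param method `"nominal"` or `"extent"`.
#' @return Named numeric `c(width, height, length)` in nm.
#' @export
measure_dimensions <- function(crystal, method = c("nominal", "extent")) {
  stopifnot(inherits(crystal, "cnc_crystal"))
  method <- match.arg(method)
  if (method == "nominal") {
    lat <- crystal$lattice
    w <- (crystal$nx - 1) * sqrt(sum(lat$u^2)) + 0.40
    h <- (crystal$ny - 1) * sqrt(sum(lat$v^2)) + 0.40
    l <- crystal$n_units * lat$c / 2
  } else {
    xyz <- as.matrix(crystal$atoms[, c("x", "y", "z")])
    pc <- stats::prcomp(xyz, center = TRUE, scale. = FALSE)
    ext <- apply(pc$x, 2, function(v) diff(range(v)))
    l <- ext[1]
    w <- min(ext[2:3]); h <- max(ext[2:3])
  }
  round(c(width = unname(w), height = unname(h), length = unname(l)), 1)
}
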