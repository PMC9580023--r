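# Glycosidic torsion angles Phi (C4'-O4'-C1-O5) and Psi (C5'-C4'-O4'-C1)
# across each beta(1->4) linkage. The linkage between unit k and unit k+1
# runs C1(k)-O4(k+1); primed atoms belong to unit k+1.

#' Glycosidic torsion angles
#'
#' One (Phi, Psi) pair per glucosidic linkage, including linkages adjacent
#' to modified units. Dihedral signs follow the right-hand (IUPAC)
#' convention; angles are in (-180, 180]. Linkages with missing named
#' atoms are skipped with a message.
#'
#' @param frame A `cnc_frame` with builder atom naming.
#' @param bin_width Histogram bin width in degrees (default 5).
#' @return A `torsion_set`: list with `angles` (data.frame chain_id, unit,
#'   phi, psi), `bin_width`, and normalized histograms `phi_hist`,
#'   `psi_hist` (densities integrating to 1).
#' @export
glycosidic_torsions <- function(frame, bin_width = 5) {
  a <- frame$atoms
  cell <- a$resname %in% c("GLC", "DAG")
  if (!any(cell)) stop("frame contains no glucose units")
  key <- paste(a$chain_id, a$unit, a$name)
  idx <- function(ch, un, nm) match(paste(ch, un, nm), key)

  units <- unique(a[cell, c("chain_id", "unit")])
  units <- units[order(units$chain_id, units$unit), ]
  # linkage k -> k+1 for consecutive units within a chain
  nx <- paste(units$chain_id, units$unit + 1)
  has_next <- nx %in% paste(units$chain_id, units$unit)
  lk <- units[has_next, , drop = FALSE]
  if (!nrow(lk)) stop("frame contains no glucosidic linkage")

  iC1 <- idx(lk$chain_id, lk$unit, "C1")
  iO5 <- idx(lk$chain_id, lk$unit, "O5")
  iO4 <- idx(lk$chain_id, lk$unit + 1, "O4")
  iC4 <- idx(lk$chain_id, lk$unit + 1, "C4")
  iC5 <- idx(lk$chain_id, lk$unit + 1, "C5")
  ok <- !(is.na(iC1) | is.na(iO5) | is.na(iO4) | is.na(iC4) | is.na(iC5))
  if (any(!ok))
    message(sum(!ok), " linkage(s) skipped: missing named atoms")
  if (!any(ok)) stop("no complete glucosidic linkage found")
  lk <- lk[ok, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  phi <- dihedral_angle(xyz[iC4[ok], , drop = FALSE],
                        xyz[iO4[ok], , drop = FALSE],
                        xyz[iC1[ok], , drop = FALSE],
                        xyz[iO5[ok], , drop = FALSE])
  psi <- dihedral_angle(xyz[iC5[ok], , drop = FALSE],
                        xyz[iC4[ok], , drop = FALSE],
                        xyz[iO4[ok], , drop = FALSE],
                        xyz[iC1[ok], , drop = FALSE])

  brk <- seq(-180, 180, by = bin_width)
  dens <- function(v) {
    h <- hist(v, breaks = brk, plot = FALSE)
    data.frame(mid = h$mids, density = h$counts / (length(v) * bin_width))
  }
  structure(list(angles = data.frame(chain_id = lk$chain_id, unit = lk$unit,
                                     phi = phi, psi = psi),
                 bin_width = bin_width,
                 phi_hist = dens(phi), psi_hist = dens(psi)),
            class = "torsion_set")
}

# Circular mode (degrees) via the maximum of a wrapped histogram.
.circular_mode <- function(v, bin_width = 5) {
  brk <- seq(-180, 180, by = bin_width)
  h <- hist(v, breaks = brk, plot = FALSE)
  h$mids[which.max(h$counts)]
}
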