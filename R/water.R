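# Hydration-shell selection.

#' Select water molecules near a solute
#'
#' Water residues with any atom within `cutoff` of any solute atom. The
#' selection is order-independent (a set of residues).
#'
#' @param frame A `cnc_frame` containing water residues (resname SOL/HOH/
#'   WAT/TIP3/SPC).
#' @param solute Optional atom indices defining the solute; default: all
#'   non-water atoms.
#' @param cutoff Distance cutoff in nm (default 0.6, i.e. 6 Angstrom).
#' @return List with `count` (number of selected waters), `residues`
#'   (data.frame chain_id, unit) and `atoms` (row indices of all atoms of
#'   the selected waters).
#' @export
water_shell <- function(frame, solute = NULL, cutoff = 0.6) {
  a <- frame$atoms
  iw <- which(a$resname %in% .WATER_RESNAMES)
  if (!length(iw)) {
    warning("frame contains no water residues")
    return(list(count = 0L,
                residues = data.frame(chain_id = integer(), unit = integer()),
                atoms = integer()))
  }
  if (is.null(solute)) solute <- setdiff(seq_len(nrow(a)), iw)
  if (!length(solute)) stop("empty solute selection")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  np <- neighbor_pairs_cpp(xyz[iw, , drop = FALSE],
                           xyz[solute, , drop = FALSE], cutoff)
  hit <- unique(iw[np$i])
  res <- unique(a[hit, c("chain_id", "unit")])
  res <- res[order(res$chain_id, res$unit), , drop = FALSE]
  rownames(res) <- NULL
  key <- paste(a$chain_id, a$unit)
  atoms <- iw[key[iw] %in% paste(res$chain_id, res$unit)]
  list(count = nrow(res), residues = res, atoms = atoms)
}
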