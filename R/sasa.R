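# Solvent-accessible surface area (Shrake-Rupley) with Bondi van der
# Waals radii and a deterministic golden-spiral point set.

.BONDI_NM <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152,
               S = 0.180, P = 0.180)

#' Solvent-accessible surface area
#'
#' Shrake-Rupley estimate: each atom is inflated by the probe radius and
#' sampled with `n_sphere_points` quasi-uniform (golden-spiral) surface
#' points; points inside any neighbouring inflated sphere are occluded.
#' Converges to the exact area as `n_sphere_points` grows; a single
#' carbon sphere gives 4*pi*(0.17+probe)^2 within quadrature error.
#'
#' @param frame A `cnc_frame`.
#' @param selection Optional atom indices; default all atoms. The area is
#'   computed for the selection in isolation.
#' @param probe_radius Probe radius in nm (default 0.14, a water probe).
#' @param n_sphere_points Surface points per atom (default 960).
#' @return Total area in nm^2, with per-atom areas in attribute
#'   `"per_atom"`.
#' @export
sasa <- function(frame, selection = NULL, probe_radius = 0.14,
                 n_sphere_points = 960) {
  a <- frame$atoms
  if (is.null(selection)) selection <- seq_len(nrow(a))
  el <- a$element[selection]
  unknown <- which(!el %in% names(.BONDI_NM))
  if (length(unknown)) {
    k <- selection[unknown[1]]
    stop("no van der Waals radius for element '", a$element[k],
         "' (atom ", a$name[k], ", row ", k, ")")
  }
  xyz <- as.matrix(a[selection, c("x", "y", "z"), drop = FALSE])
  rext <- .BONDI_NM[el] + probe_radius
  per <- sasa_cpp(xyz, as.numeric(rext), as.integer(n_sphere_points))
  structure(sum(per), per_atom = per)
}
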