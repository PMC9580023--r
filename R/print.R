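# Compact print methods.

#' @export
print.cnc_crystal <- function(x, ...) {
  dims <- measure_dimensions(x)
  cat("Cellulose I-beta nanocrystal\n")
  cat(sprintf("  chains: %d (%d x %d), %d glucose units each\n",
              nrow(x$chains), x$nx, x$ny, x$n_units))
  cat(sprintf("  atoms: %d   bonds: %d\n", nrow(x$atoms), nrow(x$bonds)))
  cat(sprintf("  degree of modification: %.1f%% (%d units)\n",
              100 * compute_dom(x), sum(x$units$modified)))
  cat(sprintf("  nominal dimensions: %.1f x %.1f x %.1f nm\n",
              dims["width"], dims["height"], dims["length"]))
  invisible(x)
}

#' @export
print.cnc_frame <- function(x, ...) {
  a <- x$atoms
  nw <- length(unique(a$unit[a$resname %in% .WATER_RESNAMES]))
  cat("Coordinate frame\n")
  cat(sprintf("  atoms: %d   chains: %d   residues: %d\n", nrow(a),
              length(unique(a$chain_id)),
              nrow(unique(a[, c("chain_id", "unit")]))))
  if (nw) cat(sprintf("  waters: %d\n", nw))
  cat(sprintf("  box: %.2f x %.2f x %.2f nm\n",
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat(sprintf("Interchain RDF %s: %d bins of %.3g nm to %.2f nm, rho = %.2f nm^-3\n",
              x$pair_class, length(x$r), x$bin_width, x$r_max, x$rho))
  invisible(x)
}

#' @export
print.sq_profile <- function(x, ...) {
  cat(sprintf("Structure factor: q in [%.2f, %.2f] nm^-1 (%d points), %s window\n",
              min(x$q), max(x$q), length(x$q), x$window))
  pk <- find_peaks(x, min_prominence = 0.1)
  if (nrow(pk))
    cat("  main peaks (nm^-1):",
        paste(sprintf("%.1f", utils::head(pk$position, 3)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.hbond_result <- function(x, ...) {
  cat(sprintf("Hydrogen bonds: %d (criteria: d <= %.2f nm, angle <= %.0f deg)\n",
              x$count, x$criteria$dist_cutoff, x$criteria$angle_cutoff))
  if (!is.na(x$per_glucose))
    cat(sprintf("  per glucose unit: %.3f (%d units)\n",
                x$per_glucose, x$n_glucose))
  invisible(x)
}

#' @export
print.torsion_set <- function(x, ...) {
  cat(sprintf("Glycosidic torsions: %d linkages, %.0f-degree bins\n",
              nrow(x$angles), x$bin_width))
  cat(sprintf("  Phi mode %.0f deg, Psi mode %.0f deg\n",
              .circular_mode(x$angles$phi, x$bin_width),
              .circular_mode(x$angles$psi, x$bin_width)))
  invisible(x)
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("Force curve: %d samples, d in [%.3f, %.3f] nm, force in %s\n",
              length(x$d), min(x$d), max(x$d), x$metadata$force_unit))
  invisible(x)
}

#' @export
print.stress_curve <- function(x, ...) {
  tm <- tau_max(x)
  cat(sprintf("Stress curve: %d samples, tau_max = %.1f MPa at d = %.2f nm (A = %.1f nm^2)\n",
              length(x$d), tm$tau_max, tm$d_at_max, x$metadata$area))
  invisible(x)
}
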