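# Synthetic-data generators: thermally jittered crystals, hydration
# shells, and parameterized stick-slip traces with closed-form ground
# truth. All generators are pure functions of (parameters, seed).

#' Thermally jitter a crystal
#'
#' Adds i.i.d. Gaussian displacements to every atom. Atoms of dialcohol
#' (`DAG`) units receive `sigma_modified` (default ten times `sigma`, i.e.
#' 0.2 nm at the default `sigma` of 0.02 nm): an amorphous shell requires
#' positional disorder comparable to the interchain spacing itself
#' (crystalline cellulose fluctuates by 0.05-0.07 nm, amorphous surface
#' chains by 0.2-0.5 nm), which is what lets a static model emulate the
#' disordered dialcohol shell of equilibrated structures.
#'
#' @param crystal A `cnc_frame` (typically a `cnc_crystal`).
#' @param sigma Displacement standard deviation per coordinate (nm),
#'   for unmodified atoms. `sigma = 0` returns the input exactly.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param sigma_modified Displacement sd for atoms of modified units.
#' @return The frame with jittered coordinates.
#' @export
jitter_crystal <- function(crystal, sigma, seed = NULL,
                           sigma_modified = 10 * sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    stop("sigma must be a single non-negative number")
  if (sigma_modified < 0) stop("sigma_modified must be non-negative")
  if (sigma == 0 && sigma_modified == 0) return(crystal)
  a <- crystal$atoms
  sd_atom <- ifelse(a$resname == "DAG", sigma_modified, sigma)
  n <- nrow(a)
  disp <- .with_seed(seed, matrix(stats::rnorm(3 * n, 0, sd_atom), n, 3))
  crystal$atoms[, c("x", "y", "z")] <-
    as.matrix(a[, c("x", "y", "z")]) + disp
  crystal$box <- .frame_box(crystal)
  crystal
}

#' Place a random hydration shell around a crystal
#'
#' Rigid three-site waters are placed uniformly at the target number
#' density inside the accessible shell: points within `thickness` of a
#' solute heavy atom but no closer than `min_dist` to any solute heavy
#' atom or previously placed water oxygen. Orientations are uniform
#' random. The target count is `density` times the accessible volume
#' (estimated by Monte Carlo); if the hard-core constraint makes the
#' density unreachable the generator stops with an error after a bounded
#' number of attempts.
#'
#' @param crystal A `cnc_frame` solute.
#' @param thickness Shell thickness (nm); 0 gives no waters.
#' @param density Target water number density (nm^-3; 33.3 is bulk water).
#' @param seed Optional integer seed.
#' @param min_dist Hard-core exclusion distance (nm).
#' @param max_attempts_factor Attempt budget, as a multiple of the target
#'   count.
#' @return A `cnc_frame` with the crystal atoms plus SOL residues; the
#'   water count is in attribute `"n_water"` and the accessible-volume
#'   estimate in `"shell_volume"`.
#' @export
place_water_shell <- function(crystal, thickness = 0.6, density = 33.3,
                              seed = NULL, min_dist = 0.25,
                              max_attempts_factor = 200) {
  if (thickness < 0) stop("thickness must be non-negative")
  a <- crystal$atoms
  heavy <- which(a$element != "H")
  Xs <- as.matrix(a[heavy, c("x", "y", "z"), drop = FALSE])
  empty <- function() {
    out <- structure(list(atoms = a, bonds = crystal$bonds),
                     class = "cnc_frame")
    out$box <- .frame_box(out)
    attr(out, "n_water") <- 0L
    attr(out, "shell_volume") <- 0
    out
  }
  if (thickness == 0) return(empty())

  lo <- apply(Xs, 2, min) - thickness
  hi <- apply(Xs, 2, max) + thickness
  Vbox <- prod(hi - lo)

  .with_seed(seed, {
    runif_box <- function(m)
      cbind(stats::runif(m, lo[1], hi[1]), stats::runif(m, lo[2], hi[2]),
            stats::runif(m, lo[3], hi[3]))
    accessible <- function(P) {
      np <- neighbor_pairs_cpp(P, Xs, thickness)
      if (!length(np$i)) return(rep(FALSE, nrow(P)))
      dmin <- rep(Inf, nrow(P))
      agg <- tapply(np$d, np$i, min)
      dmin[as.integer(names(agg))] <- agg
      is.finite(dmin) & dmin >= min_dist
    }
    # Monte-Carlo accessible volume
    M <- 20000
    Vacc <- Vbox * mean(accessible(runif_box(M)))
    n_target <- round(density * Vacc)
    if (n_target == 0) return(empty())

    acc <- matrix(numeric(0), 0, 3)
    attempts <- 0
    budget <- max_attempts_factor * n_target
    while (nrow(acc) < n_target) {
      if (attempts >= budget)
        stop("could not place ", n_target, " waters at density ", density,
             " nm^-3 within ", budget, " attempts: density too high for ",
             "the hard-core exclusion of ", min_dist, " nm")
      m <- min(max(2000, n_target), budget - attempts)
      attempts <- attempts + m
      P <- runif_box(m)
      P <- P[accessible(P), , drop = FALSE]
      if (!nrow(P)) next
      if (nrow(acc)) {
        np <- neighbor_pairs_cpp(P, acc, min_dist)
        if (length(np$i)) P <- P[-unique(np$i), , drop = FALSE]
      }
      if (!nrow(P)) next
      # intra-batch conflicts: greedy keep-first
      np <- neighbor_pairs_cpp(P, P, min_dist)
      drop <- unique(np$i[np$i > np$j])
      if (length(drop)) P <- P[-drop, , drop = FALSE]
      need <- n_target - nrow(acc)
      if (nrow(P) > need) P <- P[seq_len(need), , drop = FALSE]
      acc <- rbind(acc, P)
    }

    # rigid 3-site water: O-H 0.09572 nm, H-O-H 104.52 deg, random rotation
    nw <- nrow(acc)
    hw <- 104.52 / 2 * pi / 180
    h1 <- 0.09572 * c(sin(hw), 0, cos(hw))
    h2 <- 0.09572 * c(-sin(hw), 0, cos(hw))
    q <- matrix(stats::rnorm(4 * nw), nw, 4)
    q <- q / sqrt(rowSums(q^2))
    rot_apply <- function(v) {
      # rotate fixed vector v by each unit quaternion row
      w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
      cbind(
        (1 - 2 * (y^2 + z^2)) * v[1] + 2 * (x * y - w * z) * v[2] +
          2 * (x * z + w * y) * v[3],
        2 * (x * y + w * z) * v[1] + (1 - 2 * (x^2 + z^2)) * v[2] +
          2 * (y * z - w * x) * v[3],
        2 * (x * z - w * y) * v[1] + 2 * (y * z + w * x) * v[2] +
          (1 - 2 * (x^2 + y^2)) * v[3])
    }
    H1 <- acc + rot_apply(h1)
    H2 <- acc + rot_apply(h2)

    wchain <- max(a$chain_id) + 1L
    watoms <- data.frame(
      name = rep(c("OW", "HW1", "HW2"), nw),
      element = rep(c("O", "H", "H"), nw),
      resname = "SOL",
      chain_id = wchain,
      unit = rep(seq_len(nw) - 1L, each = 3),
      ord = rep(1:3, nw),
      x = as.vector(t(cbind(acc[, 1], H1[, 1], H2[, 1]))),
      y = as.vector(t(cbind(acc[, 2], H1[, 2], H2[, 2]))),
      z = as.vector(t(cbind(acc[, 3], H1[, 3], H2[, 3]))),
      stringsAsFactors = FALSE)
    out <- structure(list(atoms = rbind(a, watoms), bonds = crystal$bonds),
                     class = "cnc_frame")
    out$box <- .frame_box(out)
    attr(out, "n_water") <- nw
    attr(out, "shell_volume") <- Vacc
    out
  })
}

#' Parameters for a synthetic stick-slip trace
#'
#' Defines a piecewise-linear engineering-stress trace: `n_events` teeth,
#' each rising from the baseline at `slope` to its programmed peak and
#' dropping back over `drop_width`, followed by a flat tail. Defaults
#' emulate the qualitative axial-shear behaviour of two native crystals
#' in close contact at room temperature: four stick-slip teeth with
#' decreasing peak stress.
#'
#' @param n_events Number of stick-slip teeth (>= 0).
#' @param peak_heights Peak stress of each tooth (MPa); length `n_events`.
#' @param slope Pre-peak loading slope (MPa/nm).
#' @param drop_width Displacement over which the stress drops after each
#'   peak (nm).
#' @param ramp_height For `n_events = 0`: height of the plain linear ramp
#'   (MPa).
#' @param noise_sd Gaussian noise added to the sampled stress (MPa).
#' @param spacing Sample spacing (nm).
#' @param tail Flat tail length after the last event (nm).
#' @param area Contact area used to convert stress to force (nm^2).
#' @param seed Optional integer seed for the noise.
#' @return A `synth_trace_params` object.
#' @export
synth_trace_params <- function(n_events = 4,
                               peak_heights = c(120, 100, 90, 80),
                               slope = 150, drop_width = 0.1,
                               ramp_height = 100,
                               noise_sd = 1, spacing = 0.005, tail = 0.5,
                               area = 65.5, seed = NULL) {
  if (n_events < 0 || n_events != round(n_events))
    stop("n_events must be a non-negative integer")
  if (n_events > 0 && length(peak_heights) != n_events)
    stop("peak_heights must have length n_events")
  if (n_events > 0 && any(peak_heights <= 0))
    stop("peak_heights must be positive")
  if (slope <= 0) stop("slope must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (spacing <= 0) stop("spacing must be positive: the displacement grid ",
                         "must be increasing")
  if (drop_width <= 0) stop("drop_width must be positive")
  if (area <= 0) stop("area must be positive")
  structure(list(n_events = n_events, peak_heights = peak_heights,
                 slope = slope, drop_width = drop_width,
                 ramp_height = ramp_height, noise_sd = noise_sd,
                 spacing = spacing, tail = tail, area = area, seed = seed),
            class = "synth_trace_params")
}

#' Generate a synthetic stick-slip force trace with ground truth
#'
#' The noise-free trace reproduces the programmed maximum stress, pre-peak
#' slope, event count and force-curve integral exactly (peak vertices are
#' included in the sample grid); the noisy trace is deterministic per
#' seed. The ground truth is returned alongside for parameter-recovery
#' testing.
#'
#' @param params A [synth_trace_params()] object.
#' @return List with `curve` (a `force_curve`, force in kJ/mol/nm),
#'   `truth` (tau_max, d_at_max, stiffness, n_events, energy in kJ/mol)
#'   and `params`.
#' @export
synth_force_trace <- function(params = synth_trace_params()) {
  stopifnot(inherits(params, "synth_trace_params"))
  p <- params
  # vertex list of the noise-free stress polyline
  vd <- 0; vt <- 0
  if (p$n_events == 0) {
    vd <- c(0, p$ramp_height / p$slope)
    vt <- c(0, p$ramp_height)
  } else {
    for (h in p$peak_heights) {
      d0 <- vd[length(vd)]
      vd <- c(vd, d0 + h / p$slope, d0 + h / p$slope + p$drop_width)
      vt <- c(vt, h, 0)
    }
    vd <- c(vd, vd[length(vd)] + p$tail)
    vt <- c(vt, 0)
  }
  d <- sort(unique(c(seq(0, vd[length(vd)], by = p$spacing), vd)))
  tau <- stats::approx(vd, vt, xout = d)$y
  tau_max_true <- max(vt)
  d_at_max <- vd[which.max(vt)]
  kF <- p$area / .KJ_PER_MOL_NM_TO_PN   # MPa -> kJ/mol/nm at this area
  energy_true <- pracma::trapz(vd, vt * kF)
  tau_noisy <- tau + if (p$noise_sd > 0)
    .with_seed(p$seed, stats::rnorm(length(d), 0, p$noise_sd)) else 0
  md <- shear_metadata(area = p$area, force_unit = "kJ/mol/nm")
  curve <- force_curve(d, tau_noisy * kF, metadata = md)
  list(curve = curve,
       truth = list(tau_max = tau_max_true, d_at_max = d_at_max,
                    stiffness = p$slope, n_events = p$n_events,
                    energy = energy_true),
       params = params)
}
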