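# Steered-shear post-processing: force-displacement ingestion,
# engineering stress, tau_max, interfacial stiffness, stick-slip events
# and force-curve integration.
#
# Unit conventions: displacement nm; force either kJ/mol/nm (simulation
# native) or pN; engineering stress MPa = pN / nm^2; energies kJ/mol.

.KJ_PER_MOL_NM_TO_PN <- 1000 / 602.214076  # 1 kJ/mol/nm in pN

#' Shear-run metadata
#'
#' Run conditions attached to a pull curve. The default contact area,
#' 65.5 nm^2, is the SASA-derived contact area of the unmodified
#' crystal pair; engineering stress keeps it constant over the run.
#'
#' @param direction `"axial"` or `"transverse"`.
#' @param separation Surface-to-surface separation (Angstrom; e.g. 3 or
#'   8), or `NA` for free runs.
#' @param temperature Temperature (degrees C).
#' @param pull_rate Pull rate (nm/ns).
#' @param spring_constant Pull spring constant (kJ/mol/nm^2).
#' @param area Contact area (nm^2).
#' @param force_unit `"kJ/mol/nm"` or `"pN"`.
#' @return A `shear_metadata` object.
#' @export
shear_metadata <- function(direction = c("axial", "transverse"),
                           separation = NA, temperature = 25,
                           pull_rate = 1, spring_constant = 10000,
                           area = 65.5, force_unit = c("kJ/mol/nm", "pN")) {
  direction <- match.arg(direction)
  force_unit <- match.arg(force_unit)
  if (!is.na(pull_rate) && pull_rate <= 0) stop("pull_rate must be positive")
  if (!is.na(spring_constant) && spring_constant <= 0)
    stop("spring_constant must be positive")
  if (!is.na(area) && area <= 0) stop("area must be positive")
  structure(list(direction = direction, separation = separation,
                 temperature = temperature, pull_rate = pull_rate,
                 spring_constant = spring_constant, area = area,
                 force_unit = force_unit),
            class = "shear_metadata")
}

#' Parse a run label of the form `Ax_3@25` / `Tr_8@100`
#'
#' @param label Character label: direction (`Ax`/`Tr`), separation in
#'   Angstrom, `@`, temperature in degrees C.
#' @param ... Further arguments passed to [shear_metadata()].
#' @return A `shear_metadata` object.
#' @export
parse_run_label <- function(label, ...) {
  m <- regmatches(label, regexec("^(Ax|Tr)_([0-9]+)@([0-9]+)$", label))[[1]]
  if (length(m) != 4) stop("cannot parse run label '", label,
                           "': expected e.g. 'Ax_3@25'")
  shear_metadata(direction = if (m[2] == "Ax") "axial" else "transverse",
                 separation = as.numeric(m[3]),
                 temperature = as.numeric(m[4]), ...)
}

#' Construct a force curve
#'
#' @param d Displacement (nm), strictly increasing after preprocessing.
#' @param force Force values in the metadata's force unit.
#' @param metadata A [shear_metadata()] object.
#' @return A `force_curve` object.
#' @export
force_curve <- function(d, force, metadata = shear_metadata()) {
  if (length(d) != length(force)) stop("d and force must have equal length")
  if (!length(d)) stop("empty force curve")
  o <- order(d)
  d <- d[o]; force <- force[o]
  if (anyDuplicated(d)) {
    force <- as.numeric(tapply(force, d, mean))
    d <- sort(unique(d))
  }
  structure(list(d = d, force = force, metadata = metadata),
            class = "force_curve")
}

#' Read a steered-pull force trace (XVG dialect or CSV)
#'
#' XVG comment/command lines (starting with `#` or `@`) are ignored; the
#' remainder must be two numeric columns. When `abscissa = "time"` the
#' first column is converted to displacement through the metadata pull
#' rate (`d = rate * t`; at 1 nm/ns the displacement equals the time in
#' ns numerically). Duplicate abscissae are collapsed by averaging.
#'
#' @param path Input file.
#' @param dialect `"auto"` (by extension), `"xvg"` or `"csv"`.
#' @param metadata A [shear_metadata()] object.
#' @param abscissa `"displacement"` or `"time"`.
#' @param time_unit `"ns"` or `"ps"` when `abscissa = "time"`.
#' @return A `force_curve`.
#' @export
read_pull_curve <- function(path, dialect = c("auto", "xvg", "csv"),
                            metadata = shear_metadata(),
                            abscissa = c("displacement", "time"),
                            time_unit = c("ns", "ps")) {
  dialect <- match.arg(dialect)
  abscissa <- match.arg(abscissa)
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto")
    dialect <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "xvg"
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  if (dialect == "xvg") {
    keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  } else {
    keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  }
  lines <- lines[keep]; lineno <- lineno[keep]
  if (dialect == "csv" && length(lines)) {
    # optional single header line
    f1 <- strsplit(trimws(lines[1]), "[,;\\s]+")[[1]]
    if (anyNA(suppressWarnings(as.numeric(f1)))) {
      lines <- lines[-1]; lineno <- lineno[-1]
    }
  }
  if (!length(lines)) stop("no data rows in '", path, "'")
  sp <- if (dialect == "csv") "[,;\\s]+" else "\\s+"
  fields <- strsplit(trimws(lines), sp)
  bad <- which(lengths(fields) < 2)
  if (length(bad))
    stop("malformed row in '", path, "' at line ", lineno[bad[1]],
         ": expected two numeric columns")
  xy <- vapply(fields, function(f) suppressWarnings(as.numeric(f[1:2])),
               numeric(2))
  badn <- which(apply(is.na(xy), 2, any))
  if (length(badn))
    stop("non-numeric value in '", path, "' at line ", lineno[badn[1]])
  x <- xy[1, ]; f <- xy[2, ]
  if (abscissa == "time") {
    t_ns <- if (time_unit == "ps") x / 1000 else x
    x <- metadata$pull_rate * t_ns
  }
  force_curve(x, f, metadata)
}

.force_to_pN <- function(force, unit) {
  switch(unit,
         "kJ/mol/nm" = force * .KJ_PER_MOL_NM_TO_PN,
         "pN" = force,
         stop("unknown force unit '", unit, "'"))
}

#' Engineering stress curve
#'
#' \eqn{\tau(d) = F(d) / A} with the constant contact area from the
#' metadata, converted to MPa.
#'
#' @param curve A `force_curve`.
#' @return A `stress_curve`: list with `d` (nm), `tau` (MPa), `metadata`.
#' @export
stress_curve <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  A <- curve$metadata$area
  if (is.null(A) || is.na(A)) stop("missing contact area in metadata")
  tau <- .force_to_pN(curve$force, curve$metadata$force_unit) / A
  structure(list(d = curve$d, tau = tau, metadata = curve$metadata),
            class = "stress_curve")
}

#' Maximum shear stress
#'
#' Global maximum of the stress curve; ties are broken by the smallest
#' displacement.
#'
#' @param curve A `stress_curve`.
#' @return List with `tau_max` (MPa) and `d_at_max` (nm).
#' @export
tau_max <- function(curve) {
  stopifnot(inherits(curve, "stress_curve"))
  i <- which(curve$tau == max(curve$tau))[1]
  list(tau_max = curve$tau[i], d_at_max = curve$d[i])
}

#' Stick-slip events
#'
#' Local stress maxima with topographic prominence at least
#' `min_prominence` (default 10% of the stress range), each paired with
#' the magnitude of the subsequent stress drop (peak minus the following
#' minimum before the next event or the end of the curve).
#'
#' @param curve A `stress_curve`.
#' @param min_prominence Prominence threshold (MPa); default
#'   `0.1 * diff(range(tau))`.
#' @return data.frame with columns `d_peak`, `tau_peak`, `drop`, ordered
#'   by displacement (possibly zero rows).
#' @export
stick_slip_events <- function(curve, min_prominence = NULL) {
  stopifnot(inherits(curve, "stress_curve"))
  if (is.null(min_prominence))
    min_prominence <- 0.1 * diff(range(curve$tau))
  pk <- .peak_prominences(curve$d, curve$tau)
  pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
  if (!nrow(pk))
    return(data.frame(d_peak = numeric(), tau_peak = numeric(),
                      drop = numeric()))
  pk <- pk[order(pk$index), , drop = FALSE]
  ends <- c(pk$index[-1], length(curve$tau))
  drop <- vapply(seq_len(nrow(pk)), function(k) {
    pk$height[k] - min(curve$tau[pk$index[k]:ends[k]])
  }, numeric(1))
  data.frame(d_peak = pk$x, tau_peak = pk$height, drop = drop)
}

#' Interfacial stiffness
#'
#' Least-squares slope of stress versus displacement from the start of
#' the curve to its first stick-slip peak. If no peak is detected the
#' fit window falls back to the first 10% of the displacement range (a
#' message is emitted).
#'
#' @param curve A `stress_curve`.
#' @param min_prominence Peak prominence threshold passed to
#'   [stick_slip_events()].
#' @return Slope in MPa/nm.
#' @export
interfacial_stiffness <- function(curve, min_prominence = NULL) {
  stopifnot(inherits(curve, "stress_curve"))
  ev <- stick_slip_events(curve, min_prominence)
  if (nrow(ev)) {
    sel <- curve$d <= ev$d_peak[1]
  } else {
    message("no stick-slip peak detected: fitting the first 10% of the ",
            "displacement range")
    sel <- curve$d <= curve$d[1] + 0.1 * diff(range(curve$d))
  }
  if (sum(sel) < 3)
    stop("need at least 3 samples before the first peak to fit a slope")
  unname(stats::coef(stats::lm(curve$tau[sel] ~ curve$d[sel]))[2])
}

#' Interaction energy by force-curve integration
#'
#' Trapezoidal integral of the force over a displacement range, with the
#' endpoints interpolated so the integral is additive over adjacent
#' ranges. Forces are converted to kJ/mol/nm, so the energy is in kJ/mol.
#'
#' @param curve A `force_curve`.
#' @param d_range Length-2 displacement range (nm); default whole curve.
#' @return Energy in kJ/mol.
#' @export
interaction_energy <- function(curve, d_range = range(curve$d)) {
  stopifnot(inherits(curve, "force_curve"))
  if (length(d_range) != 2) stop("d_range must have length 2")
  if (d_range[1] > d_range[2])
    stop("inverted d_range: lower bound exceeds upper bound")
  if (d_range[1] < min(curve$d) - 1e-9 || d_range[2] > max(curve$d) + 1e-9)
    stop("d_range outside the curve's displacement span")
  fkj <- .force_to_pN(curve$force, curve$metadata$force_unit) /
    .KJ_PER_MOL_NM_TO_PN
  inner <- curve$d > d_range[1] & curve$d < d_range[2]
  dd <- c(d_range[1], curve$d[inner], d_range[2])
  ff <- c(stats::approx(curve$d, fkj, d_range[1])$y, fkj[inner],
          stats::approx(curve$d, fkj, d_range[2])$y)
  keep <- !duplicated(dd)
  pracma::trapz(dd[keep], ff[keep])
}
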