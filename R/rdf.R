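# Interchain radial distribution functions and the derived structure
# factor. The RDF counts only atom pairs on different chains (the
# same-chain exclusion targets inter-chain packing, which is what the
# diffraction-like S(q) peaks probe). Normalization uses the partner-atom
# density over the frame's bounding-box volume: the analysis targets a
# single finite crystal, not a bulk liquid.

.PAIR_CLASSES <- list("C-O" = c("C", "O"), "C-H" = c("C", "H"),
                      "O-H" = c("O", "H"))

#' Interchain radial distribution function
#'
#' Histogram of distances between atoms of a given element pair class on
#' *different* chains, normalized by shell volume and partner density.
#'
#' @param frame A `cnc_frame` (chain partitioning required).
#' @param pair_class One of `"C-O"`, `"C-H"`, `"O-H"`.
#' @param r_max Histogram range (nm).
#' @param bin_width Bin width (nm), must be > 0.
#' @param volume Normalization volume (nm^3); default is the bounding-box
#'   volume of the frame.
#' @return An `rdf_profile`: list with `r` (bin centers), `g`, `rho`
#'   (partner density), pair counts and parameters.
#' @export
interchain_rdf <- function(frame, pair_class, r_max = 3, bin_width = 0.002,
                           volume = NULL) {
  if (!pair_class %in% names(.PAIR_CLASSES))
    stop("unknown pair_class '", pair_class, "': use one of ",
         paste(names(.PAIR_CLASSES), collapse = ", "))
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be > 0")
  a <- frame$atoms
  el <- .PAIR_CLASSES[[pair_class]]
  ia <- which(a$element == el[1])
  ib <- which(a$element == el[2])
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (is.null(volume)) {
    ext <- apply(xyz, 2, function(v) diff(range(v)))
    volume <- prod(pmax(ext, bin_width))
  }
  cnt <- pair_hist_cpp(xyz[ia, , drop = FALSE], as.integer(a$chain_id[ia]),
                       xyz[ib, , drop = FALSE], as.integer(a$chain_id[ib]),
                       r_max, bin_width, TRUE)
  nb <- length(cnt)
  r <- (seq_len(nb) - 0.5) * bin_width
  rho <- length(ib) / volume
  g <- if (length(ia) == 0) rep(0, nb) else
    cnt / (length(ia) * 4 * pi * r^2 * bin_width * rho)
  structure(list(pair_class = pair_class, r = r, g = g, rho = rho,
                 n_ref = length(ia), n_partner = length(ib),
                 r_max = r_max, bin_width = bin_width, volume = volume,
                 exclusion = "interchain"),
            class = "rdf_profile")
}

#' Structure factor from interchain RDFs
#'
#' Sine Fourier transform of each pair-class RDF,
#' \deqn{S_c(q) = 1 + 4\pi\rho_c \int_0^{r_{max}} r^2 (g_c(r)-1)
#'   \frac{\sin qr}{qr} w(r)\, dr,}
#' combined as a weighted mean over the pair classes (default:
#' unweighted). The Lorch window `w(r) = sinc(pi r / r_max)` suppresses
#' truncation ripples.
#'
#' @param rdfs An `rdf_profile` or list of them; all must share one r grid.
#' @param q_min,q_max,dq q grid (nm^-1).
#' @param window `"lorch"` or `"none"`.
#' @param weights Optional numeric vector, one weight per profile
#'   (normalized internally); default equal weights.
#' @return An `sq_profile`: list with `q`, `S`, per-class `components`,
#'   `window`, `weights`.
#' @export
structure_factor <- function(rdfs, q_min = 0.5, q_max = 30, dq = 0.05,
                             window = c("lorch", "none"), weights = NULL) {
  window <- match.arg(window)
  if (inherits(rdfs, "rdf_profile")) rdfs <- list(rdfs)
  if (!length(rdfs) || !all(vapply(rdfs, inherits, TRUE, "rdf_profile")))
    stop("rdfs must be rdf_profile objects")
  r0 <- rdfs[[1]]$r
  for (p in rdfs)
    if (length(p$r) != length(r0) || any(abs(p$r - r0) > 1e-9))
      stop("mismatched r grids across RDF profiles")
  if (is.null(weights)) weights <- rep(1, length(rdfs))
  if (length(weights) != length(rdfs))
    stop("need one weight per RDF profile")
  weights <- weights / sum(weights)

  q <- seq(q_min, q_max, by = dq)
  w <- switch(window,
              lorch = {
                x <- pi * r0 / max(rdfs[[1]]$r_max, r0[length(r0)])
                sin(x) / x
              },
              none = rep(1, length(r0)))
  dr <- r0[2] - r0[1]
  # kernel matrix: sin(q r)/(q r), rows r, cols q
  K <- sin(outer(r0, q)) / outer(r0, q)
  comps <- lapply(rdfs, function(p) {
    integrand <- p$r^2 * (p$g - 1) * w
    as.numeric(1 + 4 * pi * p$rho * (integrand %*% K) * dr)
  })
  names(comps) <- vapply(rdfs, function(p) p$pair_class, "")
  S <- Reduce(`+`, Map(`*`, comps, weights))
  structure(list(q = q, S = S, components = comps, window = window,
                 weights = weights),
            class = "sq_profile")
}

# Topographic prominence of each strict local maximum of y.
.peak_prominences <- function(x, y) {
  i <- which(diff(sign(diff(y))) == -2) + 1
  if (!length(i))
    return(data.frame(index = integer(), x = numeric(), height = numeric(),
                      prominence = numeric()))
  prom <- vapply(i, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1)]
    hi <- which(left > h)
    lcol <- if (length(hi)) min(y[max(hi):p]) else min(y[1:p])
    right <- y[(p + 1):length(y)]
    hi2 <- which(right > h)
    rcol <- if (length(hi2)) min(y[p:(p + min(hi2))]) else min(y[p:length(y)])
    h - max(lcol, rcol)
  }, numeric(1))
  data.frame(index = i, x = x[i], height = y[i], prominence = prom)
}

#' Find peaks in a structure-factor (or any x-y) profile
#'
#' Local maxima with topographic prominence at least `min_prominence`,
#' sorted by descending height. Peak positions are refined by a local
#' quadratic (three-point parabola) interpolation.
#'
#' @param profile An `sq_profile`, or a list/data.frame with numeric
#'   elements `x`/`q` and `y`/`S`.
#' @param min_prominence Minimum prominence (same units as the profile
#'   values).
#' @return data.frame with columns `position`, `height`, `prominence`
#'   (possibly zero rows).
#' @export
find_peaks <- function(profile, min_prominence = 0.1) {
  if (inherits(profile, "sq_profile")) {
    x <- profile$q; y <- profile$S
  } else {
    x <- profile$x %||% profile$q
    y <- profile$y %||% profile$S
  }
  if (is.null(x) || is.null(y) || !length(x))
    stop("profile must provide x/q and y/S")
  pk <- .peak_prominences(x, y)
  pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
  if (!nrow(pk))
    return(data.frame(position = numeric(), height = numeric(),
                      prominence = numeric()))
  pos <- vapply(pk$index, function(i) {
    if (i <= 1 || i >= length(x)) return(x[i])
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (abs(denom) < 1e-15) return(x[i])
    delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
    x[i] + delta * (x[i + 1] - x[i])
  }, numeric(1))
  out <- data.frame(position = pos, height = pk$height,
                    prominence = pk$prominence)
  out[order(out$height, decreasing = TRUE), , drop = FALSE]
}
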