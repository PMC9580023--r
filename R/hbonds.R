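# Geometric hydrogen-bond detection. A bond is counted when the
# donor-acceptor oxygen distance is within the cutoff and the
# hydrogen-donor-acceptor angle is within the angular cutoff - the
# criterion used by the standard trajectory tools, with their default
# values (0.35 nm / 30 degrees).

.WATER_RESNAMES <- c("SOL", "HOH", "WAT", "TIP3", "TIP", "SPC")

#' Hydrogen-bond criteria
#'
#' @param dist_cutoff Donor-acceptor distance cutoff (nm).
#' @param angle_cutoff Hydrogen-donor-acceptor angle cutoff (degrees,
#'   must be <= 90).
#' @return An `hbond_criteria` object.
#' @export
hbond_criteria <- function(dist_cutoff = 0.35, angle_cutoff = 30) {
  if (dist_cutoff <= 0) stop("dist_cutoff must be positive")
  if (angle_cutoff <= 0 || angle_cutoff > 90)
    stop("angle_cutoff must be in (0, 90] degrees")
  structure(list(dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_criteria")
}

#' Select atoms of a frame by role
#'
#' @param frame A `cnc_frame`.
#' @param group `"cellulose"` (GLC/DAG residues), `"water"`, or `"all"`.
#' @param chains Optional chain ids to restrict to.
#' @return Integer atom row indices.
#' @export
select_atoms <- function(frame, group = c("cellulose", "water", "all"),
                         chains = NULL) {
  group <- match.arg(group)
  a <- frame$atoms
  idx <- switch(group,
                cellulose = which(a$resname %in% c("GLC", "DAG")),
                water = which(a$resname %in% .WATER_RESNAMES),
                all = seq_len(nrow(a)))
  if (!is.null(chains)) idx <- idx[a$chain_id[idx] %in% chains]
  idx
}

# O-H covalent assignments within a set of atom indices: from the bond
# table when available, else geometric (O-H pairs within 0.115 nm).
.donor_table <- function(frame, idx) {
  a <- frame$atoms
  isO <- a$element == "O"
  isH <- a$element == "H"
  if (!is.null(frame$bonds) && nrow(frame$bonds)) {
    b <- frame$bonds
    oh <- rbind(b[isO[b[, 1]] & isH[b[, 2]], , drop = FALSE],
                b[isO[b[, 2]] & isH[b[, 1]], 2:1, drop = FALSE])
  } else {
    iO <- which(isO)
    iH <- which(isH)
    xyz <- as.matrix(a[, c("x", "y", "z")])
    np <- neighbor_pairs_cpp(xyz[iO, , drop = FALSE],
                             xyz[iH, , drop = FALSE], 0.115)
    oh <- cbind(iO[np$i], iH[np$j])
  }
  oh[oh[, 1] %in% idx, , drop = FALSE]
}

#' Detect hydrogen bonds between two atom groups
#'
#' Counts directed bonds D-H...A with the donor hydroxyl in one group and
#' the acceptor oxygen in the other, in both directions (once only when
#' the groups are identical). When the groups contain glucose units the
#' count is also normalized per glucose unit.
#'
#' @param frame A `cnc_frame`.
#' @param group_donor,group_acceptor Atom index vectors or the keywords
#'   accepted by [select_atoms()].
#' @param criteria An [hbond_criteria()] object.
#' @return An `hbond_result`: list with `count`, `per_glucose`,
#'   `n_donors`, `n_acceptors`, `criteria` and the bond table `pairs`.
#' @export
detect_hbonds <- function(frame, group_donor = "cellulose",
                          group_acceptor = group_donor,
                          criteria = hbond_criteria()) {
  stopifnot(inherits(criteria, "hbond_criteria"))
  a <- frame$atoms
  g1 <- if (is.character(group_donor)) select_atoms(frame, group_donor) else
    as.integer(group_donor)
  g2 <- if (is.character(group_acceptor)) select_atoms(frame, group_acceptor) else
    as.integer(group_acceptor)
  lab1 <- if (is.character(group_donor)) group_donor else "group_donor"
  lab2 <- if (is.character(group_acceptor)) group_acceptor else "group_acceptor"
  if (!any(a$element[g1] == "H"))
    stop("group '", lab1, "' contains no hydrogens: cannot define donors")
  if (!any(a$element[g2] == "H"))
    stop("group '", lab2, "' contains no hydrogens: cannot define donors")

  xyz <- as.matrix(a[, c("x", "y", "z")])
  identical_groups <- length(g1) == length(g2) && all(sort(g1) == sort(g2))

  one_direction <- function(gd, ga) {
    dt <- .donor_table(frame, gd)
    if (!nrow(dt)) return(NULL)
    accO <- intersect(which(a$element == "O"), ga)
    if (!length(accO)) return(NULL)
    uD <- sort(unique(dt[, 1]))
    np <- neighbor_pairs_cpp(xyz[uD, , drop = FALSE],
                             xyz[accO, , drop = FALSE],
                             criteria$dist_cutoff)
    if (!length(np$i)) return(NULL)
    Didx <- uD[np$i]
    Aidx <- accO[np$j]
    keep <- Didx != Aidx
    Didx <- Didx[keep]; Aidx <- Aidx[keep]; dda <- np$d[keep]
    if (!length(Didx)) return(NULL)
    # expand over the hydrogens of each donor oxygen
    hs <- split(dt[, 2], dt[, 1])
    nh <- lengths(hs[as.character(Didx)])
    Dexp <- rep(Didx, nh)
    Aexp <- rep(Aidx, nh)
    dexp <- rep(dda, nh)
    Hexp <- unlist(hs[as.character(Didx)], use.names = FALSE)
    ang <- .angle3(xyz[Hexp, , drop = FALSE], xyz[Dexp, , drop = FALSE],
                   xyz[Aexp, , drop = FALSE])
    ok <- ang <= criteria$angle_cutoff
    data.frame(donor = Dexp[ok], hydrogen = Hexp[ok], acceptor = Aexp[ok],
               dist = dexp[ok], angle = ang[ok])
  }

  pairs <- one_direction(g1, g2)
  if (!identical_groups) {
    pairs <- rbind(pairs, one_direction(g2, g1))
  }
  if (is.null(pairs))
    pairs <- data.frame(donor = integer(), hydrogen = integer(),
                        acceptor = integer(), dist = numeric(),
                        angle = numeric())
  cell <- union(g1, g2)
  cell <- cell[a$resname[cell] %in% c("GLC", "DAG")]
  n_glc <- if (length(cell))
    nrow(unique(a[cell, c("chain_id", "unit")])) else NA_integer_
  structure(list(count = nrow(pairs),
                 per_glucose = if (is.na(n_glc)) NA_real_ else
                   nrow(pairs) / n_glc,
                 n_glucose = n_glc,
                 n_donors = length(unique(pairs$donor)),
                 n_acceptors = length(unique(pairs$acceptor)),
                 criteria = criteria, pairs = pairs),
            class = "hbond_result")
}
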