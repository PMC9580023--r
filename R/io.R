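# Structure file I/O: PDB (via bio3d, plus CONECT handling) and GRO
# (fixed-column, nm; no R package in the stack reads GRO, so the parser
# and writer live here). Internal coordinates are nm; PDB files are
# Angstrom per the format standard.

.CHAIN_CHARS <- c(LETTERS, letters, 0:9)

.ordered_atoms <- function(frame) {
  a <- frame$atoms
  ord <- order(a$chain_id, a$unit, a$ord %||% seq_len(nrow(a)))
  list(atoms = a[ord, , drop = FALSE], perm = ord)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a structure file (PDB or GRO)
#'
#' PDB files carry chain identifiers (cycling A-Z, a-z, 0-9), residue
#' names (`GLC` for native glucose, `DAG` for dialcohol units, `SOL` for
#' water) and, when the frame has a bond table, CONECT records in which
#' modified units have no C2-C3 bond. GRO files are fixed-column with nm
#' coordinates; chain boundaries are recoverable from residue-number
#' resets.
#'
#' @param frame A `cnc_frame` or `cnc_crystal`.
#' @param path Output path; format inferred from the `.pdb`/`.gro`
#'   extension unless `format` is given.
#' @param format `"auto"`, `"pdb"` or `"gro"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(frame, path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("pdb", "gro"))
      stop("unknown structure format for extension '", ext,
           "': use .pdb or .gro or pass format=")
    format <- ext
  }
  oa <- .ordered_atoms(frame)
  a <- oa$atoms
  n <- nrow(a)
  chain_char <- .CHAIN_CHARS[(a$chain_id %% length(.CHAIN_CHARS)) + 1]
  resno <- a$unit + 1L

  if (format == "pdb") {
    # fixed-width ATOM records assembled in one vectorized pass (the
    # reader side stays with bio3d, which validates this layout in the
    # round-trip tests)
    xyz <- as.matrix(a[, c("x", "y", "z")]) * 10
    name4 <- ifelse(nchar(a$name) < 4,
                    sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
    rec <- paste0(
      "ATOM  ", formatC(((seq_len(n) - 1L) %% 99999L) + 1L, width = 5),
      " ", name4, " ", formatC(a$resname, width = -3), " ", chain_char,
      formatC(((resno - 1L) %% 9999L) + 1L, width = 4), "    ",
      formatC(xyz[, 1], format = "f", digits = 3, width = 8),
      formatC(xyz[, 2], format = "f", digits = 3, width = 8),
      formatC(xyz[, 3], format = "f", digits = 3, width = 8),
      "  1.00  0.00          ", formatC(a$element, width = 2))
    writeLines(c(rec, "END"), path)
    if (!is.null(frame$bonds) && nrow(frame$bonds)) {
      inv <- integer(n)
      inv[oa$perm] <- seq_len(n)   # old row -> serial
      b1 <- inv[frame$bonds[, 1]]
      b2 <- inv[frame$bonds[, 2]]
      # per-atom partner lists, both directions, <=4 partners per line
      s <- c(b1, b2)
      p <- c(b2, b1)
      o <- order(s, p)
      s <- s[o]; p <- p[o]
      keep <- c(TRUE, s[-1] != s[-length(s)] | p[-1] != p[-length(p)])
      s <- s[keep]; p <- p[keep]
      rank <- stats::ave(seq_along(s), s, FUN = seq_along)
      line_id <- s * 8 + (rank - 1) %/% 4   # groups partners 4 per line
      ptxt <- formatC(p, width = 5)
      body <- vapply(split(ptxt, line_id), paste0, "", collapse = "")
      lead <- formatC(vapply(split(s, line_id), `[`, 0L, 1L), width = 5)
      con <- paste0("CONECT", lead, body)
      lines <- readLines(path)
      endi <- which(lines == "END")
      if (length(endi)) {
        lines <- append(lines, con, after = min(endi) - 1)
      } else lines <- c(lines, con)
      writeLines(lines, path)
    }
  } else {
    xyz <- as.matrix(a[, c("x", "y", "z")])
    box <- apply(xyz, 2, function(v) diff(range(v))) + 0.2
    lines <- c(
      "dacnc structure",
      sprintf("%5d", n),
      sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
              ((resno - 1L) %% 99999L) + 1L, a$resname,
              substr(a$name, 1, 5), ((seq_len(n) - 1L) %% 99999L) + 1L,
              xyz[, 1], xyz[, 2], xyz[, 3]),
      sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a structure file (PDB or GRO)
#'
#' Returns a `cnc_frame`. Chains are reconstructed from chain identifiers
#' (PDB) or residue-number resets (GRO); units (residues) are 0-based;
#' the dialcohol flag is recovered from the `DAG` residue name; CONECT
#' records, when present, populate the bond table.
#'
#' @param path Input file.
#' @param format `"auto"`, `"pdb"` or `"gro"`.
#' @param multi For multi-model PDB files, return a list of frames
#'   (default `FALSE`: first model only).
#' @return A `cnc_frame`, or a list of frames when `multi = TRUE`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           multi = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("pdb", "gro"))
      stop("unknown structure format for extension '", ext, "'")
    format <- ext
  }
  if (format == "pdb") .read_pdb(path, multi) else .read_gro(path)
}

.chain_ids_from <- function(chain_char, resno) {
  # new chain when the chain character changes or residue numbering resets
  n <- length(chain_char)
  if (n == 0) return(integer())
  new <- c(TRUE, chain_char[-1] != chain_char[-n] |
                 resno[-1] < resno[-n])
  cumsum(new) - 1L
}

.read_pdb <- function(path, multi = FALSE) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = multi, verbose = FALSE),
                  error = function(e) {
                    ln <- .first_bad_pdb_line(path)
                    stop("malformed PDB file '", path, "'",
                         if (!is.na(ln)) paste0(" at line ", ln), ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  at <- pdb$atom
  chain_char <- ifelse(is.na(at$chain), "A", at$chain)
  frame_of <- function(xyz_row) {
    m <- matrix(xyz_row, ncol = 3, byrow = TRUE)
    atoms <- data.frame(
      name = at$elety,
      element = ifelse(!is.na(at$elesy) & nzchar(at$elesy), at$elesy,
                       .element_of(at$elety)),
      resname = at$resid,
      chain_id = .chain_ids_from(chain_char, at$resno),
      unit = at$resno - 1L,
      ord = seq_len(nrow(at)),
      x = m[, 1] / 10, y = m[, 2] / 10, z = m[, 3] / 10,
      stringsAsFactors = FALSE)
    fr <- structure(list(atoms = atoms, bonds = .read_conect(path, at$eleno)),
                    class = "cnc_frame")
    fr$box <- .frame_box(fr)
    fr
  }
  nxyz <- length(pdb$xyz) / (3 * nrow(at))
  if (multi && nxyz > 1) {
    lapply(seq_len(nxyz), function(k) frame_of(pdb$xyz[k, ]))
  } else {
    frame_of(if (is.matrix(pdb$xyz)) pdb$xyz[1, ] else pdb$xyz)
  }
}

.first_bad_pdb_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  for (i in which(rec)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (anyNA(xyz)) return(i)
  }
  NA_integer_
}

.read_conect <- function(path, serials) {
  lines <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
  if (!length(lines)) return(NULL)
  pairs <- do.call(rbind, lapply(lines, function(l) {
    f <- suppressWarnings(as.integer(
      vapply(seq(7, nchar(l), by = 5),
             function(s) substr(l, s, s + 4), "")))
    f <- f[!is.na(f)]
    if (length(f) < 2) return(NULL)
    cbind(f[1], f[-1])
  }))
  if (is.null(pairs) || !nrow(pairs)) return(NULL)
  idx <- match(pairs, serials)
  m <- matrix(idx, ncol = 2)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  m <- t(apply(m, 1, sort))
  unique(m)
}

.read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("malformed GRO file '", path, "': too short")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO file '", path, "' at line 2: bad atom count")
  if (length(lines) < 2 + n)
    stop("malformed GRO file '", path, "': expected ", n, " atom lines")
  al <- lines[3:(2 + n)]
  resno <- suppressWarnings(as.integer(substr(al, 1, 5)))
  resname <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed GRO file '", path, "' at line ", bad[1] + 2,
         ": non-numeric field")
  atoms <- data.frame(
    name = name, element = .element_of(name), resname = resname,
    chain_id = .chain_ids_from(rep("A", n), resno),
    unit = resno - 1L, ord = seq_len(n),
    x = x, y = y, z = z, stringsAsFactors = FALSE)
  fr <- structure(list(atoms = atoms, bonds = NULL), class = "cnc_frame")
  fr$box <- .frame_box(fr)
  fr
}
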