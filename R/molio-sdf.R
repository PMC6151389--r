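# SDF V2000 reading and writing.

# Effective valence for implicit-hydrogen assignment; charge shifts the
# valence of heteroatoms (N+ binds 4, O- binds 1) and reduces it for carbon.
.effectiveValence <- function(element, charge) {
  # unknown elements get no implicit hydrogens rather than failing here;
  # property assignment is where unsupported elements are reported
  tab <- elementProperties()
  v <- ifelse(element %in% rownames(tab), tab[element, "valence"], 0)
  adj <- ifelse(element %in% c("N", "P", "O", "S"), v + charge,
                v - abs(charge))
  pmax(adj, 0)
}

.computeHcount <- function(element, charge, bonds, n) {
  deg <- numeric(n)
  if (nrow(bonds)) {
    ord <- bonds$order
    for (i in seq_len(nrow(bonds))) {
      deg[bonds$a1[i]] <- deg[bonds$a1[i]] + ord[i]
      deg[bonds$a2[i]] <- deg[bonds$a2[i]] + ord[i]
    }
  }
  pmax(.effectiveValence(element, charge) - round(deg), 0)
}

#' Construct a Molecule from atom and bond tables
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix n x 3 (Angstrom) or NULL for a 2D molecule.
#' @param bonds data.frame / matrix with columns a1, a2, order (1-based).
#' @param charges integer formal charges (default 0).
#' @param name molecule title.
#' @param is3D logical; default TRUE when any non-zero z coordinate.
#' @return a [Molecule-class]; implicit hydrogen counts are derived from
#'   standard valences minus the sum of bond orders at each atom.
#' @export
newMolecule <- function(elements, coords = NULL, bonds = NULL,
                        charges = NULL, name = "", is3D = NULL) {
  n <- length(elements)
  if (is.null(coords)) coords <- matrix(0, n, 3)
  coords <- matrix(as.numeric(coords), n, 3)
  if (is.null(charges)) charges <- integer(n)
  if (is.null(bonds) || NROW(bonds) == 0) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = numeric())
  } else {
    bonds <- data.frame(a1 = as.integer(bonds[, 1]),
                        a2 = as.integer(bonds[, 2]),
                        order = as.numeric(bonds[, 3]))
  }
  if (is.null(is3D)) is3D <- any(abs(coords[, 3]) > 0)
  hc <- .computeHcount(elements, as.integer(charges), bonds, n)
  methods::new("Molecule", name = as.character(name),
    atoms = data.frame(element = as.character(elements),
                       charge = as.integer(charges),
                       x = coords[, 1], y = coords[, 2], z = coords[, 3],
                       hcount = hc, stringsAsFactors = FALSE),
    bonds = bonds, is3D = is3D,
    properties = matrix(numeric(), n, 0))
}

.num3 <- function(line, from) {
  f <- substr(line, from, from + 2)
  suppressWarnings(as.integer(f))
}

.parseRecord <- function(lines, recno, offset) {
  perr <- function(lineIdx, what)
    stop(sprintf("SDF parse error in record %d, line %d: %s",
                 recno, offset + lineIdx, what), call. = FALSE)
  if (length(lines) < 4) perr(length(lines), "truncated record header")
  counts <- lines[4]
  if (grepl("V3000", counts))
    stop(sprintf("record %d: V3000 connection tables are not supported; %s",
                 recno, "supply V2000"), call. = FALSE)
  natoms <- .num3(counts, 1); nbonds <- .num3(counts, 4)
  if (is.na(natoms) || is.na(nbonds) || natoms < 0 || nbonds < 0)
    perr(4, "malformed counts line")
  if (length(lines) < 4 + natoms + nbonds)
    perr(length(lines), "fewer atom/bond lines than the counts line declares")
  el <- character(natoms); xs <- ys <- zs <- numeric(natoms)
  ccode <- integer(natoms)
  for (i in seq_len(natoms)) {
    ln <- lines[4 + i]
    x <- suppressWarnings(as.numeric(substr(ln, 1, 10)))
    y <- suppressWarnings(as.numeric(substr(ln, 11, 20)))
    z <- suppressWarnings(as.numeric(substr(ln, 21, 30)))
    e <- trimws(substr(ln, 32, 34))
    if (is.na(x) || is.na(y) || is.na(z) || !nzchar(e))
      perr(4 + i, "malformed atom line")
    xs[i] <- x; ys[i] <- y; zs[i] <- z; el[i] <- e
    cc <- .num3(ln, 37)
    ccode[i] <- if (is.na(cc)) 0L else cc
  }
  # V2000 atom-block charge codes: 1..3 = +3..+1, 5..7 = -1..-3
  chg <- integer(natoms)
  pos <- ccode >= 1 & ccode <= 3
  neg <- ccode >= 5 & ccode <= 7
  chg[pos] <- 4L - ccode[pos]
  chg[neg] <- 4L - ccode[neg]
  b1 <- b2 <- integer(nbonds); bo <- numeric(nbonds)
  for (i in seq_len(nbonds)) {
    ln <- lines[4 + natoms + i]
    a1 <- .num3(ln, 1); a2 <- .num3(ln, 4); o <- .num3(ln, 7)
    if (is.na(a1) || is.na(a2) || is.na(o)) perr(4 + natoms + i,
                                                 "malformed bond line")
    if (a1 < 1 || a1 > natoms || a2 < 1 || a2 > natoms)
      perr(4 + natoms + i, sprintf("bond index %d-%d out of range", a1, a2))
    b1[i] <- a1; b2[i] <- a2
    bo[i] <- if (o == 4) 1.5 else o
  }
  # property block: M CHG overrides all atom-block charges
  rest <- lines[seq.int(4 + natoms + nbonds + 1, length.out =
                          max(0, length(lines) - 4 - natoms - nbonds))]
  chgLines <- grep("^M  CHG", rest, value = TRUE)
  if (length(chgLines)) {
    chg <- integer(natoms)
    for (cl in chgLines) {
      nn <- .num3(cl, 7)
      if (is.na(nn)) next
      for (j in seq_len(nn)) {  # entries are 4-wide " aaa vvvv" pairs
        at <- suppressWarnings(as.integer(substr(cl, 10 + (j - 1) * 8,
                                                 13 + (j - 1) * 8)))
        vv <- suppressWarnings(as.integer(substr(cl, 14 + (j - 1) * 8,
                                                 17 + (j - 1) * 8)))
        if (!is.na(at) && at >= 1 && at <= natoms && !is.na(vv))
          chg[at] <- vv
      }
    }
  }
  is3D <- any(abs(zs) > 0) || grepl("3D", substr(lines[2], 21, 22))
  newMolecule(el, cbind(xs, ys, zs),
              data.frame(a1 = b1, a2 = b2, order = bo),
              charges = chg, name = trimws(lines[1]), is3D = is3D)
}

#' Read molecules from an SDF V2000 document
#'
#' Parses a concatenation of V2000 records terminated by `$$$$`. Atom
#' order, coordinates (Angstrom) and formal charges (atom-block codes,
#' overridden by `M CHG` property lines as the format prescribes) are
#' preserved. A molecule is flagged 3D when any z coordinate is non-zero
#' or the header's dimension field says `3D`. V3000 records are rejected.
#'
#' @param input path to an SDF file, or a character vector of lines, or a
#'   single string containing the whole document.
#' @param skipErrors if TRUE, malformed records are dropped with a warning
#'   instead of failing the whole read.
#' @return list of [Molecule-class] objects.
#' @export
readMoleculesSDF <- function(input, skipErrors = FALSE) {
  lines <- if (length(input) == 1 && !grepl("\n", input) &&
               file.exists(input)) readLines(input, warn = FALSE)
           else if (length(input) == 1)
             strsplit(input, "\n", fixed = TRUE)[[1]]
           else input  # already a vector of lines
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) {
    if (all(!nzchar(trimws(lines)))) return(list())
    ends <- length(lines)  # single record without terminator
  }
  out <- list(); start <- 1L; recno <- 0L
  for (e in ends) {
    rec <- lines[start:e]
    rec <- rec[!grepl("^\\$\\$\\$\\$", rec)]
    if (!any(nzchar(trimws(rec)))) { start <- e + 1L; next }
    recno <- recno + 1L
    mol <- if (skipErrors)
      tryCatch(.parseRecord(rec, recno, start - 1L),
               error = function(err) { warning(conditionMessage(err),
                                               call. = FALSE); NULL })
    else .parseRecord(rec, recno, start - 1L)
    if (!is.null(mol)) out[[length(out) + 1L]] <- mol
    start <- e + 1L
  }
  out
}

.chargeCode <- function(chg) {
  code <- integer(length(chg))
  code[chg >= 1 & chg <= 3] <- 4L - chg[chg >= 1 & chg <= 3]
  code[chg <= -1 & chg >= -3] <- 4L - chg[chg <= -1 & chg >= -3]
  code
}

#' Write molecules to SDF V2000
#'
#' Coordinates are written at the V2000 precision of 4 decimals, so a
#' read/write round trip is bit-stable at that precision. Non-zero formal
#' charges are emitted as `M CHG` property lines.
#'
#' @param mols a [Molecule-class] or list of them.
#' @param path output file; if NULL the SDF text is returned invisibly.
#' @return character vector of SDF lines, invisibly.
#' @export
writeMoleculesSDF <- function(mols, path = NULL) {
  if (methods::is(mols, "Molecule")) mols <- list(mols)
  out <- character()
  for (m in mols) {
    a <- m@atoms; b <- m@bonds
    # dimensionality code sits at columns 21-22 of the second header line
    hdr <- c(m@name, sprintf("  KinomeQSAR        %s",
                             if (m@is3D) "3D" else "2D"), "")
    counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                      nrow(a), nrow(b))
    atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                     a$x, a$y, a$z, a$element, .chargeCode(a$charge))
    bonds <- if (nrow(b)) sprintf("%3d%3d%3d  0  0  0  0", b$a1, b$a2,
                                  ifelse(b$order == 1.5, 4L,
                                         as.integer(round(b$order))))
             else character()
    props <- character()
    idx <- which(a$charge != 0)
    while (length(idx)) {
      take <- idx[seq_len(min(8, length(idx)))]
      idx <- idx[-seq_len(min(8, length(idx)))]
      props <- c(props, paste0(sprintf("M  CHG%3d", length(take)),
                               paste(sprintf("%4d%4d", take,
                                             a$charge[take]),
                                     collapse = "")))
    }
    out <- c(out, hdr, counts, atoms, bonds, props, "M  END", "$$$$")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Interatomic distance matrix of a 3D molecule
#'
#' @param mol a 3D [Molecule-class].
#' @return symmetric matrix of pairwise distances in Angstrom.
#' @export
distanceMatrix <- function(mol) {
  if (!mol@is3D)
    stop("molecule '", mol@name, "' has no 3D coordinates; ",
         "supply an SDF with a 3D conformation")
  as.matrix(stats::dist(cbind(mol@atoms$x, mol@atoms$y, mol@atoms$z)))
}
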