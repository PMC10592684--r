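# PDB reading and writing (ATOM/HETATM fixed-column records).

#' Read a PDB file or text into a Structure
#'
#' Parses ATOM/HETATM records with standard columns. Alternate locations
#' are resolved to the highest-occupancy copy of each atom; insertion codes
#' are retained in the author numbering. Residues missing any of N/CA/C
#' are reported in a warning and attached as the `flagged` attribute.
#'
#' @param input path to a PDB file, or a character vector of PDB lines.
#' @param entities optional chain -> entity mapping (see [new_structure()]).
#' @return A `Structure`.
#' @export
read_pdb <- function(input, entities = NULL) {
  lines <- if (length(input) == 1L && !grepl("\n", input) &&
               file.exists(input)) readLines(input, warn = FALSE)
           else unlist(strsplit(input, "\n", fixed = TRUE))
  rec <- substr(lines, 1, 6)
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!length(sel)) stop("no ATOM/HETATM records found")
  ln <- lines[sel]
  fx <- function(a, b) substr(ln, a, b)
  num <- function(txt, what) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v) & trimws(txt) != "")
    if (length(bad)) {
      stop(sprintf("format error at line %d: non-numeric %s field '%s'",
                   sel[bad[1]], what, trimws(txt[bad[1]])))
    }
    v
  }
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(trimws(fx(7, 11)))),
    name = trimws(fx(13, 16)),
    altloc = trimws(fx(17, 17)),
    resn = trimws(fx(18, 20)),
    chain = trimws(fx(22, 22)),
    resi = as.integer(num(trimws(fx(23, 26)), "residue number")),
    icode = trimws(fx(27, 27)),
    x = num(fx(31, 38), "x"),
    y = num(fx(39, 46), "y"),
    z = num(fx(47, 54), "z"),
    occ = num(fx(55, 60), "occupancy"),
    element = trimws(fx(77, 78)),
    stringsAsFactors = FALSE)
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z)) {
    i <- which(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z))[1]
    stop(sprintf("format error at line %d: missing coordinate", sel[i]))
  }
  atoms$occ[is.na(atoms$occ)] <- 1
  # altloc resolution: keep the highest-occupancy copy of each atom
  akey <- paste(atoms$chain, atoms$resi, atoms$icode, atoms$name)
  if (any(atoms$altloc != "")) {
    ord <- order(akey, -atoms$occ)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(akey[ord]), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  atoms$altloc <- NULL
  s <- new_structure(atoms, entities = entities)
  flagged <- flag_incomplete_backbone(s)
  if (nrow(flagged)) {
    warning(sprintf("%d residue(s) missing backbone atoms (N/CA/C): %s",
                    nrow(flagged),
                    paste(utils::head(paste0(flagged$chain, flagged$resi), 5),
                          collapse = ", ")))
  }
  attr(s, "flagged") <- flagged
  s
}

#' Write a Structure as PDB text
#'
#' @param s Structure.
#' @param path optional output file; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`), the PDB lines.
#' @export
write_pdb <- function(s, path = NULL) {
  a <- s$atoms
  name4 <- ifelse(nchar(a$name) >= 4, a$name, paste0(" ", a$name))
  name4 <- formatC(name4, width = -4)
  lines <- character(0)
  serial <- 0L
  for (ch in unique(a$chain)) {
    idx <- which(a$chain == ch)
    for (i in idx) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, name4[i], " ", a$resn[i], ch, a$resi[i],
        ifelse(a$icode[i] == "", " ", a$icode[i]),
        a$x[i], a$y[i], a$z[i], a$occ[i], 0,
        a$element[i]))
    }
    last <- idx[length(idx)]
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d",
                              serial, a$resn[last], ch, a$resi[last]))
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
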