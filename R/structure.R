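# The Structure data model: a flat atom table plus entity bookkeeping.
# All geometry in the package operates on this container.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3TO1 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
            GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
            MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
            SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y",
            MSE = "M", SEC = "C")

AA1TO3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
            G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
            M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
            S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Construct a Structure
#'
#' @param atoms data frame with columns `serial`, `name`, `resn`, `chain`,
#'   `resi`, `icode`, `x`, `y`, `z`, `occ`, `element`. Missing `element`
#'   values are inferred from the atom name; a logical `polar` column
#'   (N/O/S atoms) is derived.
#' @param entities optional named character vector mapping chain id to an
#'   entity label (chains that are copies of the same protein share a
#'   label). Defaults to one entity per chain.
#' @return Object of class `Structure`.
#' @export
new_structure <- function(atoms, entities = NULL) {
  req <- c("name", "resn", "chain", "resi", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ",
                         paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$element) || any(is.na(atoms$element)) ||
      any(atoms$element == "")) {
    atoms$element <- element_from_name(atoms$name)
  }
  atoms$polar <- atoms$element %in% c("N", "O", "S")
  atoms$resi <- as.integer(atoms$resi)
  if (is.null(entities)) {
    ch <- unique(atoms$chain)
    entities <- stats::setNames(ch, ch)
  }
  structure(list(atoms = atoms, entities = entities), class = "Structure")
}

# Element symbol from a PDB atom name (digits stripped, first letter).
element_from_name <- function(name) {
  el <- toupper(gsub("[^A-Za-z].*|(?<=.).*", "", gsub("[0-9']", "", name),
                     perl = TRUE))
  el[el == ""] <- "C"
  el
}

#' @export
print.Structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("Structure: %d atoms, %d residues, %d chains (%s)\n",
              nrow(x$atoms), nrow(rt), length(unique(x$atoms$chain)),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Coordinate matrix of a Structure
#' @param s Structure.
#' @param sel optional logical/integer atom selection.
#' @export
atom_coords <- function(s, sel = NULL) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  if (!is.null(sel)) m <- m[sel, , drop = FALSE]
  m
}

set_atom_coords <- function(s, xyz) {
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Residue table (one row per chain/residue)
#' @param s Structure.
#' @export
residue_table <- function(s) {
  key <- paste(s$atoms$chain, s$atoms$resi, s$atoms$icode, sep = "|")
  keep <- !duplicated(key)
  data.frame(chain = s$atoms$chain[keep], resi = s$atoms$resi[keep],
             icode = s$atoms$icode[keep], resn = s$atoms$resn[keep],
             stringsAsFactors = FALSE)
}

residue_key <- function(chain, resi, icode = "") {
  paste(chain, resi, icode, sep = "|")
}

atom_residue_key <- function(s) {
  residue_key(s$atoms$chain, s$atoms$resi, s$atoms$icode)
}

#' Apply a rigid transform to a Structure
#' @param s Structure.
#' @param tf `rigid_transform`.
#' @export
transform_structure <- function(s, tf) {
  set_atom_coords(s, transform_points(atom_coords(s), tf))
}

#' Subset a Structure by atom index
#' @param s Structure.
#' @param idx logical or integer atom selection.
#' @export
structure_subset <- function(s, idx) {
  atoms <- s$atoms[idx, , drop = FALSE]
  keep <- intersect(names(s$entities), unique(atoms$chain))
  new_structure(atoms, entities = s$entities[keep])
}

#' Concatenate Structures into one
#'
#' Chain ids must be unique across the inputs; entities are merged.
#' @param ... Structure objects (or a single list of them).
#' @export
combine_structures <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "Structure")) xs <- xs[[1]]
  atoms <- do.call(rbind, lapply(xs, function(s) s$atoms))
  ent <- do.call(c, lapply(xs, function(s) s$entities))
  if (anyDuplicated(names(ent))) stop("duplicate chain ids when combining")
  atoms$serial <- seq_len(nrow(atoms))
  new_structure(atoms, entities = ent)
}

#' One-letter sequence of a chain
#' @param s Structure.
#' @param chain chain id (default: first chain).
#' @export
get_sequence <- function(s, chain = NULL) {
  if (is.null(chain)) chain <- s$atoms$chain[1]
  rt <- residue_table(s)
  rt <- rt[rt$chain == chain, , drop = FALSE]
  aa <- AA3TO1[rt$resn]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' C-beta proxy coordinates per residue
#'
#' Returns one coordinate per residue: the C-beta atom, or the C-alpha for
#' glycine (and for any residue lacking a C-beta).
#'
#' @param s Structure.
#' @return list with `res` (residue table) and `xyz` (n x 3 matrix).
#' @export
cbeta_coords <- function(s) {
  rt <- residue_table(s)
  keys <- residue_key(rt$chain, rt$resi, rt$icode)
  akey <- atom_residue_key(s)
  xyz <- matrix(NA_real_, nrow(rt), 3)
  for (i in seq_len(nrow(rt))) {
    in_res <- which(akey == keys[i])
    j <- in_res[s$atoms$name[in_res] == "CB"]
    if (!length(j) || rt$resn[i] == "GLY") {
      j <- in_res[s$atoms$name[in_res] == "CA"]
    }
    if (length(j)) xyz[i, ] <- as.numeric(s$atoms[j[1], c("x", "y", "z")])
  }
  list(res = rt, xyz = xyz)
}

#' Flag residues missing backbone atoms
#' @param s Structure.
#' @return data frame of chain/resi lacking any of N, CA, C.
#' @export
flag_incomplete_backbone <- function(s) {
  rt <- residue_table(s)
  keys <- residue_key(rt$chain, rt$resi, rt$icode)
  akey <- atom_residue_key(s)
  bad <- logical(nrow(rt))
  for (i in seq_len(nrow(rt))) {
    nm <- s$atoms$name[akey == keys[i]]
    bad[i] <- !all(c("N", "CA", "C") %in% nm)
  }
  rt[bad, , drop = FALSE]
}

#' C-beta to C-beta neighbor pairs between two residue sets
#'
#' Distances are measured between C-beta atoms, using the C-alpha for
#' glycine. The pair list is symmetric: swapping `query` and `target`
#' returns the same unordered pairs.
#'
#' @param s Structure.
#' @param query,target data frames with `chain` and `resi` columns
#'   (defaults: all residues).
#' @param cutoff inclusive distance cutoff in Angstrom (9 for docking
#'   measurements, 8 for design, per the interface-residue convention).
#' @return data frame of pairs with their distance.
#' @export
cbeta_neighbors <- function(s, query = NULL, target = NULL, cutoff = 8) {
  cb <- cbeta_coords(s)
  keys <- residue_key(cb$res$chain, cb$res$resi, cb$res$icode)
  pick <- function(set) {
    if (is.null(set)) return(seq_along(keys))
    ic <- if (is.null(set$icode)) "" else set$icode
    match(residue_key(set$chain, set$resi, ic), keys)
  }
  qi <- pick(query); ti <- pick(target)
  qi <- qi[!is.na(qi)]; ti <- ti[!is.na(ti)]
  if (!length(qi) || !length(ti)) {
    return(data.frame(chain_a = character(), resi_a = integer(),
                      chain_b = character(), resi_b = integer(),
                      dist = numeric(), stringsAsFactors = FALSE))
  }
  A <- cb$xyz[qi, , drop = FALSE]; B <- cb$xyz[ti, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  hit <- which(sqrt(d2) <= cutoff & outer(qi, ti, "!="), arr.ind = TRUE)
  data.frame(chain_a = cb$res$chain[qi[hit[, 1]]],
             resi_a = cb$res$resi[qi[hit[, 1]]],
             chain_b = cb$res$chain[ti[hit[, 2]]],
             resi_b = cb$res$resi[ti[hit[, 2]]],
             dist = sqrt(d2[hit]), stringsAsFactors = FALSE)
}
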