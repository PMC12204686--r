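# Structure I/O: PDB and mmCIF readers, a PDB writer, chain selection.
# Hand-rolled because no structural-bioinformatics reader is available in
# this R stack; only the fields the analyses need are parsed.

.elementFromName <- function(name) {
  # Fallback for files lacking the element column. Protein/nucleic heavy
  # atoms start with C/N/O/S/P/H; anything else is tried as a two-letter
  # element (FE, ZN, MG, ...). Ambiguities such as CA (alpha-carbon vs
  # calcium) resolve to the biopolymer reading; files with ions should carry
  # the element column.
  nm <- toupper(gsub("[0-9']", "", trimws(name)))
  one <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  ifelse(one %in% c("C", "N", "O", "S", "P", "H"), one,
         ifelse(two %in% names(VDW_RADII), two, one))
}

.buildAtoms <- function(serial, name, altloc, resname, chain, resnum, icode,
                        x, y, z, occ, element, hetero) {
  el <- toupper(trimws(element))
  fallback <- el == "" | is.na(el)
  if (any(fallback)) el[fallback] <- .elementFromName(name[fallback])
  atoms <- data.frame(
    serial = as.integer(serial), name = trimws(name), resname = trimws(resname),
    chain = trimws(chain), resnum = as.integer(resnum),
    icode = trimws(icode), x = as.numeric(x), y = as.numeric(y),
    z = as.numeric(z), occ = as.numeric(occ), element = el,
    hetero = hetero, stringsAsFactors = FALSE
  )
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$vdw <- vdwRadius(atoms$element, atoms$serial)
  # waters are always flagged hetero regardless of record type
  atoms$hetero <- atoms$hetero | atoms$resname %in% c("HOH", "WAT", "DOD")
  # alternate locations: keep the highest-occupancy conformer per atom
  al <- trimws(altloc)
  if (any(al != "")) {
    key <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$name, sep = "\r")
    ord <- order(key, -atoms$occ, atoms$serial)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resnum, atoms$icode,
                                     atoms$name, sep = "\r")), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  atoms
}

.parsePdbAtoms <- function(lines, path) {
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  idx <- which(keep)
  if (!length(idx)) stop("no ATOM/HETATM records in ", path)
  ln <- lines[idx]
  serial <- suppressWarnings(as.integer(substr(ln, 7, 11)))
  x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(serial))
  if (length(bad))
    stop(sprintf("unparseable ATOM record at line %d of %s", idx[bad[1]], path))
  .buildAtoms(
    serial = serial, name = substr(ln, 13, 16), altloc = substr(ln, 17, 17),
    resname = substr(ln, 18, 20), chain = substr(ln, 22, 22),
    resnum = suppressWarnings(as.integer(substr(ln, 23, 26))),
    icode = substr(ln, 27, 27), x = x, y = y, z = z,
    occ = suppressWarnings(as.numeric(substr(ln, 55, 60))),
    element = substr(ln, 77, 78), hetero = substr(ln, 1, 6) == "HETATM"
  )
}

# Minimal whitespace tokenizer honouring single/double quotes (mmCIF rows).
.cifTokens <- function(line) {
  toks <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

.parseCifAtoms <- function(lines, path) {
  loops <- which(trimws(lines) == "loop_")
  for (start in loops) {
    i <- start + 1L
    tags <- character(0)
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1L
    }
    if (!length(tags) || !startsWith(tags[1], "_atom_site.")) next
    fields <- sub("^_atom_site\\.", "", tags)
    rows <- list()
    while (i <= length(lines)) {
      tl <- trimws(lines[i])
      if (tl == "" || startsWith(tl, "#") || tl == "loop_" || startsWith(tl, "_")) break
      rows[[length(rows) + 1L]] <- .cifTokens(lines[i])
      i <- i + 1L
    }
    if (!length(rows)) stop("empty _atom_site loop in ", path)
    nf <- lengths(rows)
    if (any(nf != length(fields)))
      stop(sprintf("mmCIF row %d has %d fields, expected %d (%s)",
                   which(nf != length(fields))[1], nf[nf != length(fields)][1],
                   length(fields), path))
    m <- do.call(rbind, rows)
    colnames(m) <- fields
    get <- function(primary, alt = NULL, default = "") {
      if (primary %in% fields) m[, primary]
      else if (!is.null(alt) && alt %in% fields) m[, alt]
      else rep(default, nrow(m))
    }
    clean <- function(v) ifelse(v %in% c("?", "."), "", v)
    model <- get("pdbx_PDB_model_num", default = "1")
    first <- model == model[1]
    sel <- function(v) v[first]
    return(.buildAtoms(
      serial = sel(get("id")),
      name = sel(clean(get("auth_atom_id", "label_atom_id"))),
      altloc = sel(clean(get("label_alt_id"))),
      resname = sel(clean(get("auth_comp_id", "label_comp_id"))),
      chain = sel(clean(get("auth_asym_id", "label_asym_id"))),
      resnum = sel(clean(get("auth_seq_id", "label_seq_id"))),
      icode = sel(clean(get("pdbx_PDB_ins_code"))),
      x = sel(get("Cartn_x")), y = sel(get("Cartn_y")), z = sel(get("Cartn_z")),
      occ = sel(get("occupancy", default = "1")),
      element = sel(clean(get("type_symbol"))),
      hetero = sel(get("group_PDB", default = "ATOM")) == "HETATM"
    ))
  }
  stop("no _atom_site loop found in ", path)
}

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Parses all ATOM/HETATM records of the first model. Author residue
#' numbering is preserved; waters are retained but flagged hetero; alternate
#' locations are reduced to the highest-occupancy conformer; structures are
#' treated as heavy-atom-only downstream (hydrogens, if present, are kept in
#' the atom table but every geometric criterion in this package is defined on
#' heavy atoms of the selections it draws).
#'
#' @param path file path.
#' @param format "auto" (by extension), "pdb" or "mmcif".
#' @param id structure identifier; defaults to the file stem.
#' @return a [SpiroStructure-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  atoms <- switch(format,
    pdb = .parsePdbAtoms(lines, path),
    mmcif = .parseCifAtoms(lines, path)
  )
  new("SpiroStructure",
      id = id %||% sub("\\.[^.]*$", "", basename(path)),
      atoms = atoms,
      metadata = list(source = path, format = format))
}

#' Construct a structure from an atom table
#'
#' Used by the synthetic-data generators and by tests; `vdw` is filled from
#' the package radius table when absent.
#'
#' @param atoms data.frame with at least serial, name, resname, chain,
#'   resnum, x, y, z, element columns.
#' @param id identifier string.
#' @param metadata provenance list.
#' @return a [SpiroStructure-class].
#' @export
newStructure <- function(atoms, id = "synthetic", metadata = list()) {
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$hetero)) atoms$hetero <- FALSE
  if (is.null(atoms$vdw)) atoms$vdw <- vdwRadius(atoms$element, atoms$serial)
  atoms <- atoms[, c("serial", "name", "resname", "chain", "resnum", "icode",
                     "x", "y", "z", "occ", "element", "vdw", "hetero")]
  rownames(atoms) <- NULL
  new("SpiroStructure", id = id, atoms = atoms, metadata = metadata)
}

#' Write a structure as a PDB file
#'
#' @param structure a [SpiroStructure-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeStructurePDB <- function(structure, path) {
  a <- atomData(structure)
  name4 <- ifelse(nchar(a$name) >= 4 | nchar(a$element) >= 2,
                  sprintf("%-4s", a$name), sprintf(" %-3s", a$name))
  rec <- ifelse(a$hetero, "HETATM", "ATOM  ")
  lines <- sprintf("%s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, a$serial %% 100000L, name4, a$resname,
                   substr(paste0(a$chain, " "), 1, 1), a$resnum %% 10000L,
                   substr(paste0(a$icode, " "), 1, 1),
                   a$x, a$y, a$z, a$occ, 0, toupper(a$element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Select chains from a structure
#'
#' @param structure a [SpiroStructure-class].
#' @param chains character vector of chain identifiers to keep.
#' @return a [SpiroStructure-class] containing exactly those chains, atoms unchanged.
#' @export
selectChains <- function(structure, chains) {
  have <- unique(atomData(structure)$chain)
  missing <- setdiff(chains, have)
  if (length(missing))
    stop("chain(s) not present in structure: ", paste(missing, collapse = ", "))
  a <- atomData(structure)
  new("SpiroStructure", id = structureId(structure),
      atoms = a[a$chain %in% chains, , drop = FALSE],
      metadata = c(structure@metadata, list(selection = chains)))
}

# Polymer (non-hetero) subset used by SASA and contact analyses.
.polymerAtoms <- function(structure, includeHetero = FALSE) {
  a <- atomData(structure)
  if (!includeHetero) a <- a[!a$hetero, , drop = FALSE]
  a
}

#' One-letter sequence of a chain, ordered by author residue number
#'
#' Non-standard residues are represented as "X".
#'
#' @param structure a [SpiroStructure-class].
#' @param chain chain identifier.
#' @return list with `seq` (string) and `keys` (residue key per position).
#' @export
chainSequence <- function(structure, chain) {
  a <- atomData(selectChains(structure, chain))
  a <- a[!a$hetero, , drop = FALSE]
  key <- residueKey(a$chain, a$resnum, a$icode)
  first <- !duplicated(key)
  ord <- order(a$resnum[first], a$icode[first])
  resname <- a$resname[first][ord]
  keys <- key[first][ord]
  letters1 <- ifelse(resname %in% names(AA3), AA3[resname], "X")
  list(seq = paste(letters1, collapse = ""), keys = keys)
}
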