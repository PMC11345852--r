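#' @name macro_structure
#' @title Macromolecular structure container
#' @description
#' A light S3 wrapper around an atom table parsed from PDB text. Fields:
#' `atoms` -- data.frame with `chain`, `resno`, `insert`, `resname`,
#' `atom` (atom name), `element`, `x`, `y`, `z` (angstrom), `occupancy`;
#' `chains` -- data.frame with `chain` and `kind`
#' (`protein` / `nucleic` / `other`), classified from residue names
#' (standard amino acids vs ribo/deoxyribo nucleotides). Waters, ions and
#' other heteroatoms are retained with kind `other` and are never part of
#' polymer-contact calls.
NULL

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE")
.nuc <- c("A", "C", "G", "T", "U", "I",
          "DA", "DC", "DG", "DT", "DU", "DI")

# Element inference from the atom name per PDB convention: digits and
# primes are decorations; a leading digit marks a hydrogen (e.g. "1HB").
infer_element <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  el <- character(length(nm))
  lead_digit <- grepl("^[0-9]", nm)
  el[lead_digit] <- "H"
  rest <- gsub("[0-9'*\"]", "", nm[!lead_digit])
  two <- c("FE", "MG", "ZN", "CL", "BR", "NA", "MN", "CU", "SE", "NI", "CO")
  first2 <- substr(rest, 1, 2)
  el[!lead_digit] <- ifelse(first2 %in% two, first2, substr(rest, 1, 1))
  el
}

#' Parse PDB text into a structure object
#'
#' Reads ATOM/HETATM records (fixed-width PDB format, via bio3d) into a
#' [macro_structure]. Insertion codes are kept as part of residue identity;
#' alternate-location groups are collapsed to the highest-occupancy
#' conformer; a blank element column is filled by inference from the atom
#' name. An empty input yields an empty structure; a malformed fixed-width
#' record raises an error naming the offending line.
#'
#' @param pdb_text character scalar (possibly multi-line) or character
#'   vector of PDB lines.
#' @return object of class `macro_structure`.
#' @export
parse_structure <- function(pdb_text) {
  lines <- unlist(strsplit(paste(pdb_text, collapse = "\n"), "\n"))
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) {
    return(empty_structure())
  }
  # validate the fixed-width coordinate fields before handing to the reader
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop(sprintf("malformed PDB record at line %d: too short", i))
    }
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (any(is.na(coords)) || any(!is.finite(coords))) {
      stop(sprintf("malformed PDB record at line %d: bad coordinates", i))
    }
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom

  atoms <- data.frame(chain = ifelse(is.na(at$chain), "", at$chain),
                      resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      resname = toupper(trimws(at$resid)),
                      atom = trimws(at$elety),
                      element = toupper(trimws(ifelse(is.na(at$elesy), "",
                                                      at$elesy))),
                      x = at$x, y = at$y, z = at$z,
                      occupancy = ifelse(is.na(at$o), 1, at$o),
                      alt = ifelse(is.na(at$alt), "", at$alt),
                      stringsAsFactors = FALSE)
  blank <- atoms$element == ""
  if (any(blank)) atoms$element[blank] <- infer_element(atoms$atom[blank])

  # altloc: keep the highest-occupancy conformer of each alternate group
  if (any(atoms$alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$atom)
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(ix) {
      if (length(ix) == 1) return(ix)
      ix[which.max(atoms$occupancy[ix])]
    }), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
  }
  atoms$alt <- NULL
  rownames(atoms) <- NULL

  chains <- unique(atoms$chain)
  kind <- vapply(chains, function(ch) {
    rn <- unique(atoms$resname[atoms$chain == ch])
    if (any(rn %in% .aa3)) "protein"
    else if (any(rn %in% .nuc)) "nucleic"
    else "other"
  }, character(1))
  out <- list(atoms = atoms,
              chains = data.frame(chain = chains, kind = unname(kind),
                                  stringsAsFactors = FALSE))
  class(out) <- "macro_structure"
  out
}

empty_structure <- function() {
  out <- list(atoms = data.frame(chain = character(), resno = integer(),
                                 insert = character(), resname = character(),
                                 atom = character(), element = character(),
                                 x = numeric(), y = numeric(), z = numeric(),
                                 occupancy = numeric(),
                                 stringsAsFactors = FALSE),
              chains = data.frame(chain = character(), kind = character(),
                                  stringsAsFactors = FALSE))
  class(out) <- "macro_structure"
  out
}

#' Read a structure from a PDB file
#' @param path path to a PDB-format file.
#' @return [macro_structure]
#' @export
read_structure <- function(path) {
  parse_structure(readLines(path, warn = FALSE))
}

#' @export
print.macro_structure <- function(x, ...) {
  cat(sprintf("macro_structure: %d atoms, %d chains\n",
              nrow(x$atoms), nrow(x$chains)))
  if (nrow(x$chains)) {
    for (i in seq_len(nrow(x$chains))) {
      ch <- x$chains$chain[i]
      nres <- length(unique(paste(x$atoms$resno, x$atoms$insert)[
        x$atoms$chain == ch]))
      cat(sprintf("  chain %s (%s): %d residues\n", ch, x$chains$kind[i],
                  nres))
    }
  }
  invisible(x)
}

format_pdb_atom <- function(serial, name, resname, chain, resno, x, y, z,
                            element, occupancy = 1) {
  nm <- if (nchar(name) < 4) paste0(" ", sprintf("%-3s", name))
        else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, resname, chain, resno, x, y, z, occupancy, 0,
          element)
}
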