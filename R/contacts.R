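#' Protein-DNA interface residues by the distance rule
#'
#' A protein residue is called an interface (DNA-contact) residue when at
#' least one of its non-hydrogen atoms lies at a Euclidean distance strictly
#' below `cutoff` angstrom from a non-hydrogen atom of any of the listed DNA
#' chains. Only polymer atoms participate: amino-acid residues on the
#' protein chain, nucleotide residues on the DNA chains (waters, ions and
#' other heteroatoms are excluded).
#'
#' @param s [macro_structure].
#' @param protein_chain chain id of the protein chain.
#' @param dna_chains character vector of nucleic chain ids.
#' @param cutoff distance threshold in angstrom (default 3.5; comparison is
#'   strict `< cutoff`).
#' @return data.frame of class `contact_set` with `chain`, `resno`,
#'   `insert`, `resname`, `min_dist`; attributes `cutoff` and `partners`.
#' @export
find_dna_contacts <- function(s, protein_chain, dna_chains, cutoff = 3.5) {
  stopifnot(inherits(s, "macro_structure"))
  if (cutoff < 0) stop("cutoff must be non-negative")
  check_chains(s, c(protein_chain, dna_chains))
  a <- polymer_atoms(s, protein_chain, "protein")
  b <- do.call(rbind, lapply(dna_chains, polymer_atoms, s = s,
                             kind = "nucleic"))
  residue_contacts(a, b, cutoff, partners = dna_chains)
}

#' Protein-protein interface residues
#'
#' Same strict-distance, non-hydrogen rule as [find_dna_contacts()], applied
#' between the amino-acid atoms of two protein chains; contacts are reported
#' on `chain_a`.
#'
#' @param s [macro_structure].
#' @param chain_a,chain_b distinct protein chain ids.
#' @param cutoff angstrom threshold, strict comparison (default 3.5).
#' @return `contact_set` data.frame (residues of `chain_a`).
#' @export
find_interchain_contacts <- function(s, chain_a, chain_b, cutoff = 3.5) {
  stopifnot(inherits(s, "macro_structure"))
  if (identical(chain_a, chain_b)) stop("chain ids must differ")
  check_chains(s, c(chain_a, chain_b))
  a <- polymer_atoms(s, chain_a, "protein")
  b <- polymer_atoms(s, chain_b, "protein")
  residue_contacts(a, b, cutoff, partners = chain_b)
}

check_chains <- function(s, chains) {
  missing <- setdiff(chains, s$chains$chain)
  if (length(missing)) {
    stop("unknown chain id(s): ", paste(missing, collapse = ", "))
  }
}

polymer_atoms <- function(s, chain, kind) {
  at <- s$atoms[s$atoms$chain == chain, , drop = FALSE]
  ok <- if (kind == "protein") at$resname %in% .aa3 else at$resname %in% .nuc
  at <- at[ok & !(at$element %in% c("H", "D")), , drop = FALSE]
  at
}

residue_contacts <- function(a, b, cutoff, partners) {
  empty <- data.frame(chain = character(), resno = integer(),
                      insert = character(), resname = character(),
                      min_dist = numeric(), stringsAsFactors = FALSE)
  attr(empty, "cutoff") <- cutoff
  attr(empty, "partners") <- partners
  class(empty) <- c("contact_set", "data.frame")
  if (nrow(a) == 0 || nrow(b) == 0 || cutoff == 0) return(empty)

  pa <- as.matrix(a[c("x", "y", "z")])
  pb <- as.matrix(b[c("x", "y", "z")])
  # squared pairwise distances, |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  d2[d2 < 0] <- 0
  dmin <- sqrt(apply(d2, 1, min))

  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  res_min <- tapply(dmin, key, min)
  hit <- names(res_min)[res_min < cutoff]
  if (!length(hit)) return(empty)

  first <- match(hit, key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    insert = a$insert[first], resname = a$resname[first],
                    min_dist = as.numeric(res_min[hit]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$resno, out$insert), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "partners") <- partners
  class(out) <- c("contact_set", "data.frame")
  out
}
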