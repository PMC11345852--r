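# shared fixtures and independent oracles, built in code at test time

# small screen for QC/normalisation tests: explicit counts + metadata
make_mini_screen <- function(counts, variant, n_barcodes = NULL,
                             mito = NULL, ribo = NULL,
                             condition = NULL) {
  ng <- nrow(counts); nc <- ncol(counts)
  genes <- sprintf("G%03d", seq_len(ng))
  cells <- sprintf("c%03d", seq_len(nc))
  dimnames(counts) <- list(genes, cells)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(
      Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")),
    rowData = S4Vectors::DataFrame(
      gene_id = genes, symbol = genes,
      mito = if (is.null(mito)) rep(FALSE, ng) else mito,
      ribo = if (is.null(ribo)) rep(FALSE, ng) else ribo,
      row.names = genes),
    colData = S4Vectors::DataFrame(
      cell_id = cells, variant = variant,
      n_barcodes = if (is.null(n_barcodes)) rep(1L, nc) else n_barcodes,
      replicate = rep(1L, nc),
      condition = if (is.null(condition)) rep("dox", nc) else condition,
      row.names = cells))
}

# O(n^2) all-pairs oracle for residue contacts (independent of the package
# implementation: plain loops over residues and atom pairs)
brute_contacts <- function(s, protein_chain, dna_chains, cutoff) {
  at <- s$atoms
  heavy <- !(at$element %in% c("H", "D"))
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
           "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
           "TYR", "VAL", "MSE")
  nuc <- c("A", "C", "G", "T", "U", "I", "DA", "DC", "DG", "DT", "DU", "DI")
  pa <- at[at$chain == protein_chain & heavy & at$resname %in% aa3, ]
  da <- at[at$chain %in% dna_chains & heavy & at$resname %in% nuc, ]
  if (nrow(pa) == 0 || nrow(da) == 0) return(integer(0))
  hits <- integer(0)
  for (rn in unique(pa$resno)) {
    ra <- pa[pa$resno == rn, ]
    found <- FALSE
    for (i in seq_len(nrow(ra))) {
      for (j in seq_len(nrow(da))) {
        d <- sqrt((ra$x[i] - da$x[j])^2 + (ra$y[i] - da$y[j])^2 +
                  (ra$z[i] - da$z[j])^2)
        if (d < cutoff) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) hits <- c(hits, rn)
  }
  sort(hits)
}

# brute-force conditional-MLE oracle: directly maximise the noncentral
# hypergeometric log-likelihood over log(psi) by golden-section search
brute_cmle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(m1, k)
  support <- lo:hi
  lw0 <- lchoose(m1, support) + lchoose(m2, k - support)
  nll <- function(lp) {
    lw <- lw0 + support * lp
    m <- max(lw)
    -(lw0[support == a] + a * lp - (m + log(sum(exp(lw - m)))))
  }
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  exp(stats::optimize(nll, c(-36, 36), tol = 1e-12)$minimum)
}

# draw one element of a vector uniformly (unlike sample(), never expands a
# scalar into 1:n)
pick1 <- function(v) v[sample.int(length(v), 1)]

# adjusted Rand index between two partitions (direct formula)
ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c / choose(n, 2)
  (a - expected) / ((b + c) / 2 - expected)
}

# rotate+translate the atoms of a structure (for invariance tests)
transform_structure <- function(s, angle = 0.7, shift = c(5, -3, 11)) {
  cs <- cos(angle); sn <- sin(angle)
  rot <- matrix(c(cs, -sn, 0, sn, cs, 0, 0, 0, 1), 3, byrow = TRUE) %*%
    matrix(c(1, 0, 0, 0, cs, -sn, 0, sn, cs), 3, byrow = TRUE)
  xyz <- as.matrix(s$atoms[c("x", "y", "z")]) %*% t(rot)
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}
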