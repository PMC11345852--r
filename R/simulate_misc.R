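#' Simulate a barcode-abundance fitness timecourse
#'
#' Starting from equal day-2 shares, each variant's expected abundance grows
#' as `exp(growth_rate * (t - 2))`; each sample (replicate x day) is a
#' multinomial draw of `reads_per_sample` reads over the variants. With all
#' growth rates equal the expected fitness of every variant is 0; a variant
#' with growth advantage `g` (per day) gains `g * (t - 2) / ln 2` log2 units
#' of expected fitness over a neutral pool by day `t`.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element of [simulate_screen()] (provides the
#'   per-variant growth rates).
#' @return data.frame `variant`, `replicate`, `day`, `count`.
#' @export
simulate_barcode_timecourse <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  local_rng(cfg$seed + 1L)
  gr <- truth$growth_rate
  variants <- names(gr)
  rows <- list()
  for (rep_i in seq_len(cfg$n_replicates)) {
    for (day in sort(cfg$timepoints)) {
      share <- exp(gr * (day - 2))
      share <- share / sum(share)
      cnt <- stats::rmultinom(1, size = cfg$reads_per_sample, prob = share)
      rows[[length(rows) + 1L]] <-
        data.frame(variant = variants, replicate = rep_i, day = day,
                   count = as.integer(cnt), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a toy protein-DNA complex with planted contact residues
#'
#' Writes standard PDB ATOM records for a synthetic two-chain complex:
#' protein chain A laid out on a line well away (>= 15 angstrom) from a DNA
#' chain B, except that each planted contact residue gets one heavy side
#' chain atom placed 2.8 angstrom from a DNA phosphorus. Optionally a
#' hydrogen decoy atom is attached to a non-planted residue 2.0 angstrom
#' from the DNA, which a correct non-hydrogen contact rule must ignore.
#' Intended as ground truth for the interface caller: running
#' [find_dna_contacts()] on the output (cutoff between 3 and 5) returns
#' exactly `planted_contacts`.
#'
#' @param n_protein_res protein residues (numbered 1..n on chain A, or per
#'   `resno_offset`).
#' @param n_dna_bases DNA nucleotides on chain B.
#' @param planted_contacts integer residue numbers (after offset) to plant
#'   as contacts.
#' @param seed seed for small coordinate jitter.
#' @param resno_offset added to 1..n residue numbering (default 0), so
#'   author-style numbering schemes can be emulated.
#' @param h_decoy optional residue number receiving the hydrogen decoy.
#' @return character scalar of PDB text.
#' @export
simulate_toy_structure <- function(n_protein_res, n_dna_bases,
                                   planted_contacts = integer(0), seed = 1,
                                   resno_offset = 0, h_decoy = NULL) {
  if (n_protein_res < 1 || n_dna_bases < 1) stop("need at least one residue")
  resnos <- seq_len(n_protein_res) + resno_offset
  planted_contacts <- as.integer(planted_contacts)
  if (!all(planted_contacts %in% resnos)) {
    stop("planted_contacts must be protein residue numbers")
  }
  if (!is.null(h_decoy) && h_decoy %in% planted_contacts) {
    stop("hydrogen decoy must sit on a non-planted residue")
  }
  if (length(planted_contacts) > n_dna_bases * 3) {
    stop("geometrically infeasible: too many planted contacts for the DNA")
  }
  local_rng(seed)
  jit <- function(n) stats::runif(n, -0.05, 0.05)

  aa_cycle <- c("ALA", "GLY", "SER", "LEU", "ARG", "THR", "VAL", "ASP")
  lines <- character(0)
  serial <- 0L
  emit <- function(name, resname, chain, resno, x, y, z, element) {
    serial <<- serial + 1L
    lines[[length(lines) + 1L]] <<-
      format_pdb_atom(serial, name, resname, chain, resno, x, y, z, element)
  }

  # DNA chain B along the x axis at y = 0
  base_x <- (seq_len(n_dna_bases) - 1) * 6
  nuc_cycle <- c("DA", "DC", "DG", "DT")
  for (i in seq_len(n_dna_bases)) {
    rn <- nuc_cycle[(i - 1) %% 4 + 1]
    emit("P", rn, "B", i, base_x[i] + jit(1), jit(1), jit(1), "P")
    emit("C1'", rn, "B", i, base_x[i] + 1.0 + jit(1), 1.2 + jit(1),
         0.8 + jit(1), "C")
    emit("N1", rn, "B", i, base_x[i] - 0.8 + jit(1), -1.0 + jit(1),
         0.6 + jit(1), "N")
  }

  # protein chain A on a parallel line at y = 20
  for (k in seq_len(n_protein_res)) {
    resno <- resnos[k]
    rn <- aa_cycle[(k - 1) %% length(aa_cycle) + 1]
    x0 <- (k - 1) * 3.8
    emit("N", rn, "A", resno, x0 + jit(1), 20 + jit(1), jit(1), "N")
    emit("CA", rn, "A", resno, x0 + 1.0 + jit(1), 20.8 + jit(1),
         0.3 + jit(1), "C")
    emit("C", rn, "A", resno, x0 + 2.0 + jit(1), 20 + jit(1),
         0.5 + jit(1), "C")
    emit("O", rn, "A", resno, x0 + 2.2 + jit(1), 19.0 + jit(1),
         0.5 + jit(1), "O")
    if (resno %in% planted_contacts) {
      which_p <- match(resno, planted_contacts)
      bi <- (which_p - 1) %% n_dna_bases + 1
      # heavy atom 2.8 A above a DNA phosphorus (no jitter: exact plant)
      emit("NH1", rn, "A", resno, base_x[bi] + 0.2 * (which_p %% 3),
           2.8, 0, "N")
    }
    if (!is.null(h_decoy) && resno == h_decoy) {
      bi <- (k - 1) %% n_dna_bases + 1
      emit("HB1", rn, "A", resno, base_x[bi], 2.0, 0, "H")
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

#' Simulate a per-variant feature table for the classifier stage
#'
#' Emulates a tabular variant-feature resource (85 biophysical /
#' conservation features per variant): `n_informative` features carry a
#' class-conditional mean difference of `effect` (in units of the
#' within-class standard deviation, which is 1); the remaining features are
#' pure noise. Class labels are balanced via `frac_positive`.
#'
#' @param n_variants rows.
#' @param n_features columns (default 85).
#' @param n_informative informative features (must not exceed
#'   `n_features`).
#' @param effect class-conditional mean difference on informative features.
#' @param seed integer seed.
#' @param frac_positive fraction of variants labelled functional
#'   (default 0.5).
#' @return list with `features` (matrix, `n_variants x n_features`) and
#'   `labels` (factor `WT-like` / `functional`), plus `informative` (the
#'   informative column names).
#' @export
simulate_feature_table <- function(n_variants, n_features = 85,
                                   n_informative = 10, effect = 1, seed = 1,
                                   frac_positive = 0.5) {
  if (n_informative > n_features) stop("n_informative exceeds n_features")
  local_rng(seed)
  n_pos <- round(frac_positive * n_variants)
  y <- c(rep(1L, n_pos), rep(0L, n_variants - n_pos))
  x <- matrix(stats::rnorm(n_variants * n_features), n_variants, n_features)
  if (n_informative > 0) {
    x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] + effect * y
  }
  colnames(x) <- sprintf("f%03d", seq_len(n_features))
  rownames(x) <- sprintf("V%03d", seq_len(n_variants))
  labels <- factor(ifelse(y == 1L, "functional", "WT-like"),
                   levels = c("WT-like", "functional"))
  list(features = x, labels = labels,
       informative = colnames(x)[seq_len(n_informative)])
}
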