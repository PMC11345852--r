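#' Enumerate missense variants reachable by a single base substitution
#'
#' For every codon of a coding sequence, each of the nine single-nucleotide
#' variants is translated under the standard genetic code. Missense changes
#' are the candidates; silent and nonsense products are kept in a separate
#' table because control categories of a mutation library are drawn from
#' them.
#'
#' @param cds coding sequence (character string or `Biostrings::DNAString`);
#'   length must be a multiple of 3 with no internal stop codon.
#' @return list with data.frames `missense` and `excluded`. Both carry
#'   `position` (codon index = protein coordinate), `ref_aa`, `alt_aa`,
#'   `codon_pos` (1-3 within the codon), `ref_base`, `alt_base`, `ref_codon`,
#'   `alt_codon`; `excluded` adds `kind` ("silent"/"nonsense").
#' @examples
#' enumerate_single_base_missense("ATGTGG")
#' @export
enumerate_single_base_missense <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0) stop("CDS length must be divisible by 3")
  bases <- strsplit(cds, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("CDS contains non-ACGT characters")
  }
  code <- Biostrings::GENETIC_CODE
  n_codon <- nchar(cds) / 3
  codons <- substring(cds, 3 * seq_len(n_codon) - 2, 3 * seq_len(n_codon))
  ref_aa <- unname(code[codons])
  if (any(ref_aa[-n_codon] == "*")) stop("CDS contains an internal stop codon")

  alt_of <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  rows <- vector("list", n_codon * 9L)
  i <- 0L
  for (pos in seq_len(n_codon)) {
    cd <- strsplit(codons[pos], "")[[1]]
    for (cp in 1:3) {
      for (alt in strsplit(alt_of[[cd[cp]]], "")[[1]]) {
        mut <- cd
        mut[cp] <- alt
        mcodon <- paste(mut, collapse = "")
        i <- i + 1L
        rows[[i]] <- data.frame(position = pos, ref_aa = ref_aa[pos],
                                alt_aa = unname(code[mcodon]),
                                codon_pos = cp, ref_base = cd[cp],
                                alt_base = alt, ref_codon = codons[pos],
                                alt_codon = mcodon, stringsAsFactors = FALSE)
      }
    }
  }
  all_rows <- do.call(rbind, rows)
  silent <- all_rows$alt_aa == all_rows$ref_aa
  nonsense <- all_rows$alt_aa == "*" & !silent
  excluded <- all_rows[silent | nonsense, ]
  excluded$kind <- ifelse(excluded$alt_aa == "*", "nonsense", "silent")
  missense <- all_rows[!silent & !nonsense, ]
  rownames(missense) <- rownames(excluded) <- NULL
  list(missense = missense, excluded = excluded)
}

#' Pick the library variant for one residue position
#'
#' Implements the most-damaging-substitution rule: if any candidate at the
#' position is observed in tumours, the choice is restricted to those;
#' among the remainder the candidate with the highest VEST pathogenicity
#' score wins, ties broken by larger FoldX destabilisation and finally by
#' alphabetical alternate amino acid (so the choice is a pure, deterministic
#' function of the candidate set).
#'
#' @param cands data.frame of candidates for one position with columns
#'   `alt_aa`, `vest` (in `[0,1]`), `foldx` (kcal/mol), `cancer_observed`
#'   (logical); missing scores are treated as `-Inf` (never preferred).
#' @return the selected row of `cands`.
#' @export
select_library_variant <- function(cands) {
  if (is.null(cands) || nrow(cands) == 0) stop("empty candidate set")
  pool <- cands
  if (any(pool$cancer_observed %in% TRUE)) {
    pool <- pool[pool$cancer_observed %in% TRUE, , drop = FALSE]
  }
  vest <- ifelse(is.na(pool$vest), -Inf, pool$vest)
  foldx <- ifelse(is.na(pool$foldx), -Inf, pool$foldx)
  ord <- order(-vest, -foldx, pool$alt_aa)
  pool[ord[1], , drop = FALSE]
}

#' Random variant barcodes with a minimum pairwise Hamming distance
#'
#' Barcodes are drawn uniformly over `{A,C,G,T}^length` and accepted only if
#' they keep the running set at pairwise Hamming distance `>= min_hamming`;
#' generation is seeded and errors out after a bounded number of rejections.
#'
#' @param n number of barcodes.
#' @param length barcode length in bases (default 12).
#' @param min_hamming minimum pairwise Hamming distance (default 3).
#' @param seed integer seed.
#' @param max_tries rejection budget per barcode (default 10000).
#' @return character vector of `n` barcodes.
#' @export
assign_barcodes <- function(n, length = 12, min_hamming = 3, seed = 1,
                            max_tries = 10000) {
  if (4^length < n) stop("barcode space too small")
  rng <- local_rng(seed)
  picked <- matrix(integer(0), nrow = 0, ncol = length)
  out <- character(n)
  letters4 <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- sample.int(4, length, replace = TRUE)
      if (nrow(picked) == 0 ||
          all(rowSums(picked != rep(cand, each = nrow(picked))) >=
              min_hamming)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("barcode distance constraint infeasible after bounded attempts")
    picked <- rbind(picked, cand)
    out[i] <- paste(letters4[cand], collapse = "")
  }
  out
}

#' Assemble the mutation library table
#'
#' Combines per-position perturbation substitutions with the control
#' categories of a variant overexpression screen: a WT and a LoF construct
#' are always included, plus configurable numbers of silent and
#' predicted-neutral negative controls, truncating and core positive
#' controls, and multi-mutation combination elements. Every element receives
#' a unique 12-base barcode.
#'
#' @param perturbations data.frame with at least `position`, `ref_aa`,
#'   `alt_aa` (one selected substitution per row).
#' @param controls_spec named integer vector with entries
#'   `negative_silent`, `negative_neutral`, `positive_truncating`,
#'   `positive_core` (all default 0). Control elements are emitted as
#'   placeholders labelled by class and index; callers that know the actual
#'   control substitutions can overwrite the `substitution` column.
#' @param combos optional character vector describing combination elements
#'   (e.g. `"R80G+R135G"`).
#' @param barcode_length,min_hamming,seed passed to [assign_barcodes()].
#' @return data.frame of class `library_table`: `element_id`, `class`,
#'   `substitution`, `barcode`.
#' @export
assemble_library <- function(perturbations,
                             controls_spec = c(negative_silent = 0,
                                               negative_neutral = 0,
                                               positive_truncating = 0,
                                               positive_core = 0),
                             combos = character(0),
                             barcode_length = 12, min_hamming = 3, seed = 1) {
  spec <- c(negative_silent = 0, negative_neutral = 0,
            positive_truncating = 0, positive_core = 0)
  spec[names(controls_spec)] <- controls_spec
  if (any(spec < 0)) stop("control counts must be non-negative")

  pert_sub <- if (nrow(perturbations) > 0) {
    paste0(perturbations$ref_aa, perturbations$position, perturbations$alt_aa)
  } else character(0)

  rows <- rbind(
    data.frame(class = "WT", substitution = "WT", stringsAsFactors = FALSE),
    data.frame(class = "LoF", substitution = "GFP", stringsAsFactors = FALSE),
    if (length(pert_sub)) data.frame(class = "perturbation",
                                     substitution = pert_sub,
                                     stringsAsFactors = FALSE),
    do.call(rbind, lapply(names(spec)[spec > 0], function(cl) {
      data.frame(class = cl,
                 substitution = paste0(cl, "_", seq_len(spec[[cl]])),
                 stringsAsFactors = FALSE)
    })),
    if (length(combos)) data.frame(class = "combination",
                                   substitution = combos,
                                   stringsAsFactors = FALSE)
  )
  rows$element_id <- sprintf("el%03d", seq_len(nrow(rows)))
  rows$barcode <- assign_barcodes(nrow(rows), length = barcode_length,
                                  min_hamming = min_hamming, seed = seed)
  rows <- rows[c("element_id", "class", "substitution", "barcode")]
  class(rows) <- c("library_table", "data.frame")
  rows
}
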