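#' Residue burial classes from relative solvent accessibility
#'
#' Computes per-atom solvent-accessible surface area by the Shrake-Rupley
#' sphere-point method: each non-hydrogen atom is surrounded by a
#' deterministic quasi-uniform point shell (golden-spiral lattice) at radius
#' `vdW + probe`; the exposed fraction is the share of points not buried
#' inside any neighbouring atom's solvent-extended sphere. Residue SASA is
#' the sum over its atoms, and relative SASA divides by a per-residue
#' maximum-accessibility reference (theoretical Gly-X-Gly values of
#' Tien et al. 2013). Classes are assigned by thresholds on the relative
#' SASA: `<= core_max` is core, `>= surface_min` is surface, otherwise
#' intermediate. Occlusion is evaluated within the selected chain, so the
#' classes describe the burial of the isolated protomer.
#'
#' @param s [macro_structure].
#' @param chain protein chain id.
#' @param thresholds numeric length-2 `(core_max, surface_min)` with
#'   `0 <= core_max < surface_min <= 1`; defaults `c(0.05, 0.25)`.
#' @param n_points sphere points per atom (default 100).
#' @param probe probe radius in angstrom (default 1.4, water).
#' @return data.frame with `resno`, `insert`, `resname`, `sasa`,
#'   `rel_sasa`, `class`, `flagged` (`TRUE` for residue names without a
#'   reference value; these are classified intermediate).
#' @export
classify_burial <- function(s, chain, thresholds = c(0.05, 0.25),
                            n_points = 100, probe = 1.4) {
  stopifnot(inherits(s, "macro_structure"))
  if (length(thresholds) != 2 || thresholds[1] < 0 ||
      thresholds[1] >= thresholds[2] || thresholds[2] > 1) {
    stop("thresholds must satisfy 0 <= core_max < surface_min <= 1")
  }
  check_chains(s, chain)
  at <- s$atoms[s$atoms$chain == chain &
                !(s$atoms$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0) stop("chain has no heavy atoms")

  sasa_atom <- shrake_rupley(as.matrix(at[c("x", "y", "z")]),
                             vdw_radius(at$element), n_points, probe)
  key <- paste(at$resno, at$insert, sep = "\r")
  first <- !duplicated(key)
  res <- data.frame(resno = at$resno[first], insert = at$insert[first],
                    resname = at$resname[first],
                    sasa = as.numeric(tapply(sasa_atom, key, sum)[
                      unique(key)]),
                    stringsAsFactors = FALSE)
  ref <- .max_sasa[res$resname]
  res$flagged <- is.na(ref)
  if (any(res$flagged)) {
    warning("no reference SASA for residue(s): ",
            paste(unique(res$resname[res$flagged]), collapse = ", "),
            "; classified as intermediate")
  }
  res$rel_sasa <- res$sasa / as.numeric(ref)
  res$class <- ifelse(res$flagged, "intermediate",
                ifelse(res$rel_sasa <= thresholds[1], "core",
                ifelse(res$rel_sasa >= thresholds[2], "surface",
                       "intermediate")))
  rownames(res) <- NULL
  res
}

# golden-spiral lattice on the unit sphere (deterministic)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

vdw_radius <- function(element) {
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
         SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
  out <- r[element]
  out[is.na(out)] <- 1.70
  as.numeric(out)
}

shrake_rupley <- function(xyz, radii, n_points = 100, probe = 1.4) {
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  rs <- radii + probe
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    # neighbours whose solvent sphere can reach atom i's shell
    dd <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(dd < rs[i] + rs & dd > 0)
    shell <- pts * rs[i]
    shell <- sweep(shell, 2, xyz[i, ], "+")
    if (length(nb)) {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        d2 <- colSums((t(shell) - xyz[j, ])^2)
        buried <- buried | d2 < rs[j]^2
        if (all(buried)) break
      }
      frac <- mean(!buried)
    } else {
      frac <- 1
    }
    sasa[i] <- frac * 4 * pi * rs[i]^2
  }
  sasa
}

# theoretical maximum accessibilities (A^2), Tien et al. 2013
.max_sasa <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0,
               CYS = 167.0, GLN = 225.0, GLU = 223.0, GLY = 104.0,
               HIS = 224.0, ILE = 197.0, LEU = 201.0, LYS = 236.0,
               MET = 224.0, PHE = 240.0, PRO = 159.0, SER = 155.0,
               THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)
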