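#' Barcode fitness scores from a pooled-screen timecourse
#'
#' Each sample (replicate x day) of barcode read counts is first normalised
#' to relative abundances (column divided by its sum); the fitness of a
#' variant in a sample is then the log2 ratio of its relative abundance to
#' its relative abundance in that replicate's day-2 baseline:
#' \deqn{f_{v,s} = \log_2\frac{c_{v,s}/\sum_v c_{v,s}}
#'                           {c_{v,2}/\sum_v c_{v,2}}.}
#' Fitness at day 2 is identically 0 and the score is invariant to
#' per-sample sequencing depth. The summary `mean_fitness` averages the
#' day-14 values over replicates.
#'
#' @param bc data.frame with columns `variant`, `replicate`, `day`, `count`
#'   (long format; days must include the day-2 baseline).
#' @param pseudocount added to every count before normalisation (default 0,
#'   matching the plain ratio definition; use a small value for sparse data).
#' @param final_day day used for the per-variant mean fitness (default 14).
#' @return object of class `fitness_table`: list with `fitness` (long
#'   data.frame: variant, replicate, day, fitness, flagged), and
#'   `mean_fitness` (named vector over variants, day-`final_day` replicate
#'   mean; `NA` for variants flagged at baseline). Variants with a zero
#'   day-2 count in a replicate are flagged and excluded from the mean.
#' @export
fitness_scores <- function(bc, pseudocount = 0, final_day = 14) {
  need <- c("variant", "replicate", "day", "count")
  if (!all(need %in% names(bc))) {
    stop("'bc' needs columns variant, replicate, day, count")
  }
  if (!2 %in% bc$day) stop("timecourse must include the day-2 baseline")
  if (any(bc$count < 0)) stop("counts must be non-negative")

  bc$count <- bc$count + pseudocount
  # relative abundance within each sample
  key <- interaction(bc$replicate, bc$day, drop = TRUE)
  tot <- tapply(bc$count, key, sum)
  rel <- bc$count / as.numeric(tot[key])

  base <- bc$day == 2
  bkey <- paste(bc$variant, bc$replicate)
  base_rel <- rel[base]
  names(base_rel) <- bkey[base]
  b <- base_rel[bkey]

  flagged <- !is.na(b) & b == 0
  fit <- log2(rel / b)
  fit[flagged] <- NA_real_

  out <- list(fitness = data.frame(variant = bc$variant,
                                   replicate = bc$replicate, day = bc$day,
                                   fitness = fit, flagged = flagged,
                                   stringsAsFactors = FALSE))
  fin <- out$fitness[out$fitness$day == final_day & !out$fitness$flagged, ]
  out$mean_fitness <- tapply(fin$fitness, fin$variant, mean)
  out$mean_fitness <- out$mean_fitness[order(names(out$mean_fitness))]
  class(out) <- "fitness_table"
  out
}

#' @export
print.fitness_table <- function(x, ...) {
  cat(sprintf("fitness_table: %d variants, %d samples\n",
              length(unique(x$fitness$variant)),
              nrow(unique(x$fitness[c("replicate", "day")]))))
  cat("mean day-final fitness (first 6):\n")
  print(utils::head(x$mean_fitness))
  invisible(x)
}

#' Pearson correlation with a two-sided t-based p-value
#'
#' @param x,y paired numeric vectors; pairs with missing values are dropped,
#'   at least three complete pairs are required.
#' @return list with `r`, `p_value`, `n`. Zero variance in either vector
#'   yields `r = NA` with `flagged = TRUE`.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = n, flagged = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n, flagged = FALSE)
}
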