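#' @include expectation.R
NULL

#' Normalize a count table across samples
#'
#' Each raw count is divided by its sample's total number of reads mapped
#' to the gene (each read counted once, over the deduplicated union of
#' exon intervals) and multiplied by a large constant factor that brings
#' the values into a convenient range. The result is invariant under any
#' uniform per-sample scaling of the raw counts. Samples with a zero total
#' are dropped with a warning.
#'
#' @param table a [CountTable-class] (exon or junction counts).
#' @param scaleFactor multiplicative factor, default `1e7`.
#' @return a [NormalizedTable-class] with an all-FALSE outlier mask.
#' @export
normalizeCounts <- function(table, scaleFactor = 1e7) {
  tot <- sampleTotals(table)
  keep <- tot > 0
  if (!all(keep))
    warning("dropping sample(s) with zero total: ",
            paste(names(tot)[!keep], collapse = ", "))
  cc <- counts(table)[keep, , drop = FALSE]
  tot <- tot[keep]
  v <- cc / tot * scaleFactor
  new("NormalizedTable", values = v,
      mask = matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v)),
      totals = tot, scaleFactor = scaleFactor)
}

#' Mask quantile outliers per feature column
#'
#' Values falling strictly outside the central `central` interval of their
#' column (for the default 0.95: below the 2.5th or above the 97.5th
#' empirical percentile, linear-interpolation quantile definition) are
#' masked as outliers. With `sides = "upper"` only the upper tail is
#' masked. Columns shorter than `minValues` are left untouched with a
#' warning.
#'
#' @param nt a [NormalizedTable-class].
#' @param central width of the central interval kept, in `[0, 1]`.
#' @param sides `"two"` (default) or `"upper"`.
#' @param minValues minimum column size for filtering (default 20).
#' @return the table with its mask updated.
#' @export
filterQuantileOutliers <- function(nt, central = 0.95,
                                   sides = c("two", "upper"),
                                   minValues = 20L) {
  sides <- match.arg(sides)
  v <- nt@values
  if (nrow(v) < minValues) {
    warning("fewer than ", minValues, " values per column; no filtering")
    return(nt)
  }
  if (central >= 1) return(nt)
  alpha <- (1 - central) / 2
  mask <- nt@mask
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    if (sides == "two") {
      q <- stats::quantile(x, c(alpha, 1 - alpha), type = 7, names = FALSE)
      mask[, j] <- mask[, j] | x < q[1] | x > q[2]
    } else {
      q <- stats::quantile(x, central, type = 7, names = FALSE)
      mask[, j] <- mask[, j] | x > q
    }
  }
  nt@mask <- mask
  validObject(nt)
  nt
}

#' Per-sample isoform ratios from junction counts
#'
#' The ref, X1 and X2 measures are the spanning-pair counts of the
#' E18.2--E18b, E18.2--E19 and E17--E19 junctions; ratios between them are
#' the per-sample isoform ratios (X1/ref, X2/ref, ref/X1, X2/X1), reported
#' raw and log2-transformed (log2 = 0 marks a ratio of 1). Samples with a
#' zero denominator are flagged undefined for that ratio and excluded from
#' the sorted series. Two sort orders are attached as attributes:
#' `orderByRef` (samples by increasing ref count) and `orderByX1`.
#'
#' @param jtable a [JunctionCountTable][CountTable-class] whose measures
#'   include `"ref"`, `"X1"` and `"X2"`.
#' @param pseudocount optional count added to numerator and denominator
#'   (default 0: undefined ratios are excluded, not imputed).
#' @return data.frame with one row per sample.
#' @export
computeIsoformRatios <- function(jtable, pseudocount = 0) {
  mc <- measureCounts(jtable)
  need <- c("ref", "X1", "X2")
  if (!all(need %in% colnames(mc)))
    stop("junction table lacks measure(s): ",
         paste(setdiff(need, colnames(mc)), collapse = ", "))
  ref <- mc[, "ref"] + pseudocount
  x1 <- mc[, "X1"] + pseudocount
  x2 <- mc[, "X2"] + pseudocount
  rat <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(
    sample = rownames(mc), ref = mc[, "ref"], X1 = mc[, "X1"], X2 = mc[, "X2"],
    x1_over_ref = rat(x1, ref), x2_over_ref = rat(x2, ref),
    ref_over_x1 = rat(ref, x1), x2_over_x1 = rat(x2, x1),
    stringsAsFactors = FALSE, row.names = NULL)
  for (cn in c("x1_over_ref", "x2_over_ref", "ref_over_x1", "x2_over_x1"))
    out[[paste0("log2_", cn)]] <- log2(out[[cn]])
  out$undefined_over_ref <- ref == 0
  out$undefined_over_x1 <- x1 == 0
  attr(out, "orderByRef") <- order(out$ref)
  attr(out, "orderByX1") <- order(out$X1)
  out
}

#' Rank correlation between isoform levels across a cohort
#'
#' Spearman rank correlation (mid-ranks for ties) between the ref measure
#' and each of the X1 and X2 measures, with a seeded permutation p-value
#' (two-sided: proportion of label permutations with at least as extreme a
#' correlation).
#'
#' @param jtable a [JunctionCountTable][CountTable-class].
#' @param nPerm permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return data.frame with columns `pair`, `rho`, `p_perm`, `n`.
#' @export
correlationStat <- function(jtable, nPerm = 10000L, seed = 1L) {
  mc <- measureCounts(jtable)
  if (nrow(mc) < 5L) stop("need at least 5 samples")
  ref <- mc[, "ref"]
  one <- function(y, label) {
    if (stats::sd(ref) == 0 || stats::sd(y) == 0)
      return(data.frame(pair = label, rho = NA_real_, p_perm = NA_real_,
                        n = nrow(mc)))
    rho <- stats::cor(ref, y, method = "spearman")
    perm <- .withSeed(seed, vapply(seq_len(nPerm), function(i)
      stats::cor(ref, sample(y), method = "spearman"), numeric(1)))
    p <- (1 + sum(abs(perm) >= abs(rho))) / (nPerm + 1)
    data.frame(pair = label, rho = rho, p_perm = p, n = nrow(mc))
  }
  rbind(one(mc[, "X1"], "ref_vs_X1"), one(mc[, "X2"], "ref_vs_X2"))
}

#' Compare isoform levels between sample groups
#'
#' Generic two-group (or reference-vs-other) comparison of normalized
#' isoform measures, as used to compare total-RNA against polysome-bound
#' samples: per group the median normalized count of each isoform measure,
#' and for every non-reference group the ratio of its median to the
#' reference group's, with a seeded bootstrap confidence interval.
#'
#' @param jtable a [JunctionCountTable][CountTable-class].
#' @param groups named character vector, sample id -> group label; the
#'   first label in sorted order (or factor level order) is the reference.
#' @param nBoot bootstrap resamples for the CI (default 1000).
#' @param seed RNG seed.
#' @param conf CI level (default 0.95).
#' @return data.frame: `measure`, `group`, `median`, `ratio_vs_ref`,
#'   `ci_lo`, `ci_hi`.
#' @export
groupRatioCompare <- function(jtable, groups, nBoot = 1000L, seed = 1L,
                              conf = 0.95) {
  mc <- measureCounts(jtable)
  norm <- mc / sampleTotals(jtable)[rownames(mc)] * 1e7
  bad <- setdiff(rownames(mc), names(groups))
  if (length(bad)) stop("sample(s) without group label: ",
                        paste(bad, collapse = ", "))
  g <- factor(groups[rownames(mc)])
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 3L)) stop("need at least 3 samples per group")
  refLev <- levels(g)[1L]
  alpha <- (1 - conf) / 2
  out <- list()
  for (m in colnames(norm)) {
    med <- tapply(norm[, m], g, stats::median)
    for (lev in levels(g)) {
      ratio <- ci <- c(NA_real_, NA_real_)
      if (lev != refLev && med[[refLev]] > 0) {
        ratio <- med[[lev]] / med[[refLev]]
        ia <- which(g == refLev); ib <- which(g == lev)
        bs <- .withSeed(seed, vapply(seq_len(nBoot), function(i) {
          a <- stats::median(norm[sample(ia, replace = TRUE), m])
          b <- stats::median(norm[sample(ib, replace = TRUE), m])
          if (a > 0) b / a else NA_real_
        }, numeric(1)))
        ci <- stats::quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE,
                              names = FALSE)
      }
      out[[length(out) + 1L]] <- data.frame(
        measure = m, group = lev, median = unname(med[[lev]]),
        ratio_vs_ref = if (lev == refLev) 1 else ratio[1],
        ci_lo = if (lev == refLev) NA_real_ else ci[1],
        ci_hi = if (lev == refLev) NA_real_ else ci[2],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
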