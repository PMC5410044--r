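#' @include read-counting.R
NULL

# per-mate genomic span (mates are contiguous in transcript space; the span
# is what containment and distance arithmetic need)
.mateSpans <- function(rs, mt) {
  mc <- mcols(rs@blocks)
  key <- .mateKey(mc$qname, mc$mate)
  idx <- match(key, .mateKey(mt$qname, mt$mate))
  f <- factor(idx, levels = seq_len(nrow(mt)))
  data.frame(s = as.integer(tapply(start(rs@blocks), f, min)),
             e = as.integer(tapply(end(rs@blocks), f, max)))
}

# transcript-orientation offset of a genomic span inside exon X
.offsetInExon <- function(s, e, X, minus) {
  if (minus) list(start = end(X) - e + 1L, end = end(X) - s + 1L)
  else list(start = s - start(X) + 1L, end = e - start(X) + 1L)
}

#' Infer the plausible mate-to-mate inner-distance range
#'
#' The "reasonable range" for a spanning pair's implied inner distance is
#' calibrated on the data themselves: every proper pair whose two mates lie
#' inside one and the same (union) exon yields a directly observed
#' transcript-space inner distance (the gap between the mates); the range
#' is an empirical percentile interval of that distribution.
#'
#' @param rs a [ReadSet-class].
#' @param model a [GeneModel-class].
#' @param percentiles two percentiles (default `c(1, 99)`).
#' @return a `fragmentRange`: list with `low`, `high`, `median`,
#'   `percentiles`, `nPairs`.
#' @export
inferFragmentRange <- function(rs, model, percentiles = c(1, 99)) {
  mt <- .mateTable(rs)
  uni <- GenomicRanges::reduce(geneExons(model), ignore.strand = TRUE)
  names(uni) <- paste0("u", seq_along(uni))
  cm <- .containmentMatrix(rs, uni, mt)
  sp <- .mateSpans(rs, mt)
  # exon index a mate is contained in (union intervals are disjoint)
  exIdx <- apply(cm, 1L, function(r) if (any(r)) which(r)[1L] else NA_integer_)
  ok <- mt$pass & !is.na(exIdx)
  m1 <- which(ok & mt$mate == 1L); m2 <- which(ok & mt$mate == 2L)
  j <- match(mt$qname[m1], mt$qname[m2])
  use <- !is.na(j) & exIdx[m1] == exIdx[m2[j]]
  if (!any(use))
    stop("no proper pair with both mates inside a single exon; ",
         "supply an explicit fragment range")
  a <- m1[use]; b <- m2[j[use]]
  d <- pmax(sp$s[a], sp$s[b]) - pmin(sp$e[a], sp$e[b]) - 1L
  q <- stats::quantile(d, percentiles / 100, type = 7, names = FALSE)
  structure(list(low = max(0, q[1]), high = q[2],
                 median = stats::median(d), percentiles = percentiles,
                 nPairs = length(d)),
            class = "fragmentRange")
}

#' @rdname inferFragmentRange
#' @param low,high explicit bounds when calibration is not wanted.
#' @export
fragmentRange <- function(low, high) {
  stopifnot(0 <= low, low <= high)
  structure(list(low = low, high = high, median = (low + high) / 2,
                 percentiles = NULL, nPairs = 0L), class = "fragmentRange")
}

#' Count exon-spanning mate pairs per named junction
#'
#' A pair increments junction J(A, B) when one mate is fully contained in
#' exon A and the other in exon B (mate order is irrelevant), both mates
#' pass the completeness filter, and the implied transcript-space inner
#' distance -- computed as if A and B were consecutive in a transcript --
#' falls inside the calibrated range. Containment uses the specific exon
#' named by the junction, so nested terminal-exon variants stay separable:
#' a pair E18.2 -> E18b is ref-specific while E18.2 -> E19 measures X1,
#' the discrimination resting entirely on the second mate's exon.
#'
#' A pair eligible for two junctions (possible only with pathological exon
#' layouts) is assigned to the junction whose implied distance is closest
#' to the calibration median; on an exact tie it is dropped.
#'
#' @param rs a [ReadSet-class].
#' @param model a [GeneModel-class].
#' @param range a `fragmentRange` from [inferFragmentRange()].
#' @return named integer vector of spanning-pair counts, one per junction
#'   in the model.
#' @export
countSpanningPairs <- function(rs, model, range) {
  stopifnot(inherits(range, "fragmentRange"))
  jn <- geneJunctions(model)
  ex <- geneExons(model)
  minus <- geneStrand(model) == "-"
  mt <- .mateTable(rs)
  cm <- .containmentMatrix(rs, ex, mt)
  sp <- .mateSpans(rs, mt)
  m1 <- which(mt$pass & mt$mate == 1L)
  m2i <- match(paste0(mt$qname, "/2")[seq_len(nrow(mt))],
               .mateKey(mt$qname, mt$mate))
  m2 <- m2i[m1]
  keep <- !is.na(m2) & mt$pass[m2]
  m1 <- m1[keep]; m2 <- m2[keep]
  nP <- length(m1)
  counts <- stats::setNames(integer(nrow(jn)), jn$junctionId)
  if (!nP) return(counts)
  dist <- matrix(NA_real_, nP, nrow(jn))
  for (k in seq_len(nrow(jn))) {
    D <- ex[jn$donor[k]]; A <- ex[jn$acceptor[k]]
    for (orient in 1:2) {
      dm <- if (orient == 1L) m1 else m2
      am <- if (orient == 1L) m2 else m1
      el <- which(cm[dm, jn$donor[k]] & cm[am, jn$acceptor[k]])
      if (!length(el)) next
      offD <- .offsetInExon(sp$s[dm[el]], sp$e[dm[el]], D, minus)
      offA <- .offsetInExon(sp$s[am[el]], sp$e[am[el]], A, minus)
      d <- (width(D) - offD$end) + (offA$start - 1L)
      ok <- d >= range$low & d <= range$high
      dist[el[ok], k] <- d[ok]
    }
  }
  nHit <- rowSums(!is.na(dist))
  one <- which(nHit == 1L)
  if (length(one)) {
    jk <- max.col(!is.na(dist[one, , drop = FALSE]), ties.method = "first")
    tab <- table(factor(jk, levels = seq_len(nrow(jn))))
    counts <- counts + as.integer(tab)
  }
  multi <- which(nHit > 1L)
  for (i in multi) {
    dev <- abs(dist[i, ] - range$median)
    best <- which(dev == min(dev, na.rm = TRUE))
    if (length(best) == 1L) counts[best] <- counts[best] + 1L
    # exact tie: counted for neither
  }
  counts
}

#' Assemble a junction count table over a cohort
#'
#' @param samples list of [ReadSet-class] objects.
#' @param model a [GeneModel-class].
#' @param range a shared `fragmentRange`; by default calibrated on the
#'   pooled same-exon pairs of all samples.
#' @return a [JunctionCountTable][CountTable-class]; per-sample totals are
#'   the deduplicated union-exon read counts (shared with the exon table),
#'   and `measures(x)` maps each junction to the isoform it measures.
#' @export
countJunctionCohort <- function(samples, model, range = NULL) {
  if (is.null(range)) {
    pools <- lapply(samples, function(s) {
      r <- try(inferFragmentRange(s, model), silent = TRUE)
      if (inherits(r, "try-error")) NULL else r
    })
    pools <- pools[!vapply(pools, is.null, logical(1))]
    if (!length(pools)) stop("fragment range not inferable from any sample")
    # pooled calibration: weighted median of per-sample bounds
    range <- structure(list(
      low = stats::median(vapply(pools, `[[`, numeric(1), "low")),
      high = stats::median(vapply(pools, `[[`, numeric(1), "high")),
      median = stats::median(vapply(pools, `[[`, numeric(1), "median")),
      percentiles = pools[[1]]$percentiles,
      nPairs = sum(vapply(pools, `[[`, integer(1), "nPairs"))),
      class = "fragmentRange")
  }
  jn <- geneJunctions(model)
  ids <- unname(vapply(samples, sampleId, character(1)))
  counts <- do.call(rbind, lapply(samples, countSpanningPairs, model = model,
                                  range = range))
  rownames(counts) <- ids
  totals <- vapply(samples, function(s) countExonReads(s, model)$total,
                   integer(1))
  names(totals) <- ids
  new("JunctionCountTable", counts = counts, totals = totals,
      measures = stats::setNames(jn$measure, jn$junctionId))
}

#' Aggregate junction counts by the isoform they measure
#'
#' @param jtable a [JunctionCountTable][CountTable-class].
#' @return matrix samples x measures; each measure column is the sum of its
#'   member junction columns.
#' @export
measureCounts <- function(jtable) {
  ms <- measures(jtable)
  um <- unique(ms[!is.na(ms)])
  out <- vapply(um, function(m)
    rowSums(counts(jtable)[, names(ms)[ms == m & !is.na(ms)], drop = FALSE]),
    numeric(nrow(counts(jtable))))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L,
                                       dimnames = list(rownames(counts(jtable)), um))
  out
}

#' Absence probe: is a junction's spanning count below threshold?
#'
#' Junctions expected in no transcribed variant (e.g. E13--E16, whose
#' presence would imply the exon-14/15-skipping variant; or NE6p--E4,
#' whose absence shows the NE6-terminated variant is truncated) are used
#' as probes: a variant is ruled out when the probe stays silent.
#'
#' @param junctionId probe junction id.
#' @param jtable a [JunctionCountTable][CountTable-class].
#' @param tau threshold in raw spanning pairs (default 1: absent means not
#'   a single pair).
#' @return named logical vector per sample; `TRUE` = absent.
#' @export
absenceProbe <- function(junctionId, jtable, tau = 1) {
  cc <- counts(jtable)
  if (!junctionId %in% colnames(cc)) stop("junction not counted: ", junctionId)
  cc[, junctionId] < tau
}
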