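#' @include junction-spanning.R
NULL

# per-base transcript -> genome position map, built directly from the exon
# walk (deliberately independent of txLocate's interval arithmetic)
.txGenomeMap <- function(model, tx) {
  e <- txExons(model, tx)
  minus <- geneStrand(model) == "-"
  unlist(lapply(seq_along(e), function(i)
    if (minus) seq(end(e)[i], start(e)[i]) else seq(start(e)[i], end(e)[i])),
    use.names = FALSE)
}

#' Probability that a fragment from one transcript is counted for a junction
#'
#' Computes, by exhaustive enumeration over every (fragment length, start
#' position) placement under the simulator's sampling model, the
#' probability that a fragment drawn from transcript `tx` yields a counted
#' spanning pair for junction `junctionId`: first mate fully inside the
#' donor exon, last mate fully inside the acceptor exon (or vice versa),
#' implied inner distance under donor--acceptor adjacency within `range`.
#' Fragment lengths are weighted by the rounded truncated normal the
#' simulator draws from; start positions by the (optionally 5'-depleted)
#' positional weights.
#'
#' @param model a [GeneModel-class].
#' @param tx source transcript id.
#' @param junctionId junction id in the model.
#' @param cfg a [simConfig()] (only the fragment-model fields are used).
#' @param range a `fragmentRange`.
#' @return a probability in `[0, 1]`.
#' @seealso [expectedJunctionCounts()]
#' @export
junctionDetectionProb <- function(model, tx, junctionId, cfg, range) {
  jn <- geneJunctions(model)
  j <- jn[jn$junctionId == junctionId, ]
  if (!nrow(j)) stop("unknown junction: ", junctionId)
  ex <- geneExons(model)
  D <- ex[j$donor]; A <- ex[j$acceptor]
  minus <- geneStrand(model) == "-"
  g <- .txGenomeMap(model, tx)
  L <- length(g)
  rl <- cfg$readLen
  inD <- g >= start(D) & g <= end(D)
  inA <- g >= start(A) & g <= end(A)
  csD <- c(0L, cumsum(inD)); csA <- c(0L, cumsum(inA))
  okIn <- function(cs, from) cs[from + rl] - cs[from] == rl   # mate [from, from+rl-1]
  # transcript-orientation offset of genomic position within exon X
  offIn <- function(pos, X) if (minus) end(X) - pos + 1L else pos - start(X) + 1L
  lo <- 2L * rl
  hi <- min(L, ceiling(cfg$fragMean + 8 * cfg$fragSd))
  if (hi < lo) return(0)
  plo <- stats::pnorm(lo, cfg$fragMean, cfg$fragSd)
  phi <- stats::pnorm(min(L, Inf), cfg$fragMean, cfg$fragSd)
  wpos <- .positionWeights(L, cfg$fivePrimeDepletion, cfg$depletionK)
  cw <- cumsum(wpos)
  total <- 0
  for (f in lo:hi) {
    pf <- (stats::pnorm(min(f + 0.5, L), cfg$fragMean, cfg$fragSd) -
             stats::pnorm(max(f - 0.5, lo), cfg$fragMean, cfg$fragSd)) /
      (phi - plo)
    if (pf <= 0) next
    ns <- L - f + 1L
    s <- seq_len(ns)                 # mate1 start; mate2 start = s + f - rl
    s2 <- s + f - rl
    for (orient in 1:2) {
      if (orient == 1L) { okD <- okIn(csD, s); okA <- okIn(csA, s2)
                          dm <- s; am <- s2 }
      else              { okD <- okIn(csD, s2); okA <- okIn(csA, s)
                          dm <- s2; am <- s }
      cand <- which(okD & okA)
      if (!length(cand)) next
      dEnd <- offIn(g[dm[cand] + rl - 1L], D)       # donor-mate 3' offset
      aStart <- offIn(g[am[cand]], A)               # acceptor-mate 5' offset
      d <- (width(D) - dEnd) + (aStart - 1L)
      cand <- cand[d >= range$low & d <= range$high]
      if (length(cand))
        total <- total + pf * sum(wpos[cand]) / cw[ns]
      if (orient == 1L && identical(j$donor, j$acceptor)) break
    }
  }
  total
}

#' Expected junction counts under a simulation configuration
#'
#' For every junction of the model, the expected spanning-pair count per
#' sample: `nPairs` times the mixture-weighted detection probability, the
#' mixture weight of transcript t being its molar proportion times its
#' length (the probability a fragment originates from t).
#'
#' @inheritParams junctionDetectionProb
#' @return named numeric vector over the model's junctions.
#' @export
expectedJunctionCounts <- function(model, cfg, range) {
  p <- cfg$profile$proportions
  p <- p[p > 0]
  L <- vapply(names(p), function(t) txLength(model, t), numeric(1))
  w <- p * L; w <- w / sum(w)
  jn <- geneJunctions(model)
  out <- stats::setNames(numeric(nrow(jn)), jn$junctionId)
  for (jid in jn$junctionId)
    out[jid] <- cfg$nPairs * sum(vapply(names(p), function(t)
      w[[t]] * junctionDetectionProb(model, t, jid, cfg, range), numeric(1)))
  out
}
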