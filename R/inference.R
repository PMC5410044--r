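#' @include normalize.R
NULL

#' Detect the true terminal-exon endpoint from coverage drop-off
#'
#' Among ordered candidate endpoints of a terminal-exon block (nt offsets
#' from the shared block start, in transcript orientation), picks the one
#' at which per-base coverage stops. The chosen endpoint is the farthest
#' candidate whose upstream segment (from the previous candidate) still
#' carries signal, i.e. mean coverage above `signalFrac` of the strongest
#' segment. This deliberately tolerates partial drops at earlier
#' endpoints: when a short and a long 3' isoform are co-expressed,
#' coverage steps down at the short isoform's end but the transcript end
#' is where it falls to background. Two structural effects motivate a
#' background fraction rather than a zero test: the final read-length of
#' a transcript is covered only by mate tails (a triangular ramp), and
#' real alignments carry stray reads past the true end.
#'
#' For every candidate the drop statistic -- the mean coverage of the
#' segment ending at e_i over the mean of the following segment plus a
#' pseudocount of one -- is reported; the call is flagged low-confidence
#' when the chosen endpoint's statistic stays below `minDrop`.
#'
#' @param coverage per-base coverage vector over the terminal-exon block,
#'   position 1 = shared block start (transcript orientation).
#' @param endpoints ascending candidate endpoints (offsets, nt); names are
#'   reported in the call.
#' @param minDrop drop statistic below which the call is flagged
#'   low-confidence (default 5).
#' @param signalFrac fraction of the strongest segment mean that counts
#'   as signal (default 0.02).
#' @return a `utrCall` list: `status` (`"call"`, `"low-confidence"`,
#'   `"no-call"`), `endpoint`, `exon`, `drop` (statistic per candidate).
#' @export
detectTerminalExon <- function(coverage, endpoints, minDrop = 5.0,
                               signalFrac = 0.02) {
  stopifnot(length(endpoints) >= 2L, !is.unsorted(endpoints),
            length(coverage) >= max(endpoints))
  if (all(coverage == 0))
    return(structure(list(status = "no-call", endpoint = NA_integer_,
                          exon = NA_character_,
                          drop = stats::setNames(rep(NA_real_,
                            length(endpoints)), names(endpoints))),
                     class = "utrCall"))
  bounds <- c(0L, endpoints, length(coverage))
  segMean <- vapply(seq_len(length(bounds) - 1L), function(i) {
    if (bounds[i + 1L] <= bounds[i]) 0 else
      mean(coverage[(bounds[i] + 1L):bounds[i + 1L]])
  }, numeric(1))
  up <- segMean[seq_along(endpoints)]
  down <- segMean[seq_along(endpoints) + 1L]
  drop <- up / (down + 1)
  names(drop) <- names(endpoints)
  bg <- signalFrac * max(segMean)
  sig <- which(up > bg)
  if (!length(sig))
    return(structure(list(status = "no-call", endpoint = NA_integer_,
                          exon = NA_character_, drop = drop),
                     class = "utrCall"))
  i <- max(sig)
  status <- if (drop[i] >= minDrop) "call" else "low-confidence"
  structure(list(status = status, endpoint = unname(endpoints[i]),
                 exon = if (!is.null(names(endpoints))) names(endpoints)[i]
                        else NA_character_,
                 drop = drop),
            class = "utrCall")
}

#' Scan the terminal-exon block of a sample and call the 3' end
#'
#' Computes per-base coverage over the gene's E18 block (the union of the
#' candidate terminal-exon variants), orients it 5'->3', and runs
#' [detectTerminalExon()] against the annotated candidate endpoints.
#'
#' @param rs a [ReadSet-class].
#' @param model a [GeneModel-class] with E18.1..E18.5 candidates.
#' @param minDrop see [detectTerminalExon()].
#' @return a `utrCall`.
#' @export
terminalExonScan <- function(rs, model, minDrop = 5.0) {
  ep <- terminalEndpoints(model)
  ex <- geneExons(model)[names(ep)]
  region <- range(ex, ignore.strand = TRUE)
  cov <- coverageProfile(rs, region)
  if (geneStrand(model) == "-") cov <- rev(cov)
  detectTerminalExon(cov, ep, minDrop)
}

#' 3'UTR length implied by a terminal-endpoint call
#'
#' The detected transcript end (the transcript's length with its terminal
#' exon cut at the called endpoint) minus the annotated CDS end; the stop
#' codon is counted as part of the CDS, so a transcript ending exactly at
#' its stop codon has a 0-nt UTR.
#'
#' @param call a `utrCall` from [detectTerminalExon()].
#' @param model a [GeneModel-class].
#' @param tx transcript whose CDS annotation applies (default `"ref"`).
#' @return UTR length in nt.
#' @export
estimateUtrLength <- function(call, model, tx = "ref") {
  if (call$status == "no-call") stop("cannot size a UTR from a no-call")
  cds <- cdsEndTx(model, tx)
  if (is.na(cds)) stop("transcript '", tx, "' has no annotated CDS end")
  e <- txExons(model, tx)
  txEnd <- txLength(model, tx) - width(e)[length(e)] + call$endpoint
  utr <- txEnd - cds
  if (utr < 0)
    stop("detected end upstream of the CDS end; annotation inconsistent")
  utr
}

#' Assess coverage homogeneity across a region
#'
#' Splits a coverage vector into near-equal windows and asks whether the
#' window means are uniform: homogeneous means their coefficient of
#' variation stays below `cvMax` and no window is empty while the region
#' as a whole has signal. Used to show that reads spread across the entire
#' ~7-kb downstream exon rather than piling at its 5' end.
#'
#' @param coverage per-base coverage vector.
#' @param nWindows number of windows (default 20).
#' @param cvMax CV threshold (default 0.5).
#' @return list: `windowMeans`, `cv`, `homogeneous`.
#' @export
assessRegionHomogeneity <- function(coverage, nWindows = 20L, cvMax = 0.5) {
  stopifnot(length(coverage) >= nWindows)
  if (nWindows == 1L) {
    warning("a single window is trivially homogeneous")
    wm <- mean(coverage)
  } else {
    idx <- cut(seq_along(coverage), nWindows, labels = FALSE)
    wm <- as.numeric(tapply(coverage, idx, mean))
  }
  cv <- if (mean(wm) > 0) stats::sd(wm) / mean(wm) else NA_real_
  hom <- if (nWindows == 1L) TRUE
         else isTRUE(cv < cvMax) && !(any(wm == 0) && mean(coverage) > 0)
  list(windowMeans = wm, cv = cv, homogeneous = hom)
}

#' Rule-based transcript-variant presence calls
#'
#' Applies, in a declared order, the observational rules that resolve
#' which transcript variants of the gene are actually transcribed:
#' \enumerate{
#'   \item Probe-exon absence: if the NE1--NE4 probe exons are silent
#'     (median normalized count below `tauAbs`), the variants that would
#'     transcribe them (005, X3--X6, X8, X9) are absent; likewise NE5 for
#'     002.
#'   \item Junction absence probes: spanning pairs across E13--E16 would
#'     imply the exon-14/15-skipping X7; their absence rules it out.
#'   \item Presence rules: spanning pairs E18.2--E18b, E18.2--E19 and
#'     E17--E19 establish ref, X1 and X2 respectively.
#'   \item 004: called when E3/NE6 show a clear read excess over the other
#'     shared exons and the NE6-specific region NE6p is expressed; the
#'     silent NE6p--E4 junction then marks it truncated.
#'   \item 003: left undetermined (negligible) unless the 5'-half exons
#'     show a clear excess over the 3'-half exons.
#' }
#' Every status records the rule that fired and the counts it used, so a
#' call can be re-derived by hand from its own evidence.
#'
#' @param normExons a [NormalizedTable-class] of exon counts.
#' @param jtable a [JunctionCountTable][CountTable-class].
#' @param model a [GeneModel-class].
#' @param tauAbs absence threshold on median normalized exon counts;
#'   default 1 percent of the median over the constitutive exons E4--E17.
#' @param tauJunction presence threshold in raw spanning pairs (default 1).
#' @param excessFactor E3/NE6 excess factor for the 004 rule (default 1.5,
#'   a tunable heuristic).
#' @param margin003 log2 margin for the 003 rule (default 0.5).
#' @return data.frame (`variant`, `status`, `rule`, `evidence`), status in
#'   present/absent/truncated/undetermined.
#' @export
callVariantPresence <- function(normExons, jtable, model, tauAbs = NULL,
                                tauJunction = 1, excessFactor = 1.5,
                                margin003 = 0.5) {
  v <- normValues(normExons, masked = TRUE)
  med <- apply(v, 2L, stats::median, na.rm = TRUE)
  const <- paste0("E", 4:17)
  const <- const[const %in% names(med)]
  if (is.null(tauAbs))
    tauAbs <- 0.01 * stats::median(med[const])
  tauAbs <- max(tauAbs, .Machine$double.eps)
  jtot <- colSums(counts(jtable))
  res <- list()
  say <- function(variant, status, rule, evidence)
    res[[length(res) + 1L]] <<- data.frame(variant = variant, status = status,
                                           rule = rule, evidence = evidence,
                                           stringsAsFactors = FALSE)
  fmt <- function(x) paste(sprintf("%s=%.3g", names(x), x), collapse = ", ")

  # (1) probe-exon absence
  pr14 <- med[c("NE1", "NE2", "NE3", "NE4")]
  dep14 <- c("005", "X3", "X4", "X5", "X6", "X8", "X9")
  if (all(pr14 < tauAbs)) {
    for (d in dep14) say(d, "absent", "probe-exons-NE1-NE4-silent", fmt(pr14))
  } else {
    for (d in dep14) say(d, "undetermined", "probe-exons-NE1-NE4-expressed",
                         fmt(pr14))
  }
  if (med[["NE5"]] < tauAbs)
    say("002", "absent", "probe-exon-NE5-silent", fmt(med["NE5"]))
  else say("002", "undetermined", "probe-exon-NE5-expressed", fmt(med["NE5"]))

  # (2) junction absence probes
  x7 <- as.integer(jtot[["E13-E16"]])
  if (x7 < tauJunction)
    say("X7", "absent", "junction-probe-E13-E16-silent",
        sprintf("E13-E16=%d", x7))
  else say("X7", "present", "junction-probe-E13-E16-detected",
           sprintf("E13-E16=%d", x7))

  # (3) presence from isoform-specific junctions
  for (p in list(c("ref", "E18.2-E18b"), c("X1", "E18.2-E19"),
                 c("X2", "E17-E19"))) {
    n <- as.integer(jtot[[p[2]]])
    say(p[1], if (n >= tauJunction) "present" else "absent",
        paste0("junction-", p[2]), sprintf("%s=%d", p[2], n))
  }

  # (4) 004: E3/NE6 excess + NE6p expression; NE6p-E4 silence = truncation
  excess <- mean(med[c("E3", "NE6")]) / mean(med[const])
  ne6p <- med[["NE6p"]]
  rt <- as.integer(jtot[["NE6p-E4"]])
  ev004 <- sprintf("excess=%.3g, NE6p=%.3g, NE6p-E4=%d", excess, ne6p, rt)
  if (is.finite(excess) && excess >= excessFactor && ne6p >= tauAbs) {
    if (rt < tauJunction) say("004", "truncated", "NE6-excess+NE6p-E4-silent",
                              ev004)
    else say("004", "present", "NE6-excess+NE6p-E4-detected", ev004)
  } else say("004", "absent", "no-NE6-excess", ev004)

  # (5) 003: 5'-half vs 3'-half balance
  five <- paste0("E", 1:9); three <- paste0("E", 10:17)
  r003 <- mean(med[five]) / mean(med[three])
  ev003 <- sprintf("mean(E1-9)/mean(E10-17)=%.3g", r003)
  if (is.finite(r003) && log2(r003) > margin003)
    say("003", "present", "five-prime-excess", ev003)
  else say("003", "undetermined", "no-five-prime-excess", ev003)

  out <- do.call(rbind, res)
  attr(out, "tauAbs") <- tauAbs
  attr(out, "tauJunction") <- tauJunction
  out
}

#' Call the exon-3--10-skipping variant and its 3'-isoform breakdown
#'
#' Full-length transcription is evidenced by E2--E3 spanning pairs, the
#' skipping variant by E2--E11 pairs (the junction its specific siRNA
#' straddles). When the skipping variant is present, its 3'-isoform
#' composition reuses the same ref/X1/X2 junction measures, since the
#' skipping variant is itself a mixture of the three 3' isoforms.
#'
#' @param jtable a [JunctionCountTable][CountTable-class].
#' @param tau presence threshold in raw spanning pairs (default 1).
#' @return list: `fullLengthPresent`, `delta310Present`, `counts` (E2-E3,
#'   E2-E11 totals), `breakdown` (ref/X1/X2 junction totals or NULL).
#' @export
callDelta310 <- function(jtable, tau = 1) {
  jtot <- colSums(counts(jtable))
  need <- c("E2-E3", "E2-E11")
  if (!all(need %in% names(jtot)))
    stop("junction table lacks: ", paste(setdiff(need, names(jtot)),
                                         collapse = ", "))
  fl <- jtot[["E2-E3"]]; dl <- jtot[["E2-E11"]]
  breakdown <- if (dl >= tau)
    c(ref = jtot[["E18.2-E18b"]], X1 = jtot[["E18.2-E19"]],
      X2 = jtot[["E17-E19"]])
  else NULL
  list(fullLengthPresent = fl >= tau, delta310Present = dl >= tau,
       counts = c(`E2-E3` = fl, `E2-E11` = dl), breakdown = breakdown)
}
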