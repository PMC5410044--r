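#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata Rle runValue
#' @importFrom GenomicRanges GRanges seqnames start end width strand ranges
#' @importFrom GenomicRanges strand<-
#' @importFrom IRanges IRanges
NULL

#' GeneModel: exon-variant catalog, transcript structures and named junctions
#'
#' A `GeneModel` describes one gene: a catalog of exon variants (possibly
#' nested or overlapping, e.g. alternative terminal-exon endpoints sharing a
#' start), a set of transcript structures (ordered exon lists in 5'->3'
#' transcript orientation), and a set of named exon--exon junctions whose
#' mate-pair spanning counts measure specific isoforms.
#'
#' Coordinates are 1-based inclusive genomic, always stored with
#' `start <= end`; the gene strand defines transcript orientation. For a
#' minus-strand gene the 5'-most exon is the one with the highest genomic
#' coordinate.
#'
#' @slot geneId single gene identifier.
#' @slot exons a [GenomicRanges::GRanges] of exon variants, names are exon
#'   ids; one chromosome, one strand.
#' @slot transcripts named list; each element is a list with entries
#'   `id`, `exons` (character vector of exon ids, 5'->3'), and `cdsEndTx`
#'   (1-based transcript-space coordinate of the last base of the stop
#'   codon, or `NA_integer_` for non-coding/truncated models).
#' @slot junctions data.frame with columns `junctionId`, `donor`,
#'   `acceptor`, `measure`, `absenceProbe` (logical). Donor precedes
#'   acceptor in at least one transcript unless the junction is an absence
#'   probe (a junction expected in no transcript, used to rule variants out).
#'
#' @seealso [brafGeneModel()], [readGeneModel()], [txProject()]
#' @export
setClass("GeneModel",
  representation(
    geneId = "character",
    exons = "GRanges",
    transcripts = "list",
    junctions = "data.frame"
  )
)

.validGeneModel <- function(object) {
  msg <- character()
  ex <- object@exons
  if (length(object@geneId) != 1L || !nzchar(object@geneId))
    msg <- c(msg, "geneId must be a single non-empty string")
  if (is.null(names(ex)) || anyDuplicated(names(ex)) || any(!nzchar(names(ex))))
    msg <- c(msg, "exon ids must be unique non-empty names on the exon GRanges")
  if (length(unique(as.character(seqnames(ex)))) > 1L)
    msg <- c(msg, "all exons must lie on one chromosome")
  st <- unique(as.character(strand(ex)))
  if (length(st) != 1L || !st %in% c("+", "-"))
    msg <- c(msg, "gene strand must be a single '+' or '-'")
  txs <- object@transcripts
  if (length(txs)) {
    if (is.null(names(txs)) || anyDuplicated(names(txs)))
      msg <- c(msg, "transcripts must be a uniquely named list")
    for (tx in txs) {
      if (!length(tx$exons))
        msg <- c(msg, sprintf("transcript '%s' has no exons", tx$id))
      bad <- setdiff(tx$exons, names(ex))
      if (length(bad))
        msg <- c(msg, sprintf("transcript '%s' references undefined exon(s): %s",
                              tx$id, paste(bad, collapse = ", ")))
      else {
        e <- ex[tx$exons]
        if (length(e) > 1L) {
          # consecutive exons must not overlap on the genome
          o <- order(start(e))
          if (any(start(e)[o][-1L] <= end(e)[o][-length(e)]))
            msg <- c(msg, sprintf("transcript '%s' has overlapping exons", tx$id))
          # exon order must be 5'->3' in transcript orientation
          gord <- if (st == "+") order(start(e)) else order(-start(e))
          if (!identical(gord, seq_along(e)))
            msg <- c(msg, sprintf("transcript '%s' exons are not in 5'->3' order", tx$id))
        }
        if (!is.na(tx$cdsEndTx) && tx$cdsEndTx > sum(width(e)))
          msg <- c(msg, sprintf("transcript '%s': cdsEndTx exceeds transcript length", tx$id))
      }
    }
  }
  jn <- object@junctions
  if (nrow(jn)) {
    need <- c("junctionId", "donor", "acceptor", "measure", "absenceProbe")
    if (!all(need %in% names(jn)))
      msg <- c(msg, "junctions must have columns junctionId, donor, acceptor, measure, absenceProbe")
    else {
      bad <- setdiff(c(jn$donor, jn$acceptor), names(ex))
      if (length(bad))
        msg <- c(msg, sprintf("junction references undefined exon(s): %s",
                              paste(unique(bad), collapse = ", ")))
      if (anyDuplicated(jn$junctionId))
        msg <- c(msg, "junction ids must be unique")
      # non-probe junctions must be realized (donor immediately before acceptor
      # is not required, but donor must precede acceptor in some transcript)
      if (!length(bad)) for (i in seq_len(nrow(jn))) {
        if (isTRUE(jn$absenceProbe[i])) next
        ok <- any(vapply(object@transcripts, function(tx) {
          d <- match(jn$donor[i], tx$exons); a <- match(jn$acceptor[i], tx$exons)
          !is.na(d) && !is.na(a) && d < a
        }, logical(1)))
        # the donor/acceptor may also be derived sub-exons (e.g. a terminal-exon
        # suffix) that are genomically inside a transcript's exon; accept when
        # both intervals are covered by one transcript's exon set in order
        if (!ok) ok <- any(vapply(object@transcripts, function(tx) {
          e <- ex[tx$exons]
          dIn <- .withinAny(ex[jn$donor[i]], e); aIn <- .withinAny(ex[jn$acceptor[i]], e)
          dIn && aIn
        }, logical(1)))
        if (!ok)
          msg <- c(msg, sprintf(
            "junction '%s' is realized in no transcript and not flagged absenceProbe",
            jn$junctionId[i]))
      }
    }
  }
  if (length(msg)) msg else TRUE
}

.withinAny <- function(q, subj) {
  length(IRanges::findOverlaps(ranges(q), ranges(subj), type = "within")) > 0L
}

setValidity("GeneModel", .validGeneModel)

#' ReadSet: aligned paired-end reads for one sample
#'
#' Holds the aligned blocks of every mate of every fragment, plus the
#' per-mate flags that the completeness filter inspects. One row of
#' `blocks` is one contiguous aligned block (a CIGAR match stretch);
#' a junction-crossing mate has several blocks separated by N gaps.
#'
#' @slot blocks a [GenomicRanges::GRanges]; metadata columns: `qname`
#'   (fragment name), `mate` (1 or 2), and logical flags `paired`,
#'   `mateMapped`, `secondary`, `supplementary`, `clipped`, replicated
#'   across the blocks of a mate.
#' @slot sampleId sample identifier.
#' @slot meta free-form list (simulation truth, provenance).
#' @export
setClass("ReadSet",
  representation(blocks = "GRanges", sampleId = "character", meta = "list"),
  prototype(meta = list())
)

.validReadSet <- function(object) {
  msg <- character()
  mc <- mcols(object@blocks)
  need <- c("qname", "mate", "paired", "mateMapped", "secondary",
            "supplementary", "clipped")
  if (!all(need %in% names(mc)))
    msg <- c(msg, paste("blocks must carry metadata columns:",
                        paste(need, collapse = ", ")))
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (length(msg)) msg else TRUE
}
setValidity("ReadSet", .validReadSet)

#' CountTable: sample x feature raw count matrix with per-sample totals
#'
#' Rows are samples, columns features (exon variants or junctions).
#' `totals` holds the per-sample total of reads mapped to the gene,
#' counted once over the deduplicated union of all exon intervals; nested
#' exon variants deliberately double-count in the matrix (each variant is
#' an independent containment probe) but never in the totals.
#'
#' @slot counts non-negative integer matrix, dimnames sample x feature.
#' @slot totals named numeric vector, one deduplicated total per sample.
#' @export
setClass("CountTable", representation(counts = "matrix", totals = "numeric"))

.validCountTable <- function(object) {
  msg <- character()
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(object@totals) != nrow(object@counts))
    msg <- c(msg, "one total per sample (row) required")
  if (!identical(names(object@totals), rownames(object@counts)))
    msg <- c(msg, "totals names must match sample rownames")
  if (length(msg)) msg else TRUE
}
setValidity("CountTable", .validCountTable)

#' @rdname CountTable-class
#' @export
setClass("ExonCountTable", contains = "CountTable")

#' JunctionCountTable: spanning-pair counts with isoform-measure mapping
#'
#' @slot measures named character vector mapping each junction column to
#'   the isoform quantity its spanning pairs measure (e.g. `"ref"`,
#'   `"X1"`, `"ref+X1"`), `NA` for absence probes.
#' @rdname CountTable-class
#' @export
setClass("JunctionCountTable", contains = "CountTable",
         representation(measures = "character"))

#' NormalizedTable: normalized counts with an outlier mask
#'
#' Values are `raw / total * 1e7`, the per-sample total being the
#' deduplicated union-exon read count. `mask` flags cells discarded by the
#' quantile outlier filter (TRUE = masked).
#'
#' @slot values numeric matrix, sample x feature.
#' @slot mask logical matrix, same dim.
#' @slot totals per-sample totals used for scaling.
#' @slot scaleFactor the multiplicative factor (default 1e7).
#' @export
setClass("NormalizedTable",
  representation(values = "matrix", mask = "matrix", totals = "numeric",
                 scaleFactor = "numeric"))

.validNormalizedTable <- function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask must have identical dimensions")
  if (any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "normalized values must be non-negative")
  if (length(msg)) msg else TRUE
}
setValidity("NormalizedTable", .validNormalizedTable)
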