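#' @include gene-model.R
NULL

#' Built-in BRAF-like gene model
#'
#' A synthetic minus-strand gene whose topology mirrors the human BRAF
#' locus as it matters for 3'-terminal isoform analysis: shared exons
#' E1--E17; a block of five alternative terminal-exon endpoints E18.1--E18.5
#' (759, 154, 250, 292 and 174 nt) sharing one start; the derived
#' ref-specific suffix E18b (96 nt, the part of E18.3 downstream of
#' E18.2's endpoint); a long (~7 kb) downstream exon E19 carrying the
#' alternative stop codon and 3'UTR of the X1/X2 isoforms; probe exons
#' NE1--NE5 (each private to annotation-only variants); NE6, a 548-nt
#' longer version of E3, with its derived specific region NE6p.
#'
#' Transcripts: `ref` (ends in E18.3, 76-nt 3'UTR under the convention that
#' the stop codon belongs to the CDS), `X1` (E18.2 spliced to E19), `X2`
#' (E17 spliced directly to E19), the truncated `004` (ends at NE6), the
#' exon-14/15-skipping `X7`, a hypothetical read-through `004rt` (NE6
#' spliced on to E4, used to exercise the NE6p--E4 absence probe), and the
#' exon-3--10-skipping `delta310-ref/X1/X2` (E2 spliced to E11).
#'
#' Junctions: `E17-E18.2` (measures ref+X1), `E18.2-E18b` (ref),
#' `E18.2-E19` (X1), `E17-E19` (X2), `E2-E3` (full length), `E2-E11`
#' (delta 3-10), and the absence probes `E13-E16` (X7) and `NE6p-E4`
#' (004 read-through).
#'
#' All genomic coordinates are invented (synthetic chromosome `chrS`);
#' only exon lengths and splice topology are meaningful.
#'
#' @return a validated [GeneModel-class].
#' @examples
#' gm <- brafGeneModel()
#' width(geneExons(gm))[c("E18.2", "E18.3", "E18b")]
#' @export
brafGeneModel <- function() {
  # 5'->3' walk on the minus strand: each exon ends where `pos` stands and
  # extends to lower coordinates; `intron` is the gap to the next exon.
  lens <- c(E1 = 300L, E2 = 120L, E3 = 150L, E4 = 135L, E5 = 102L,
            E6 = 120L, E7 = 138L, E8 = 111L, E9 = 126L, E10 = 144L,
            E11 = 117L, E12 = 108L, E13 = 132L, E14 = 177L, E15 = 216L,
            E16 = 123L, E17 = 153L)
  introns <- c(900L, 1200L, 1200L, 800L, 700L, 600L, 900L, 500L, 700L,
               1000L, 600L, 800L, 600L, 500L, 700L, 400L, 1000L)
  pos <- 1400000L
  ends <- starts <- integer(length(lens))
  for (i in seq_along(lens)) {
    ends[i] <- pos
    starts[i] <- pos - lens[i] + 1L
    pos <- starts[i] - 1L - introns[i]
  }
  names(ends) <- names(starts) <- names(lens)
  b18 <- pos                      # shared start (genomic end) of the E18 block
  e18 <- c(E18.1 = 759L, E18.2 = 154L, E18.3 = 250L, E18.4 = 292L,
           E18.5 = 174L)
  e19end <- b18 - 759L - 4000L    # 4-kb intron past the longest E18 variant
  probes <- data.frame(            # NE1..NE5 sit inside introns 10..13 and 1
    id = c("NE1", "NE2", "NE3", "NE4", "NE5"),
    end = c(starts[["E10"]] - 301L, starts[["E11"]] - 201L,
            starts[["E12"]] - 301L, starts[["E13"]] - 201L,
            starts[["E1"]] - 301L))
  probes$start <- probes$end - 149L

  exd <- rbind(
    data.frame(id = names(lens), start = unname(starts), end = unname(ends)),
    data.frame(id = names(e18), start = b18 - unname(e18) + 1L, end = b18),
    data.frame(id = "E19", start = e19end - 6999L, end = e19end),
    data.frame(id = "NE6", start = starts[["E3"]] - 548L, end = ends[["E3"]]),
    probes[, c("id", "start", "end")]
  )

  e117 <- names(lens)
  txs <- list(
    list(id = "ref", exons = c(e117, "E18.3"), cdsEndTx = 2472L + 174L),
    list(id = "X1", exons = c(e117, "E18.2", "E19"), cdsEndTx = 2472L + 154L + 300L),
    list(id = "X2", exons = c(e117, "E19"), cdsEndTx = 2472L + 350L),
    list(id = "004", exons = c("E1", "E2", "NE6"), cdsEndTx = NA),
    list(id = "004rt", exons = c("E1", "E2", "NE6", "E4", "E5", "E6"),
         cdsEndTx = NA),
    list(id = "X7", exons = c(e117[1:13], "E16", "E17", "E18.3"), cdsEndTx = NA),
    list(id = "delta310-ref", exons = c("E1", "E2", e117[11:17], "E18.3"),
         cdsEndTx = NA),
    list(id = "delta310-X1", exons = c("E1", "E2", e117[11:17], "E18.2", "E19"),
         cdsEndTx = NA),
    list(id = "delta310-X2", exons = c("E1", "E2", e117[11:17], "E19"),
         cdsEndTx = NA)
  )

  jn <- data.frame(
    junctionId = c("E17-E18.2", "E18.2-E18b", "E18.2-E19", "E17-E19",
                   "E2-E3", "E2-E11", "E13-E16", "NE6p-E4"),
    donor = c("E17", "E18.2", "E18.2", "E17", "E2", "E2", "E13", "NE6p"),
    acceptor = c("E18.2", "E18b", "E19", "E19", "E3", "E11", "E16", "E4"),
    measure = c("ref+X1", "ref", "X1", "X2", "fl", "delta310", "X7", "004rt"),
    absenceProbe = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )

  gm <- GeneModel("BRAFlike", "chrS", "-", exd, txs, emptyJunctions())
  gm <- deriveSpecificRegion(gm, "E18.3", "E18.2", "E18b")
  gm <- deriveSpecificRegion(gm, "NE6", "E3", "NE6p")
  gm@junctions <- jn
  validObject(gm)
  gm
}

#' Candidate terminal-exon endpoints of the E18 block
#'
#' Transcript-orientation offsets (nt from the shared E18 start) of the
#' five annotated endpoints, sorted ascending, named by exon variant.
#'
#' @param model a [GeneModel-class] with E18.1..E18.5 in its catalog.
#' @return named integer vector of endpoint offsets.
#' @export
terminalEndpoints <- function(model) {
  ids <- paste0("E18.", 1:5)
  w <- width(geneExons(model)[ids])
  stats::setNames(w, ids)[order(w)]
}
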