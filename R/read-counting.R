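#' @include simulate.R
NULL

#' Read paired-end alignments from SAM/BAM
#'
#' Loads every primary alignment (secondary and supplementary records are
#' dropped) overlapping `region`, with aligned blocks parsed from the
#' CIGAR (an `N` gap splits a mate into several blocks) and the flags the
#' completeness filter inspects.
#'
#' @param path a `.sam` or `.bam` file; SAM input is converted (sorted and
#'   indexed) on the fly.
#' @param region optional [GenomicRanges::GRanges] of length 1 restricting
#'   the fetch; requires a sorted, indexed BAM (automatic for SAM input).
#' @param sampleId sample name to attach; default the file base name.
#' @return a [ReadSet-class].
#' @export
readAlignments <- function(path, region = NULL, sampleId = NULL) {
  if (is.null(sampleId))
    sampleId <- sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    dest <- tempfile()
    path <- suppressMessages(Rsamtools::asBam(path, dest, overwrite = TRUE,
                                              indexDestination = TRUE))
  } else if (ext != "bam") stop("expected .sam or .bam: ", path)
  param <- if (is.null(region)) Rsamtools::ScanBamParam(what = c("qname", "flag"))
  else Rsamtools::ScanBamParam(what = c("qname", "flag"), which = region)
  gal <- GenomicAlignments::readGAlignments(path, param = param)
  flag <- mcols(gal)$flag
  keep <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  gal <- gal[keep]; flag <- flag[keep]
  qname <- mcols(gal)$qname
  paired <- bitwAnd(flag, 1L) > 0L
  mate <- ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)
  mateMapped <- paired & bitwAnd(flag, 8L) == 0L
  clipped <- grepl("[SH]", GenomicAlignments::cigar(gal))
  grl <- GenomicAlignments::grglist(gal)
  n <- lengths(grl)
  gr <- unlist(grl, use.names = FALSE)
  strand(gr) <- "*"
  mcols(gr) <- S4Vectors::DataFrame(
    qname = rep(qname, n), mate = rep(mate, n), paired = rep(paired, n),
    mateMapped = rep(mateMapped, n), secondary = rep(FALSE, length(gr)),
    supplementary = rep(FALSE, length(gr)), clipped = rep(clipped, n))
  new("ReadSet", blocks = gr, sampleId = sampleId, meta = list(source = path))
}

# ---- internal mate-level machinery ---------------------------------------

# mate key; returns zero-length for zero-length input (paste0 would recycle)
.mateKey <- function(q, m) paste0(q, "/", m)[seq_along(q)]

# one row per mate: qname, mate, first/last block index, nBlocks, pass
.mateTable <- function(rs) {
  mc <- mcols(rs@blocks)
  key <- .mateKey(mc$qname, mc$mate)
  f <- factor(key, levels = unique(key))
  idx <- as.integer(f)
  nb <- tabulate(idx, nbins = nlevels(f))
  first <- which(!duplicated(idx))
  data.frame(
    qname = mc$qname[first], mate = mc$mate[first], id = seq_len(nlevels(f)),
    nBlocks = nb,
    pass = (mc$paired & mc$mateMapped & !mc$secondary & !mc$supplementary &
              !mc$clipped)[first],
    stringsAsFactors = FALSE)
}

# logical matrix [mates x exons]: every block of the mate within the exon
.containmentMatrix <- function(rs, exons, mt = .mateTable(rs)) {
  mc <- mcols(rs@blocks)
  key <- .mateKey(mc$qname, mc$mate)
  mateIdx <- match(key, .mateKey(mt$qname, mt$mate))
  hits <- GenomicRanges::findOverlaps(rs@blocks, exons, type = "within",
                                      ignore.strand = TRUE)
  m <- matrix(0L, nrow = nrow(mt), ncol = length(exons),
              dimnames = list(NULL, names(exons)))
  if (length(hits)) {
    qh <- mateIdx[S4Vectors::queryHits(hits)]
    sh <- S4Vectors::subjectHits(hits)
    tab <- table(factor(qh, levels = seq_len(nrow(mt))),
                 factor(sh, levels = seq_along(exons)))
    m <- matrix(as.integer(tab), nrow = nrow(mt),
                dimnames = list(NULL, names(exons)))
  }
  m == mt$nBlocks
}

#' Does a read lie completely within an exon?
#'
#' The completeness filter keeps primary, unclipped, properly paired mates
#' with a mapped mate ("completely mapped reads"); assignment additionally
#' requires every aligned block of the mate to lie fully inside the exon
#' interval, so boundary-overhanging and junction-crossing mates are never
#' assigned.
#'
#' @param rs a [ReadSet-class].
#' @param exon a length-1 `GRanges` (or an exon id present in `model`).
#' @param model optional [GeneModel-class] used to resolve an exon id.
#' @return named logical vector, one element per mate (`qname/mate`).
#' @export
assignReadToExon <- function(rs, exon, model = NULL) {
  if (is.character(exon)) {
    stopifnot(!is.null(model))
    exon <- geneExons(model)[exon]
  }
  mt <- .mateTable(rs)
  cm <- .containmentMatrix(rs, exon, mt)
  stats::setNames(mt$pass & cm[, 1L], paste0(mt$qname, "/", mt$mate))
}

#' Count reads on each exon variant of the gene model
#'
#' Counts, per exon variant, the mates passing the completeness filter that
#' are fully contained in the exon's interval. A read inside two nested
#' variants (e.g. within E18.2, hence also within E18.3) increments both:
#' each variant is an independent "how far does coverage extend" probe.
#' The per-sample total counts each mate once, over the deduplicated union
#' of all exon intervals, so nested variants never inflate it.
#'
#' @param rs a [ReadSet-class].
#' @param model a [GeneModel-class].
#' @return list with `counts` (named integer vector over the exon catalog)
#'   and `total` (deduplicated union-exon read count).
#' @seealso [countExonCohort()] to assemble a sample x exon table.
#' @export
countExonReads <- function(rs, model) {
  ex <- geneExons(model)
  mt <- .mateTable(rs)
  cm <- .containmentMatrix(rs, ex, mt)
  counts <- colSums(cm[mt$pass, , drop = FALSE])
  uni <- GenomicRanges::reduce(ex, ignore.strand = TRUE)
  names(uni) <- paste0("u", seq_along(uni))
  total <- sum(.allBlocksInUnion(rs, uni, mt) & mt$pass)
  list(counts = stats::setNames(as.integer(counts), names(ex)),
       total = as.integer(total))
}

# every block of the mate inside some reduced interval (blocks may sit in
# different intervals for junction-crossing mates)
.allBlocksInUnion <- function(rs, uni, mt) {
  if (!nrow(mt)) return(logical(0))
  mc <- mcols(rs@blocks)
  key <- .mateKey(mc$qname, mc$mate)
  mateIdx <- match(key, .mateKey(mt$qname, mt$mate))
  hits <- GenomicRanges::findOverlaps(rs@blocks, uni, type = "within",
                                      ignore.strand = TRUE)
  inAny <- tabulate(S4Vectors::queryHits(hits), nbins = length(rs@blocks)) > 0L
  ok <- tapply(inAny, factor(mateIdx, levels = seq_len(nrow(mt))), all)
  as.logical(ok)
}

#' Assemble an exon count table over a cohort
#'
#' @param samples list of [ReadSet-class] objects.
#' @param model a [GeneModel-class].
#' @return an [ExonCountTable][CountTable-class] (samples x exon variants,
#'   with deduplicated per-sample totals).
#' @export
countExonCohort <- function(samples, model) {
  rows <- lapply(samples, countExonReads, model = model)
  ids <- unname(vapply(samples, sampleId, character(1)))
  counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
  rownames(counts) <- ids
  totals <- stats::setNames(vapply(rows, `[[`, integer(1), "total"), ids)
  new("ExonCountTable", counts = counts, totals = totals)
}

#' Per-base coverage over a region
#'
#' Counts, at every base of `region`, the completeness-filtered mates whose
#' aligned blocks cover it (ascending genomic order).
#'
#' @param rs a [ReadSet-class].
#' @param region a length-1 `GRanges`.
#' @return integer vector of length `width(region)`.
#' @export
coverageProfile <- function(rs, region) {
  stopifnot(length(region) == 1L)
  mt <- .mateTable(rs)
  mc <- mcols(rs@blocks)
  key <- .mateKey(mc$qname, mc$mate)
  pass <- mt$pass[match(key, .mateKey(mt$qname, mt$mate))]
  bl <- rs@blocks[pass]
  bl <- bl[as.character(seqnames(bl)) == as.character(seqnames(region))]
  cov <- IRanges::coverage(ranges(bl), width = end(region))
  as.integer(S4Vectors::window(cov, start(region), end(region)))
}
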