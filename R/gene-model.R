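#' @include AllGenerics.R
NULL

#' Construct a GeneModel
#'
#' Low-level constructor; most users load a model with [readGeneModel()] or
#' use the built-in fixture [brafGeneModel()]. Exon coordinates given in
#' descending order (as minus-strand gene tables often are) are normalized
#' to `start <= end`.
#'
#' @param geneId gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `id`, `start`, `end` (1-based
#'   inclusive; may be descending).
#' @param transcripts list of lists with `id`, `exons` (exon-id vector,
#'   5'->3' transcript order), optional `cdsEndTx`.
#' @param junctions data.frame with `junctionId`, `donor`, `acceptor`,
#'   `measure`, `absenceProbe`; may be empty.
#' @return a validated [GeneModel-class].
#' @export
GeneModel <- function(geneId, chrom, strand, exons, transcripts,
                      junctions = emptyJunctions()) {
  lo <- pmin(exons$start, exons$end)
  hi <- pmax(exons$start, exons$end)
  gr <- GRanges(chrom, IRanges(lo, hi), strand = strand)
  names(gr) <- as.character(exons$id)
  txs <- lapply(transcripts, function(t) {
    list(id = t$id, exons = as.character(t$exons),
         cdsEndTx = if (is.null(t$cdsEndTx) || is.na(t$cdsEndTx))
           NA_integer_ else as.integer(t$cdsEndTx))
  })
  names(txs) <- vapply(txs, `[[`, "", "id")
  if (nrow(junctions)) junctions$absenceProbe <- as.logical(junctions$absenceProbe)
  new("GeneModel", geneId = geneId, exons = gr, transcripts = txs,
      junctions = junctions)
}

#' @rdname GeneModel
#' @export
emptyJunctions <- function() {
  data.frame(junctionId = character(), donor = character(),
             acceptor = character(), measure = character(),
             absenceProbe = logical(), stringsAsFactors = FALSE)
}

# cumulative transcript-space layout of a transcript's exons:
# data.frame(exon, width, txStart, txEnd) in 5'->3' order
.txLayout <- function(model, tx) {
  e <- txExons(model, tx)
  w <- width(e)
  cb <- cumsum(c(0L, w[-length(w)]))
  data.frame(exon = names(e), width = w, txStart = cb + 1L, txEnd = cb + w,
             gStart = start(e), gEnd = end(e), stringsAsFactors = FALSE)
}

#' Project genomic positions into transcript space
#'
#' Maps 1-based genomic positions onto 1-based transcript coordinates of
#' `tx`, strictly monotone along transcript orientation (for a minus-strand
#' gene, higher genomic coordinates map to smaller transcript coordinates).
#'
#' @param model a [GeneModel-class].
#' @param tx transcript id.
#' @param gpos integer vector of genomic positions; every position must be
#'   exonic for this transcript.
#' @return integer vector of transcript-space positions.
#' @seealso [txToGenome()] for the inverse, [txLocate()] for intervals.
#' @export
txProject <- function(model, tx, gpos) {
  lay <- .txLayout(model, tx)
  minus <- geneStrand(model) == "-"
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(lay))) {
    inEx <- gpos >= lay$gStart[i] & gpos <= lay$gEnd[i]
    if (any(inEx)) {
      off <- if (minus) lay$gEnd[i] - gpos[inEx] + 1L else gpos[inEx] - lay$gStart[i] + 1L
      out[inEx] <- lay$txStart[i] + off - 1L
    }
  }
  if (anyNA(out))
    stop("position(s) intronic or outside transcript '", tx, "': ",
         paste(utils::head(gpos[is.na(out)], 3L), collapse = ", "))
  out
}

#' Project transcript positions back to the genome
#'
#' @inheritParams txProject
#' @param tpos transcript-space positions, `1 <= tpos <= txLength`.
#' @return integer vector of genomic positions.
#' @export
txToGenome <- function(model, tx, tpos) {
  lay <- .txLayout(model, tx)
  minus <- geneStrand(model) == "-"
  if (any(tpos < 1L | tpos > lay$txEnd[nrow(lay)]))
    stop("transcript position out of range for '", tx, "'")
  i <- findInterval(tpos, lay$txStart)
  off <- tpos - lay$txStart[i] + 1L
  if (minus) lay$gEnd[i] - off + 1L else lay$gStart[i] + off - 1L
}

#' Map transcript-space intervals to genomic aligned blocks
#'
#' Splits each transcript-space interval at exon boundaries and returns the
#' genomic blocks an aligner would report (one block per exon crossed).
#'
#' @inheritParams txProject
#' @param tstart,tend equal-length integer vectors of interval bounds in
#'   transcript space (`tstart <= tend`).
#' @return data.frame with columns `query` (interval index), `gStart`,
#'   `gEnd`, `exon`; within a query, blocks are ordered 5'->3' in
#'   transcript orientation.
#' @export
txLocate <- function(model, tx, tstart, tend) {
  stopifnot(length(tstart) == length(tend), all(tstart <= tend))
  lay <- .txLayout(model, tx)
  minus <- geneStrand(model) == "-"
  q <- IRanges(tstart, tend)
  s <- IRanges(lay$txStart, lay$txEnd)
  hits <- IRanges::findOverlaps(q, s)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  # clip each query to the exon's transcript span
  ts <- pmax(tstart[qi], lay$txStart[si])
  te <- pmin(tend[qi], lay$txEnd[si])
  offS <- ts - lay$txStart[si] + 1L
  offE <- te - lay$txStart[si] + 1L
  if (minus) {
    gS <- lay$gEnd[si] - offE + 1L
    gE <- lay$gEnd[si] - offS + 1L
  } else {
    gS <- lay$gStart[si] + offS - 1L
    gE <- lay$gStart[si] + offE - 1L
  }
  ord <- order(qi, ts)
  data.frame(query = qi, gStart = gS, gEnd = gE, exon = lay$exon[si],
             stringsAsFactors = FALSE)[ord, , drop = FALSE]
}

#' Derive the specific suffix of a longer exon variant
#'
#' Two exon variants that share their transcript-orientation start point
#' (e.g. alternative terminal-exon endpoints) differ only in a suffix; the
#' suffix of the longer one downstream of the shorter one's endpoint is
#' specific to transcripts using the longer variant. Reads or mates mapped
#' there discriminate those transcripts.
#'
#' @param model a [GeneModel-class].
#' @param container exon id of the longer variant.
#' @param prefix exon id of the shorter variant sharing its start.
#' @param newId id for the derived exon.
#' @return a `GeneModel` with the derived exon appended to the catalog.
#' @examples
#' gm <- brafGeneModel()
#' width(geneExons(gm)["E18b"])  # 250 - 154 = 96
#' @export
deriveSpecificRegion <- function(model, container, prefix, newId) {
  ex <- geneExons(model)
  if (!all(c(container, prefix) %in% names(ex)))
    stop("unknown exon id(s)")
  a <- ex[container]; b <- ex[prefix]
  minus <- geneStrand(model) == "-"
  sameStart <- if (minus) end(a) == end(b) else start(a) == start(b)
  if (!sameStart) stop("exons do not share a transcript-orientation start point")
  if (width(a) <= width(b)) stop("prefix must be strictly shorter than container")
  d <- if (minus) GRanges(seqnames(a), IRanges(start(a), start(b) - 1L), strand = "-")
       else GRanges(seqnames(a), IRanges(end(b) + 1L, end(a)), strand = "+")
  names(d) <- newId
  model@exons <- c(ex, d)
  validObject(model)
  model
}

# ---- file I/O -------------------------------------------------------------

#' Read a gene model from GTF or YAML
#'
#' Two formats are supported. A GTF with `exon` features carrying
#' `gene_id`, `transcript_id` and `exon_id` attributes (plus optional
#' `transcript` features carrying a `cds_end_tx` attribute) yields the exon
#' catalog and transcript structures; junction definitions cannot be
#' expressed in GTF and start out empty. A YAML gene-model file carries the
#' full content including junctions and derived exons; its exon coordinates
#' may be listed descending (transcript orientation of a minus-strand
#' gene) and are normalized on load.
#'
#' @param path file path ending in `.gtf`/`.gff` or `.yaml`/`.yml`.
#' @return a validated [GeneModel-class].
#' @export
readGeneModel <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff")) .readGeneModelGTF(path)
  else if (ext %in% c("yaml", "yml")) .readGeneModelYAML(path)
  else stop("unrecognized gene-model format: .", ext)
}

.readGeneModelGTF <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (!length(ex)) stop("no exon features in ", path)
  if (is.null(ex$exon_id) || anyNA(ex$exon_id))
    stop("exon features must carry an exon_id attribute")
  gid <- unique(ex$gene_id)
  if (length(gid) != 1L) stop("exactly one gene_id expected, found: ",
                              paste(gid, collapse = ", "))
  # exon catalog: unique exon_id, coordinates must agree across transcripts
  first <- !duplicated(ex$exon_id)
  cat_df <- data.frame(id = ex$exon_id[first], start = start(ex)[first],
                       end = end(ex)[first])
  chk <- paste(ex$exon_id, start(ex), end(ex))
  if (anyDuplicated(unique(data.frame(ex$exon_id, start(ex), end(ex)))$ex.exon_id))
    stop("conflicting coordinates for one exon_id")
  st <- as.character(strand(ex))[1L]
  txf <- gr[gr$type == "transcript"]
  cdsMap <- if (length(txf) && !is.null(txf$cds_end_tx))
    stats::setNames(suppressWarnings(as.integer(txf$cds_end_tx)), txf$transcript_id)
  else integer()
  txs <- lapply(split(seq_along(ex), ex$transcript_id), function(ix) {
    e <- ex[ix]
    ord <- if (st == "-") order(-start(e)) else order(start(e))
    list(id = e$transcript_id[1L], exons = e$exon_id[ord],
         cdsEndTx = if (e$transcript_id[1L] %in% names(cdsMap))
           cdsMap[[e$transcript_id[1L]]] else NA_integer_)
  })
  GeneModel(gid, as.character(seqnames(ex))[1L], st, cat_df, unname(txs))
}

.readGeneModelYAML <- function(path) {
  y <- yaml::read_yaml(path)
  exd <- do.call(rbind, lapply(y$exons, function(e)
    data.frame(id = e$id, start = e$start, end = e$end)))
  txs <- lapply(y$transcripts, function(t)
    list(id = t$id, exons = unlist(t$exons),
         cdsEndTx = if (is.null(t$cds_end_tx)) NA_integer_ else t$cds_end_tx))
  jn <- if (length(y$junctions)) do.call(rbind, lapply(y$junctions, function(j)
    data.frame(junctionId = j$id, donor = j$donor, acceptor = j$acceptor,
               measure = if (is.null(j$measure)) NA_character_ else j$measure,
               absenceProbe = isTRUE(j$absence_probe),
               stringsAsFactors = FALSE)))
  else emptyJunctions()
  GeneModel(y$gene, y$chrom, y$strand, exd, txs, jn)
}

#' Write a gene model
#'
#' `writeGeneModelYAML` round-trips the full model (catalog including
#' derived exons, transcripts, junctions). `writeGeneModelGTF` emits
#' standard `transcript` + `exon` features; catalog exons attached to no
#' transcript, and junction definitions, are not expressible in GTF and
#' are dropped with a message.
#'
#' @param model a [GeneModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneModelYAML <- function(model, path) {
  ex <- geneExons(model)
  y <- list(
    gene = geneId(model),
    chrom = as.character(seqnames(ex))[1L],
    strand = geneStrand(model),
    exons = lapply(seq_along(ex), function(i)
      list(id = names(ex)[i], start = start(ex)[i], end = end(ex)[i])),
    transcripts = lapply(unname(model@transcripts), function(t)
      list(id = t$id, exons = as.list(t$exons),
           cds_end_tx = if (is.na(t$cdsEndTx)) NULL else t$cdsEndTx)),
    junctions = if (nrow(model@junctions)) lapply(seq_len(nrow(model@junctions)),
      function(i) {
        j <- model@junctions[i, ]
        list(id = j$junctionId, donor = j$donor, acceptor = j$acceptor,
             measure = j$measure, absence_probe = j$absenceProbe)
      }) else list()
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname writeGeneModelYAML
#' @export
writeGeneModelGTF <- function(model, path) {
  ex <- geneExons(model)
  chrom <- as.character(seqnames(ex))[1L]
  st <- geneStrand(model)
  used <- unique(unlist(lapply(model@transcripts, `[[`, "exons")))
  orphan <- setdiff(names(ex), used)
  if (length(orphan))
    message("GTF export drops catalog-only exon(s): ",
            paste(orphan, collapse = ", "))
  lines <- character()
  for (t in model@transcripts) {
    e <- ex[t$exons]
    attr0 <- sprintf('gene_id "%s"; transcript_id "%s";', geneId(model), t$id)
    tl <- sprintf("%s\tisoscan\ttranscript\t%d\t%d\t.\t%s\t.\t%s%s",
                  chrom, min(start(e)), max(end(e)), st, attr0,
                  if (is.na(t$cdsEndTx)) "" else
                    sprintf(' cds_end_tx "%d";', t$cdsEndTx))
    el <- sprintf('%s\tisoscan\texon\t%d\t%d\t.\t%s\t.\t%s exon_id "%s";',
                  chrom, start(e), end(e), st, attr0, names(e))
    lines <- c(lines, tl, el)
  }
  writeLines(lines, path)
  invisible(path)
}
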