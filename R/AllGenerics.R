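#' @include AllClasses.R
NULL

#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @export
setGeneric("geneExons", function(x) standardGeneric("geneExons"))
#' @export
setGeneric("geneStrand", function(x) standardGeneric("geneStrand"))
#' @export
setGeneric("txIds", function(x) standardGeneric("txIds"))
#' @export
setGeneric("txExons", function(x, tx) standardGeneric("txExons"))
#' @export
setGeneric("txLength", function(x, tx) standardGeneric("txLength"))
#' @export
setGeneric("cdsEndTx", function(x, tx) standardGeneric("cdsEndTx"))
#' @export
setGeneric("geneJunctions", function(x) standardGeneric("geneJunctions"))
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @export
setGeneric("readBlocks", function(x) standardGeneric("readBlocks"))
#' @export
setGeneric("nMates", function(x) standardGeneric("nMates"))
#' @importFrom BiocGenerics counts
#' @export
BiocGenerics::counts
#' @export
setGeneric("sampleTotals", function(x) standardGeneric("sampleTotals"))
#' @export
setGeneric("measures", function(x) standardGeneric("measures"))
#' @export
setGeneric("normValues", function(x, masked = TRUE) standardGeneric("normValues"))
#' @export
setGeneric("outlierMask", function(x) standardGeneric("outlierMask"))

# ---- GeneModel accessors ----

#' Accessors for GeneModel
#'
#' @param x a [GeneModel-class] object.
#' @param tx a transcript id.
#' @return `geneId`, `geneStrand`: single strings; `geneExons`: the exon
#'   catalog `GRanges`; `txIds`: character vector; `txExons(x, tx)`: the
#'   transcript's exon `GRanges` in 5'->3' transcript order; `txLength`:
#'   integer; `cdsEndTx`: integer or `NA`; `geneJunctions`: data.frame.
#' @name GeneModel-accessors
#' @aliases geneId geneExons geneStrand txIds txExons txLength cdsEndTx
#'   geneJunctions
#' @examples
#' gm <- brafGeneModel()
#' geneStrand(gm)
#' txLength(gm, "ref")
NULL

#' @rdname GeneModel-accessors
#' @export
setMethod("geneId", "GeneModel", function(x) x@geneId)
#' @rdname GeneModel-accessors
#' @export
setMethod("geneExons", "GeneModel", function(x) x@exons)
#' @rdname GeneModel-accessors
#' @export
setMethod("geneStrand", "GeneModel",
          function(x) as.character(strand(x@exons))[1L])
#' @rdname GeneModel-accessors
#' @export
setMethod("txIds", "GeneModel", function(x) names(x@transcripts))
#' @rdname GeneModel-accessors
#' @export
setMethod("txExons", "GeneModel", function(x, tx) {
  t <- x@transcripts[[tx]]
  if (is.null(t)) stop("unknown transcript: ", tx)
  x@exons[t$exons]
})
#' @rdname GeneModel-accessors
#' @export
setMethod("txLength", "GeneModel", function(x, tx) sum(width(txExons(x, tx))))
#' @rdname GeneModel-accessors
#' @export
setMethod("cdsEndTx", "GeneModel", function(x, tx) {
  t <- x@transcripts[[tx]]
  if (is.null(t)) stop("unknown transcript: ", tx)
  t$cdsEndTx
})
#' @rdname GeneModel-accessors
#' @export
setMethod("geneJunctions", "GeneModel", function(x) x@junctions)

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel:", object@geneId,
      sprintf("(%s strand, %s)\n", geneStrand(object),
              as.character(seqnames(object@exons))[1L]))
  cat(" ", length(object@exons), "exon variants;",
      length(object@transcripts), "transcripts;",
      nrow(object@junctions), "junctions\n")
  cat("  transcripts:", paste(names(object@transcripts), collapse = ", "), "\n")
})

# ---- ReadSet accessors ----

#' Accessors for ReadSet
#'
#' @param x a [ReadSet-class].
#' @return `readBlocks`: the block-level `GRanges`; `sampleId`: string;
#'   `nMates`: number of distinct aligned mates.
#' @name ReadSet-accessors
#' @aliases sampleId readBlocks nMates
NULL

#' @rdname ReadSet-accessors
#' @export
setMethod("sampleId", "ReadSet", function(x) x@sampleId)
#' @rdname ReadSet-accessors
#' @export
setMethod("readBlocks", "ReadSet", function(x) x@blocks)
#' @rdname ReadSet-accessors
#' @export
setMethod("nMates", "ReadSet", function(x) {
  mc <- mcols(x@blocks)
  length(unique(paste(mc$qname, mc$mate)))
})

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet:", object@sampleId, "-", nMates(object), "mates in",
      length(object@blocks), "aligned blocks\n")
})

# ---- CountTable accessors ----

#' Accessors for count tables
#'
#' @param x,object a [CountTable-class] (or subclass) or
#'   [NormalizedTable-class].
#' @param masked for `normValues`, replace masked cells by `NA`.
#' @return `counts`: sample x feature matrix; `sampleTotals`: named
#'   per-sample deduplicated totals; `measures`: junction -> isoform map;
#'   `normValues`: normalized matrix; `outlierMask`: logical matrix.
#' @name CountTable-accessors
#' @aliases counts sampleTotals measures normValues outlierMask
NULL

#' @rdname CountTable-accessors
#' @export
setMethod("counts", "CountTable", function(object) object@counts)
#' @rdname CountTable-accessors
#' @export
setMethod("sampleTotals", "CountTable", function(x) x@totals)
#' @rdname CountTable-accessors
#' @export
setMethod("measures", "JunctionCountTable", function(x) x@measures)
#' @rdname CountTable-accessors
#' @export
setMethod("normValues", "NormalizedTable", function(x, masked = TRUE) {
  v <- x@values
  if (masked && any(x@mask)) v[x@mask] <- NA_real_
  v
})
#' @rdname CountTable-accessors
#' @export
setMethod("outlierMask", "NormalizedTable", function(x) x@mask)
#' @rdname CountTable-accessors
#' @export
setMethod("sampleTotals", "NormalizedTable", function(x) x@totals)

setMethod("show", "CountTable", function(object) {
  cat(class(object), ":", nrow(object@counts), "samples x",
      ncol(object@counts), "features\n")
})
setMethod("show", "NormalizedTable", function(object) {
  cat("NormalizedTable:", nrow(object@values), "samples x",
      ncol(object@values), "features;", sum(object@mask), "cells masked\n")
})
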