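suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# shared fixture model (built once; tests must not mutate it)
.gm <- brafGeneModel()

# a plus-strand toy gene: two exons, one intron, two transcripts of equal
# length (short-A uses exon A only at double length via exon A2)
toyModel <- function() {
  GeneModel(
    geneId = "TOY", chrom = "chrT", strand = "+",
    exons = data.frame(id = c("A", "B", "C"),
                       start = c(1001, 2001, 3001),
                       end = c(1600, 2600, 3600)),
    transcripts = list(
      list(id = "AB", exons = c("A", "B"), cdsEndTx = 900),
      list(id = "AC", exons = c("A", "C"), cdsEndTx = 900)),
    junctions = data.frame(
      junctionId = c("A-B", "A-C"), donor = c("A", "A"),
      acceptor = c("B", "C"), measure = c("AB", "AC"),
      absenceProbe = c(FALSE, FALSE), stringsAsFactors = FALSE))
}

# build a ReadSet from a block table by hand (one row per block)
handReadSet <- function(df, sampleId = "H1", chrom = "chrS") {
  defaults <- list(paired = TRUE, mateMapped = TRUE, secondary = FALSE,
                   supplementary = FALSE, clipped = FALSE)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- rep(defaults[[nm]], nrow(df))
  gr <- if (nrow(df)) GRanges(rep(chrom, nrow(df)),
                              IRanges(df$start, df$end), strand = "*")
        else GRanges()
  mcols(gr) <- DataFrame(qname = df$qname,
                         mate = if (is.null(df$mate)) 1L else df$mate,
                         paired = df$paired, mateMapped = df$mateMapped,
                         secondary = df$secondary,
                         supplementary = df$supplementary,
                         clipped = df$clipped)
  new("ReadSet", blocks = gr, sampleId = sampleId)
}

# ---- independent brute-force oracles -------------------------------------

# exon counting: double loop over mates x exons, literal containment test
bruteExonCounts <- function(rs, model) {
  bl <- readBlocks(rs)
  mc <- mcols(bl)
  key <- paste0(mc$qname, "/", mc$mate)
  ex <- geneExons(model)
  out <- setNames(integer(length(ex)), names(ex))
  for (k in unique(key)) {
    i <- which(key == k)
    ok <- mc$paired[i[1]] && mc$mateMapped[i[1]] && !mc$secondary[i[1]] &&
      !mc$supplementary[i[1]] && !mc$clipped[i[1]]
    if (!ok) next
    for (e in seq_along(ex)) {
      inside <- TRUE
      for (j in i)
        if (start(bl)[j] < start(ex)[e] || end(bl)[j] > end(ex)[e])
          inside <- FALSE
      if (inside) out[e] <- out[e] + 1L
    }
  }
  out
}

# junction-spanning counting: loop over pairs x junctions, literal rules
bruteSpanningCounts <- function(rs, model, range) {
  bl <- readBlocks(rs)
  mc <- mcols(bl)
  ex <- geneExons(model)
  jn <- geneJunctions(model)
  minus <- geneStrand(model) == "-"
  out <- setNames(integer(nrow(jn)), jn$junctionId)
  spanIn <- function(i, X) all(start(bl)[i] >= start(X)) &&
    all(end(bl)[i] <= end(X))
  off <- function(pos, X) if (minus) end(X) - pos + 1L else pos - start(X) + 1L
  pass <- function(i) mc$paired[i[1]] && mc$mateMapped[i[1]] &&
    !mc$secondary[i[1]] && !mc$supplementary[i[1]] && !mc$clipped[i[1]]
  key <- paste0(mc$qname, "/", mc$mate)
  for (q in unique(mc$qname)) {
    i1 <- which(key == paste0(q, "/1")); i2 <- which(key == paste0(q, "/2"))
    if (!length(i1) || !length(i2) || !pass(i1) || !pass(i2)) next
    hits <- c(); devs <- c()
    for (k in seq_len(nrow(jn))) {
      D <- ex[jn$donor[k]]; A <- ex[jn$acceptor[k]]
      for (o in 1:2) {
        dm <- if (o == 1) i1 else i2; am <- if (o == 1) i2 else i1
        if (spanIn(dm, D) && spanIn(am, A)) {
          dEnd <- if (minus) off(min(start(bl)[dm]), D)
                  else off(max(end(bl)[dm]), D)
          aStart <- if (minus) off(max(end(bl)[am]), A)
                    else off(min(start(bl)[am]), A)
          d <- (width(D) - dEnd) + (aStart - 1L)
          if (d >= range$low && d <= range$high) {
            hits <- c(hits, k); devs <- c(devs, abs(d - range$median))
          }
        }
      }
    }
    hits <- unique(hits)
    if (length(hits) == 1L) out[hits] <- out[hits] + 1L
    else if (length(hits) > 1L) {
      best <- which(devs == min(devs))
      if (length(best) == 1L) out[hits[best]] <- out[hits[best]] + 1L
    }
  }
  out
}

# random hand-style fixture: n mates scattered over the gene (some paired)
randomReadSet <- function(model, n, seed) {
  set.seed(seed)
  ex <- geneExons(model)
  rows <- lapply(seq_len(n), function(i) {
    e <- sample(length(ex), 1L)
    w <- sample(20:60, 1L)
    s <- sample(start(ex)[e]:(max(start(ex)[e], end(ex)[e] - w)), 1L)
    data.frame(qname = sprintf("r%03d", ((i - 1L) %/% 2L) + 1L),
               mate = ((i - 1L) %% 2L) + 1L,
               start = s, end = s + w,
               clipped = runif(1) < 0.1)
  })
  handReadSet(do.call(rbind, rows))
}

# cohort of independently profiled samples sharing one fragment range
mixedCohortJunctions <- function(model, profiles, nPairs, seed,
                                 range = fragmentRange(15, 190)) {
  samples <- lapply(seq_along(profiles), function(i) {
    cfg <- simConfig(profiles[[i]], nPairs = nPairs, seed = 1L)
    simulateSample(model, cfg, sprintf("M%03d", i), seed = seed + 13L * i)
  })
  countJunctionCohort(samples, model, range)
}
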