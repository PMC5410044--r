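#' @include braf-fixture.R
NULL

# run code under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

.deriveSeed <- function(master, i) as.integer((master * 48271 + i * 7919) %% 2147483629)

#' Simulation profile: molar transcript mixture
#'
#' @param proportions named numeric vector, transcript id -> molar
#'   proportion; must be non-negative and sum to 1 (tolerance 1e-9).
#' @param label free-text profile name (e.g. `"melanoma-like"`).
#' @return a `simProfile` list.
#' @examples
#' melanomaLikeProfile()
#' @export
simProfile <- function(proportions, label = "custom") {
  if (!length(proportions) || is.null(names(proportions)))
    stop("proportions must be a non-empty named vector")
  if (any(proportions < 0)) stop("proportions must be non-negative")
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  structure(list(proportions = proportions, label = label),
            class = "simProfile")
}

#' @rdname simProfile
#' @details `melanomaLikeProfile()` encodes a molar ref:X1:X2 = 1:3:1
#'   mixture, the ordering (X1 above ref, X2 near ref) seen in melanoma.
#' @export
melanomaLikeProfile <- function() {
  simProfile(c(ref = 0.2, X1 = 0.6, X2 = 0.2), "melanoma-like")
}

#' Simulation configuration
#'
#' @param profile a [simProfile()].
#' @param nPairs fragments per sample.
#' @param readLen read length (nt).
#' @param fragMean,fragSd fragment-length truncated-normal parameters (nt);
#'   the defaults (200 +/- 40 nt with 50-nt reads) emulate the short-insert
#'   2x50 libraries of TCGA-era RNA-seq; the lower truncation point is
#'   `2 * readLen` so mates never overlap.
#' @param fivePrimeDepletion weight in `[0, 1]`: sampling weight ramps
#'   linearly from `1 - fivePrimeDepletion` at transcript position 1 up to 1
#'   at position `depletionK`, emulating the 5'-end depletion of polyA
#'   libraries.
#' @param depletionK ramp length (nt).
#' @param nSamples samples per cohort.
#' @param depthJitter coefficient of variation of per-sample fragment
#'   totals (log-normal around `nPairs`); 0 = constant depth.
#' @param seed master seed; everything downstream is deterministic in it.
#' @return a `simConfig` list.
#' @export
simConfig <- function(profile, nPairs = 2000L, readLen = 50L,
                      fragMean = 200, fragSd = 40,
                      fivePrimeDepletion = 0, depletionK = 1000L,
                      nSamples = 1L, depthJitter = 0, seed = 1L) {
  stopifnot(inherits(profile, "simProfile"), nPairs > 0,
            fragMean >= 2 * readLen, readLen > 0,
            fivePrimeDepletion >= 0, fivePrimeDepletion <= 1,
            depthJitter >= 0, nSamples >= 1)
  structure(list(profile = profile, nPairs = as.integer(nPairs),
                 readLen = as.integer(readLen), fragMean = fragMean,
                 fragSd = fragSd, fivePrimeDepletion = fivePrimeDepletion,
                 depletionK = as.integer(depletionK),
                 nSamples = as.integer(nSamples), depthJitter = depthJitter,
                 seed = as.integer(seed)),
            class = "simConfig")
}

# positional sampling weights over transcript positions 1..L
.positionWeights <- function(L, w, k) {
  if (w <= 0 || k <= 1L) return(rep(1, L))
  ramp <- (1 - w) + w * (seq_len(min(k, L)) - 1) / (k - 1)
  c(ramp, rep(1, max(0L, L - k)))
}

# rounded truncated normal on [lo, hi]
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  f <- round(stats::qnorm(stats::runif(n, plo, phi), mean, sd))
  pmin(pmax(f, lo), hi)
}

#' Simulate one sample of splice-aware paired-end fragments
#'
#' Draws each fragment's source transcript with probability proportional to
#' molar proportion times transcript length (a molar mixture observed
#' through uniform fragmentation), its length from a truncated normal, and
#' its start position uniformly over valid positions (optionally depleted
#' near the 5' end); the two mates are the fragment's first and last
#' `readLen` bases, projected to genome-coordinate aligned blocks (split
#' across exons where a mate crosses a junction). No sequencing errors are
#' simulated: alignment is taken as given.
#'
#' @param model a [GeneModel-class].
#' @param cfg a [simConfig()].
#' @param sampleId sample name.
#' @param nPairs override of `cfg$nPairs` (used by [simulateCohort()]).
#' @param seed override of `cfg$seed`.
#' @return a [ReadSet-class]; `x@meta$truth` holds the per-fragment source
#'   transcript, transcript-space start and fragment length.
#' @export
simulateSample <- function(model, cfg, sampleId = "S1",
                           nPairs = cfg$nPairs, seed = cfg$seed) {
  p <- cfg$profile$proportions
  p <- p[p > 0]
  if (!length(p)) stop("empty simulation profile")
  bad <- setdiff(names(p), txIds(model))
  if (length(bad)) stop("profile transcript(s) not in model: ",
                        paste(bad, collapse = ", "))
  L <- vapply(names(p), function(t) txLength(model, t), numeric(1))
  short <- names(p)[L < cfg$fragMean]
  if (length(short))
    stop("transcript(s) shorter than fragMean: ", paste(short, collapse = ", "))
  rl <- cfg$readLen
  .withSeed(seed, {
    src <- sample(names(p), nPairs, replace = TRUE, prob = p * L)
    fl <- integer(nPairs); st <- integer(nPairs)
    for (t in unique(src)) {
      i <- which(src == t)
      fl[i] <- .rtruncnorm(length(i), cfg$fragMean, cfg$fragSd, 2 * rl, L[[t]])
      cw <- cumsum(.positionWeights(L[[t]], cfg$fivePrimeDepletion,
                                    cfg$depletionK))
      u <- stats::runif(length(i)) * cw[L[[t]] - fl[i] + 1L]
      st[i] <- findInterval(u, cw) + 1L
    }
    truth <- data.frame(qname = sprintf("%s_p%06d", sampleId, seq_len(nPairs)),
                        transcript = src, txStart = st, fragLen = fl,
                        stringsAsFactors = FALSE)
    blocks <- .pairsToBlocks(model, truth, rl)
    new("ReadSet", blocks = blocks, sampleId = sampleId,
        meta = list(truth = truth, cfg = cfg, seed = seed))
  })
}

# mate intervals -> genome blocks GRanges with read metadata
.pairsToBlocks <- function(model, truth, rl) {
  chrom <- as.character(seqnames(geneExons(model)))[1L]
  res <- vector("list", 2L * length(unique(truth$transcript)))
  k <- 0L
  for (t in unique(truth$transcript)) {
    i <- which(truth$transcript == t)
    for (m in 1:2) {
      a <- if (m == 1L) truth$txStart[i] else truth$txStart[i] + truth$fragLen[i] - rl
      bl <- txLocate(model, t, a, a + rl - 1L)
      k <- k + 1L
      res[[k]] <- data.frame(qname = truth$qname[i][bl$query], mate = m,
                             gStart = bl$gStart, gEnd = bl$gEnd,
                             stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, res[seq_len(k)])
  df <- df[order(match(df$qname, truth$qname), df$mate, df$gStart), ]
  gr <- GRanges(chrom, IRanges(df$gStart, df$gEnd), strand = "*")
  mcols(gr) <- S4Vectors::DataFrame(
    qname = df$qname, mate = df$mate, paired = TRUE, mateMapped = TRUE,
    secondary = FALSE, supplementary = FALSE, clipped = FALSE)
  gr
}

#' Simulate a cohort of samples with a truth table
#'
#' Per-sample seeds are derived deterministically from the master seed;
#' per-sample fragment totals are drawn log-normal around `nPairs` with
#' coefficient of variation `depthJitter` (constant when 0), reflecting
#' roughly constant gene-level depth across samples.
#'
#' @inheritParams simulateSample
#' @return list with `samples` (list of [ReadSet-class]) and `truth`
#'   (data.frame: `sample_id`, `transcript_id`, `true_proportion`,
#'   `n_pairs`).
#' @export
simulateCohort <- function(model, cfg) {
  n <- cfg$nSamples
  ids <- sprintf("S%03d", seq_len(n))
  sizes <- if (cfg$depthJitter > 0) {
    sg <- sqrt(log(1 + cfg$depthJitter^2))
    .withSeed(cfg$seed, pmax(1L, as.integer(round(stats::rlnorm(
      n, log(cfg$nPairs) - sg^2 / 2, sg)))))
  } else rep(cfg$nPairs, n)
  samples <- lapply(seq_len(n), function(i)
    simulateSample(model, cfg, ids[i], nPairs = sizes[i],
                   seed = .deriveSeed(cfg$seed, i)))
  names(samples) <- ids
  p <- cfg$profile$proportions
  truth <- data.frame(
    sample_id = rep(ids, each = length(p)),
    transcript_id = rep(names(p), n),
    true_proportion = rep(unname(p), n),
    n_pairs = rep(sizes, each = length(p)),
    stringsAsFactors = FALSE)
  list(samples = samples, truth = truth)
}

#' Write a ReadSet as SAM
#'
#' Emits a minimal, valid SAM file: `@HD`/`@SQ` header (no date fields, so
#' output is byte-stable), proper-pair flags, mate linkage via
#' `RNEXT=`/`PNEXT`, and `N` CIGAR operations across introns for
#' junction-crossing mates. [readAlignments()] recovers every mate's
#' aligned blocks exactly.
#'
#' @param rs a [ReadSet-class].
#' @param path output `.sam` path.
#' @param seqLengths named vector of reference lengths; default covers the
#'   blocks with margin.
#' @return `path`, invisibly.
#' @export
writeSAM <- function(rs, path, seqLengths = NULL) {
  bl <- readBlocks(rs)
  if (is.null(seqLengths)) {
    if (length(bl))
      seqLengths <- stats::setNames(max(end(bl)) + 1000L,
                                    as.character(seqnames(bl))[1L])
    else seqLengths <- c(chrUnknown = 1000L)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqLengths),
                   as.integer(seqLengths)))
  if (!length(bl)) { writeLines(hdr, path); return(invisible(path)) }
  mc <- mcols(bl)
  key <- paste(mc$qname, mc$mate)
  o <- order(match(mc$qname, unique(mc$qname)), mc$mate, start(bl))
  bl <- bl[o]; mc <- mcols(bl); key <- key[o]
  sp <- split(seq_along(bl), factor(key, levels = unique(key)))
  mateRec <- vapply(sp, function(ix) {
    s <- start(bl)[ix]; e <- end(bl)[ix]
    cig <- paste0(e[1] - s[1] + 1L, "M")
    if (length(ix) > 1L) for (j in 2:length(ix))
      cig <- paste0(cig, s[j] - e[j - 1L] - 1L, "N", e[j] - s[j] + 1L, "M")
    paste(mc$qname[ix[1]], mc$mate[ix[1]], s[1], max(e), cig, sep = "\t")
  }, character(1))
  rec <- utils::read.table(text = mateRec, sep = "\t",
                           col.names = c("qname", "mate", "pos", "end", "cigar"),
                           stringsAsFactors = FALSE)
  m1 <- rec[rec$mate == 1L, ]; m2 <- rec[rec$mate == 2L, ]
  m2 <- m2[match(m1$qname, m2$qname), ]
  chrom <- as.character(seqnames(bl))[1L]
  lo <- pmin(m1$pos, m2$pos); hi <- pmax(m1$end, m2$end)
  tlen <- hi - lo + 1L
  readLen <- function(cig) {
    ops <- regmatches(cig, gregexpr("[0-9]+M", cig))
    vapply(ops, function(x) sum(as.integer(sub("M", "", x))), integer(1))
  }
  line <- function(q, flag, pos, cig, pnext, tl) {
    n <- readLen(cig)
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s", q, flag, chrom,
            pos, cig, pnext, tl, strrep("A", n), strrep("I", n))
  }
  l1 <- line(m1$qname, 99L, m1$pos, m1$cigar, m2$pos,
             ifelse(m1$pos <= m2$pos, tlen, -tlen))
  l2 <- line(m2$qname, 147L, m2$pos, m2$cigar, m1$pos,
             ifelse(m1$pos <= m2$pos, -tlen, tlen))
  writeLines(c(hdr, as.vector(rbind(l1, l2))), path)
  invisible(path)
}
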