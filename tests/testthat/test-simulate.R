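test_that("a single-transcript profile yields only that transcript", {
  cfg <- simConfig(simProfile(c(ref = 1)), nPairs = 200, seed = 5)
  rs <- simulateSample(.gm, cfg, "S1")
  expect_true(all(rs@meta$truth$transcript == "ref"))
  expect_equal(nrow(rs@meta$truth), 200L)
  expect_equal(nMates(rs), 400L)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- simConfig(melanomaLikeProfile(), nPairs = 300, seed = 99)
  a <- simulateSample(.gm, cfg, "S1")
  b <- simulateSample(.gm, cfg, "S1")
  expect_identical(a@meta$truth, b@meta$truth)
  expect_identical(start(readBlocks(a)), start(readBlocks(b)))
  c <- simulateSample(.gm, cfg, "S1", seed = 100)
  expect_false(identical(a@meta$truth, c@meta$truth))
})

test_that("source sampling follows molar-proportion x length weighting", {
  # equal-length transcripts: read fraction reduces to the molar fraction
  toy <- toyModel()
  cfg <- simConfig(simProfile(c(AB = 0.25, AC = 0.75)),
                   nPairs = 20000, readLen = 50, fragMean = 200, fragSd = 30,
                   seed = 17)
  rs <- simulateSample(toy, cfg, "S1")
  frac <- mean(rs@meta$truth$transcript == "AC")
  se <- sqrt(0.75 * 0.25 / 20000)
  expect_lt(abs(frac - 0.75), 3 * se)

  # unequal lengths: weight must be proportion x transcript length
  cfg2 <- simConfig(simProfile(c(ref = 0.5, X1 = 0.5)), nPairs = 20000,
                    seed = 18)
  rs2 <- simulateSample(.gm, cfg2, "S1")
  w <- txLength(.gm, "X1") / (txLength(.gm, "X1") + txLength(.gm, "ref"))
  frac2 <- mean(rs2@meta$truth$transcript == "X1")
  expect_lt(abs(frac2 - w), 4 * sqrt(w * (1 - w) / 20000))
})

test_that("per-transcript read fractions track weights over the cohort", {
  cfg <- simConfig(melanomaLikeProfile(), nPairs = 10000, seed = 4,
                   nSamples = 2)
  co <- simulateCohort(.gm, cfg)
  p <- melanomaLikeProfile()$proportions
  L <- vapply(names(p), function(t) txLength(.gm, t), numeric(1))
  w <- p * L / sum(p * L)
  pooled <- table(do.call(rbind, lapply(co$samples,
                                        function(s) s@meta$truth))$transcript)
  n <- sum(pooled)
  for (t in names(w))
    expect_lt(abs(pooled[[t]] / n - w[[t]]),
              4 * sqrt(w[[t]] * (1 - w[[t]]) / n))
})

test_that("fragment geometry: mates reproject to contiguous read-length intervals", {
  cfg <- simConfig(melanomaLikeProfile(), nPairs = 500, seed = 21,
                   fivePrimeDepletion = 0.4)
  rs <- simulateSample(.gm, cfg, "S1")
  bl <- readBlocks(rs)
  mc <- mcols(bl)
  truth <- rs@meta$truth
  key <- paste0(mc$qname, "/", mc$mate)
  set.seed(2)
  for (k in sample(unique(key), 60)) {
    i <- which(key == k)
    q <- sub("/.*", "", k); m <- as.integer(sub(".*/", "", k))
    tr <- truth[truth$qname == q, ]
    tpos <- sort(txProject(.gm, tr$transcript,
                           unlist(lapply(i, function(j)
                             seq(start(bl)[j], end(bl)[j])))))
    expect_equal(length(tpos), 50L)
    expect_true(all(diff(tpos) == 1L))  # contiguous in transcript space
    expStart <- if (m == 1L) tr$txStart else tr$txStart + tr$fragLen - 50L
    expect_equal(tpos[1], expStart)
  }
})

test_that("cohort simulation: sizes, truth table, reproducibility", {
  cfg <- simConfig(melanomaLikeProfile(), nPairs = 150, nSamples = 3,
                   seed = 8, depthJitter = 0)
  co <- simulateCohort(.gm, cfg)
  expect_length(co$samples, 3L)
  expect_equal(nrow(co$truth), 9L)  # 3 samples x 3 transcripts
  expect_true(all(co$truth$n_pairs == 150L))  # jitter 0: exact depth
  co2 <- simulateCohort(.gm, cfg)
  expect_identical(co$truth, co2$truth)
  expect_identical(readBlocks(co$samples[[2]]), readBlocks(co2$samples[[2]]))

  cfgJ <- simConfig(melanomaLikeProfile(), nPairs = 500, nSamples = 6,
                    seed = 8, depthJitter = 0.2)
  sizes <- unique(simulateCohort(.gm, cfgJ)$truth$n_pairs)
  expect_gt(length(sizes), 1L)  # jitter produces varying depths
})

test_that("five-prime depletion thins coverage of the 5'-most exons", {
  cfgFlat <- simConfig(simProfile(c(ref = 1)), nPairs = 8000, seed = 31)
  cfgDep <- simConfig(simProfile(c(ref = 1)), nPairs = 8000, seed = 31,
                      fivePrimeDepletion = 0.8)
  e1 <- countExonReads(simulateSample(.gm, cfgFlat, "F"), .gm)$counts["E1"]
  e1d <- countExonReads(simulateSample(.gm, cfgDep, "D"), .gm)$counts["E1"]
  expect_lt(e1d, 0.6 * e1)
})

test_that("SAM output round-trips exactly and is byte-stable", {
  cfg <- simConfig(melanomaLikeProfile(), nPairs = 50, seed = 12)
  rs <- simulateSample(.gm, cfg, "S1")
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  writeSAM(rs, f1); writeSAM(rs, f2)
  expect_identical(readLines(f1), readLines(f2))  # deterministic bytes
  rs2 <- readAlignments(f1)
  expect_equal(nMates(rs2), nMates(rs))
  b1 <- sort(readBlocks(rs)); b2 <- sort(readBlocks(rs2))
  expect_identical(start(b1), start(b2))
  expect_identical(end(b1), end(b2))
})

test_that("junction-crossing mates carry an N gap equal to the intron", {
  # place a fragment straddling E17 -> E18 block in transcript space
  e <- txExons(.gm, "ref")
  off17 <- sum(width(e)[1:16])          # tx offset before E17
  truth <- data.frame(qname = "j1", transcript = "ref",
                      txStart = off17 + width(e)[17] - 19L, fragLen = 120L)
  rs <- new("ReadSet",
            blocks = isoscan:::.pairsToBlocks(.gm, truth, 50L),
            sampleId = "J", meta = list())
  f <- tempfile(fileext = ".sam")
  writeSAM(rs, f)
  sam <- readLines(f)
  cig <- strsplit(grep("^j1", sam, value = TRUE)[1], "\t")[[1]][6]
  intron <- start(geneExons(.gm)["E17"]) - end(geneExons(.gm)["E18.1"]) - 1L
  expect_equal(cig, sprintf("30M%dN20M", intron))
})

test_that("an empty pair list writes a header-only SAM", {
  rs <- handReadSet(data.frame(qname = character(), mate = integer(),
                               start = integer(), end = integer()))
  f <- tempfile(fileext = ".sam")
  writeSAM(rs, f)
  expect_true(all(startsWith(readLines(f), "@")))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simProfile(c(a = 0.5, b = 0.6)), "sum to 1")
  expect_error(simProfile(c(a = -0.1, b = 1.1)), "non-negative")
  expect_error(simConfig(melanomaLikeProfile(), fragMean = 80, readLen = 50))
  cfg <- simConfig(simProfile(c(`004` = 1)), fragMean = 1200)
  expect_error(simulateSample(.gm, cfg, "S"), "shorter than fragMean")
  cfgBad <- simConfig(simProfile(c(ghost = 1)))
  expect_error(simulateSample(.gm, cfgBad, "S"), "not in model")
})
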