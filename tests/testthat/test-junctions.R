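test_that("fragment range matches empirical percentiles of same-exon gaps", {
  # pairs inside E19 with known inner distances
  ex <- geneExons(.gm)
  set.seed(6)
  gaps <- pmax(0L, as.integer(round(rnorm(1000, 200, 30))))
  s1 <- start(ex["E19"]) + sample(0:5000, 1000, replace = TRUE)
  rows <- rbind(
    data.frame(qname = sprintf("p%04d", 1:1000), mate = 1L,
               start = s1, end = s1 + 49L),
    data.frame(qname = sprintf("p%04d", 1:1000), mate = 2L,
               start = s1 + 50L + gaps, end = s1 + 99L + gaps))
  fr <- inferFragmentRange(handReadSet(rows), .gm)
  q <- unname(stats::quantile(gaps, c(0.01, 0.99), type = 7))
  expect_equal(fr$low, max(0, q[1]))
  expect_equal(fr$high, q[2])
  expect_equal(fr$median, stats::median(gaps))
  expect_equal(fr$nPairs, 1000L)
})

test_that("degenerate range inputs behave as specified", {
  ex <- geneExons(.gm)
  s <- start(ex["E19"]) + 100L
  one <- handReadSet(data.frame(qname = "p1", mate = 1:2,
                                start = c(s, s + 230L),
                                end = c(s + 49L, s + 279L)))
  fr <- inferFragmentRange(one, .gm)
  expect_equal(c(fr$low, fr$high), c(180, 180))  # single gap d -> [d, d]
  none <- handReadSet(data.frame(qname = "q1", mate = 1L,
                                 start = s, end = s + 49L))
  expect_error(inferFragmentRange(none, .gm), "explicit")
})

test_that("hand-placed pairs are counted per the spanning rules", {
  ex <- geneExons(.gm)
  fr <- fragmentRange(50, 150); fr$median <- 100
  e17 <- ex["E17"]; e182 <- ex["E18.2"]
  # minus strand: acceptor-side offsets measured from the genomic end
  rows <- rbind(
    # 3 pairs spanning E17 -> E18.2 with implied distance inside [50, 150]
    data.frame(qname = c("a1", "a1", "a2", "a2", "a3", "a3"),
               mate = c(1L, 2L, 1L, 2L, 1L, 2L),
               start = c(start(e17) + 10L, end(e182) - 89L,
                         start(e17) + 30L, end(e182) - 99L,
                         start(e17) + 50L, end(e182) - 149L),
               end = c(start(e17) + 59L, end(e182) - 40L,
                       start(e17) + 79L, end(e182) - 50L,
                       start(e17) + 99L, end(e182) - 100L)),
    # out of range: mate2 sits too deep into E18.2
    data.frame(qname = c("b1", "b1"), mate = 1:2,
               start = c(end(e17) - 49L, start(e182)),
               end = c(end(e17), start(e182) + 49L)),
    # same-exon pair (no junction)
    data.frame(qname = c("c1", "c1"), mate = 1:2,
               start = c(start(ex["E19"]) + 100L, start(ex["E19"]) + 300L),
               end = c(start(ex["E19"]) + 149L, start(ex["E19"]) + 349L)),
    # clipped pair over the same junction: filtered out
    data.frame(qname = c("d1", "d1"), mate = 1:2,
               start = c(start(e17) + 10L, end(e182) - 89L),
               end = c(start(e17) + 59L, end(e182) - 40L)))
  rows$clipped <- rows$qname == "d1"
  rs <- handReadSet(rows)
  cnt <- countSpanningPairs(rs, .gm, fr)
  expect_equal(unname(cnt["E17-E18.2"]), 3L)
  expect_equal(sum(cnt), 3L)
})

test_that("mate order never changes spanning counts", {
  cfg <- simConfig(melanomaLikeProfile(), nPairs = 2000, seed = 33)
  rs <- simulateSample(.gm, cfg, "S1")
  fr <- inferFragmentRange(rs, .gm)
  swapped <- rs
  mc <- mcols(swapped@blocks)
  mc$mate <- 3L - mc$mate
  mcols(swapped@blocks) <- mc
  expect_identical(countSpanningPairs(rs, .gm, fr),
                   countSpanningPairs(swapped, .gm, fr))
})

test_that("spanning counter equals brute-force enumeration on random fixtures", {
  fr <- fragmentRange(20, 190); fr$median <- 105
  for (seed in 23:42) {
    rs <- randomReadSet(.gm, n = 60L + (seed * 11L) %% 141L, seed = seed)
    expect_identical(countSpanningPairs(rs, .gm, fr),
                     bruteSpanningCounts(rs, .gm, fr),
                     label = paste("fixture seed", seed))
  }
  # and on simulated reads with junction-crossing mates present
  cfg <- simConfig(melanomaLikeProfile(), nPairs = 100, seed = 77)
  sim <- simulateSample(.gm, cfg, "S1")
  expect_identical(countSpanningPairs(sim, .gm, fr),
                   bruteSpanningCounts(sim, .gm, fr))
})

test_that("junction counts match isoform content of pure simulations", {
  fr <- fragmentRange(15, 190)
  cfgRef <- simConfig(simProfile(c(ref = 1)), nPairs = 10000, seed = 3)
  jRef <- countSpanningPairs(simulateSample(.gm, cfgRef, "R"), .gm, fr)
  expect_equal(unname(jRef["E18.2-E19"]), 0L)
  expect_equal(unname(jRef["E17-E19"]), 0L)
  expect_gt(jRef["E18.2-E18b"], 0L)
  expect_gt(jRef["E17-E18.2"], 0L)

  cfgX2 <- simConfig(simProfile(c(X2 = 1)), nPairs = 4000, seed = 3)
  jX2 <- countSpanningPairs(simulateSample(.gm, cfgX2, "X"), .gm, fr)
  expect_true(all(jX2[c("E17-E18.2", "E18.2-E18b", "E18.2-E19")] == 0L))
  expect_gt(jX2["E17-E19"], 0L)
})

test_that("observed junction counts agree with the placement-enumeration expectation", {
  cfg <- simConfig(melanomaLikeProfile(), nPairs = 20000, seed = 19,
                   fivePrimeDepletion = 0.3)
  rs <- simulateSample(.gm, cfg, "S1")
  fr <- inferFragmentRange(rs, .gm)
  obs <- countSpanningPairs(rs, .gm, fr)
  for (j in c("E17-E18.2", "E18.2-E18b", "E18.2-E19", "E17-E19")) {
    p <- cfg$profile$proportions
    L <- vapply(names(p), function(t) txLength(.gm, t), numeric(1))
    w <- p * L / sum(p * L)
    expc <- 20000 * sum(vapply(names(p), function(t)
      w[[t]] * junctionDetectionProb(.gm, t, j, cfg, fr), numeric(1)))
    expect_lt(abs(obs[[j]] - expc), 4 * sqrt(max(expc, 1)) + 1,
              label = paste("junction", j))
  }
})

test_that("absence probes flag silent junctions per sample", {
  counts <- matrix(c(0L, 50L, 2L, 0L), nrow = 2,
                   dimnames = list(c("s1", "s2"), c("E13-E16", "NE6p-E4")))
  jt <- new("JunctionCountTable", counts = counts,
            totals = c(s1 = 100, s2 = 100),
            measures = c(`E13-E16` = "X7", `NE6p-E4` = "004rt"))
  expect_equal(unname(absenceProbe("E13-E16", jt)), c(TRUE, FALSE))
  expect_equal(unname(absenceProbe("NE6p-E4", jt, tau = 0)), c(FALSE, FALSE))
  expect_equal(unname(absenceProbe("NE6p-E4", jt, tau = 1)), c(FALSE, TRUE))
  expect_error(absenceProbe("nope", jt), "not counted")
})

test_that("an X7-like admixture lights up the E13-E16 probe", {
  cfg <- simConfig(simProfile(c(ref = 0.6, X7 = 0.4)), nPairs = 20000,
                   seed = 55)
  rs <- simulateSample(.gm, cfg, "S1")
  fr <- inferFragmentRange(rs, .gm)
  cnt <- countSpanningPairs(rs, .gm, fr)
  expect_gt(cnt["E13-E16"], 0L)
})
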