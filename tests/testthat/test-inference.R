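.ep <- c(E18.2 = 154L, E18.5 = 174L, E18.3 = 250L, E18.4 = 292L,
         E18.1 = 759L)

test_that("drop statistic picks the endpoint where coverage stops", {
  cov <- c(rep(100, 250), rep(0, 550))
  call <- detectTerminalExon(cov, .ep)
  expect_equal(call$status, "call")
  expect_equal(call$endpoint, 250L)
  expect_equal(call$exon, "E18.3")
  # drop statistic at the chosen endpoint: 100 / (0 + 1)
  expect_equal(unname(call$drop["E18.3"]), 100)
  # no interior drop: coverage through the longest candidate
  full <- detectTerminalExon(rep(80, 800), .ep)
  expect_equal(full$endpoint, 759L)
  # all-zero coverage cannot be called
  expect_equal(detectTerminalExon(rep(0, 800), .ep)$status, "no-call")
})

test_that("drop detection is invariant to uniform coverage scaling", {
  set.seed(12)
  base <- c(rpois(250, 20), rep(0, 550))
  c1 <- detectTerminalExon(base, .ep)
  c2 <- detectTerminalExon(base * 50L, .ep)
  expect_equal(c1$endpoint, c2$endpoint)
  expect_equal(c1$endpoint, 250L)
})

test_that("UTR arithmetic: endpoint minus CDS end, stop codon inside CDS", {
  call <- detectTerminalExon(c(rep(60, 250), rep(0, 550)), .ep)
  expect_equal(estimateUtrLength(call, .gm, "ref"), 76)
  # a transcript ending exactly at its stop codon has a 0-nt UTR
  callStop <- list(status = "call", endpoint = 174L, exon = "E18.5")
  class(callStop) <- "utrCall"
  expect_equal(estimateUtrLength(callStop, .gm, "ref"), 0)
  callEarly <- list(status = "call", endpoint = 154L, exon = "E18.2")
  class(callEarly) <- "utrCall"
  expect_error(estimateUtrLength(callEarly, .gm, "ref"), "inconsistent")
  expect_error(estimateUtrLength(call, .gm, "004"), "no annotated CDS")
})

test_that("simulated ref reads recover the 76-nt UTR end to end", {
  cfg <- simConfig(simProfile(c(ref = 1)), nPairs = 1500, seed = 42)
  rs <- simulateSample(.gm, cfg, "S1")
  call <- terminalExonScan(rs, .gm)
  expect_equal(call$exon, "E18.3")
  expect_equal(estimateUtrLength(call, .gm, "ref"), 76)
})

test_that("window homogeneity separates flat from collapsing coverage", {
  flat <- assessRegionHomogeneity(rep(40, 2000))
  expect_true(flat$homogeneous)
  expect_lt(flat$cv, 0.05)
  half <- assessRegionHomogeneity(c(rep(100, 1000), rep(0, 1000)))
  expect_false(half$homogeneous)
  expect_warning(one <- assessRegionHomogeneity(rep(5, 100), nWindows = 1),
                 "single window")
  expect_true(one$homogeneous)
})

test_that("melanoma-like mixtures yield the expected presence calls", {
  cfg <- simConfig(melanomaLikeProfile(), nPairs = 8000, nSamples = 3,
                   seed = 7, fivePrimeDepletion = 0.3)
  co <- simulateCohort(.gm, cfg)
  et <- countExonCohort(co$samples, .gm)
  jt <- countJunctionCohort(co$samples, .gm, fragmentRange(15, 190))
  vc <- callVariantPresence(normalizeCounts(et), jt, .gm)
  st <- setNames(vc$status, vc$variant)
  expect_equal(unname(st[c("ref", "X1", "X2")]), rep("present", 3))
  expect_equal(unname(st[c("002", "005", "X7", "004")]), rep("absent", 4))
  expect_true(all(st[c("X3", "X4", "X5", "X6", "X8", "X9")] == "absent"))
  expect_equal(unname(st["003"]), "undetermined")
  # audit: every row records a rule and evidence
  expect_true(all(nzchar(vc$rule)) && all(nzchar(vc$evidence)))
})

test_that("a truncated NE6-terminated admixture is called truncated", {
  prof <- simProfile(c(ref = 0.35, X1 = 0.35, `004` = 0.30))
  cfg <- simConfig(prof, nPairs = 12000, nSamples = 2, seed = 13)
  co <- simulateCohort(.gm, cfg)
  et <- countExonCohort(co$samples, .gm)
  jt <- countJunctionCohort(co$samples, .gm, fragmentRange(15, 190))
  vc <- callVariantPresence(normalizeCounts(et), jt, .gm)
  expect_equal(vc$status[vc$variant == "004"], "truncated")
  expect_true(all(absenceProbe("NE6p-E4", jt)))
  # a read-through version of the same transcript flips the probe
  profRT <- simProfile(c(ref = 0.5, `004rt` = 0.5))
  cfgRT <- simConfig(profRT, nPairs = 12000, seed = 13)
  jrt <- countJunctionCohort(list(simulateSample(.gm, cfgRT, "RT")), .gm,
                             fragmentRange(15, 190))
  expect_false(all(absenceProbe("NE6p-E4", jrt)))
})

test_that("presence calls are monotone in supporting reads", {
  cfg <- simConfig(melanomaLikeProfile(), nPairs = 6000, seed = 23)
  s1 <- simulateSample(.gm, cfg, "S1")
  et <- countExonCohort(list(s1), .gm)
  jt <- countJunctionCohort(list(s1), .gm, fragmentRange(15, 190))
  vc <- callVariantPresence(normalizeCounts(et), jt, .gm)
  # add more X1-supporting reads: X1 must not flip away from present
  cfg2 <- simConfig(simProfile(c(X1 = 1)), nPairs = 3000, seed = 24)
  extra <- simulateSample(.gm, cfg2, "S1")
  merged <- new("ReadSet",
                blocks = c(readBlocks(s1), readBlocks(extra)),
                sampleId = "S1")
  et2 <- countExonCohort(list(merged), .gm)
  jt2 <- countJunctionCohort(list(merged), .gm, fragmentRange(15, 190))
  vc2 <- callVariantPresence(normalizeCounts(et2), jt2, .gm)
  expect_equal(vc$status[vc$variant == "X1"], "present")
  expect_equal(vc2$status[vc2$variant == "X1"], "present")
})

test_that("all-zero input yields only absent/undetermined calls", {
  empty <- handReadSet(data.frame(qname = character(), mate = integer(),
                                  start = integer(), end = integer()))
  cc <- matrix(0L, 1, length(geneExons(.gm)),
               dimnames = list("s1", names(geneExons(.gm))))
  et <- new("ExonCountTable", counts = cc, totals = c(s1 = 1L))
  jn <- geneJunctions(.gm)
  jc <- matrix(0L, 1, nrow(jn), dimnames = list("s1", jn$junctionId))
  jt <- new("JunctionCountTable", counts = jc, totals = c(s1 = 1L),
            measures = setNames(jn$measure, jn$junctionId))
  vc <- callVariantPresence(normalizeCounts(et), jt, .gm)
  expect_true(all(vc$status %in% c("absent", "undetermined")))
  expect_false(any(vc$status %in% c("present", "truncated")))
})

test_that("the exon-3-10-skipping variant is resolved by its junctions", {
  fr <- fragmentRange(15, 190)
  mixed <- simConfig(simProfile(c(ref = 0.5, `delta310-X1` = 0.5)),
                     nPairs = 12000, seed = 44)
  jt <- countJunctionCohort(list(simulateSample(.gm, mixed, "M")), .gm, fr)
  dl <- callDelta310(jt)
  expect_true(dl$fullLengthPresent)
  expect_true(dl$delta310Present)
  expect_true(dl$breakdown[["X1"]] > dl$breakdown[["ref"]] ||
                dl$breakdown[["X1"]] > 0)

  pureFl <- simConfig(simProfile(c(ref = 0.6, X1 = 0.4)), nPairs = 8000,
                      seed = 45)
  jfl <- countJunctionCohort(list(simulateSample(.gm, pureFl, "F")), .gm, fr)
  dfl <- callDelta310(jfl)
  expect_equal(unname(dfl$counts["E2-E11"]), 0L)
  expect_false(dfl$delta310Present)

  pureDl <- simConfig(simProfile(c(`delta310-ref` = 0.5,
                                   `delta310-X1` = 0.5)),
                      nPairs = 8000, seed = 46)
  jdl <- countJunctionCohort(list(simulateSample(.gm, pureDl, "D")), .gm, fr)
  ddl <- callDelta310(jdl)
  expect_equal(unname(ddl$counts["E2-E3"]), 0L)
  expect_false(ddl$fullLengthPresent)
  expect_true(ddl$delta310Present)
})
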