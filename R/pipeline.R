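#' @include inference.R
NULL

.pipelineDefaults <- function() list(
  model = "builtin",
  simulate = NULL,
  bams = NULL,
  params = list(percentiles = c(1, 99), central = 0.95, min_drop = 5,
                tau_junction = 1, n_perm = 10000, scale_factor = 1e7),
  seed = 1L,
  out_dir = NULL
)

.mergeConfig <- function(cfg) {
  def <- .pipelineDefaults()
  for (nm in names(def)) if (is.null(cfg[[nm]])) cfg[[nm]] <- def[[nm]]
  for (nm in names(def$params))
    if (is.null(cfg$params[[nm]])) cfg$params[[nm]] <- def$params[[nm]]
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full terminal-isoform pipeline
#'
#' Composes the stages in order: gene-model loading, sample acquisition
#' (splice-aware simulation or BAM input), exon counting, fragment-range
#' calibration, junction-spanning counting, normalization with quantile
#' outlier masking, isoform ratios and rank correlation, terminal-exon /
#' 3'UTR call from pooled coverage, downstream-exon homogeneity, and
#' rule-based variant presence calls. All randomness flows from the single
#' config seed, so a rerun with the same config reproduces every output
#' byte for byte.
#'
#' @param config a YAML file path or an equivalent nested list. Keys:
#'   `model` (`"builtin"` or a gene-model file), either `simulate`
#'   (fields `profile`, `n_pairs`, `read_len`, `frag_mean`, `frag_sd`,
#'   `five_prime_depletion`, `n_samples`, `depth_jitter`) or `bams`
#'   (paths), `params` (`percentiles`, `central`, `min_drop`,
#'   `tau_junction`, `n_perm`, `scale_factor`), `seed`, `out_dir`.
#' @param outDir output directory; overrides `config$out_dir`; when both
#'   are `NULL` results are returned without being written.
#' @return (invisibly) a list with every stage's tables plus the paths of
#'   any files written.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(config)
  if (is.null(outDir)) outDir <- cfg$out_dir
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  note("isoscan pipeline, seed ", cfg$seed)

  model <- .stage("model", {
    if (identical(cfg$model, "builtin")) brafGeneModel()
    else readGeneModel(cfg$model)
  })
  note("model: ", geneId(model), " (", length(geneExons(model)), " exons, ",
       length(txIds(model)), " transcripts)")

  samples <- .stage("input", {
    if (!is.null(cfg$simulate)) {
      s <- cfg$simulate
      prof <- simProfile(unlist(s$profile), label = "config")
      sc <- simConfig(prof,
                      nPairs = s$n_pairs %||% 2000L,
                      readLen = s$read_len %||% 50L,
                      fragMean = s$frag_mean %||% 300,
                      fragSd = s$frag_sd %||% 50,
                      fivePrimeDepletion = s$five_prime_depletion %||% 0,
                      nSamples = s$n_samples %||% 1L,
                      depthJitter = s$depth_jitter %||% 0,
                      seed = cfg$seed)
      simulateCohort(model, sc)$samples
    } else if (!is.null(cfg$bams)) {
      cfg$bams <- unlist(cfg$bams)
      miss <- cfg$bams[!file.exists(cfg$bams)]
      if (length(miss)) stop("missing alignment file(s): ",
                             paste(miss, collapse = ", "))
      lapply(cfg$bams, readAlignments)
    } else stop("config needs either 'simulate' or 'bams'")
  })
  note(length(samples), " sample(s)")

  exonTab <- .stage("exon-counts", countExonCohort(samples, model))
  fragRange <- .stage("fragment-range", {
    rgs <- lapply(samples, function(s)
      try(inferFragmentRange(s, model, cfg$params$percentiles), silent = TRUE))
    rgs <- rgs[!vapply(rgs, inherits, logical(1), "try-error")]
    if (!length(rgs)) stop("no sample yields same-exon pairs; ",
                           "supply an explicit range")
    structure(list(low = stats::median(vapply(rgs, `[[`, numeric(1), "low")),
                   high = stats::median(vapply(rgs, `[[`, numeric(1), "high")),
                   median = stats::median(vapply(rgs, `[[`, numeric(1), "median")),
                   percentiles = cfg$params$percentiles,
                   nPairs = sum(vapply(rgs, `[[`, integer(1), "nPairs"))),
              class = "fragmentRange")
  })
  note(sprintf("fragment inner-distance range: [%g, %g] (median %g, n=%d)",
               fragRange$low, fragRange$high, fragRange$median, fragRange$nPairs))
  juncTab <- .stage("junction-counts",
                    countJunctionCohort(samples, model, fragRange))
  normExons <- .stage("normalize", {
    ne <- normalizeCounts(exonTab, cfg$params$scale_factor)
    if (nrow(counts(exonTab)) >= 20L)
      filterQuantileOutliers(ne, cfg$params$central)
    else ne
  })
  normJunc <- .stage("normalize", normalizeCounts(juncTab,
                                                  cfg$params$scale_factor))
  ratios <- .stage("ratios", computeIsoformRatios(juncTab))
  correlation <- if (nrow(counts(juncTab)) >= 5L)
    .stage("correlation", correlationStat(juncTab, cfg$params$n_perm,
                                          seed = cfg$seed))
  else NULL

  utr <- .stage("utr", {
    ep <- terminalEndpoints(model)
    ex <- geneExons(model)[names(ep)]
    region <- range(ex, ignore.strand = TRUE)
    cov <- Reduce(`+`, lapply(samples, coverageProfile, region = region))
    if (geneStrand(model) == "-") cov <- rev(cov)
    call <- detectTerminalExon(cov, ep, cfg$params$min_drop)
    utrLen <- if (call$status != "no-call" && "ref" %in% txIds(model) &&
                  !is.na(cdsEndTx(model, "ref")))
      tryCatch(estimateUtrLength(call, model, "ref"),
               error = function(e) NA_real_)
    else NA_real_
    list(call = call, utrLength = utrLen)
  })
  note("terminal endpoint: ", utr$call$exon, " (", utr$call$status, ")")

  homog <- .stage("homogeneity", {
    e19 <- geneExons(model)["E19"]
    cov <- Reduce(`+`, lapply(samples, coverageProfile, region = e19))
    if (geneStrand(model) == "-") cov <- rev(cov)
    assessRegionHomogeneity(cov)
  })

  calls <- .stage("variant-calls",
                  callVariantPresence(normExons, juncTab, model,
                                      tauJunction = cfg$params$tau_junction))
  delta <- .stage("delta310", callDelta310(juncTab,
                                           cfg$params$tau_junction))

  res <- list(config = cfg, model = model, exonCounts = exonTab,
              fragmentRange = fragRange, junctionCounts = juncTab,
              normalizedExons = normExons, normalizedJunctions = normJunc,
              ratios = ratios, correlation = correlation, utr = utr,
              homogeneity = homog, variantCalls = calls, delta310 = delta,
              log = log)
  if (!is.null(outDir)) res$files <- .writePipelineOutputs(res, outDir)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.writePipelineOutputs <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outDir, f)
  asDf <- function(m, what) cbind(data.frame(sample = rownames(m)),
                                  as.data.frame(m, check.names = FALSE))
  files <- c(
    .writeTsv(cbind(asDf(counts(res$exonCounts)),
                    total = sampleTotals(res$exonCounts)),
              fp("exon_counts.tsv")),
    .writeTsv(asDf(counts(res$junctionCounts)), fp("junction_counts.tsv")),
    .writeTsv(asDf(signif(normValues(res$normalizedExons, masked = FALSE), 10)),
              fp("normalized_exons.tsv")),
    .writeTsv(asDf(signif(normValues(res$normalizedJunctions, masked = FALSE),
                          10)),
              fp("normalized_junctions.tsv")),
    .writeTsv(within(res$ratios, {
      order_by_ref <- order(attr(res$ratios, "orderByRef"))
      order_by_x1 <- order(attr(res$ratios, "orderByX1"))
    }), fp("ratios.tsv")),
    .writeTsv(res$variantCalls, fp("variant_calls.tsv")),
    .writeTsv(data.frame(exon = names(res$utr$call$drop),
                         drop = res$utr$call$drop,
                         chosen = names(res$utr$call$drop) ==
                           (res$utr$call$exon %||% ""),
                         utr_length = res$utr$utrLength),
              fp("utr_call.tsv")))
  if (!is.null(res$correlation))
    files <- c(files, .writeTsv(res$correlation, fp("correlation.tsv")))
  files <- c(files,
             .writeTsv(data.frame(junction = names(res$delta310$counts),
                                  pairs = as.integer(res$delta310$counts)),
                       fp("delta310.tsv")))
  writeLines(res$log, fp("run_log.txt"))
  yaml::write_yaml(res$config, fp("effective_config.yaml"))
  makeCohortReport(res, fp("report.md"))
  c(files, fp("run_log.txt"), fp("effective_config.yaml"), fp("report.md"))
}

#' Write a cohort-level Markdown report
#'
#' Summarizes a pipeline run the way the cohort figures do: per-exon count
#' medians, junction box-plot statistics (quartiles), the sorted
#' log2-ratio series against the 0 reference line (samples ordered by
#' increasing ref junction count, the same order for counts and ratios),
#' the rank-correlation summary, the terminal-endpoint call and the
#' variant presence table.
#'
#' @param res a [runPipeline()] result list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
makeCohortReport <- function(res, path) {
  out <- c("# Cohort report", "",
           paste0("Gene: ", geneId(res$model), "; samples: ",
                  nrow(counts(res$exonCounts)), "; seed: ", res$config$seed),
           "")
  md <- function(df) {
    if (!nrow(df)) return("(empty)")
    hdr <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    rows <- apply(df, 1L, function(r)
      paste("|", paste(format(r, trim = TRUE), collapse = " | "), "|"))
    c(hdr, sep, rows)
  }
  ec <- counts(res$exonCounts)
  out <- c(out, "## Exon counts (per-exon median across samples)", "",
           md(data.frame(exon = colnames(ec),
                         median = apply(ec, 2L, stats::median))), "")
  jc <- counts(res$junctionCounts)
  qs <- t(apply(jc, 2L, stats::quantile, probs = c(.25, .5, .75), type = 7))
  out <- c(out, "## Junction spanning-pair statistics", "",
           md(data.frame(junction = rownames(qs), q1 = qs[, 1],
                         median = qs[, 2], q3 = qs[, 3],
                         measure = unname(measures(
                           res$junctionCounts)[rownames(qs)]))), "")
  rt <- res$ratios[attr(res$ratios, "orderByRef"), ]
  ok <- !rt$undefined_over_ref
  out <- c(out, "## Sorted log2 ratios (samples by increasing ref count; 0 = equal levels)",
           "",
           md(data.frame(sample = rt$sample[ok], ref = rt$ref[ok],
                         log2_x1_over_ref = round(rt$log2_x1_over_ref[ok], 3),
                         log2_x2_over_ref = round(rt$log2_x2_over_ref[ok], 3))),
           "")
  if (!is.null(res$correlation))
    out <- c(out, "## Rank correlation", "", md(res$correlation), "")
  out <- c(out, "## Terminal-exon call", "",
           paste0("Chosen endpoint: ", res$utr$call$exon %||% "none",
                  " (status ", res$utr$call$status, "); 3'UTR length: ",
                  res$utr$utrLength %||% NA, " nt"), "",
           "## Variant calls", "", md(res$variantCalls), "")
  writeLines(out, path)
  invisible(path)
}
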