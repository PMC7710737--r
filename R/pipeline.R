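#' Run the full synthetic-to-report analysis pipeline
#'
#' Executes every analysis stage in dependency order from one hierarchical
#' YAML (or list) configuration: transcript simulation, chimera detection
#' and long-group calling, enrichment profiling with clustering and PCA,
#' repeat-unit averaging, motif scanning, duplex-group overlap testing,
#' domain quantification, and irCLIP cluster calling. All randomness flows
#' from the single top-level `seed`, offset deterministically per stage, so
#' re-running an identical configuration reproduces every output file
#' byte for byte. A run manifest (JSON) records the parameters, package
#' version, seed and an MD5 checksum of every output.
#'
#' @param config path to a YAML configuration or an equivalent named list.
#'   Required fields: `seed`, `samples` (sample sheet with at least a
#'   `protein` and `role` per profiling sample), and a `transcript` block;
#'   each stage block (`chimera`, `profiles`, `dgoverlap`, `domains`,
#'   `irclip`, `motif`) is optional and falls back to defaults. See the
#'   packaged `demo-config.yaml` under `inst/extdata`.
#' @param outDir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @examples
#' cfg <- system.file("extdata", "demo-config.yaml", package = "rnparch")
#' \donttest{runPipeline(cfg, tempfile("demo"))}
#' @importFrom yaml read_yaml
#' @importFrom Biostrings writeXStringSet DNAStringSet
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  for (field in c("seed", "samples", "transcript")) {
    if (is.null(config[[field]]))
      stop("config schema violation: missing required field \"", field, "\"")
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  stages <- character()
  outputs <- character()
  emit <- function(path) { outputs[[length(outputs) + 1L]] <<- path; path }

  ## stage 1: transcript simulation -----------------------------------------
  txc <- config$transcript
  L <- txc$length %||% 19000L
  reps <- lapply(txc$repeats, function(r)
    list(name = r$name, unitLength = r$unit_length, copies = r$copies,
         at = r$at))
  doms <- list()
  for (d in txc$domains) doms[[d$name]] <- c(d$start, d$end)
  tx <- simulateTranscript(L, gc = txc$gc %||% 0.5, repeats = reps,
                           domains = doms, seed = seed + 101L)
  fa <- file.path(outDir, "transcript.fa")
  seqs <- Biostrings::DNAStringSet(tx$sequence)
  names(seqs) <- "transcript"
  Biostrings::writeXStringSet(seqs, emit(fa))
  ann <- unlist(IRanges::IRangesList(tx$repeatUnits))
  if (length(tx$repeatUnits)) {
    names(ann) <- rep(names(tx$repeatUnits), lengths(tx$repeatUnits))
    writeBedAnnotations(ann, emit(file.path(outDir, "repeats.bed")))
  }
  if (length(transcriptDomains(tx$model)))
    writeBedAnnotations(transcriptDomains(tx$model),
                        emit(file.path(outDir, "domains.bed")))
  stages <- c(stages, "transcript")

  ## stage 2: chimera detection ---------------------------------------------
  chc <- config$chimera
  if (!is.null(chc)) {
    anchors <- lapply(chc$anchors, function(a)
      list(left = c(a$left_start, a$left_end),
           right = c(a$right_start, a$right_end)))
    pairs <- simulateFripPairs(chc$n_pairs %||% 20000L, L, anchors,
                               chimeraRate = chc$chimera_rate %||% 0.02,
                               seed = seed + 202L)
    cls <- classifyPairs(pairs, chc$long_threshold %||% 1000, L)
    writePairTable(cls, emit(file.path(outDir, "pairs.tsv")))
    lgs <- callLongGroups(cls[cls$class == "long", ],
                          linkDistance = chc$link_distance %||% 500,
                          minSupport = chc$min_support %||% 5)
    lgOut <- lgs[, setdiff(names(lgs), "members")]
    utils::write.table(lgOut, emit(file.path(outDir, "long_groups.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLgBedpe(lgs, emit(file.path(outDir, "long_groups.bedpe")))
    writeCoverageTrack(pairTagCoverage(cls, L),
                       emit(file.path(outDir, "coverage_all.bedGraph")))
    writeCoverageTrack(pairTagCoverage(cls[cls$class == "long", ], L),
                       emit(file.path(outDir, "coverage_long.bedGraph")))
    stages <- c(stages, "chimera")
  }

  ## stage 3: enrichment profiles, clustering, PCA --------------------------
  prc <- config$profiles
  if (!is.null(prc)) {
    window <- prc$window %||% 100L
    sheet <- do.call(rbind, lapply(config$samples, function(s)
      data.frame(sample_id = s$sample_id, protein = s$protein,
                 role = s$role, domain_name = s$domain %||% NA_character_,
                 fold = s$fold %||% 1)))
    inputBins <- NULL
    profs <- list(); mat <- NULL
    ipRows <- sheet[sheet$role == "IP", , drop = FALSE]
    inputRows <- sheet[sheet$role == "input", , drop = FALSE]
    if (nrow(inputRows) == 0L)
      stop("config schema violation: \"samples\" needs >= 1 input role")
    inputCovs <- lapply(seq_len(nrow(inputRows)), function(i)
      simulateIpInput(L, seed = seed + 300L + i,
                      ipReads = prc$library_size %||% 50000L,
                      inputReads = prc$library_size %||% 50000L)$input)
    inputMeanBins <- binCoverage(Reduce(`+`, inputCovs) / length(inputCovs),
                                 window)
    for (i in seq_len(nrow(ipRows))) {
      r <- ipRows[i, ]
      dm <- if (!is.na(r$domain_name))
        transcriptDomains(tx$model)[r$domain_name] else IRanges()
      cov <- simulateIpInput(L, domains = dm, folds = r$fold,
                             ipReads = prc$library_size %||% 50000L,
                             inputReads = 1,
                             seed = seed + 400L + i)$ip
      profs[[r$sample_id]] <- normalizeProfile(binCoverage(cov, window),
                                               inputMeanBins,
                                               window = window,
                                               sampleId = r$sample_id,
                                               protein = r$protein)
    }
    mat <- profileMatrix(profs)
    utils::write.table(
      data.frame(sample_id = rownames(mat), mat, check.names = FALSE),
      emit(file.path(outDir, "profiles.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(profs) >= 2L) {
      cl <- clusterProfiles(profs, k = prc$k %||% 2L)
      writeDendrogramNewick(cl$hclust,
                            emit(file.path(outDir, "dendrogram.nwk")))
      pca <- pcaProfiles(profs)
      utils::write.table(
        data.frame(sample_id = rownames(pca$scores), pca$scores,
                   check.names = FALSE),
        emit(file.path(outDir, "pca_scores.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(component = colnames(pca$components),
                   variance_explained = pca$variance_explained),
        emit(file.path(outDir, "pca_variance.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    stages <- c(stages, "profiles")

    ## stage 4: repeat-unit averaging (first repeat, on mean IP coverage) ---
    if (length(tx$repeatUnits)) {
      units <- tx$repeatUnits[[1]]
      sig <- simulateIpInput(L, domains = IRanges(min(start(units)),
                                                  max(end(units))),
                             folds = 4,
                             seed = seed + 500L)$ip
      rap <- averageOverUnits(sig, units, flank = prc$repeat_flank %||% 10L)
      utils::write.table(
        data.frame(offset = rap$offset, mean_signal = rap$profile),
        emit(file.path(outDir, "repeat_average.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      stages <- c(stages, "repeats")
    }
  }

  ## stage 5: motif scan ------------------------------------------------------
  moc <- config$motif
  motif <- moc$motif %||% "DRACH"
  pos <- scanMotif(tx$sequence, motif)
  if (length(pos)) {
    writeMotifBed(pos, nchar(motif),
                  emit(file.path(outDir, "motif_matches.bed")),
                  motif = motif)
    dens <- motifDensity(pos, L, moc$window %||% 300L, moc$step %||% 50L)
    utils::write.table(dens, emit(file.path(outDir, "motif_density.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stages <- c(stages, "motif")

  ## stage 6: duplex-group overlap test --------------------------------------
  dgc <- config$dgoverlap
  if (!is.null(dgc)) {
    sets <- simulateDgSets(dgc$n_query %||% 100L, dgc$n_reference %||% 100L,
                           dgc$shared_fraction %||% 0.5, L,
                           seed = seed + 600L)
    writeDgTable(sets$query, emit(file.path(outDir, "query.dg.tsv")))
    writeDgTable(sets$reference, emit(file.path(outDir, "reference.dg.tsv")))
    res <- permutationPvalue(sets$query, sets$reference, L,
                             nShuffles = dgc$n_shuffles %||% 1000L,
                             seed = seed + 601L)
    writeOverlapResult(res, emit(file.path(outDir, "dg_overlap.json")),
                       emit(file.path(outDir, "dg_shuffles.tsv")))
    stages <- c(stages, "dgoverlap")
  }

  ## stage 7: domain quantification ------------------------------------------
  doc <- config$domains
  if (!is.null(doc) && length(transcriptDomains(tx$model))) {
    dm <- transcriptDomains(tx$model)
    alleles <- doc$alleles
    if (is.null(alleles))
      alleles <- list(list(name = "WT",
                           folds = rep(4, length(dm))),
                      list(name = "MUT",
                           folds = rep(1, length(dm))))
    quants <- do.call(rbind, lapply(seq_along(alleles), function(i) {
      al <- alleles[[i]]
      cov <- simulateIpInput(L, domains = dm,
                             folds = unlist(al$folds),
                             ipReads = doc$library_size %||% 50000L,
                             inputReads = doc$library_size %||% 50000L,
                             seed = seed + 700L + i)
      q <- domainEnrichment(cov$ip, cov$input, dm)
      q$allele <- al$name
      q
    }))
    quants <- relativeToReference(quants, doc$reference %||% "WT")
    writeDomainQuant(quants, emit(file.path(outDir, "domain_quant.tsv")))
    stages <- c(stages, "domains")
  }

  ## stage 8: irCLIP cluster calling ------------------------------------------
  irc <- config$irclip
  if (!is.null(irc)) {
    planted <- unlist(irc$positions)
    if (is.null(planted))
      planted <- withSeed(seed + 799L,
                          sort(sample(seq(100L, L - 100L),
                                      irc$n_sites %||% 20L)))
    sim <- simulateIrclip(planted, L, lambda = irc$lambda %||% 20,
                          noiseRate = irc$noise_rate %||% 0.05,
                          seed = seed + 800L)
    s1 <- crosslinkSites(sim$rep1, L)
    s2 <- crosslinkSites(sim$rep2, L)
    writeSiteTrack(s1, emit(file.path(outDir, "sites_rep1.bedGraph")))
    writeSiteTrack(s2, emit(file.path(outDir, "sites_rep2.bedGraph")))
    clusters <- callClusters(s1, s2, extend = irc$extend %||% 5L,
                             trim = irc$trim %||% 5L)
    writeClusterBed(clusters, emit(file.path(outDir, "irclip_clusters.bed")))
    stages <- c(stages, "irclip")
  }

  ## manifest ------------------------------------------------------------------
  outputs <- unlist(outputs)
  sums <- tools::md5sum(outputs)
  manifest <- list(
    tool = "rnparch",
    version = as.character(utils::packageVersion("rnparch")),
    seed = seed,
    config = config,
    stages = stages,
    outputs = lapply(seq_along(outputs), function(i)
      list(file = basename(outputs[i]), md5 = unname(sums[i])))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# BEDPE arcs for long groups: two anchor blocks per record.
writeLgBedpe <- function(lgs, file, transcriptName = "transcript") {
  if (nrow(lgs) == 0L) {
    writeLines(character(), file)
    return(invisible(file))
  }
  rows <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%d\t.\t.",
                  transcriptName, lgs$left_start - 1L, lgs$left_end,
                  transcriptName, lgs$right_start - 1L, lgs$right_end,
                  lgs$lg_id, lgs$support)
  writeLines(rows, file)
  invisible(file)
}
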