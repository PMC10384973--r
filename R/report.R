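#' Pipeline run configuration
#'
#' Either `alignments` + `genome` + `catalog` paths (classify mode) or a
#' `simulate` block (simulate mode: the toy genome and reads are generated,
#' then classified from the ground-truth SAM). All randomness flows from
#' `seed`.
#'
#' @param outdir output directory (created if missing).
#' @param genome,catalog,alignments input paths (classify mode).
#' @param simulate `NULL` or a list with `n_reads`, `profile`
#'   (`"nonpermissive"` or `"permissive"`), optional `toy_params`
#'   ([toyGenomeParams()]) and `noise` ([noiseModel()]).
#' @param params classification tolerances ([groupingParams()]).
#' @param sample sample name for the accounting row.
#' @param mapped_host externally supplied host-transcriptome mapped count.
#' @param min_read_length,primary_only alignment filters.
#' @param decimals gene-table percentage decimals (`NULL` = auto).
#' @param seed integer seed.
#' @return a validated `RunConfig` list.
#' @export
runConfig <- function(outdir, genome = NULL, catalog = NULL,
                      alignments = NULL, simulate = NULL,
                      params = groupingParams(), sample = "sample",
                      mapped_host = NA_integer_, min_read_length = 0L,
                      primary_only = TRUE, decimals = NULL, seed = 1L) {
  cfg <- list(outdir = outdir, genome = genome, catalog = catalog,
              alignments = alignments, simulate = simulate, params = params,
              sample = sample, mapped_host = mapped_host,
              min_read_length = min_read_length, primary_only = primary_only,
              decimals = decimals, seed = as.integer(seed))
  validateRunConfig(cfg)
  cfg
}

#' @rdname runConfig
#' @param config a config list.
#' @export
validateRunConfig <- function(config) {
  need <- c("outdir", "params", "seed")
  for (f in need)
    if (is.null(config[[f]]))
      stop("config field missing: '", f, "'")
  if (is.null(config$simulate)) {
    for (f in c("genome", "catalog", "alignments"))
      if (is.null(config[[f]]))
        stop("config field missing: '", f,
             "' (required unless a 'simulate' block is given)")
  } else if (is.null(config$simulate$n_reads))
    stop("config field missing: 'simulate$n_reads'")
  if (any(unlist(config$params) < 0))
    stop("config tolerances must all be >= 0")
  invisible(TRUE)
}

.writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Export transcript groups as BED12
#'
#' One BED12 line per group: `score` is the read count capped at 1000,
#' blocks are the representative exon chain, and `thickStart`/`thickEnd`
#' span the called catalog ORF (clipped to the transcript) when an ORF call
#' table is supplied. Coordinates follow the BED convention (0-based
#' half-open).
#'
#' @param tgs a [TranscriptGroupSet-class] (non-empty).
#' @param contig contig name for column 1.
#' @param calls optional [assignOrf()] result for thick (CDS) intervals.
#' @param catalog optional [FeatureCatalog-class] (needed with `calls`).
#' @param path optional output file.
#' @return character vector of BED12 lines (invisibly if `path` given).
#' @export
exportBed12 <- function(tgs, contig, calls = NULL, catalog = NULL,
                        path = NULL) {
  g <- groups(tgs)
  if (!nrow(g)) stop("no transcript groups to export")
  chains <- groupChains(tgs)
  orf_by_label <- NULL
  if (!is.null(calls) && !is.null(catalog))
    orf_by_label <- setNames(seq_along(catalog@orfs),
                             mcols(catalog@orfs)$label)
  lines <- vapply(seq_len(nrow(g)), function(i) {
    ch <- chains[[i]]
    cs <- start(ch)[1L] - 1L          # chromStart, 0-based
    ce <- end(ch)[length(ch)]         # chromEnd, half-open
    thick_s <- cs; thick_e <- cs
    if (!is.null(orf_by_label) && calls$category[i] == "catalog" &&
        calls$orf_label[i] %in% names(orf_by_label)) {
      o <- catalog@orfs[orf_by_label[[calls$orf_label[i]]]]
      thick_s <- max(start(o) - 1L, cs)
      thick_e <- min(end(o), ce)
    }
    paste(contig, cs, ce, g$group_id[i], min(g$count[i], 1000L),
          g$strand[i], thick_s, thick_e, "0", length(ch),
          paste(width(ch), collapse = ","),
          paste(start(ch) - 1L - cs, collapse = ","),
          sep = "\t")
  }, "")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Run the full classification pipeline
#'
#' Orchestrates simulate (optional) -> ingest -> group -> ORF call ->
#' splice audit / RCA screen -> report. Writes into `config$outdir`:
#' `accounting.tsv` (read accounting), `groups.tsv` (transcript groups,
#' junction chains as 1-based donor-acceptor pairs), `orf_calls.tsv`,
#' `gene_table.tsv` (per-ORF counts and percents), `splice_audit.tsv`
#' (per-junction transgene audit), `novel_ends.tsv`, `rca.txt`,
#' `transcripts.bed` (BED12) and `manifest.txt` (key=value: version, config
#' hash, counts). Re-running with the same config reproduces all outputs
#' bytewise.
#'
#' @param config a [runConfig()] list.
#' @param verbose log stage progress.
#' @return invisibly, a list with all intermediate objects (`genome`,
#'   `catalog`, `reads`, `tgs`, `calls`, `gene_table`, `splice_stats`,
#'   `rca`, `accounting`, `novel_ends`, `outdir`).
#' @export
runPipeline <- function(config, verbose = FALSE) {
  validateRunConfig(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  host_genome <- NULL
  truth <- NULL
  if (!is.null(config$simulate)) {
    vlog("simulate", "building toy genome and sampling ",
         config$simulate$n_reads, " reads", verbose = verbose)
    tp <- config$simulate$toy_params
    if (is.null(tp)) tp <- toyGenomeParams()
    toy <- buildToyGenome(tp, seed = config$seed)
    genome <- toy$genome; catalog <- toy$catalog
    host_genome <- toy$host_genome
    prof_name <- config$simulate$profile
    if (is.null(prof_name)) prof_name <- "nonpermissive"
    profile <- if (inherits(prof_name, "AbundanceProfile")) prof_name
      else switch(prof_name,
                  nonpermissive = nonpermissiveProfile(toy$models),
                  permissive = permissiveProfile(toy$models),
                  stop("unknown profile: ", prof_name))
    noise <- config$simulate$noise
    if (is.null(noise)) noise <- noiseModel()
    sim <- sampleReads(toy$models, profile, config$simulate$n_reads,
                       noise, genome, host_genome, seed = config$seed)
    simdir <- file.path(config$outdir, "sim")
    dir.create(simdir, showWarnings = FALSE)
    writeGenome(genome, file.path(simdir, "genome.fa"))
    writeFeatureCatalog(catalog, file.path(simdir, "catalog.tsv"))
    writeSimulatedReads(sim, fastq = file.path(simdir, "reads.fastq"),
                        sam = file.path(simdir, "truth.sam"),
                        truth_tsv = file.path(simdir, "truth.tsv"))
    alignments <- file.path(simdir, "truth.sam")
    truth <- sim$truth
  } else {
    vlog("ingest", "loading genome and catalog", verbose = verbose)
    genome <- loadGenome(config$genome)
    catalog <- loadFeatureCatalog(config$catalog, genome)
    alignments <- config$alignments
  }

  vlog("ingest", "parsing ", alignments, verbose = verbose)
  reads <- parseSplicedAlignments(alignments)
  reads <- filterAlignments(reads, config$min_read_length,
                            config$primary_only, verbose = verbose)
  nb <- lengths(reads)
  contigs <- if (length(reads))
    as.character(GenomeInfoDb::seqnames(
      unlist(reads, use.names = FALSE)))[cumsum(nb) - nb + 1L]
  else character()
  on_vector <- contigs == genomeName(genome)
  e1_contig_count <- sum(!on_vector)
  vreads <- reads[on_vector]

  vlog("group", length(vreads), " vector reads", verbose = verbose)
  tgs <- groupTranscripts(vreads, catalog, config$params)
  g <- groups(tgs)

  vlog("orfcall", nrow(g), " groups", verbose = verbose)
  calls <- assignOrf(tgs, genome, catalog)
  total_classified <- sum(g$count)
  gene_tab <- if (total_classified > 0)
    geneTable(calls, tgs, total = total_classified,
              decimals = config$decimals)
  else data.frame(feature = character(), count = integer(),
                  percent = numeric())

  vlog("audit", "transgene splice audit and RCA screen", verbose = verbose)
  sstats <- transgeneSpliceStats(tgs, catalog)
  rca <- screenE1(calls, tgs, catalog,
                  e1_contig_count = if (!is.null(host_genome) ||
                                        e1_contig_count > 0)
                    e1_contig_count else NA_integer_)

  # novel 5' ends: representatives of TSS-less groups, weighted by count
  novel <- data.frame()
  noTss <- which(is.na(g$tss))
  if (length(noTss)) {
    ch <- groupChains(tgs)[noTss]
    for (s in c("+", "-")) {
      sel <- noTss[g$strand[noTss] == s]
      if (!length(sel)) next
      ends <- unlist(lapply(sel, function(i) {
        cc <- groupChains(tgs)[[i]]
        e <- if (s == "+") start(cc)[1L] else end(cc)[length(cc)]
        rep(e, g$count[i])
      }))
      novel <- rbind(novel,
                     clusterNovelEnds(ends, config$params$cluster_gap,
                                      config$params$min_cluster_count,
                                      strand = s))
    }
  }

  acct <- readAccounting(mcols(reads)$read_length,
                         mapped_host = config$mapped_host,
                         vaccine_reads = vreads,
                         e1_reads = if (e1_contig_count > 0 ||
                                        !is.null(host_genome))
                           e1_contig_count else NA_integer_,
                         sample = config$sample)

  vlog("report", "writing tables to ", config$outdir, verbose = verbose)
  .writeTsv(acct, file.path(config$outdir, "accounting.tsv"))
  gdf <- as.data.frame(g)
  gdf$unclassified_total <- c(unclassifiedCount(tgs),
                              rep(NA, max(nrow(gdf) - 1L, 0L)))
  .writeTsv(gdf, file.path(config$outdir, "groups.tsv"))
  .writeTsv(calls, file.path(config$outdir, "orf_calls.tsv"))
  gt_out <- gene_tab
  attr(gt_out, "total") <- NULL; attr(gt_out, "decimals") <- NULL
  .writeTsv(cbind(gt_out,
                  denominator_total = c(total_classified,
                                        rep(NA, max(nrow(gt_out) - 1L, 0L)))),
            file.path(config$outdir, "gene_table.tsv"))
  .writeTsv(sstats$junctions_in_orf,
            file.path(config$outdir, "splice_audit.tsv"))
  .writeTsv(novel, file.path(config$outdir, "novel_ends.tsv"))
  writeLines(c(sprintf("e1_orf_read_count=%d", rca$e1_orf_read_count),
               sprintf("e1_contig_read_count=%s", rca$e1_contig_read_count),
               sprintf("verdict=%s", rca$verdict),
               sprintf("transgene_unspliced=%d", sstats$unspliced_count),
               sprintf("transgene_spliced=%d", sstats$spliced_count),
               sprintf("pct_spliced_vs_unspliced=%s",
                       sstats$pct_spliced_vs_unspliced)),
             file.path(config$outdir, "rca.txt"))
  if (nrow(g))
    exportBed12(tgs, genomeName(genome), calls, catalog,
                path = file.path(config$outdir, "transcripts.bed"))

  cfg_path <- file.path(config$outdir, "config.yaml")
  writeLines(yaml::as.yaml(config[setdiff(names(config), "outdir")]),
             cfg_path)
  manifest <- c(
    sprintf("tool=VectorTxAudit %s",
            as.character(utils::packageVersion("VectorTxAudit"))),
    sprintf("config_md5=%s", unname(tools::md5sum(cfg_path))),
    sprintf("seed=%d", config$seed),
    sprintf("reads_parsed=%d", length(reads)),
    sprintf("reads_vector=%d", length(vreads)),
    sprintf("reads_e1_contig=%d", e1_contig_count),
    sprintf("groups=%d", nrow(g)),
    sprintf("classified=%d", total_classified),
    sprintf("unclassified=%d", unclassifiedCount(tgs)))
  writeLines(manifest, file.path(config$outdir, "manifest.txt"))

  invisible(list(genome = genome, catalog = catalog, reads = vreads,
                 truth = truth, tgs = tgs, calls = calls,
                 gene_table = gene_tab, splice_stats = sstats, rca = rca,
                 accounting = acct, novel_ends = novel,
                 outdir = config$outdir))
}
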