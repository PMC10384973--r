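test_that("run configs are validated with field-naming errors", {
  expect_error(runConfig(outdir = tempfile()), "catalog|genome|alignments")
  expect_error(runConfig(outdir = tempfile(), genome = "g.fa",
                         alignments = "a.sam"),
               "'catalog'")
  cfg <- runConfig(outdir = tempfile(), simulate = list(n_reads = 10))
  expect_true(validateRunConfig(cfg))
  expect_error(runConfig(outdir = tempfile(),
                         simulate = list(n_reads = 10),
                         params = groupingParams(junction_tol = -1)),
               ">= 0")
})

test_that("the pipeline is bytewise reproducible for a fixed seed", {
  d1 <- file.path(tempdir(), "run1"); d2 <- file.path(tempdir(), "run2")
  for (d in c(d1, d2)) {
    unlink(d, recursive = TRUE)
    runPipeline(runConfig(outdir = d, simulate = list(n_reads = 400),
                          seed = 7L))
  }
  for (f in c("manifest.txt", "gene_table.tsv", "groups.tsv",
              "accounting.tsv", "transcripts.bed", "rca.txt"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("a nonpermissive run is dominated by the transgene ORF", {
  out <- file.path(tempdir(), "np_run")
  unlink(out, recursive = TRUE)
  res <- runPipeline(runConfig(outdir = out,
                               simulate = list(n_reads = 1500,
                                               profile = "nonpermissive"),
                               seed = 41L))
  gt <- res$gene_table
  expect_equal(gt$feature[1], "TG")
  expect_gt(gt$percent[1], 75)
  expect_equal(res$rca$verdict, "no E1 transcripts detected")
  expect_true(file.exists(file.path(out, "manifest.txt")))
  expect_true(file.exists(file.path(out, "transcripts.bed")))
})

test_that("a permissive run shows the full repertoire with late units on top", {
  out <- file.path(tempdir(), "perm_run")
  unlink(out, recursive = TRUE)
  res <- runPipeline(runConfig(outdir = out,
                               simulate = list(n_reads = 2000,
                                               profile = "permissive"),
                               seed = 42L))
  gt <- res$gene_table
  expect_gt(nrow(gt), 5)
  expect_true(grepl("\\(L[0-9]\\)", gt$feature[1]))  # a late ORF dominates
  tg_pct <- gt$percent[gt$feature == "TG"]
  expect_lt(tg_pct, 15)
  expect_gt(tg_pct, 2)
})

test_that("BED12 export is well-formed and round-trips through a reference parser", {
  toy <- toySetup()
  np <- nonpermissiveProfile(toy$models)
  sim <- sampleReads(toy$models, np, 300, noiselessModel(), toy$genome,
                     seed = 19)
  sam <- tempfile(fileext = ".sam")
  writeSimulatedReads(sim, sam = sam)
  tgs <- groupTranscripts(parseSplicedAlignments(sam), toy$catalog)
  calls <- assignOrf(tgs, toy$genome, toy$catalog)
  lines <- exportBed12(tgs, genomeName(toy$genome), calls, toy$catalog)
  expect_equal(length(lines), nrow(groups(tgs)))
  f <- strsplit(lines, "\t")
  expect_true(all(lengths(f) == 12L))

  # single- vs multi-exon block structure
  nexons <- lengths(groupChains(tgs))
  expect_equal(as.integer(vapply(f, `[`, "", 10L)), unname(nexons))
  one <- which(nexons == 1L)[1]
  expect_equal(f[[one]][11], as.character(
    GenomicRanges::width(groupChains(tgs)[[one]])))

  skip_if_not_installed("rtracklayer")
  bed <- tempfile(fileext = ".bed")
  writeLines(lines, bed)
  back <- rtracklayer::import(bed)
  expect_equal(length(back), nrow(groups(tgs)))
  expect_equal(back$name, groups(tgs)$group_id)
  expect_equal(back$score, pmin(groups(tgs)$count, 1000L))
  for (i in seq_along(back)) {
    blocks_back <- IRanges::shift(back$blocks[[i]],
                                  GenomicRanges::start(back)[i] - 1L)
    ch <- groupChains(tgs)[[i]]
    expect_equal(GenomicRanges::start(blocks_back),
                 GenomicRanges::start(ch))
    expect_equal(GenomicRanges::end(blocks_back), GenomicRanges::end(ch))
  }

  empty <- groupTranscripts(GenomicRanges::GRangesList(), toy$catalog)
  expect_error(exportBed12(empty, "x"), "no transcript groups")
})

test_that("thick intervals span the called ORF", {
  toy <- toySetup()
  np <- nonpermissiveProfile(toy$models)
  sim <- sampleReads(toy$models, np, 200, noiselessModel(), toy$genome,
                     seed = 20)
  sam <- tempfile(fileext = ".sam")
  writeSimulatedReads(sim, sam = sam)
  tgs <- groupTranscripts(parseSplicedAlignments(sam), toy$catalog)
  calls <- assignOrf(tgs, toy$genome, toy$catalog)
  lines <- exportBed12(tgs, genomeName(toy$genome), calls, toy$catalog)
  f <- strsplit(lines, "\t")
  orfs <- toy$catalog@orfs
  lab <- S4Vectors::mcols(orfs)$label
  for (i in seq_along(f)) {
    if (calls$category[i] != "catalog") next
    o <- orfs[lab == calls$orf_label[i]]
    expect_equal(as.integer(f[[i]][7]), GenomicRanges::start(o) - 1L)
    expect_equal(as.integer(f[[i]][8]), GenomicRanges::end(o))
  }
})

test_that("classify mode consumes files written by simulate mode", {
  out <- file.path(tempdir(), "sim_then_classify")
  unlink(out, recursive = TRUE)
  res1 <- runPipeline(runConfig(outdir = out,
                                simulate = list(n_reads = 300), seed = 5L))
  out2 <- file.path(tempdir(), "classify_only")
  unlink(out2, recursive = TRUE)
  res2 <- runPipeline(runConfig(outdir = out2,
                                genome = file.path(out, "sim", "genome.fa"),
                                catalog = file.path(out, "sim", "catalog.tsv"),
                                alignments = file.path(out, "sim", "truth.sam"),
                                seed = 5L))
  expect_identical(as.data.frame(groups(res1$tgs)),
                   as.data.frame(groups(res2$tgs)))
  expect_identical(res1$gene_table, res2$gene_table)
})
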