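snapFixture <- function() {
  gen <- tinyGenome(strrep("ACGT", 2000))
  cat <- tinyCatalog(rbind(
    catRow("tss", "P1", 4000),
    catRow("polya", "pA1", 7500),
    catRow("donor", "d1", 4998),
    catRow("acceptor", "a1", 7003)), gen)
  list(gen = gen, cat = cat)
}

test_that("junction ends snap independently to catalog sites within tol", {
  fx <- snapFixture()
  # observed intron [5000, 7000]; catalog donor 4998, acceptor 7003
  ch <- chainOf(c(4000, 7001), c(4999, 7500))
  j <- snapJunctions(ch, fx$cat, tol = 10)
  expect_equal(j$donor, 4998L)
  expect_equal(j$acceptor, 7003L)
  expect_false(j$is_novel)

  # acceptor 40 nt off with tol 10 -> novel, observed acceptor kept
  ch2 <- chainOf(c(4000, 7044), c(4999, 7500))
  j2 <- snapJunctions(ch2, fx$cat, tol = 10)
  expect_true(j2$is_novel)
  expect_true(j2$acceptor_novel)
  expect_equal(j2$acceptor, 7043L)
  expect_equal(j2$donor, 4998L)  # matched end still snapped

  expect_equal(nrow(snapJunctions(chainOf(4000, 4999), fx$cat, 10)), 0L)
})

test_that("snapping is idempotent", {
  fx <- snapFixture()
  ch <- chainOf(c(4000, 7001), c(4999, 7500))
  j1 <- snapJunctions(ch, fx$cat, tol = 10)
  # rebuild a chain whose intron already sits on the snapped coordinates
  ch_snapped <- chainOf(c(4000, j1$acceptor + 1L), c(j1$donor - 1L, 7500))
  j2 <- snapJunctions(ch_snapped, fx$cat, tol = 10)
  expect_equal(j1$donor, j2$donor)
  expect_equal(j1$acceptor, j2$acceptor)
})

test_that("equidistant catalog sites resolve to the lower coordinate", {
  gen <- tinyGenome(strrep("ACGT", 500))
  cat <- tinyCatalog(rbind(
    catRow("tss", "P1", 100),
    catRow("donor", "dA", 490), catRow("donor", "dB", 510),
    catRow("acceptor", "aA", 800)), gen)
  ch <- chainOf(c(100, 801), c(499, 900))  # observed donor 500: 490 vs 510
  j <- snapJunctions(ch, cat, tol = 20)
  expect_equal(j$donor, 490L)
})

test_that("TSS assignment uses a one-sided downstream window", {
  fx <- snapFixture()
  expect_equal(assignTss(chainOf(4030, 7500), fx$cat, window = 100),
               list(label = "P1", offset = 30L))
  expect_equal(assignTss(chainOf(4000, 7500), fx$cat, window = 100)$offset,
               0L)
  expect_null(assignTss(chainOf(4500, 7500), fx$cat, window = 100))
  # 5' ends upstream of every TSS never match
  expect_null(assignTss(chainOf(3950, 7500), fx$cat, window = 100))
})

test_that("polyA assignment is two-sided within tol", {
  fx <- snapFixture()
  a <- assignPolya(chainOf(4000, 7495), fx$cat, tol = 30)
  expect_equal(a$label, "pA1")
  expect_equal(a$offset, -5L)
  expect_equal(assignPolya(chainOf(4000, 7500), fx$cat, tol = 0)$offset, 0L)
  expect_null(assignPolya(chainOf(4000, 7600), fx$cat, tol = 30))
})

test_that("minus-strand ends assign against minus-strand features", {
  gen <- tinyGenome(strrep("ACGT", 500))
  cat <- tinyCatalog(rbind(
    catRow("tss", "M1", 1500, strand = "-"),
    catRow("polya", "mpA", 300, strand = "-"),
    catRow("tss", "P1", 10, strand = "+")), gen)
  ch <- chainOf(305, 1470, "-")
  expect_equal(assignTss(ch, cat, 100), list(label = "M1", offset = 30L))
  expect_equal(assignPolya(ch, cat, 30), list(label = "mpA", offset = 5L))
})

test_that("grouping collapses reads by signature and conserves read counts", {
  toy <- toySetup()
  np <- nonpermissiveProfile(toy$models)
  sim <- sampleReads(toy$models, np, 800, noiseModel(), toy$genome, seed = 17)
  sam <- tempfile(fileext = ".sam")
  writeSimulatedReads(sim, sam = sam)
  reads <- parseSplicedAlignments(sam)
  tgs <- groupTranscripts(reads, toy$catalog)
  expect_equal(sum(groups(tgs)$count) + unclassifiedCount(tgs),
               length(reads))
  expect_true(all(diff(groups(tgs)$count) <= 0))  # sorted by count
})

test_that("reads differing only by 5' truncation share a group", {
  fx <- snapFixture()
  sam <- writeTinySam(c(
    samRecord("full", 0, "chr", 4000, "1000M2003N497M"),
    samRecord("trunc", 0, "chr", 4060, "940M2003N497M")),
    contigs = c(chr = 8000L))
  reads <- parseSplicedAlignments(sam)
  tgs <- groupTranscripts(reads, fx$cat)
  expect_equal(nrow(groups(tgs)), 1L)
  expect_equal(groups(tgs)$count, 2L)
  # representative is the least-truncated member
  expect_equal(GenomicRanges::start(groupChains(tgs)[[1]])[1], 4000L)
})

test_that("zero-noise grouping equals the ground-truth aggregation", {
  toy <- toySetup()
  np <- nonpermissiveProfile(toy$models)
  sim <- sampleReads(toy$models, np, 1000, noiselessModel(), toy$genome,
                     seed = 23)
  sam <- tempfile(fileext = ".sam")
  writeSimulatedReads(sim, sam = sam)
  tgs <- groupTranscripts(parseSplicedAlignments(sam), toy$catalog)
  g <- groups(tgs)
  truth_counts <- table(sim$truth$model_id)
  expect_equal(unclassifiedCount(tgs), 0L)
  expect_equal(sort(as.integer(g$count)),
               sort(as.integer(truth_counts)))
  # match each group to its generating model via the representative chain
  chains <- lapply(toy$models, modelChain)
  names(chains) <- vapply(toy$models, `[[`, "", "model_id")
  for (i in seq_len(nrow(g))) {
    rep_ch <- groupChains(tgs)[[i]]
    hit <- names(Filter(function(mc)
      length(mc) == length(rep_ch) &&
        all(GenomicRanges::start(mc) == GenomicRanges::start(rep_ch)) &&
        all(GenomicRanges::end(mc) == GenomicRanges::end(rep_ch)) &&
        all(as.character(GenomicRanges::strand(mc)) ==
              as.character(GenomicRanges::strand(rep_ch))), chains))
    expect_length(hit, 1L)
    expect_equal(g$count[i], unname(as.integer(truth_counts[hit])),
                 label = hit)
  }
})

test_that("raising the junction tolerance never increases the group count", {
  toy <- toySetup()
  np <- nonpermissiveProfile(toy$models)
  sim <- sampleReads(toy$models, np, 500, noiseModel(), toy$genome, seed = 29)
  sam <- tempfile(fileext = ".sam")
  writeSimulatedReads(sim, sam = sam)
  reads <- parseSplicedAlignments(sam)
  n_groups <- vapply(c(0L, 5L, 10L, 25L, 60L), function(tol)
    nrow(groups(groupTranscripts(reads, toy$catalog,
                                 groupingParams(junction_tol = tol)))), 1L)
  expect_true(all(diff(n_groups) <= 0))
})

test_that("unclassifiable reads are counted, not grouped", {
  fx <- snapFixture()
  sam <- writeTinySam(c(
    samRecord("stray", 0, "chr", 6000, "100M"),      # no TSS/polyA/junction
    samRecord("good", 0, "chr", 4000, "3501M")),     # TSS + polyA
    contigs = c(chr = 8000L))
  tgs <- groupTranscripts(parseSplicedAlignments(sam), fx$cat)
  expect_equal(unclassifiedCount(tgs), 1L)
  expect_equal(nrow(groups(tgs)), 1L)
})

test_that("novel 5' ends cluster by single linkage with a min count", {
  c1 <- clusterNovelEnds(c(1000, 1003, 1008), gap = 10, min_count = 3)
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$count, 3L)
  expect_equal(c1$position, 1000L)  # modal, ties -> lowest

  c2 <- clusterNovelEnds(c(1000, 2000), gap = 10, min_count = 1)
  expect_equal(nrow(c2), 2L)

  expect_equal(nrow(clusterNovelEnds(c(1, 2, 3), gap = 10, min_count = 5)),
               0L)
  expect_equal(nrow(clusterNovelEnds(integer(), 10, 1)), 0L)
  # modal position with a genuine mode
  c3 <- clusterNovelEnds(c(50, 52, 52, 60), gap = 10, min_count = 2)
  expect_equal(c3$position, 52L)
})
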