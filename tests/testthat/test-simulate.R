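test_that("toy genome construction is deterministic and validated", {
  a <- buildToyGenome(toyGenomeParams(), seed = 3L)
  b <- buildToyGenome(toyGenomeParams(), seed = 3L)
  expect_identical(as.character(genomeSequence(a$genome)),
                   as.character(genomeSequence(b$genome)))
  expect_identical(vapply(a$models, `[[`, "", "model_id"),
                   vapply(b$models, `[[`, "", "model_id"))
  c <- buildToyGenome(toyGenomeParams(), seed = 4L)
  expect_false(identical(as.character(genomeSequence(a$genome)),
                         as.character(genomeSequence(c$genome))))

  expect_error(buildToyGenome(toyGenomeParams(n_late = 0L)),
               "at least one")
  expect_error(buildToyGenome(toyGenomeParams(genome_length = 5000L)),
               "too small")
})

test_that("toy transgene mRNA starts with the leader motif then its AUG", {
  toy <- toySetup()
  tg <- toy$models[[which(vapply(toy$models, `[[`, "", "model_id") == "TG")]]
  mrna <- as.character(splicedSequence(toy$genome, modelChain(tg)))
  expect_equal(substr(mrna, 1, 20), "GGCTCCGCTCCTTGGCTGCC")
  tr <- translateFirstOrf(mrna)
  expect_equal(tr$start_offset, 151L)  # 150 nt scrubbed 5'UTR
  expect_equal(substr(tr$peptide, 1, 1), "M")
})

test_that("every toy model's first AUG is its annotated start codon", {
  toy <- toySetup()
  sc <- setNames(S4Vectors::mcols(toy$catalog@orfs)$start_codon,
                 S4Vectors::mcols(toy$catalog@orfs)$label)
  for (m in toy$models) {
    ch <- modelChain(m)
    tr <- translateFirstOrf(splicedSequence(toy$genome, ch))
    expect_equal(VectorTxAudit:::mrnaToGenomic(ch, tr$start_offset),
                 unname(sc[m$encodes_orf]), label = m$model_id)
  }
})

test_that("abundance profiles are valid and encode the design fractions", {
  toy <- toySetup()
  np <- nonpermissiveProfile(toy$models)
  expect_equal(sum(np$fractions), 1, tolerance = 1e-12)
  expect_equal(unname(np$fractions["TG"] + np$fractions["TG-aberrant"]), 0.86)
  expect_equal(unname(np$fractions["TG-aberrant"] /
                        (np$fractions["TG"] + np$fractions["TG-aberrant"])),
               0.03, tolerance = 1e-12)
  expect_equal(unname(np$fractions["E1-sentinel"]), 0)

  pp <- permissiveProfile(toy$models)
  expect_equal(sum(pp$fractions), 1, tolerance = 1e-12)
  expect_lt(pp$fractions["TG"], max(pp$fractions))  # late units dominate

  expect_error(abundanceProfile(c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(abundanceProfile(c(a = 1.2, b = -0.2)), "non-negative")
  expect_error(noiseModel(sub_rate = 1.2), "rates")
})

test_that("sampleReads is reproducible, conserves counts, honours n = 0", {
  toy <- toySetup()
  np <- nonpermissiveProfile(toy$models)
  s1 <- sampleReads(toy$models, np, 300, noiseModel(), toy$genome, seed = 11)
  s2 <- sampleReads(toy$models, np, 300, noiseModel(), toy$genome, seed = 11)
  expect_identical(as.character(s1$reads), as.character(s2$reads))
  expect_identical(s1$sam, s2$sam)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$truth), 300L)
  expect_equal(sum(table(s1$truth$model_id)), 300L)

  s0 <- sampleReads(toy$models, np, 0, noiseModel(), toy$genome, seed = 1)
  expect_length(s0$reads, 0L)
  expect_equal(nrow(s0$truth), 0L)
  expect_true(any(grepl("^@SQ", s0$sam)))

  bad <- np; bad$fractions <- bad$fractions[-1]
  expect_error(sampleReads(toy$models, bad, 10, noiseModel(), toy$genome),
               "cover")
})

test_that("zero-noise reads equal their model's mRNA plus a polyA tail", {
  toy <- toySetup()
  np <- nonpermissiveProfile(toy$models)
  sim <- sampleReads(toy$models, np, 50, noiselessModel(), toy$genome,
                     seed = 5)
  mrna <- lapply(toy$models, function(m)
    as.character(splicedSequence(toy$genome, modelChain(m))))
  names(mrna) <- vapply(toy$models, `[[`, "", "model_id")
  expect_true(all(sim$truth$truncated_nt == 0L))
  expect_true(all(sim$truth$n_errors == 0L))
  for (i in seq_along(sim$reads)) {
    r <- as.character(sim$reads[[i]])
    m <- mrna[[sim$truth$model_id[i]]]
    expect_identical(substr(r, 1, nchar(m)), m)
    tail <- substring(r, nchar(m) + 1)
    expect_true(grepl("^A*$", tail))
  }
})

test_that("empirical 5' truncation matches the configured geometric mean", {
  toy <- toySetup()
  np <- nonpermissiveProfile(toy$models)
  sim <- sampleReads(toy$models, np, 10000,
                     noiseModel(truncation_mean = 50, sub_rate = 0,
                                ins_rate = 0, del_rate = 0,
                                polya_len_mean = 0),
                     toy$genome, seed = 21)
  expect_lt(abs(mean(sim$truth$truncated_nt) - 50) / 50, 0.05)
})

test_that("empirical model fractions converge to the profile", {
  toy <- toySetup()
  np <- nonpermissiveProfile(toy$models)
  n <- 10000
  sim <- sampleReads(toy$models, np, n, noiselessModel(), toy$genome,
                     seed = 31)
  emp <- table(factor(sim$truth$model_id, names(np$fractions))) / n
  p <- np$fractions
  bound <- 3 * sqrt(p * (1 - p) / n)
  dev <- abs(as.numeric(emp) - p)
  expect_true(all(dev <= pmax(bound, 1e-12)))
})

test_that("ground-truth SAM matches read sequences and chains", {
  toy <- toySetup()
  np <- nonpermissiveProfile(toy$models)
  sim <- sampleReads(toy$models, np, 40, noiselessModel(), toy$genome,
                     seed = 9)
  body <- sim$sam[!grepl("^@", sim$sam)]
  expect_length(body, 40L)
  f <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(f)) {
    flag <- as.integer(f[[i]][2])
    sam_seq <- f[[i]][10]
    read <- as.character(sim$reads[[f[[i]][1]]])
    if (bitwAnd(flag, 16L) > 0)
      read <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(read)))
    expect_identical(sam_seq, read)
  }
})

test_that("an optional host contig carries E1 reads kept apart from the vector", {
  toy <- buildToyGenome(toyGenomeParams(include_host_e1 = TRUE), seed = 2L)
  expect_false(is.null(toy$host_genome))
  expect_equal(genomeName(toy$host_genome), "hostE1")
  ids <- vapply(toy$models, `[[`, "", "model_id")
  expect_true("hostE1-E1a" %in% ids)
  fr <- setNames(rep(0, length(ids)), ids)
  fr["hostE1-E1a"] <- 0.2; fr["TG"] <- 0.8
  sim <- sampleReads(toy$models, abundanceProfile(fr), 100, noiselessModel(),
                     toy$genome, toy$host_genome, seed = 3)
  sam <- writeTinySamFrom <- tempfile(fileext = ".sam")
  writeSimulatedReads(sim, sam = sam)
  reads <- parseSplicedAlignments(sam)
  contig1 <- vapply(seq_along(reads), function(i)
    as.character(GenomeInfoDb::seqnames(reads[[i]]))[1], "")
  expect_equal(sort(unique(contig1)), c("hostE1", "vector_toy"))
  expect_equal(sum(contig1 == "hostE1"),
               sum(sim$truth$model_id == "hostE1-E1a"))
})
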