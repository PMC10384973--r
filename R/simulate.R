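#' @importFrom stats rgeom rpois runif setNames
NULL

# ---- transcript models ------------------------------------------------------

#' Construct a ground-truth transcript model
#'
#' A transcript model is the simulator's mirror of a transcript group: an
#' exon chain anchored at a catalogued TSS and polyA site, plus the label of
#' the ORF its mature mRNA encodes (the target of the 5'-proximal ORF call).
#'
#' @param model_id unique identifier.
#' @param contig contig name the chain lives on.
#' @param strand `"+"` or `"-"`.
#' @param blocks two-column matrix of 1-based inclusive (start, end) exon
#'   blocks, sorted by genomic position.
#' @param tss_label,polya_label catalog labels of the end features.
#' @param encodes_orf catalog label of the 5'-proximal ORF.
#' @param aberrant `TRUE` for models whose junctions are deliberately absent
#'   from the catalog (unintended splicing).
#' @return a `TranscriptModel` (a named list).
#' @export
transcriptModel <- function(model_id, contig, strand, blocks, tss_label,
                            polya_label, encodes_orf, aberrant = FALSE) {
  stopifnot(is.matrix(blocks), ncol(blocks) == 2L, nrow(blocks) >= 1L,
            strand %in% c("+", "-"))
  if (is.unsorted(blocks[, 1L]) || any(blocks[, 2L] < blocks[, 1L]))
    stop("model '", model_id, "': blocks must be sorted with start <= end")
  structure(list(model_id = model_id, contig = contig, strand = strand,
                 blocks = blocks, tss_label = tss_label,
                 polya_label = polya_label, encodes_orf = encodes_orf,
                 aberrant = isTRUE(aberrant)),
            class = "TranscriptModel")
}

#' @describeIn transcriptModel exon chain of a model as a GRanges.
#' @param model a `TranscriptModel`.
#' @export
modelChain <- function(model) {
  GRanges(model$contig,
          IRanges(model$blocks[, 1L], model$blocks[, 2L]),
          strand = model$strand)
}

# ---- abundance profiles -----------------------------------------------------

#' Expected transcript-model fractions
#'
#' @param fractions named non-negative numeric vector (names are model ids)
#'   summing to 1 within 1e-9; unnormalized weights are rejected.
#' @param profile_name free-text label.
#' @return an `AbundanceProfile` (a named list).
#' @export
abundanceProfile <- function(fractions, profile_name = "custom") {
  stopifnot(is.numeric(fractions), !is.null(names(fractions)))
  if (any(fractions < 0))
    stop("abundance fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("abundance fractions must sum to 1 (got ", sum(fractions), ")")
  structure(list(fractions = fractions, profile_name = profile_name),
            class = "AbundanceProfile")
}

#' Default abundance profiles for the toy vector
#'
#' `nonpermissiveProfile()` emulates an E1-deleted vector in cells that do
#' not complement E1: the transgene promoter carries `transgene_total` of all
#' vector reads (default 0.86), split between the intended unspliced mRNA and
#' the aberrantly spliced species so that the aberrant transcripts are
#' `aberrant_rate` of the promoter's output; the residual mass is spread
#' thinly over the backbone models. `permissiveProfile()` emulates
#' E1-complementing cells where the late units dominate and the transgene
#' drops to a few percent.
#'
#' @param models list of [transcriptModel()]s (from [buildToyGenome()]).
#' @param transgene_total fraction of reads from the transgene promoter.
#' @param aberrant_rate fraction of transgene-promoter reads that carry an
#'   unintended junction.
#' @return an [abundanceProfile()].
#' @export
nonpermissiveProfile <- function(models, transgene_total = 0.86,
                                 aberrant_rate = 0.03) {
  ids <- vapply(models, `[[`, "", "model_id")
  ab <- vapply(models, `[[`, TRUE, "aberrant")
  tss <- vapply(models, `[[`, "", "tss_label")
  tg_tss <- tss[match("TG", ids)]
  fr <- setNames(numeric(length(ids)), ids)
  promoter <- tss == tg_tss
  has_ab <- any(promoter & ab)
  fr[promoter & !ab] <- transgene_total * (if (has_ab) 1 - aberrant_rate else 1)
  if (has_ab)
    fr[promoter & ab] <- transgene_total * aberrant_rate /
      sum(promoter & ab)
  rest <- ids[!promoter & !grepl("^E1", ids) & !grepl("^hostE1", ids)]
  if (length(rest))
    fr[rest] <- (1 - transgene_total) / length(rest)
  else
    fr[promoter & !ab] <- fr[promoter & !ab] + (1 - transgene_total)
  abundanceProfile(fr, "nonpermissive")
}

#' @rdname nonpermissiveProfile
#' @param transgene_total_permissive transgene-promoter fraction in the
#'   permissive profile.
#' @export
permissiveProfile <- function(models, transgene_total_permissive = 0.077,
                              aberrant_rate = 0.03) {
  ids <- vapply(models, `[[`, "", "model_id")
  ab <- vapply(models, `[[`, TRUE, "aberrant")
  tss <- vapply(models, `[[`, "", "tss_label")
  tg_tss <- tss[match("TG", ids)]
  promoter <- tss == tg_tss
  # rank-order weights for the backbone: late units >> early/reverse units
  w <- setNames(numeric(length(ids)), ids)
  late <- grepl("\\(L[0-9]\\)$", ids)
  w[late] <- seq(2.2, 1.4, length.out = sum(late))
  w[ids == "DBP (E2A)"] <- 0.9
  w[ids == "pIX"] <- 0.5
  w[ids == "E4orf-a"] <- 0.55
  w[ids == "E4orf-b"] <- 0.35
  w[grepl("^hostE1", ids)] <- 0
  w[promoter] <- 0
  w <- w / sum(w) * (1 - transgene_total_permissive)
  has_ab <- any(promoter & ab)
  w[promoter & !ab] <- transgene_total_permissive *
    (if (has_ab) 1 - aberrant_rate else 1)
  if (has_ab)
    w[promoter & ab] <- transgene_total_permissive * aberrant_rate /
      sum(promoter & ab)
  abundanceProfile(w, "permissive")
}

# ---- noise model ------------------------------------------------------------

#' Direct-RNA read corruption parameters
#'
#' Emulates the characteristic artefacts of nanopore direct RNA sequencing:
#' reads enter the pore 3'-first, so 3' ends (and the polyA tail) are intact
#' while 5' ends lose a geometric number of nucleotides; base errors are
#' i.i.d. substitutions/insertions/deletions.
#'
#' @param truncation_mean mean 5' loss in nt (geometric; 0 disables).
#' @param sub_rate,ins_rate,del_rate per-base error probabilities in `[0,1)`.
#' @param polya_len_mean mean polyA-tail length (Poisson).
#' @return a `NoiseModel` (a named list).
#' @export
noiseModel <- function(truncation_mean = 25, sub_rate = 0.03,
                       ins_rate = 0.01, del_rate = 0.01,
                       polya_len_mean = 60) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates >= 1))
    stop("error rates must lie in [0, 1)")
  if (truncation_mean < 0 || polya_len_mean < 0)
    stop("truncation_mean and polya_len_mean must be >= 0")
  structure(list(truncation_mean = truncation_mean, sub_rate = sub_rate,
                 ins_rate = ins_rate, del_rate = del_rate,
                 polya_len_mean = polya_len_mean),
            class = "NoiseModel")
}

#' @rdname noiseModel
#' @export
noiselessModel <- function(polya_len_mean = 60)
  noiseModel(truncation_mean = 0, sub_rate = 0, ins_rate = 0, del_rate = 0,
             polya_len_mean = polya_len_mean)

# ---- toy genome -------------------------------------------------------------

#' Parameters for the toy vector genome
#'
#' @param genome_length total contig length in nt (>= the span required by
#'   the requested units; extra tail is random sequence).
#' @param n_late number of alternatively spliced forward late-unit ORFs
#'   sharing the tripartite-leader TSS (1-6).
#' @param n_reverse number of reverse-strand transcription units (0-2: an
#'   E2/DBP-like unit and an E4-like unit with two spliced isoforms).
#' @param include_aberrant include the unintended-splice transgene model.
#' @param include_host_e1 also build a separate host contig carrying an
#'   E1-like gene (an HEK293-style E1-complementing cell analogue).
#' @return a named list of parameters.
#' @export
toyGenomeParams <- function(genome_length = 35000L, n_late = 3L,
                            n_reverse = 2L, include_aberrant = TRUE,
                            include_host_e1 = FALSE) {
  list(genome_length = as.integer(genome_length), n_late = as.integer(n_late),
       n_reverse = as.integer(n_reverse),
       include_aberrant = isTRUE(include_aberrant),
       include_host_e1 = isTRUE(include_host_e1))
}

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(0.27, 0.23, 0.23, 0.27)), collapse = "")
}

# remove every occurrence of `motif` inside [from, to] of the char vector by
# mutating its middle base
.scrubMotif <- function(chars, from, to, motif, replacement_mid) {
  repeat {
    s <- paste(chars[from:to], collapse = "")
    hit <- regexpr(motif, s, fixed = TRUE)
    if (hit < 0L) break
    chars[from + hit] <- replacement_mid  # middle base of the 3-mer
  }
  chars
}

.implant <- function(chars, at, triplet) {
  chars[at:(at + 2L)] <- strsplit(triplet, "")[[1L]]
  chars
}

#' Build a deterministic toy adenovirus-vector genome with ground truth
#'
#' Constructs a random genome with an implanted architecture that mirrors an
#' E1-deleted adenovirus vaccine vector: a transgene expression cassette
#' (its own promoter, a 150-nt leader, an intronless ORF, a polyA site) in
#' the deleted-E1 locus; a pIX-like forward gene; a major-late-like forward
#' unit whose `n_late` isoforms share a spliced tripartite leader and differ
#' in their final exon; reverse-strand E2(DBP)- and E4-like units (the E4
#' unit has an unspliced and a spliced isoform whose intron removes the
#' unspliced isoform's start codon); an E1-like sentinel ORF tagged `E1` for
#' the replication-competent-adenovirus screen (no model emits it by
#' default); and optionally an aberrant transgene model whose junction lies
#' inside the transgene ORF at splice sites deliberately missing from the
#' catalog. 5' leaders are scrubbed of AUG so that the first AUG of every
#' mature mRNA is its model's annotated start codon (asserted before
#' returning).
#'
#' @param params a [toyGenomeParams()] list.
#' @param seed integer seed; the result is bytewise reproducible for a given
#'   seed.
#' @return a list with elements `genome` ([VectorGenome-class]), `catalog`
#'   ([FeatureCatalog-class]), `models` (list of [transcriptModel()]),
#'   and `host_genome` (a second [VectorGenome-class] or `NULL`).
#' @export
buildToyGenome <- function(params = toyGenomeParams(), seed = 1L) {
  if (params$n_late < 1L)
    stop("at least one forward late-unit ORF is required")
  if (params$n_late > 6L)
    stop("at most 6 late-unit ORFs are supported")
  if (!params$n_reverse %in% 0:2)
    stop("n_reverse must be 0, 1 or 2")

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(deriveSeed(seed, 101L))

  contig <- "vector_toy"
  cat_rows <- list()
  addRow <- function(class, label, start, end, strandv, tags = "")
    cat_rows[[length(cat_rows) + 1L]] <<- data.frame(
      class = class, label = label, start = start, end = end,
      strand = strandv, tags = tags, stringsAsFactors = FALSE)
  models <- list()
  scrub_plus <- list()   # forward-strand UTR spans: no ATG allowed
  scrub_minus <- list()  # reverse-strand UTR spans: no CAT (plus strand)
  starts_plus <- integer(); stops_plus <- integer()
  starts_minus <- integer(); stops_minus <- integer()

  # -- transgene cassette (deleted-E1 locus) --
  cas_start <- 201L
  tg_tss <- cas_start + 100L
  tg_atg <- tg_tss + 150L
  tg_orf_end <- tg_atg + 1799L
  tg_pa <- tg_orf_end + 250L
  cas_end <- tg_pa + 100L
  addRow("tss", "CMV", tg_tss, tg_tss, "+", "transgene")
  addRow("polya", "TG-pA", tg_pa, tg_pa, "+")
  addRow("orf", "TG", tg_atg, tg_orf_end, "+", "transgene")
  addRow("cassette", "cassette", cas_start, cas_end, "+")
  scrub_plus <- c(scrub_plus, list(c(tg_tss, tg_atg - 1L)))
  starts_plus <- c(starts_plus, tg_atg); stops_plus <- c(stops_plus, tg_orf_end)
  models$TG <- transcriptModel("TG", contig, "+",
                               cbind(tg_tss, tg_pa), "CMV", "TG-pA", "TG")
  if (params$include_aberrant) {
    ab_donor <- tg_atg + 549L          # first intronic base, inside the ORF
    ab_acceptor <- tg_orf_end - 150L   # last intronic base
    models$`TG-aberrant` <- transcriptModel(
      "TG-aberrant", contig, "+",
      rbind(c(tg_tss, ab_donor - 1L), c(ab_acceptor + 1L, tg_pa)),
      "CMV", "TG-pA", "TG", aberrant = TRUE)
  }

  # -- pIX-like forward gene --
  pix_tss <- cas_end + 100L
  pix_atg <- pix_tss + 120L
  pix_end <- pix_atg + 419L
  pix_pa <- pix_end + 160L
  addRow("tss", "pIX-TSS", pix_tss, pix_tss, "+")
  addRow("polya", "pIX-pA", pix_pa, pix_pa, "+")
  addRow("orf", "pIX", pix_atg, pix_end, "+", "backbone")
  scrub_plus <- c(scrub_plus, list(c(pix_tss, pix_atg - 1L)))
  starts_plus <- c(starts_plus, pix_atg); stops_plus <- c(stops_plus, pix_end)
  models$pIX <- transcriptModel("pIX", contig, "+",
                                cbind(pix_tss, pix_pa), "pIX-TSS", "pIX-pA",
                                "pIX")

  # -- major-late-like unit: tripartite leader + n_late alternative exons --
  mlp <- pix_pa + 2400L
  l1 <- c(mlp, mlp + 199L); d1 <- mlp + 200L; a1 <- mlp + 999L
  l2 <- c(mlp + 1000L, mlp + 1099L); d2 <- mlp + 1100L; a2 <- mlp + 1999L
  l3 <- c(mlp + 2000L, mlp + 2099L); d3 <- mlp + 2100L
  addRow("tss", "MLP", mlp, mlp, "+")
  for (p in c(d1, d2, d3)) addRow("donor", paste0("don", p), p, p, "+")
  for (p in c(a1, a2)) addRow("acceptor", paste0("acc", p), p, p, "+")
  scrub_plus <- c(scrub_plus, list(l1, l2, l3))
  late_labels <- c("52/55K (L1)", "Hexon (L3)", "Fibre (L5)", "100K (L4)",
                   "pV (L2)", "preVII (L2)")[seq_len(params$n_late)]
  late_lens <- c(900L, 2700L, 1500L, 2100L, 1000L, 600L)[seq_len(params$n_late)]
  cur <- d3
  for (i in seq_len(params$n_late)) {
    acc <- cur + 899L
    atg <- acc + 101L
    oend <- atg + late_lens[i] - 1L
    pa <- oend + 200L
    addRow("acceptor", paste0("acc", acc), acc, acc, "+")
    addRow("polya", paste0("L-pA", i), pa, pa, "+")
    addRow("orf", late_labels[i], atg, oend, "+", "backbone,late")
    scrub_plus <- c(scrub_plus, list(c(acc + 1L, atg - 1L)))
    starts_plus <- c(starts_plus, atg); stops_plus <- c(stops_plus, oend)
    models[[late_labels[i]]] <- transcriptModel(
      late_labels[i], contig, "+",
      rbind(c(l1[1], l1[2]), c(l2[1], l2[2]), c(l3[1], l3[2]),
            c(acc + 1L, pa)),
      "MLP", paste0("L-pA", i), late_labels[i])
    cur <- pa + 300L
  }

  # -- reverse-strand E2 (DBP-like) unit --
  if (params$n_reverse >= 1L) {
    e2_pa <- cur + 2000L
    e2_tss <- e2_pa + 3000L
    e2_atg <- e2_tss - 150L
    e2_stop <- e2_atg - 1199L
    addRow("tss", "E2-TSS", e2_tss, e2_tss, "-")
    addRow("polya", "E2-pA", e2_pa, e2_pa, "-")
    addRow("orf", "DBP (E2A)", e2_stop, e2_atg, "-", "backbone")
    scrub_minus <- c(scrub_minus, list(c(e2_atg + 1L, e2_tss)))
    starts_minus <- c(starts_minus, e2_atg)
    stops_minus <- c(stops_minus, e2_stop)
    models$`DBP (E2A)` <- transcriptModel("DBP (E2A)", contig, "-",
                                          cbind(e2_pa, e2_tss),
                                          "E2-TSS", "E2-pA", "DBP (E2A)")
    cur <- e2_tss
  }

  # -- E1-like sentinel ORF for the RCA screen (no default expression) --
  e1_tss <- cur + 1000L
  e1_atg <- e1_tss + 100L
  e1_end <- e1_atg + 599L
  e1_pa <- e1_end + 200L
  addRow("tss", "E1-TSS", e1_tss, e1_tss, "+")
  addRow("polya", "E1-pA", e1_pa, e1_pa, "+")
  addRow("orf", "E1a-like", e1_atg, e1_end, "+", "E1")
  scrub_plus <- c(scrub_plus, list(c(e1_tss, e1_atg - 1L)))
  starts_plus <- c(starts_plus, e1_atg); stops_plus <- c(stops_plus, e1_end)
  models$`E1-sentinel` <- transcriptModel("E1-sentinel", contig, "+",
                                          cbind(e1_tss, e1_pa),
                                          "E1-TSS", "E1-pA", "E1a-like")
  cur <- e1_pa

  # -- reverse-strand E4-like unit: unspliced + spliced isoform --
  if (params$n_reverse >= 2L) {
    e4_pa <- cur + 1200L
    e4_tss <- e4_pa + 2500L
    addRow("tss", "E4-TSS", e4_tss, e4_tss, "-")
    addRow("polya", "E4-pA", e4_pa, e4_pa, "-")
    # unspliced isoform
    a_atg <- e4_tss - 700L
    a_stop <- a_atg - 899L
    addRow("orf", "E4orf-a", a_stop, a_atg, "-", "backbone")
    scrub_minus <- c(scrub_minus, list(c(a_atg + 1L, e4_tss)))
    starts_minus <- c(starts_minus, a_atg); stops_minus <- c(stops_minus, a_stop)
    models$`E4orf-a` <- transcriptModel("E4orf-a", contig, "-",
                                        cbind(e4_pa, e4_tss),
                                        "E4-TSS", "E4-pA", "E4orf-a")
    # spliced isoform: the intron removes E4orf-a's start codon
    e4_don <- e4_tss - 500L   # first intronic base in transcription direction
    e4_acc <- e4_tss - 1499L  # last intronic base
    b_atg <- e4_tss - 1700L
    b_stop <- b_atg - 599L
    addRow("donor", paste0("don", e4_don), e4_don, e4_don, "-")
    addRow("acceptor", paste0("acc", e4_acc), e4_acc, e4_acc, "-")
    addRow("orf", "E4orf-b", b_stop, b_atg, "-", "backbone")
    scrub_minus <- c(scrub_minus, list(c(b_atg + 1L, e4_acc - 1L)))
    starts_minus <- c(starts_minus, b_atg); stops_minus <- c(stops_minus, b_stop)
    models$`E4orf-b` <- transcriptModel(
      "E4orf-b", contig, "-",
      rbind(c(e4_pa, e4_acc - 1L), c(e4_don + 1L, e4_tss)),
      "E4-TSS", "E4-pA", "E4orf-b")
    cur <- e4_tss
  }

  need <- cur + 300L
  if (params$genome_length < need)
    stop("genome_length ", params$genome_length, " too small for the ",
         "requested units (need >= ", need, ")")

  # -- assemble the sequence: implant codons first, then scrub the 5'UTRs.
  # Scrubbing mutates only the middle base of an AUG/CAU occurrence and the
  # UTR spans exclude the start codons themselves, so implants survive it;
  # doing it in this order removes spurious AUGs that implanted codons of
  # one unit would otherwise create inside another unit's leader.
  chars <- strsplit(.randomDna(params$genome_length), "")[[1L]]
  # recognizable GC-rich leader motif at the transgene 5'UTR start
  chars[tg_tss:(tg_tss + 19L)] <- strsplit("GGCTCCGCTCCTTGGCTGCC", "")[[1L]]
  for (k in seq_along(starts_plus)) {
    chars <- .implant(chars, starts_plus[k], "ATG")
    chars <- .implant(chars, stops_plus[k] - 2L, "TAA")
  }
  for (k in seq_along(starts_minus)) {
    chars <- .implant(chars, starts_minus[k] - 2L, "CAT")  # minus-strand ATG
    chars <- .implant(chars, stops_minus[k], "TTA")        # minus-strand TAA
  }
  for (sp in scrub_plus)
    chars <- .scrubMotif(chars, sp[1L], sp[2L], "ATG", "C")
  for (sp in scrub_minus)
    chars <- .scrubMotif(chars, sp[1L], sp[2L], "CAT", "G")

  # splice junctions can still assemble an AUG from bases of two exons;
  # repair any such upstream AUG by mutating its middle base, rechecking
  # every model until the layout is clean (bounded, deterministic)
  sc_tab <- do.call(rbind, cat_rows)
  sc_orf <- sc_tab[sc_tab$class == "orf", , drop = FALSE]
  sc <- setNames(ifelse(sc_orf$strand == "-", sc_orf$end, sc_orf$start),
                 sc_orf$label)
  vec_models <- Filter(function(m) m$contig == contig, models)
  for (iter in seq_len(50L)) {
    genome <- new("VectorGenome", name = contig,
                  sequence = DNAString(paste(chars, collapse = "")))
    bad <- NULL
    for (m in vec_models) {
      chain <- modelChain(m)
      tr <- translateFirstOrf(splicedSequence(genome, chain))
      if (is.na(tr$start_offset) ||
          mrnaToGenomic(chain, tr$start_offset) != sc[[m$encodes_orf]]) {
        bad <- list(chain = chain, k = tr$start_offset, strand = m$strand,
                    id = m$model_id)
        break
      }
    }
    if (is.null(bad)) break
    if (is.na(bad$k))
      stop("internal error: model '", bad$id, "' lost its start codon")
    g_mid <- mrnaToGenomic(bad$chain, bad$k + 1L)  # middle base of the AUG
    chars[g_mid] <- if (bad$strand == "+") "C" else "G"
    if (iter == 50L)
      stop("internal error: could not scrub spurious AUGs from the layout")
  }

  cat_tab <- do.call(rbind, cat_rows)
  cat_path <- tempfile(fileext = ".tsv")
  utils::write.table(cat_tab, cat_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  catalog <- loadFeatureCatalog(cat_path, genome)
  unlink(cat_path)

  # -- optional host contig carrying a functional E1-like gene --
  host_genome <- NULL
  if (params$include_host_e1) {
    hchars <- strsplit(.randomDna(3000L), "")[[1L]]
    hchars <- .scrubMotif(hchars, 101L, 250L, "ATG", "C")
    hchars <- .implant(hchars, 251L, "ATG")
    hchars <- .implant(hchars, 1148L, "TAA")
    host_genome <- new("VectorGenome", name = "hostE1",
                       sequence = DNAString(paste(hchars, collapse = "")))
    models$`hostE1-E1a` <- transcriptModel("hostE1-E1a", "hostE1", "+",
                                           cbind(101L, 1400L),
                                           "hostE1-TSS", "hostE1-pA",
                                           "hostE1-E1a")
  }

  # -- sanity: the first AUG of every vector model is its annotated start --
  sc <- setNames(mcols(catalog@orfs)$start_codon, mcols(catalog@orfs)$label)
  for (m in models) {
    if (m$contig != contig) next
    chain <- modelChain(m)
    tr <- translateFirstOrf(splicedSequence(genome, chain))
    got <- mrnaToGenomic(chain, tr$start_offset)
    if (is.na(tr$start_offset) || got != sc[[m$encodes_orf]])
      stop("internal error: model '", m$model_id,
           "' first AUG at ", got, " != annotated start of '",
           m$encodes_orf, "' (", sc[[m$encodes_orf]], ")")
  }

  list(genome = genome, catalog = catalog, models = unname(models),
       host_genome = host_genome)
}

# ---- read sampling ----------------------------------------------------------

# drop `t` nucleotides from the transcription 5' end of a chain
.truncateChain <- function(blocks, strand, t) {
  if (t <= 0L) return(blocks)
  w <- blocks[, 2L] - blocks[, 1L] + 1L
  if (strand == "+") {
    i <- 1L
    while (t >= w[i]) { t <- t - w[i]; blocks <- blocks[-1L, , drop = FALSE]
      w <- w[-1L]; }
    blocks[1L, 1L] <- blocks[1L, 1L] + t
  } else {
    n <- nrow(blocks)
    while (t >= w[n]) { t <- t - w[n]
      blocks <- blocks[-n, , drop = FALSE]; w <- w[-n]; n <- n - 1L }
    blocks[n, 2L] <- blocks[n, 2L] - t
  }
  blocks
}

.corruptSeq <- function(s, sub_rate, ins_rate, del_rate) {
  if (sub_rate == 0 && ins_rate == 0 && del_rate == 0)
    return(list(seq = s, n_errors = 0L))
  x <- strsplit(s, "")[[1L]]
  n <- length(x)
  bases <- c("A", "C", "G", "T")
  subs <- which(runif(n) < sub_rate)
  if (length(subs)) {
    repl <- sample(bases, length(subs), replace = TRUE)
    same <- repl == x[subs]
    while (any(same)) {
      repl[same] <- sample(bases, sum(same), replace = TRUE)
      same <- repl == x[subs]
    }
    x[subs] <- repl
  }
  dels <- runif(n) < del_rate
  ins <- which(runif(n) < ins_rate)
  out <- x
  out[dels] <- ""
  if (length(ins))
    out[ins] <- paste0(out[ins], sample(bases, length(ins), replace = TRUE))
  list(seq = paste(out, collapse = ""),
       n_errors = length(subs) + sum(dels) + length(ins))
}

#' Sample noisy direct-RNA reads from transcript models
#'
#' Draws a model per read from the abundance profile, applies geometric 5'
#' truncation, appends a polyA tail, and corrupts bases per the noise model.
#' Alongside the reads it emits ground-truth SAM records that encode the true
#' (truncated) exon chain with `N` CIGAR operations and the pre-error
#' sequence — the noise-free coordinate path used for offline testing; noisy
#' sequences are intended for an external spliced aligner.
#'
#' @param models list of [transcriptModel()].
#' @param profile an [abundanceProfile()] covering exactly the model ids.
#' @param n number of reads (>= 0).
#' @param noise a [noiseModel()].
#' @param genome the vector [VectorGenome-class]; `host_genome` a second
#'   contig (or `NULL`).
#' @param seed integer seed; output is bytewise reproducible.
#' @return a list with `reads` (named [Biostrings::DNAStringSet], read
#'   orientation = mRNA sense), `quals` (constant per-base quality strings),
#'   `sam` (character vector: header + one line per read), and `truth`
#'   (data.frame `read_id`, `model_id`, `truncated_nt`, `n_errors`).
#' @seealso [writeSimulatedReads()]
#' @export
sampleReads <- function(models, profile, n, noise = noiseModel(),
                        genome, host_genome = NULL, seed = 1L) {
  stopifnot(inherits(profile, "AbundanceProfile"),
            inherits(noise, "NoiseModel"), n >= 0L)
  ids <- vapply(models, `[[`, "", "model_id")
  if (!setequal(ids, names(profile$fractions)))
    stop("profile must cover exactly the model ids; missing: ",
         paste(setdiff(ids, names(profile$fractions)), collapse = ", "),
         "; extra: ",
         paste(setdiff(names(profile$fractions), ids), collapse = ", "))
  names(models) <- ids
  seqs <- list(genomeSequence(genome))
  names(seqs) <- genomeName(genome)
  lens <- setNames(genomeLength(genome), genomeName(genome))
  if (!is.null(host_genome)) {
    seqs[[genomeName(host_genome)]] <- genomeSequence(host_genome)
    lens[genomeName(host_genome)] <- genomeLength(host_genome)
  }

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(deriveSeed(seed, 202L))

  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens),
              "@PG\tID:VectorTxAudit\tPN:VectorTxAudit")
  if (n == 0L)
    return(list(reads = DNAStringSet(), quals = character(),
                sam = header,
                truth = data.frame(read_id = character(),
                                   model_id = character(),
                                   truncated_nt = integer(),
                                   n_errors = integer())))

  # mature mRNA per model, computed once
  mrna <- lapply(models, function(m) {
    gen <- if (m$contig == genomeName(genome)) genome else host_genome
    if (is.null(gen)) stop("model '", m$model_id, "' on unknown contig '",
                           m$contig, "'")
    as.character(splicedSequence(gen, modelChain(m)))
  })

  draw <- sample(ids, n, replace = TRUE,
                 prob = profile$fractions[ids])
  trunc_p <- if (noise$truncation_mean > 0)
    1 / (1 + noise$truncation_mean) else 1
  truncs <- if (noise$truncation_mean > 0) rgeom(n, trunc_p) else integer(n)
  tails <- if (noise$polya_len_mean > 0)
    rpois(n, noise$polya_len_mean) else integer(n)

  read_ids <- sprintf("r%06d", seq_len(n))
  out_seq <- character(n)
  sam_lines <- character(n)
  nerr <- integer(n)
  for (i in seq_len(n)) {
    m <- models[[draw[i]]]
    full <- mrna[[draw[i]]]
    t_i <- min(truncs[i], nchar(full) - 30L)  # keep >= 30 nt of transcript
    t_i <- max(t_i, 0L)
    truncs[i] <- t_i
    body <- substring(full, t_i + 1L)
    tail <- strrep("A", tails[i])
    clean <- paste0(body, tail)
    cor <- .corruptSeq(clean, noise$sub_rate, noise$ins_rate, noise$del_rate)
    out_seq[i] <- cor$seq
    nerr[i] <- cor$n_errors

    blocks <- .truncateChain(m$blocks, m$strand, t_i)
    w <- blocks[, 2L] - blocks[, 1L] + 1L
    gaps <- if (nrow(blocks) > 1L)
      blocks[-1L, 1L] - blocks[-nrow(blocks), 2L] - 1L else integer()
    cig_core <- paste0(w[1L], "M")
    if (length(gaps))
      cig_core <- paste0(cig_core,
                         paste0(gaps, "N", w[-1L], "M", collapse = ""))
    if (m$strand == "+") {
      flag <- 0L
      cigar <- if (tails[i] > 0L)
        paste0(cig_core, tails[i], "S") else cig_core
      sam_seq <- clean
    } else {
      flag <- 16L
      cigar <- if (tails[i] > 0L)
        paste0(tails[i], "S", cig_core) else cig_core
      sam_seq <- as.character(reverseComplement(DNAString(clean)))
    }
    sam_lines[i] <- paste(read_ids[i], flag, m$contig, blocks[1L, 1L], 60L,
                          cigar, "*", 0L, 0L, sam_seq,
                          strrep("I", nchar(sam_seq)), sep = "\t")
  }

  reads <- DNAStringSet(out_seq)
  names(reads) <- read_ids
  list(reads = reads,
       quals = strrep("'", nchar(out_seq)),  # constant Q6, typical of dRNA
       sam = c(header, sam_lines),
       truth = data.frame(read_id = read_ids, model_id = draw,
                          truncated_nt = truncs, n_errors = nerr,
                          stringsAsFactors = FALSE))
}

#' Write simulator output to FASTQ / SAM / TSV
#'
#' @param sim result of [sampleReads()].
#' @param fastq,sam,truth_tsv output paths (`NULL` skips a file).
#' @return invisibly, the paths written.
#' @export
writeSimulatedReads <- function(sim, fastq = NULL, sam = NULL,
                                truth_tsv = NULL) {
  written <- character()
  if (!is.null(fastq)) {
    con <- file(fastq, "w")
    ids <- names(sim$reads)
    if (length(ids))
      writeLines(paste0("@", ids, "\n", as.character(sim$reads), "\n+\n",
                        sim$quals), con)
    close(con)
    written <- c(written, fastq)
  }
  if (!is.null(sam)) {
    writeLines(sim$sam, sam)
    written <- c(written, sam)
  }
  if (!is.null(truth_tsv)) {
    utils::write.table(sim$truth, truth_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, truth_tsv)
  }
  invisible(written)
}
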