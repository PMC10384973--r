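#' @importFrom Rsamtools asBam BamFile ScanBamParam scanBamFlag
#' @importFrom GenomicAlignments readGAlignments cigarRangesAlongReferenceSpace
#'   cigar qwidth
#' @importFrom IRanges reduce togroup PartitioningByEnd
NULL

#' Decode spliced alignments into exon chains
#'
#' Reads a SAM or BAM file and turns every mapped record into an exon chain.
#' `N` CIGAR operations always open a new block; deletions (`D`) up to
#' `max_del` nt are absorbed into the surrounding block (aligner dialects
#' differ on small-gap encoding) while longer deletions are treated like
#' junctions; soft/hard clips and insertions consume read bases only. Strand
#' is taken from the reverse flag: direct RNA sequencing is strand-faithful,
#' so no re-orientation heuristic is applied.
#'
#' @param path SAM (`.sam`) or BAM file. SAM input is converted on the fly
#'   with [Rsamtools::asBam()].
#' @param max_del largest deletion absorbed into a block (default 30 nt).
#' @return a [GenomicRanges::GRangesList] (one element per alignment, blocks
#'   sorted by genomic position) with `mcols` `read_id`, `read_length`
#'   (aligned read length incl. soft clips) and `is_primary`; unmapped
#'   records are excluded and counted in `metadata()$skipped_unmapped`.
#' @seealso [filterAlignments()], [groupTranscripts()]
#' @export
parseSplicedAlignments <- function(path, max_del = 30L) {
  if (!file.exists(path))
    stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- tryCatch(
      asBam(path, dest, overwrite = TRUE, indexDestination = FALSE),
      error = function(e) stop("malformed SAM '", path, "': ",
                               conditionMessage(e)))
  }
  param <- ScanBamParam(what = c("qname", "flag"),
                        flag = scanBamFlag(isUnmappedQuery = FALSE))
  ga <- readGAlignments(BamFile(bam), param = param)
  n_total <- Rsamtools::countBam(BamFile(bam))$records
  skipped <- n_total - length(ga)

  if (length(ga) == 0L) {
    out <- GRangesList()
    metadata(out)$skipped_unmapped <- skipped
    return(out)
  }

  rl <- cigarRangesAlongReferenceSpace(cigar(ga), pos = start(ga),
                                       ops = c("M", "=", "X", "D", "N"),
                                       with.ops = TRUE)
  ul <- unlist(rl, use.names = FALSE)
  op <- unlist(lapply(rl, names), use.names = FALSE)
  grp <- togroup(PartitioningByEnd(rl))
  keep <- op %in% c("M", "=", "X") | (op == "D" & width(ul) <= max_del)
  # reduce() merges touching ranges, so absorbed deletions fuse their
  # neighbours while excluded N / long-D ranges leave real gaps
  blocks <- reduce(S4Vectors::split(ul[keep],
                                    factor(grp[keep], seq_along(rl))))
  flag <- mcols(ga)$flag
  st <- ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")
  gr <- GRanges(rep(as.character(GenomeInfoDb::seqnames(ga)),
                    lengths(blocks)),
                unlist(blocks, use.names = FALSE),
                strand = rep(st, lengths(blocks)))
  chains <- S4Vectors::split(gr, rep(seq_along(ga), lengths(blocks)))
  names(chains) <- NULL
  mcols(chains)$read_id <- mcols(ga)$qname
  mcols(chains)$read_length <- qwidth(ga)
  mcols(chains)$is_primary <- bitwAnd(flag, 0x900L) == 0L
  metadata(chains)$skipped_unmapped <- skipped
  chains
}

#' Filter exon chains
#'
#' @param reads a [GenomicRanges::GRangesList] from
#'   [parseSplicedAlignments()].
#' @param min_read_length drop reads shorter than this many nt (0 keeps all).
#' @param primary_only drop secondary and supplementary alignments
#'   (default `TRUE`; supplementary alignments are dropped rather than
#'   stitched).
#' @param verbose log removal counts.
#' @return the filtered `GRangesList`, order preserved;
#'   `metadata()$removed_*` record the counts.
#' @export
filterAlignments <- function(reads, min_read_length = 0L,
                             primary_only = TRUE, verbose = FALSE) {
  keep <- rep(TRUE, length(reads))
  removed_secondary <- 0L
  if (primary_only) {
    keep <- mcols(reads)$is_primary
    removed_secondary <- sum(!keep)
  }
  rl <- mcols(reads)$read_length
  removed_short <- sum(keep & rl < min_read_length)
  keep <- keep & rl >= min_read_length
  out <- reads[keep]
  metadata(out)$removed_secondary <- removed_secondary
  metadata(out)$removed_short <- removed_short
  vlog("filter", removed_secondary, " non-primary and ", removed_short,
       " short alignments removed; ", length(out), " kept",
       verbose = verbose)
  if (length(out) == 0L)
    warning("no alignments left after filtering")
  out
}

#' Read-accounting summary row
#'
#' Per-sample accounting in the layout of the published read-count table:
#' totals and lengths over all reads of the run, externally supplied
#' host-transcriptome mapped count, vector-mapped count, optional count of
#' reads mapped to the host's integrated E1 region, and the vector-mapped
#' reads as a percentage of host-mapped reads (1 decimal, half-up; `NA` when
#' no host count is available).
#'
#' @param read_lengths lengths (nt) of all reads in the run.
#' @param mapped_host number of reads mapped to the host transcriptome
#'   (accepted as an external count, not recomputed).
#' @param vaccine_reads vector-mapped reads: a `GRangesList` from
#'   [parseSplicedAlignments()] or an integer count.
#' @param e1_reads optional count of reads mapped to the host E1 region.
#' @param sample sample name.
#' @return a one-row `data.frame` with columns `sample`, `total_reads`,
#'   `longest_read`, `average_read_length`, `mapped_host`, `mapped_vaccine`,
#'   `mapped_e1`, `vaccine_pct_of_host`.
#' @export
readAccounting <- function(read_lengths, mapped_host, vaccine_reads,
                           e1_reads = NA_integer_, sample = "sample") {
  stopifnot(is.na(mapped_host) || mapped_host >= 0)
  mv <- if (is.numeric(vaccine_reads)) as.integer(vaccine_reads)
        else length(vaccine_reads)
  data.frame(
    sample = sample,
    total_reads = length(read_lengths),
    longest_read = if (length(read_lengths)) max(read_lengths) else 0L,
    average_read_length = if (length(read_lengths))
      as.integer(roundHalfUp(mean(read_lengths))) else NA_integer_,
    mapped_host = as.integer(mapped_host),
    mapped_vaccine = mv,
    mapped_e1 = as.integer(e1_reads),
    vaccine_pct_of_host = if (!is.na(mapped_host) && mapped_host > 0)
      percentOf(mv, mapped_host, 1L) else NA_real_,
    stringsAsFactors = FALSE)
}
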