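#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList
#' @importFrom BiocGenerics start end width strand start<- end<-
#' @importFrom GenomeInfoDb seqnames
#' @importClassesFrom Biostrings DNAString
#' @importClassesFrom GenomicRanges GRanges GRangesList
#' @importClassesFrom S4Vectors DataFrame
NULL

#' Annotated vector genome sequence
#'
#' A single-contig viral vector genome: the DNA sequence plus its name.
#' Coordinates throughout the package are 1-based inclusive (the
#' GRanges/IRanges convention).
#'
#' @slot name contig name (FASTA header word).
#' @slot sequence a [Biostrings::DNAString] restricted to A/C/G/T/N.
#'
#' @seealso [loadGenome()], [FeatureCatalog-class]
#' @export
setClass("VectorGenome",
  representation(name = "character", sequence = "DNAString"))

setValidity("VectorGenome", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@sequence) < 1L)
    msg <- c(msg, "genome sequence is empty")
  bad <- setdiff(unique(strsplit(as.character(object@sequence), "")[[1]]),
                 c("A", "C", "G", "T", "N"))
  if (length(bad))
    msg <- c(msg, paste0("non-nucleotide characters in sequence: ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Feature catalog of a vector genome
#'
#' Catalogued features the classifier assigns reads to: ORFs (genomic start
#' codon + stop), transcription start sites (TSS), polyadenylation sites,
#' splice donors/acceptors, and the transgene expression cassette bounds.
#' All positions are 1-based genomic coordinates on the contig of the
#' accompanying [VectorGenome-class].
#'
#' Donor positions are the first intronic base of an intron and acceptor
#' positions the last intronic base, both in transcription direction
#' (so on the minus strand a donor has a larger coordinate than its acceptor).
#'
#' @slot orfs GRanges; `mcols`: `label`, `tags` (comma-separated, e.g.
#'   "transgene" or "E1"). The range runs from the A of the start codon to the
#'   last base of the stop codon in genomic coordinates; `start_codon` mcol
#'   holds the genomic coordinate of the A of ATG on the coding strand.
#' @slot tss GRanges of width 1; `mcols`: `label`.
#' @slot polya GRanges of width 1; `mcols`: `label`.
#' @slot donors,acceptors GRanges of width 1 (strand set).
#' @slot cassette GRanges of length 1 spanning the transgene cassette.
#' @slot transgeneTss label of the TSS driving the transgene.
#'
#' @seealso [loadFeatureCatalog()]
#' @export
setClass("FeatureCatalog",
  representation(orfs = "GRanges", tss = "GRanges", polya = "GRanges",
                 donors = "GRanges", acceptors = "GRanges",
                 cassette = "GRanges", transgeneTss = "character"))

setValidity("FeatureCatalog", function(object) {
  msg <- character()
  for (nm in c("tss", "polya")) {
    gr <- slot(object, nm)
    lab <- mcols(gr)$label
    if (length(gr) && is.null(lab))
      msg <- c(msg, paste0("'", nm, "' needs a 'label' metadata column"))
    else if (anyDuplicated(lab))
      msg <- c(msg, paste0("duplicate ", nm, " labels: ",
                           paste(unique(lab[duplicated(lab)]), collapse = ", ")))
  }
  if (length(object@orfs)) {
    lab <- mcols(object@orfs)$label
    if (is.null(lab) || is.null(mcols(object@orfs)$start_codon))
      msg <- c(msg, "'orfs' needs 'label' and 'start_codon' metadata columns")
    else if (anyDuplicated(lab))
      msg <- c(msg, paste0("duplicate ORF labels: ",
                           paste(unique(lab[duplicated(lab)]), collapse = ", ")))
  }
  if (length(object@cassette) != 1L)
    msg <- c(msg, "'cassette' must contain exactly one range")
  if (length(object@transgeneTss) != 1L)
    msg <- c(msg, "'transgeneTss' must be a single label")
  else if (length(object@tss) &&
           !object@transgeneTss %in% mcols(object@tss)$label)
    msg <- c(msg, paste0("transgene TSS label '", object@transgeneTss,
                         "' not present among TSS labels"))
  if (length(msg)) msg else TRUE
})

#' Transcript groups from classified reads
#'
#' The result of [groupTranscripts()]: reads collapsed by their canonical
#' signature (strand, assigned TSS, snapped junction chain, assigned polyA
#' site), with one representative exon chain per group (the member whose 5'
#' end reaches furthest upstream, i.e. the least-truncated read).
#'
#' @slot groups a [S4Vectors::DataFrame] with columns `group_id`, `strand`,
#'   `tss`, `tss_offset`, `junctions` (encoded "donor-acceptor,..." 1-based),
#'   `polya`, `polya_offset`, `count`, `novel_junction` (any junction end off
#'   catalog), sorted by decreasing `count`.
#' @slot chains GRangesList of representative exon chains, parallel to
#'   `groups`.
#' @slot unclassified number of input reads with no TSS, no polyA and no
#'   junction.
#'
#' @seealso [groupTranscripts()], [assignOrf()], [exportBed12()]
#' @export
setClass("TranscriptGroupSet",
  representation(groups = "DataFrame", chains = "GRangesList",
                 unclassified = "integer"))

setValidity("TranscriptGroupSet", function(object) {
  msg <- character()
  need <- c("group_id", "strand", "tss", "junctions", "polya", "count",
            "novel_junction")
  miss <- setdiff(need, colnames(object@groups))
  if (length(miss))
    msg <- c(msg, paste0("missing group columns: ", paste(miss, collapse = ", ")))
  if (nrow(object@groups) != length(object@chains))
    msg <- c(msg, "'chains' must be parallel to 'groups'")
  if (nrow(object@groups) && any(object@groups$count < 1L))
    msg <- c(msg, "group counts must be >= 1")
  if (length(object@unclassified) != 1L || object@unclassified < 0L)
    msg <- c(msg, "'unclassified' must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})
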