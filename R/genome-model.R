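#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   reverseComplement translate GENETIC_CODE subseq writeXStringSet
#'   xscat matchPattern
NULL

#' Load a vector genome from FASTA
#'
#' Reads the first record of a FASTA file, uppercases it, and validates the
#' alphabet (A/C/G/T/N).
#'
#' @param path path to a FASTA file.
#' @return a [VectorGenome-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">toy", "acgtACGT"), fa)
#' gen <- loadGenome(fa)
#' genomeLength(gen)  # 8
#' @export
loadGenome <- function(path) {
  if (!file.exists(path))
    stop("genome FASTA not found: ", path)
  set <- tryCatch(readDNAStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L)
    stop("empty FASTA: ", path)
  seqn <- Biostrings::DNAString(toupper(as.character(set[[1L]])))
  name <- strsplit(names(set)[1L], "\\s+")[[1L]][1L]
  new("VectorGenome", name = name, sequence = seqn)
}

#' @describeIn loadGenome genome length in nucleotides.
#' @param x a `VectorGenome`.
#' @export
genomeLength <- function(x) length(x@sequence)

#' @describeIn loadGenome genome sequence as a [Biostrings::DNAString].
#' @export
genomeSequence <- function(x) x@sequence

#' @describeIn loadGenome contig name.
#' @export
genomeName <- function(x) x@name

setMethod("show", "VectorGenome", function(object) {
  cat("VectorGenome '", object@name, "': ", length(object@sequence),
      " nt\n", sep = "")
})

#' Write a genome to FASTA
#'
#' @param genome a [VectorGenome-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(genome, path) {
  set <- DNAStringSet(genome@sequence)
  names(set) <- genome@name
  writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

.catalogClasses <- c("orf", "tss", "polya", "donor", "acceptor", "cassette")

#' Load a feature catalog (TSV or GFF3)
#'
#' The native catalog format is a 6-column tab-separated file with header
#' `class  label  start  end  strand  tags` and `#` comment lines. `class` is
#' one of `orf`, `tss`, `polya`, `donor`, `acceptor`, `cassette`. Coordinates
#' are 1-based inclusive; point features (tss/polya/donor/acceptor) use
#' `start` with `end` equal or empty. For ORFs, `start`/`end` span from the A
#' of the start codon to the last base of the stop codon in genomic
#' coordinates (so on the minus strand the start codon is at `end`). `tags`
#' is a comma-separated set; the ORF tagged `transgene` and the cassette row
#' define the transgene cassette; the row `tss` whose tags contain
#' `transgene` is taken as the transgene promoter. ORFs tagged `E1` feed the
#' replication-competent-adenovirus screen.
#'
#' Files ending in `.gff3`/`.gff` are read with `rtracklayer` and mapped onto
#' the same classes via their `type` (`CDS` -> orf, `TSS`, `polyA_site`,
#' `five_prime_cis_splice_site` -> donor, `three_prime_cis_splice_site` ->
#' acceptor, `region` with tag `cassette`).
#'
#' @param path catalog TSV or GFF3 file.
#' @param genome the [VectorGenome-class] the coordinates refer to; used for
#'   bounds checking and contig naming.
#' @return a [FeatureCatalog-class].
#' @export
loadFeatureCatalog <- function(path, genome) {
  if (!file.exists(path))
    stop("feature catalog not found: ", path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE))
    tab <- .gffToCatalogTable(path)
  else
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE,
                             colClasses = c("character", "character",
                                            "integer", "integer",
                                            "character", "character"))
  need <- c("class", "label", "start", "end", "strand", "tags")
  if (!all(need %in% colnames(tab)))
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  tab$class <- tolower(tab$class)
  tab$end <- ifelse(is.na(tab$end), tab$start, tab$end)
  bad <- !tab$class %in% .catalogClasses
  if (any(bad))
    stop("unknown feature class in rows ", paste(which(bad), collapse = ", "),
         ": ", paste(unique(tab$class[bad]), collapse = ", "))
  glen <- genomeLength(genome)
  oob <- tab$start < 1L | tab$end > glen | tab$start > tab$end
  if (any(oob))
    stop("catalog coordinates out of range [1, ", glen, "] in rows: ",
         paste(which(oob), collapse = ", "))
  for (cls in c("orf", "tss", "polya")) {
    lab <- tab$label[tab$class == cls]
    if (anyDuplicated(lab))
      stop("duplicate ", cls, " label(s): ",
           paste(unique(lab[duplicated(lab)]), collapse = ", "))
  }
  if (sum(tab$class == "cassette") != 1L)
    stop("catalog must declare exactly one 'cassette' row")

  contig <- genomeName(genome)
  mk <- function(rows, point = FALSE) {
    if (!nrow(rows))
      return(GRanges(seqnames = character(), ranges = IRanges(),
                     strand = character()))
    GRanges(contig,
            IRanges(rows$start, if (point) rows$start else rows$end),
            strand = ifelse(rows$strand %in% c("+", "-"), rows$strand, "*"))
  }
  orf_rows <- tab[tab$class == "orf", , drop = FALSE]
  orfs <- mk(orf_rows)
  if (length(orfs)) {
    mcols(orfs)$label <- orf_rows$label
    mcols(orfs)$tags <- orf_rows$tags
    mcols(orfs)$start_codon <- ifelse(orf_rows$strand == "-",
                                      orf_rows$end, orf_rows$start)
  }
  tss <- mk(tab[tab$class == "tss", , drop = FALSE], point = TRUE)
  if (length(tss)) {
    mcols(tss)$label <- tab$label[tab$class == "tss"]
    mcols(tss)$tags <- tab$tags[tab$class == "tss"]
  }
  polya <- mk(tab[tab$class == "polya", , drop = FALSE], point = TRUE)
  if (length(polya)) mcols(polya)$label <- tab$label[tab$class == "polya"]
  donors <- mk(tab[tab$class == "donor", , drop = FALSE], point = TRUE)
  acceptors <- mk(tab[tab$class == "acceptor", , drop = FALSE], point = TRUE)
  cassette <- mk(tab[tab$class == "cassette", , drop = FALSE])

  tg <- tab$label[tab$class == "tss" &
                    grepl("(^|,)\\s*transgene\\s*(,|$)", tab$tags)]
  if (length(tg) != 1L)
    stop("exactly one TSS row must carry tag 'transgene' (found ",
         length(tg), ")")
  new("FeatureCatalog", orfs = orfs, tss = tss, polya = polya,
      donors = donors, acceptors = acceptors, cassette = cassette,
      transgeneTss = tg)
}

.gffToCatalogTable <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 catalogs requires the 'rtracklayer' package")
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  map <- c(CDS = "orf", TSS = "tss", polyA_site = "polya",
           five_prime_cis_splice_site = "donor",
           three_prime_cis_splice_site = "acceptor", region = "cassette")
  keep <- type %in% names(map)
  gr <- gr[keep]; type <- type[keep]
  lab <- if (!is.null(gr$Name)) as.character(gr$Name) else
    if (!is.null(gr$ID)) as.character(gr$ID) else rep("", length(gr))
  tags <- if (!is.null(gr$tags)) as.character(gr$tags) else rep("", length(gr))
  tags[is.na(tags)] <- ""
  data.frame(class = unname(map[type]), label = lab,
             start = start(gr), end = end(gr),
             strand = as.character(strand(gr)), tags = tags,
             stringsAsFactors = FALSE)
}

#' Write a feature catalog to the native TSV format
#'
#' @param catalog a [FeatureCatalog-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureCatalog <- function(catalog, path) {
  row <- function(class, label, start, end, strandv, tags)
    data.frame(class = class, label = label, start = start, end = end,
               strand = strandv, tags = tags, stringsAsFactors = FALSE)
  parts <- list()
  o <- catalog@orfs
  if (length(o))
    parts$orf <- row("orf", mcols(o)$label, start(o), end(o),
                     as.character(strand(o)), mcols(o)$tags)
  ts <- catalog@tss
  if (length(ts))
    parts$tss <- row("tss", mcols(ts)$label, start(ts), start(ts),
                     as.character(strand(ts)),
                     ifelse(mcols(ts)$label == catalog@transgeneTss,
                            "transgene", ""))
  pa <- catalog@polya
  if (length(pa))
    parts$polya <- row("polya", mcols(pa)$label, start(pa), start(pa),
                       as.character(strand(pa)), "")
  d <- catalog@donors
  if (length(d))
    parts$donor <- row("donor", paste0("D", seq_along(d)), start(d), start(d),
                       as.character(strand(d)), "")
  a <- catalog@acceptors
  if (length(a))
    parts$acceptor <- row("acceptor", paste0("A", seq_along(a)), start(a),
                          start(a), as.character(strand(a)), "")
  cs <- catalog@cassette
  parts$cassette <- row("cassette", "cassette", start(cs), end(cs),
                        as.character(strand(cs)), "")
  tab <- do.call(rbind, parts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# VectorTxAudit feature catalog (1-based inclusive coordinates)",
             con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

setMethod("show", "FeatureCatalog", function(object) {
  cat("FeatureCatalog:", length(object@orfs), "ORFs,",
      length(object@tss), "TSSs,", length(object@polya), "polyA sites,",
      length(object@donors), "donors,", length(object@acceptors),
      "acceptors\n")
  cat("  cassette: ", start(object@cassette), "-", end(object@cassette),
      "; transgene TSS: '", object@transgeneTss, "'\n", sep = "")
})

#' Mature mRNA sequence of an exon chain
#'
#' Concatenates the genomic sequence of the exon blocks in transcription
#' order; minus-strand chains are reverse-complemented so the result is the
#' sense (mRNA) strand.
#'
#' @param genome a [VectorGenome-class].
#' @param chain a [GenomicRanges::GRanges] of exon blocks on one strand,
#'   sorted by genomic position, non-overlapping.
#' @return a [Biostrings::DNAString] with the mature mRNA.
#' @export
splicedSequence <- function(genome, chain) {
  if (length(chain) == 0L)
    stop("empty exon chain")
  st <- unique(as.character(strand(chain)))
  if (length(st) != 1L || !st %in% c("+", "-"))
    stop("exon chain must lie on a single explicit strand")
  s <- start(chain); e <- end(chain)
  if (is.unsorted(s) || any(s[-1L] <= e[-length(e)]))
    stop("exon blocks must be sorted and non-overlapping")
  if (s[1L] < 1L || e[length(e)] > genomeLength(genome))
    stop("exon blocks outside the genome")
  pieces <- DNAStringSet(genome@sequence,
                         start = s, end = e)
  mrna <- unlist(pieces)
  if (st == "-") mrna <- reverseComplement(mrna)
  mrna
}

#' Translate the 5'-proximal ORF of a mature mRNA
#'
#' Scans 5'->3' for the first AUG and translates with the standard genetic
#' code until the first stop codon or the transcript end (a run-off ORF is
#' reported with `stop_found = FALSE`).
#'
#' @param mrna mRNA sequence (character or [Biostrings::DNAString]), sense
#'   strand, T or U.
#' @return a list with `peptide` (amino acids, no stop symbol; `""` if no
#'   AUG), `start_offset` (1-based offset of the A of the first AUG in the
#'   mRNA; `NA_integer_` if no AUG) and `stop_found` (logical).
#' @examples
#' translateFirstOrf("AAATGGCCTAA")  # peptide "MA", start_offset 3
#' @export
translateFirstOrf <- function(mrna) {
  s <- toupper(gsub("U", "T", as.character(mrna)))
  if (!nzchar(s)) stop("empty mRNA")
  at <- regexpr("ATG", s, fixed = TRUE)
  if (at < 0L)
    return(list(peptide = "", start_offset = NA_integer_, stop_found = FALSE))
  cds <- substring(s, at)
  ncod <- nchar(cds) %/% 3L
  cds <- substring(cds, 1L, ncod * 3L)
  aa <- as.character(translate(DNAString(cds), if.fuzzy.codon = "X"))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L)
    list(peptide = substring(aa, 1L, stop_at - 1L),
         start_offset = as.integer(at), stop_found = TRUE)
  else
    list(peptide = aa, start_offset = as.integer(at), stop_found = FALSE)
}

# map a 1-based position in the mature mRNA back to its genomic coordinate
mrnaToGenomic <- function(chain, k) {
  w <- width(chain)
  st <- as.character(strand(chain))[1L]
  if (k < 1L || k > sum(w)) stop("mRNA offset outside transcript")
  if (st == "+") {
    cum <- cumsum(w)
    i <- which(k <= cum)[1L]
    start(chain)[i] + (k - 1L) - (if (i > 1L) cum[i - 1L] else 0L)
  } else {
    wrev <- rev(w)
    cum <- cumsum(wrev)
    i <- which(k <= cum)[1L]
    j <- length(w) - i + 1L  # genomic block index, walking from the right
    end(chain)[j] - (k - 1L) + (if (i > 1L) cum[i - 1L] else 0L)
  }
}
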