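# fixtures are built in code: tiny genomes, catalogs and SAM files

writeTempFasta <- function(seq, name = "chr") {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", name), seq), fa)
  fa
}

tinyGenome <- function(seq, name = "chr") loadGenome(writeTempFasta(seq, name))

# catalog from a data.frame of rows (class,label,start,end,strand,tags);
# a cassette row is appended if absent so that validation passes
tinyCatalog <- function(rows, genome, add_cassette = TRUE) {
  if (add_cassette && !"cassette" %in% rows$class)
    rows <- rbind(rows, data.frame(class = "cassette", label = "cassette",
                                   start = 1L, end = genomeLength(genome),
                                   strand = "+", tags = ""))
  if (!any(rows$class == "tss" & grepl("transgene", rows$tags)) &&
      any(rows$class == "tss"))
    rows$tags[which(rows$class == "tss")[1L]] <- "transgene"
  path <- tempfile(fileext = ".tsv")
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  loadFeatureCatalog(path, genome)
}

catRow <- function(class, label, start, end = start, strand = "+", tags = "")
  data.frame(class = class, label = label, start = start, end = end,
             strand = strand, tags = tags, stringsAsFactors = FALSE)

chainOf <- function(starts, ends, strand = "+", contig = "chr")
  GenomicRanges::GRanges(contig, IRanges::IRanges(starts, ends),
                         strand = strand)

# minimal SAM writer for hand-made alignment records
writeTinySam <- function(records, contigs = c(chr = 2000L)) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs),
               records), path)
  path
}

samRecord <- function(qname, flag, rname, pos, cigar, seq_len = NULL) {
  if (is.null(seq_len)) {
    # derive read length from the CIGAR query-consuming ops
    ops <- gregexpr("\\d+[MIS=X]", cigar)[[1]]
    seq_len <- if (ops[1] == -1) 1L else
      sum(as.integer(gsub("[MIS=X]", "",
                          regmatches(cigar, gregexpr("\\d+[MIS=X]", cigar))[[1]])))
  }
  paste(qname, flag, rname, pos, 60, cigar, "*", 0, 0,
        strrep("A", seq_len), strrep("I", seq_len), sep = "\t")
}

# hand-built TranscriptGroupSet for unit tests of downstream modules
makeTgs <- function(df, chains, unclassified = 0L) {
  g <- S4Vectors::DataFrame(df)
  methods::new("TranscriptGroupSet", groups = g,
               chains = GenomicRanges::GRangesList(chains),
               unclassified = as.integer(unclassified))
}

# independent three-frame-scan translation oracle: locate the first ATG by
# string search and translate codon-by-codon via the standard code table
oracleFirstOrf <- function(s) {
  s <- toupper(s)
  at <- regexpr("ATG", s, fixed = TRUE)
  if (at < 0) return(list(peptide = "", start_offset = NA_integer_,
                          stop_found = FALSE))
  code <- Biostrings::GENETIC_CODE
  pep <- character()
  i <- as.integer(at)
  stop_found <- FALSE
  while (i + 2 <= nchar(s)) {
    aa <- unname(code[substr(s, i, i + 2)])
    if (aa == "*") { stop_found <- TRUE; break }
    pep <- c(pep, aa)
    i <- i + 3
  }
  list(peptide = paste(pep, collapse = ""), start_offset = as.integer(at),
       stop_found = stop_found)
}

# default toy setup shared by several test files (built once per test run)
toySetup <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- buildToyGenome(toyGenomeParams(), seed = 1L)
    cache
  }
})
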