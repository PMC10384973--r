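#' Transgene-cassette splice audit
#'
#' Partitions the transcript groups assigned to the transgene promoter into
#' unspliced (the intended intronless mRNA) and spliced (any junction —
#' the cassette is designed without an intron, so every junction is
#' unintended). The headline statistic is spliced reads per 100 unspliced
#' reads (`denominator = "unspliced"`, the published convention); a
#' conventional percentage of all promoter reads is available with
#' `denominator = "total"`. Every distinct junction whose donor lies inside
#' the transgene ORF is listed with its read support.
#'
#' @param tgs a [TranscriptGroupSet-class].
#' @param catalog a [FeatureCatalog-class] declaring the transgene TSS and
#'   the transgene-tagged ORF.
#' @param denominator `"unspliced"` (spliced per 100 unspliced) or
#'   `"total"` (spliced per 100 promoter reads).
#' @return a list: `promoter`, `unspliced_count`, `spliced_count`,
#'   `pct_spliced_vs_unspliced` (1 decimal; `NA` when the denominator is 0),
#'   `denominator`, and `junctions_in_orf` (data.frame `donor`, `acceptor`,
#'   `strand`, `count`, `donor_in_orf`).
#' @export
transgeneSpliceStats <- function(tgs, catalog,
                                 denominator = c("unspliced", "total")) {
  denominator <- match.arg(denominator)
  g <- groups(tgs)
  tg <- g[!is.na(g$tss) & g$tss == catalog@transgeneTss, , drop = FALSE]
  unspliced <- sum(tg$count[tg$junctions == ""])
  spliced <- sum(tg$count[tg$junctions != ""])
  den <- if (denominator == "unspliced") unspliced else unspliced + spliced
  pct <- if (den > 0) percentOf(spliced, den, 1L) else
    if (spliced == 0) 0.0 else NA_real_

  jdf <- data.frame(donor = integer(), acceptor = integer(),
                    strand = character(), count = integer(),
                    donor_in_orf = logical(), stringsAsFactors = FALSE)
  sp <- tg[tg$junctions != "", , drop = FALSE]
  if (nrow(sp)) {
    pieces <- strsplit(sp$junctions, ",", fixed = TRUE)
    jd <- do.call(rbind, lapply(seq_along(pieces), function(k) {
      da <- do.call(rbind, strsplit(pieces[[k]], "-", fixed = TRUE))
      data.frame(donor = as.integer(da[, 1L]),
                 acceptor = as.integer(da[, 2L]),
                 strand = sp$strand[k], count = sp$count[k],
                 stringsAsFactors = FALSE)
    }))
    jd <- stats::aggregate(count ~ donor + acceptor + strand, jd, sum)
    tg_orf <- catalog@orfs[grepl("(^|,)\\s*transgene\\s*(,|$)",
                                 mcols(catalog@orfs)$tags)]
    jd$donor_in_orf <- if (length(tg_orf))
      jd$donor >= start(tg_orf)[1L] & jd$donor <= end(tg_orf)[1L]
    else FALSE
    jdf <- jd[order(-jd$count), , drop = FALSE]
    rownames(jdf) <- NULL
  }
  list(promoter = catalog@transgeneTss,
       unspliced_count = unspliced, spliced_count = spliced,
       pct_spliced_vs_unspliced = pct, denominator = denominator,
       junctions_in_orf = jdf)
}

#' Replication-competent adenovirus (RCA) screen
#'
#' An E1-deleted vector must produce no E1 transcripts; any vector read whose
#' 5'-proximal ORF call carries the catalog tag `E1` indicates possible
#' replication-competent recombinants in the stock. Reads mapped to the
#' host's integrated E1 region (E1-complementing cell lines) are passed
#' through for reporting and do not affect the vector verdict.
#'
#' @param calls result of [assignOrf()].
#' @param tgs the matching [TranscriptGroupSet-class].
#' @param catalog a [FeatureCatalog-class] with `E1`-tagged ORFs.
#' @param e1_contig_count reads mapped to the host E1 contig (pass-through).
#' @param threshold vector E1 read count strictly above which the verdict is
#'   positive (default 0: any E1 transcript is reported).
#' @return a list: `e1_orf_read_count`, `e1_contig_read_count`, `threshold`,
#'   `verdict` (`"no E1 transcripts detected"` or
#'   `"E1 transcripts present"`).
#' @export
screenE1 <- function(calls, tgs, catalog, e1_contig_count = NA_integer_,
                     threshold = 0L) {
  g <- groups(tgs)
  stopifnot(identical(calls$group_id, g$group_id))
  e1_labels <- mcols(catalog@orfs)$label[
    grepl("(^|,)\\s*E1\\s*(,|$)", mcols(catalog@orfs)$tags)]
  hit <- calls$category == "catalog" & calls$orf_label %in% e1_labels
  n_e1 <- sum(g$count[hit])
  list(e1_orf_read_count = as.integer(n_e1),
       e1_contig_read_count = as.integer(e1_contig_count),
       threshold = as.integer(threshold),
       verdict = if (n_e1 > threshold) "E1 transcripts present"
                 else "no E1 transcripts detected")
}
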