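#' Assign the 5'-proximal ORF to each transcript group
#'
#' For every group, the mature mRNA is rebuilt from the representative exon
#' chain re-anchored at the assigned catalog TSS (not at the observed,
#' possibly 5'-truncated read end, which would spuriously shift the first
#' AUG); groups without a TSS assignment are scanned from their observed 5'
#' end. The first AUG is located and the group is called:
#'
#' * `"catalog"` — the AUG's genomic position coincides exactly with a
#'   catalog ORF start codon on the same strand (no fuzzy or out-of-frame
#'   matching);
#' * `"none_from_list"` — an AUG exists but matches no catalog ORF; the
#'   translated peptide is reported;
#' * `"no_orf"` — the mRNA contains no AUG.
#'
#' @param tgs a [TranscriptGroupSet-class].
#' @param genome a [VectorGenome-class].
#' @param catalog a [FeatureCatalog-class].
#' @return a `data.frame` with one row per group: `group_id`, `category`,
#'   `orf_label`, `peptide`, `start_offset` (1-based nt in the mature mRNA),
#'   `start_genomic`, `stop_found`.
#' @export
assignOrf <- function(tgs, genome, catalog) {
  g <- groups(tgs)
  chains <- groupChains(tgs)
  tss_pos <- setNames(start(catalog@tss), mcols(catalog@tss)$label)
  orf_strand <- as.character(strand(catalog@orfs))
  orf_start <- mcols(catalog@orfs)$start_codon
  orf_label <- mcols(catalog@orfs)$label

  n <- nrow(g)
  category <- character(n); label <- rep(NA_character_, n)
  peptide <- rep(NA_character_, n)
  start_off <- rep(NA_integer_, n); start_gen <- rep(NA_integer_, n)
  stop_found <- rep(NA, n)

  for (i in seq_len(n)) {
    chain <- chains[[i]]
    st <- g$strand[i]
    if (!is.na(g$tss[i]) && g$tss[i] %in% names(tss_pos)) {
      anchor <- tss_pos[[g$tss[i]]]
      # extend the transcription-first block back to the TSS
      if (st == "+" && anchor <= end(chain)[1L] && anchor < start(chain)[1L])
        start(chain)[1L] <- anchor
      else if (st == "-" && anchor >= start(chain)[length(chain)] &&
               anchor > end(chain)[length(chain)])
        end(chain)[length(chain)] <- anchor
    }
    tr <- translateFirstOrf(splicedSequence(genome, chain))
    if (is.na(tr$start_offset)) {
      category[i] <- "no_orf"
      next
    }
    start_off[i] <- tr$start_offset
    start_gen[i] <- mrnaToGenomic(chain, tr$start_offset)
    stop_found[i] <- tr$stop_found
    hit <- which(orf_strand == st & orf_start == start_gen[i])
    if (length(hit)) {
      category[i] <- "catalog"
      label[i] <- orf_label[hit[1L]]
    } else {
      category[i] <- "none_from_list"
      peptide[i] <- tr$peptide
    }
  }
  data.frame(group_id = g$group_id, category = category, orf_label = label,
             peptide = peptide, start_offset = start_off,
             start_genomic = start_gen, stop_found = stop_found,
             stringsAsFactors = FALSE)
}

#' Per-ORF gene transcription table
#'
#' Aggregates ORF calls over transcript groups (weighted by group read
#' count) into the published tables' layout: one row per catalog feature,
#' plus a `"None from the list"` row for novel-peptide calls and a
#' `"No ORF"` row for AUG-less groups, sorted by decreasing count, with
#' percentages of the declared `total` computed by [percentOf()].
#'
#' @param calls result of [assignOrf()].
#' @param tgs the matching [TranscriptGroupSet-class].
#' @param total declared denominator (> 0); stated explicitly in the output
#'   attributes rather than guessed.
#' @param decimals decimal places for percentages; `NULL` (default) uses 1
#'   unless any nonzero row would round to 0.0, then 2.
#' @return a `data.frame` with `feature`, `count`, `percent`; attributes
#'   `total` and `decimals`.
#' @export
geneTable <- function(calls, tgs, total, decimals = NULL) {
  if (total <= 0) stop("total must be > 0")
  g <- groups(tgs)
  stopifnot(identical(calls$group_id, g$group_id))
  feature <- ifelse(calls$category == "catalog", calls$orf_label,
                    ifelse(calls$category == "none_from_list",
                           "None from the list", "No ORF"))
  if (!nrow(g)) {
    out <- data.frame(feature = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE)
    attr(out, "total") <- total
    attr(out, "decimals") <- if (is.null(decimals)) 1L else decimals
    return(out)
  }
  agg <- tapply(g$count, feature, sum)
  out <- data.frame(feature = names(agg), count = as.integer(agg),
                    stringsAsFactors = FALSE)
  if (is.null(decimals)) {
    decimals <- 1L
    if (any(out$count > 0 & percentOf(out$count, total, 1L) == 0))
      decimals <- 2L
  }
  out$percent <- percentOf(out$count, total, decimals)
  out <- out[order(-out$count, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total") <- total
  attr(out, "decimals") <- decimals
  out
}
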