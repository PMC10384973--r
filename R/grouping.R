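# nearest value of sorted `sites` for each x, within tol; ties resolve to the
# lower coordinate. Returns NA where nothing is within tol.
.nearestWithin <- function(x, sites, tol) {
  out <- rep(NA_real_, length(x))
  if (!length(sites) || !length(x)) return(out)
  sites <- sort(sites)
  i <- findInterval(x, sites)
  left <- ifelse(i >= 1L, sites[pmax(i, 1L)], NA_real_)
  right <- ifelse(i < length(sites), sites[pmin(i + 1L, length(sites))],
                  NA_real_)
  dl <- x - left
  dr <- right - x
  pick_left <- !is.na(left) & (is.na(right) | dl <= dr)  # tie -> lower coord
  out <- ifelse(pick_left, left, right)
  d <- abs(x - out)
  out[is.na(out) | d > tol] <- NA_real_
  out
}

#' Default classification tolerances
#'
#' Junction snap distance, TSS window (downstream offsets only, to absorb the
#' 5' truncation of direct RNA reads), polyA tolerance, and novel-5'-end
#' clustering parameters. All values are in nucleotides and exposed here
#' because the choice is a tunable of the method, not a constant.
#'
#' @param junction_tol max distance (nt) between an observed junction end and
#'   a catalog donor/acceptor for snapping (default 10).
#' @param tss_window max downstream offset (nt) of an observed 5' end from a
#'   catalog TSS (default 100).
#' @param polya_tol max absolute offset (nt) of an observed 3' end from a
#'   catalog polyA site (default 30).
#' @param cluster_gap single-linkage gap (nt) for novel-end clustering
#'   (default 20).
#' @param min_cluster_count minimum reads per reported novel-end cluster
#'   (default 10).
#' @return a named list.
#' @export
groupingParams <- function(junction_tol = 10L, tss_window = 100L,
                           polya_tol = 30L, cluster_gap = 20L,
                           min_cluster_count = 10L) {
  p <- list(junction_tol = junction_tol, tss_window = tss_window,
            polya_tol = polya_tol, cluster_gap = cluster_gap,
            min_cluster_count = min_cluster_count)
  if (any(unlist(p) < 0)) stop("all tolerances must be >= 0")
  p
}

#' Snap the junctions of one exon chain to catalogued splice sites
#'
#' Each junction end is snapped independently to the nearest same-strand
#' catalog donor/acceptor within `tol` (equidistant sites resolve to the
#' lower genomic coordinate). A junction with either end unmatched is flagged
#' novel and keeps the observed coordinate at the unmatched end. Snapping is
#' idempotent: already-snapped coordinates are at distance 0.
#'
#' @param chain a [GenomicRanges::GRanges] exon chain on one strand.
#' @param catalog a [FeatureCatalog-class].
#' @param tol snap distance in nt (>= 0).
#' @return a `data.frame` with one row per junction, in transcription order:
#'   `donor`, `acceptor` (genomic, 1-based, donor = first intronic base in
#'   transcription direction), `strand`, `donor_novel`, `acceptor_novel`,
#'   `is_novel`. Zero rows for single-block chains.
#' @export
snapJunctions <- function(chain, catalog, tol = 10L) {
  st <- as.character(strand(chain))[1L]
  n <- length(chain)
  empty <- data.frame(donor = integer(), acceptor = integer(),
                      strand = character(), donor_novel = logical(),
                      acceptor_novel = logical(), is_novel = logical())
  if (n < 2L) return(empty)
  gap_start <- end(chain)[-n] + 1L
  gap_end <- start(chain)[-1L] - 1L
  if (st == "+") { donor <- gap_start; acceptor <- gap_end }
  else { donor <- gap_end; acceptor <- gap_start }
  dsites <- start(catalog@donors)[as.character(strand(catalog@donors)) == st]
  asites <- start(catalog@acceptors)[
    as.character(strand(catalog@acceptors)) == st]
  sd <- .nearestWithin(donor, dsites, tol)
  sa <- .nearestWithin(acceptor, asites, tol)
  res <- data.frame(donor = as.integer(ifelse(is.na(sd), donor, sd)),
                    acceptor = as.integer(ifelse(is.na(sa), acceptor, sa)),
                    strand = st,
                    donor_novel = is.na(sd), acceptor_novel = is.na(sa))
  res$is_novel <- res$donor_novel | res$acceptor_novel
  if (st == "-") res <- res[rev(seq_len(nrow(res))), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assign the 5' end of a chain to a catalog TSS
#'
#' Candidate TSSs lie at or upstream (in transcription direction) of the
#' observed 5' end with a downstream offset of at most `window` nt — the
#' one-sided window reflects that direct RNA reads are 5'-truncated, never
#' 5'-extended. The nearest candidate wins; equidistant candidates resolve to
#' the lower genomic coordinate.
#'
#' @inheritParams snapJunctions
#' @param window max downstream offset in nt.
#' @return `list(label, offset)` or `NULL` when unassigned.
#' @export
assignTss <- function(chain, catalog, window = 100L) {
  st <- as.character(strand(chain))[1L]
  obs5 <- if (st == "+") start(chain)[1L] else end(chain)[length(chain)]
  sel <- as.character(strand(catalog@tss)) == st
  pos <- start(catalog@tss)[sel]
  lab <- mcols(catalog@tss)$label[sel]
  if (!length(pos)) return(NULL)
  off <- if (st == "+") obs5 - pos else pos - obs5
  ok <- off >= 0L & off <= window
  if (!any(ok)) return(NULL)
  cand <- which(ok)
  best <- cand[order(off[cand], pos[cand])][1L]
  list(label = lab[best], offset = as.integer(off[best]))
}

#' Assign the 3' end of a chain to a catalog polyA site
#'
#' The observed 3' end is matched to the nearest same-strand catalog polyA
#' site within `tol` nt on either side (3' ends are read first by the pore
#' and are reliable, so the window is two-sided and tight).
#'
#' @inheritParams snapJunctions
#' @param tol max absolute offset in nt.
#' @return `list(label, offset)` (offset signed, observed minus site) or
#'   `NULL` when unassigned.
#' @export
assignPolya <- function(chain, catalog, tol = 30L) {
  st <- as.character(strand(chain))[1L]
  obs3 <- if (st == "+") end(chain)[length(chain)] else start(chain)[1L]
  sel <- as.character(strand(catalog@polya)) == st
  pos <- start(catalog@polya)[sel]
  lab <- mcols(catalog@polya)$label[sel]
  if (!length(pos)) return(NULL)
  site <- .nearestWithin(obs3, pos, tol)
  if (is.na(site)) return(NULL)
  list(label = lab[match(site, pos)], offset = as.integer(obs3 - site))
}

# vectorized internals shared by groupTranscripts ------------------------------

.chainTable <- function(reads) {
  ul <- unlist(reads, use.names = FALSE)
  nb <- lengths(reads)
  rid <- rep(seq_along(reads), nb)
  list(start = start(ul), end = end(ul),
       strand = as.character(strand(ul)), rid = rid, nb = nb,
       first = cumsum(nb) - nb + 1L, last = cumsum(nb))
}

#' Collapse classified reads into transcript groups
#'
#' Canonicalizes every read (junction snapping, TSS and polyA assignment)
#' and collapses reads by the signature (strand, TSS label, snapped junction
#' chain, polyA label). Reads with no TSS, no polyA and no junction are
#' unclassifiable and only counted. Each group keeps the exon chain of its
#' least 5'-truncated member as representative.
#'
#' @param reads a [GenomicRanges::GRangesList] from
#'   [parseSplicedAlignments()] (vector contig only).
#' @param catalog a [FeatureCatalog-class].
#' @param params a [groupingParams()] list.
#' @return a [TranscriptGroupSet-class]; `metadata(groups(x))` records the
#'   parameters.
#' @export
groupTranscripts <- function(reads, catalog, params = groupingParams()) {
  if (length(reads) == 0L)
    return(new("TranscriptGroupSet",
               groups = DataFrame(group_id = character(),
                                  strand = character(), tss = character(),
                                  tss_offset = integer(),
                                  junctions = character(),
                                  polya = character(),
                                  polya_offset = integer(),
                                  count = integer(),
                                  novel_junction = logical()),
               chains = GRangesList(), unclassified = 0L))

  ct <- .chainTable(reads)
  n <- length(reads)
  st <- ct$strand[ct$first]
  obs5 <- ifelse(st == "+", ct$start[ct$first], ct$end[ct$last])
  obs3 <- ifelse(st == "+", ct$end[ct$last], ct$start[ct$first])

  # --- TSS assignment (one-sided window, nearest, tie -> lower coordinate)
  tss_lab <- rep(NA_character_, n)
  tss_off <- rep(NA_integer_, n)
  for (s in c("+", "-")) {
    sel <- as.character(strand(catalog@tss)) == s
    pos <- start(catalog@tss)[sel]
    lab <- mcols(catalog@tss)$label[sel]
    idx <- which(st == s)
    if (!length(pos) || !length(idx)) next
    o <- order(pos)
    pos <- pos[o]; lab <- lab[o]
    x <- obs5[idx]
    if (s == "+") {
      i <- findInterval(x, pos)        # nearest TSS at or below obs5
      ok <- i >= 1L
      off <- ifelse(ok, x - pos[pmax(i, 1L)], NA_integer_)
      hit <- ok & !is.na(off) & off <= params$tss_window
      tss_lab[idx[hit]] <- lab[i[hit]]
      tss_off[idx[hit]] <- as.integer(off[hit])
    } else {
      i <- findInterval(x - 1L, pos) + 1L  # nearest TSS at or above obs5
      ok <- i <= length(pos)
      off <- ifelse(ok, pos[pmin(i, length(pos))] - x, NA_integer_)
      hit <- ok & !is.na(off) & off <= params$tss_window
      tss_lab[idx[hit]] <- lab[i[hit]]
      tss_off[idx[hit]] <- as.integer(off[hit])
    }
  }

  # --- polyA assignment (two-sided, nearest, tie -> lower coordinate)
  pa_lab <- rep(NA_character_, n)
  pa_off <- rep(NA_integer_, n)
  for (s in c("+", "-")) {
    sel <- as.character(strand(catalog@polya)) == s
    pos <- start(catalog@polya)[sel]
    lab <- mcols(catalog@polya)$label[sel]
    idx <- which(st == s)
    if (!length(pos) || !length(idx)) next
    site <- .nearestWithin(obs3[idx], pos, params$polya_tol)
    hit <- !is.na(site)
    pa_lab[idx[hit]] <- lab[match(site[hit], pos)]
    pa_off[idx[hit]] <- as.integer(obs3[idx][hit] - site[hit])
  }

  # --- junction snapping, vectorized over all introns
  intron_row <- which(ct$rid[-1L] == ct$rid[-length(ct$rid)])
  jkey <- rep("", n)
  jnovel <- rep(FALSE, n)
  if (length(intron_row)) {
    g_start <- ct$end[intron_row] + 1L
    g_end <- ct$start[intron_row + 1L] - 1L
    jr <- ct$rid[intron_row]
    js <- st[jr]
    donor <- ifelse(js == "+", g_start, g_end)
    acceptor <- ifelse(js == "+", g_end, g_start)
    sd <- rep(NA_real_, length(donor))
    sa <- rep(NA_real_, length(acceptor))
    for (s in c("+", "-")) {
      dsites <- start(catalog@donors)[
        as.character(strand(catalog@donors)) == s]
      asites <- start(catalog@acceptors)[
        as.character(strand(catalog@acceptors)) == s]
      sel <- js == s
      sd[sel] <- .nearestWithin(donor[sel], dsites, params$junction_tol)
      sa[sel] <- .nearestWithin(acceptor[sel], asites, params$junction_tol)
    }
    nov <- is.na(sd) | is.na(sa)
    dfin <- as.integer(ifelse(is.na(sd), donor, sd))
    afin <- as.integer(ifelse(is.na(sa), acceptor, sa))
    pair <- paste0(dfin, "-", afin)
    # transcription order: genomic order for +, reversed for -
    ord <- order(jr, ifelse(js == "+", dfin, -dfin))
    agg <- tapply(pair[ord], jr[ord], paste, collapse = ",")
    jkey[as.integer(names(agg))] <- unname(agg)
    nov_agg <- tapply(nov, jr, any)
    jnovel[as.integer(names(nov_agg))] <- unname(nov_agg)
  }

  unclassifiable <- is.na(tss_lab) & is.na(pa_lab) & jkey == ""
  keep <- which(!unclassifiable)
  key <- paste(st, tss_lab, jkey, pa_lab, sep = "|")[keep]
  fac <- factor(key)
  counts <- tabulate(fac)
  gidx <- as.integer(fac)
  # representative: least-truncated member (most upstream 5' end)
  ext <- ifelse(st[keep] == "+", -obs5[keep], obs5[keep])
  best <- keep[vapply(split(seq_along(keep), gidx), function(ii)
    ii[which.max(ext[ii])], 1L)]

  first_of <- vapply(split(seq_along(keep), gidx), `[`, 1L, 1L)
  g <- DataFrame(strand = st[keep][first_of],
                 tss = tss_lab[keep][first_of],
                 tss_offset = tss_off[best],
                 junctions = jkey[keep][first_of],
                 polya = pa_lab[keep][first_of],
                 polya_offset = pa_off[best],
                 count = counts,
                 novel_junction = jnovel[keep][first_of])
  ord <- order(-g$count, g$strand, g$tss, g$junctions)
  g <- g[ord, , drop = FALSE]
  g$group_id <- sprintf("G%04d", seq_len(nrow(g)))
  g <- g[, c("group_id", "strand", "tss", "tss_offset", "junctions",
             "polya", "polya_offset", "count", "novel_junction")]
  chains <- reads[best[ord]]
  mcols(chains) <- NULL
  names(chains) <- g$group_id
  metadata(g) <- params
  new("TranscriptGroupSet", groups = g, chains = chains,
      unclassified = sum(unclassifiable))
}

#' @describeIn groupTranscripts group table of a `TranscriptGroupSet`.
#' @param x a `TranscriptGroupSet`.
#' @export
groups <- function(x) x@groups

#' @describeIn groupTranscripts representative exon chains.
#' @export
groupChains <- function(x) x@chains

#' @describeIn groupTranscripts number of unclassifiable reads.
#' @export
unclassifiedCount <- function(x) x@unclassified

setMethod("show", "TranscriptGroupSet", function(object) {
  g <- object@groups
  cat("TranscriptGroupSet:", nrow(g), "groups,", sum(g$count),
      "classified reads,", object@unclassified, "unclassifiable\n")
  if (nrow(g)) {
    top <- utils::head(as.data.frame(g), 5L)
    print(top)
    if (nrow(g) > 5L) cat("  ...", nrow(g) - 5L, "more groups\n")
  }
})

#' Cluster unassigned transcript ends into novel-end candidates
#'
#' Single-linkage clustering of genomic end positions: sorted positions are
#' chained while consecutive gaps are at most `gap` nt; clusters smaller than
#' `min_count` are discarded. The reported position is the modal end (ties
#' resolve to the lower coordinate). Used to nominate novel promoters (5'
#' ends that match no catalog TSS) and novel polyA sites.
#'
#' @param ends integer vector of genomic end positions (one strand at a
#'   time).
#' @param gap single-linkage gap in nt (>= 0).
#' @param min_count minimum cluster size.
#' @param strand strand label stored in the result.
#' @param kind `"promoter-candidate"` or `"polya-candidate"`.
#' @return a `data.frame` with `cluster_id`, `position`, `strand`, `count`,
#'   `kind`, sorted by decreasing count.
#' @export
clusterNovelEnds <- function(ends, gap = 20L, min_count = 10L,
                             strand = "+", kind = "promoter-candidate") {
  stopifnot(gap >= 0L)
  empty <- data.frame(cluster_id = character(), position = integer(),
                      strand = character(), count = integer(),
                      kind = character(), stringsAsFactors = FALSE)
  if (!length(ends)) return(empty)
  ends <- sort(as.integer(ends))
  brk <- c(0L, cumsum(diff(ends) > gap))
  sizes <- tabulate(brk + 1L)
  keep <- which(sizes >= min_count)
  if (!length(keep)) return(empty)
  res <- lapply(keep, function(k) {
    v <- ends[brk == (k - 1L)]
    tb <- table(v)
    data.frame(position = as.integer(names(tb)[which.max(tb)]),
               count = length(v), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- res[order(-res$count, res$position), , drop = FALSE]
  data.frame(cluster_id = sprintf("NC%03d", seq_len(nrow(res))),
             position = res$position, strand = strand, count = res$count,
             kind = kind, stringsAsFactors = FALSE)
}
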