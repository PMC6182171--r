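# Lineage-specific erosion calling, independent-intersection, ranking and
# mechanism classification.

split_species <- function(x) strsplit(x, ",", fixed = TRUE)

# Index blocks by reference interval for site -> covering-block lookup.
block_index <- function(blocks) {
  data.frame(
    chrom = vapply(blocks, `[[`, character(1), "chrom"),
    start = vapply(blocks, function(b) b$ref_start, integer(1)),
    end = vapply(blocks, function(b) b$ref_end, integer(1)),
    i = seq_along(blocks),
    stringsAsFactors = FALSE
  )
}

blocks_covering <- function(bidx, chrom, start, end) {
  bidx$i[bidx$chrom == chrom & bidx$start < end & bidx$end > start]
}

#' Classify the mechanism of an erosion event
#'
#' An erosion is a `"mismatch"` when the target species has at least one
#' aligned (non-gap) base over the site's alignment columns — the
#' ancestral sequence is present but disrupted by substitutions or small
#' indels. When the target has no aligning sequence at all (entirely
#' gapped, or absent from every covering block) the event is a
#' `"deletion"`.
#'
#' @param site One-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param blocks List of [alignment_block()]s covering the genome.
#' @param target Target species name.
#' @param bidx Optional precomputed [block_index].
#' @return `"mismatch"` or `"deletion"`.
#' @export
classify_mechanism <- function(site, blocks, target, bidx = NULL) {
  if (is.null(bidx)) bidx <- block_index(blocks)
  hits <- blocks_covering(bidx, site$chrom, site$start, site$end)
  for (i in hits) {
    b <- blocks[[i]]
    if (!target %in% names(b$rows)) next
    refcols <- block_ref_columns(b)
    lo <- max(site$start, b$ref_start) - b$ref_start + 1L
    hi <- min(site$end, b$ref_end) - b$ref_start
    if (hi < lo) next
    cols <- refcols[lo]:refcols[hi]
    chars <- strsplit(b$rows[[target]], "", fixed = TRUE)[[1]][cols]
    if (any(chars != "-")) return("mismatch")
  }
  "deletion"
}

# TRUE when the target row over the site contains an assembly-gap 'N', or
# the site overlaps the supplied target assembly-gap BED (reference
# coordinates).
site_gap_overlap <- function(site, blocks, target, bidx, gaps_gr = NULL) {
  if (!is.null(gaps_gr) && length(gaps_gr)) {
    q <- GenomicRanges::GRanges(site$chrom,
                                IRanges::IRanges(site$start + 1L, site$end))
    if (length(GenomicRanges::findOverlaps(q, gaps_gr)) > 0L) return(TRUE)
  }
  hits <- blocks_covering(bidx, site$chrom, site$start, site$end)
  for (i in hits) {
    b <- blocks[[i]]
    if (!target %in% names(b$rows)) next
    refcols <- block_ref_columns(b)
    lo <- max(site$start, b$ref_start) - b$ref_start + 1L
    hi <- min(site$end, b$ref_end) - b$ref_start
    if (hi < lo) next
    cols <- refcols[lo]:refcols[hi]
    chars <- toupper(strsplit(b$rows[[target]], "", fixed = TRUE)[[1]][cols])
    if (any(chars == "N")) return(TRUE)
  }
  FALSE
}

#' Call binding sites eroded in a target lineage
#'
#' A conserved binding site is eroded in the target species when the
#' target is absent from the site's matching-species set while at least
#' one declared outgroup species is present (so the site was likely
#' present in the common ancestor). Calls whose target sequence overlaps
#' an assembly gap (an `N` run in the target row, or an interval of the
#' supplied gap BED) are discarded rather than being mistaken for
#' erosion. Each retained call is annotated with its mechanism
#' ([classify_mechanism()]).
#'
#' @param sites Conserved-site data.frame from [predict_sites()].
#' @param target Target species name.
#' @param outgroups Non-empty character vector of outgroup species.
#' @param tree A `phylo` object (species validation).
#' @param blocks List of [alignment_block()]s (gap check and mechanism).
#' @param gaps Optional assembly-gap BED data.frame in reference
#'   coordinates.
#' @return Subset of `sites` with `target`, `mechanism` and `gap_overlap`
#'   columns added (retained rows always have `gap_overlap = FALSE`).
#' @export
call_eroded <- function(sites, target, outgroups, tree, blocks,
                        gaps = NULL) {
  stopifnot(length(outgroups) >= 1L)
  if (target %in% outgroups) stop("target cannot be its own outgroup")
  known <- tree$tip.label
  miss <- setdiff(c(target, outgroups), known)
  if (length(miss)) stop("species absent from tree: ",
                         paste(miss, collapse = ", "))
  if (!nrow(sites)) {
    out <- sites
    out$target <- character(0); out$mechanism <- character(0)
    out$gap_overlap <- logical(0)
    return(out)
  }
  msets <- split_species(sites$matching_species)
  has_target <- vapply(msets, function(s) target %in% s, logical(1))
  has_out <- vapply(msets, function(s) any(outgroups %in% s), logical(1))
  cand <- which(!has_target & has_out)
  bidx <- block_index(blocks)
  gaps_gr <- if (!is.null(gaps) && nrow(gaps)) bed_to_gr(gaps) else NULL
  keep <- logical(length(cand))
  mech <- character(length(cand))
  for (j in seq_along(cand)) {
    site <- sites[cand[j], ]
    if (site_gap_overlap(site, blocks, target, bidx, gaps_gr)) next
    keep[j] <- TRUE
    mech[j] <- classify_mechanism(site, blocks, target, bidx)
  }
  out <- sites[cand[keep], , drop = FALSE]
  out$target <- if (nrow(out)) target else character(0)
  out$mechanism <- mech[keep]
  out$gap_overlap <- rep(FALSE, nrow(out))
  rownames(out) <- NULL
  out
}

site_key <- function(df) {
  paste(df$chrom, df$start, df$end, df$strand, df$motif_id, sep = "|")
}

#' Intersect eroded-site sets across independent target lineages
#'
#' A site is independently eroded when the same conserved-site prediction
#' (same interval, strand and motif) is eroded in every target lineage
#' (two or three). Per-target mechanisms are carried along as
#' `mechanism_<target>` columns.
#'
#' @param eroded_sets List of two or three [call_eroded()] data.frames,
#'   all derived from one shared conserved-site catalog.
#' @return data.frame of independently eroded sites; the target species
#'   are recorded in the `targets` attribute.
#' @export
intersect_independent <- function(eroded_sets) {
  if (length(eroded_sets) < 2L) {
    stop("need eroded-site sets for at least two target lineages")
  }
  targets <- vapply(eroded_sets, function(df) {
    if (nrow(df)) df$target[1] else NA_character_
  }, character(1))
  keys <- lapply(eroded_sets, site_key)
  shared <- Reduce(intersect, keys)
  base <- eroded_sets[[1]]
  out <- base[match(shared, keys[[1]]),
              setdiff(names(base), c("target", "mechanism", "gap_overlap")),
              drop = FALSE]
  for (i in seq_along(eroded_sets)) {
    tname <- targets[i]
    col <- paste0("mechanism_", ifelse(is.na(tname), i, tname))
    out[[col]] <- eroded_sets[[i]]$mechanism[match(shared, keys[[i]])]
  }
  rownames(out) <- NULL
  attr(out, "targets") <- targets
  out
}

rank_order <- function(df) {
  order(df$empirical_p, -df$bbl, df$chrom, df$start)
}

#' Keep the top-k sites by conservation significance, with ties
#'
#' Sites are ranked by empirical conservation p-value (ascending; ties
#' broken by higher BBL, then coordinate) and the first `k` are kept —
#' plus every additional site whose p-value equals that of the k-th, so
#' the cutoff never breaks ties arbitrarily.
#'
#' @param sites Ranked-site data.frame (needs `empirical_p`, `bbl`).
#' @param k Number of sites to keep (default 5000).
#' @return The top subset, in rank order.
#' @export
rank_top_k <- function(sites, k = 5000L) {
  if (k < 1L) stop("k must be at least 1")
  ord <- rank_order(sites)
  sorted <- sites[ord, , drop = FALSE]
  if (nrow(sorted) <= k) {
    rownames(sorted) <- NULL
    return(sorted)
  }
  cutoff <- sorted$empirical_p[k]
  out <- sorted[sorted$empirical_p <= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove overlapping sites, keeping the most significant
#'
#' Greedy deduplication in rank order (best empirical p-value first, ties
#' by BBL then coordinate): a site is kept iff it overlaps no
#' already-kept site (half-open interval overlap, strand-agnostic). The
#' output is pairwise non-overlapping and maximal under that order.
#'
#' @param sites Site data.frame.
#' @return Non-overlapping subset in rank order.
#' @export
dedup_overlaps <- function(sites) {
  if (nrow(sites) <= 1L) return(sites)
  ord <- rank_order(sites)
  sorted <- sites[ord, , drop = FALSE]
  kept <- logical(nrow(sorted))
  kept_by_chrom <- list()
  for (i in seq_len(nrow(sorted))) {
    ch <- sorted$chrom[i]
    ivs <- kept_by_chrom[[ch]]
    s <- sorted$start[i]; e <- sorted$end[i]
    if (is.null(ivs) || !any(ivs$start < e & ivs$end > s)) {
      kept[i] <- TRUE
      kept_by_chrom[[ch]] <- rbind(ivs, data.frame(start = s, end = e))
    }
  }
  out <- sorted[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-tabulate erosion mechanisms over target lineages
#'
#' Counts, over an independently eroded set with per-target mechanism
#' columns, how many sites are disrupted by motif mismatches in every
#' target, by deletions in every target, or by a mixture. The counts
#' partition the set.
#'
#' @param ind Data.frame from [intersect_independent()] (columns
#'   `mechanism_*`).
#' @return Named integer vector `all_mismatch`, `mixed`, `all_deletion`.
#' @export
mechanism_table <- function(ind) {
  cols <- grep("^mechanism_", names(ind), value = TRUE)
  if (length(cols) < 2L) stop("need mechanism columns for >= 2 targets")
  m <- as.matrix(ind[, cols, drop = FALSE]) == "mismatch"
  n_mm <- rowSums(m)
  c(
    all_mismatch = sum(n_mm == length(cols)),
    mixed = sum(n_mm > 0 & n_mm < length(cols)),
    all_deletion = sum(n_mm == 0)
  )
}
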