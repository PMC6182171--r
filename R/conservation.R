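#' Per-base weighted percent identity over an alignment block
#'
#' For each reference base in the block, the weighted percent identity (PID)
#' is the branch length of the minimal subtree connecting the reference
#' species and every species whose aligned base equals the reference base
#' (case-insensitive; gaps and `N` count as non-matching), normalised by
#' the total branch length of the phylogeny. PID is 1 only when every
#' species in the tree aligns and matches the reference base, and 0 when
#' the reference base is supported by no other species.
#'
#' @param block An [alignment_block()].
#' @param tree A `phylo` object covering all block species.
#' @param index Optional precomputed [tree_branch_index] of `tree`.
#' @return Numeric vector of PID values, one per reference base.
#' @export
per_base_identity <- function(block, tree, index = NULL) {
  if (is.null(index)) index <- tree_branch_index(tree)
  species <- names(block$rows)
  if (!all(species %in% index$species)) {
    stop("block species missing from tree: ",
         paste(setdiff(species, index$species), collapse = ", "))
  }
  m <- block_char_matrix(block)
  refcols <- block_ref_columns(block)
  sub <- m[, refcols, drop = FALSE]
  refbase <- sub[block$ref, ]
  member <- sweep(sub, 2, refbase, "==") & sub != "-" & sub != "N"
  member[block$ref, ] <- TRUE
  induced_lengths(index, member) / index$total
}

#' Smooth a conservation profile with a centred window mean
#'
#' Each base receives the mean of the raw values in a window of
#' `window` bases centred on it; the window is truncated (not mirrored) at
#' the ends of the profile. For even window sizes the window covers
#' `window/2 - 1` bases to the left and `window/2` to the right.
#'
#' @param raw Numeric vector of per-base scores.
#' @param window Window size in bases (>= 1; default 100).
#' @return Numeric vector, same length as `raw`.
#' @export
smooth_profile <- function(raw, window = 100L) {
  stopifnot(window >= 1L)
  n <- length(raw)
  if (n == 0L) return(numeric(0))
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  cs <- c(0, cumsum(raw))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Conservation bin of a smoothed identity score
#'
#' Smoothed percent identity values in \[0, 1\] are grouped into 1% bins
#' 0..99: `floor(v * 100)`, with 1.0 clamped into bin 99.
#'
#' @param smoothed_pid Numeric vector in \[0, 1\].
#' @return Integer bin indices 0..99.
#' @export
bin_conservation <- function(smoothed_pid) {
  if (any(!is.finite(smoothed_pid)) ||
      any(smoothed_pid < 0) || any(smoothed_pid > 1)) {
    stop("smoothed identity values must lie in [0, 1]")
  }
  as.integer(pmin(floor(smoothed_pid * 100), 99))
}

#' Full conservation profile of a block
#'
#' Convenience wrapper computing raw PID, the smoothed profile and the 1%
#' conservation bin for every reference base of a block.
#'
#' @inheritParams per_base_identity
#' @param window Smoothing window in bases.
#' @return List with `raw`, `smoothed` and `bin` vectors.
#' @export
conservation_profile <- function(block, tree, window = 100L, index = NULL) {
  raw <- per_base_identity(block, tree, index = index)
  smoothed <- smooth_profile(raw, window = window)
  list(raw = raw, smoothed = smoothed, bin = bin_conservation(smoothed))
}
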