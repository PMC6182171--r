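#' Default screen parameters
#'
#' The parameter block used across the screen. Defaults are the method's
#' published operating point: MATCH threshold 0.8, empirical conservation
#' p-value at most 1e-3, preservation in at least 5 species spanning at
#' least 3.0 substitutions/site, top-5000 ranking with ties, GREAT basal
#' domain 5 kb upstream / 1 kb downstream with up to 1 Mb extension, fold
#' >= 2 and FDR <= 0.05 on both enrichment tests, and 10,000 permutations.
#'
#' @param ... Named overrides of any default.
#' @return Named list of parameters.
#' @export
screen_params <- function(...) {
  p <- list(
    match_threshold = 0.8,
    p_max = 1e-3,
    min_species = 5L,
    min_bbl = 3.0,
    smooth_window = 100L,
    n_shuffles = 10L,
    min_null = 3000L,
    top_k = 5000L,
    basal_up = 5000L,
    basal_down = 1000L,
    max_extension = 1000000L,
    fold_min = 2,
    q_max = 0.05,
    min_term_genes = 10L,
    max_term_genes = 500L,
    n_permutations = 10000L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown screen parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(over)] <- over
  p
}

# Per-block precomputation shared by null building and prediction:
# character matrix, reference column map, encoded rows, conservation bins
# and the allowed-space indicator per reference base.
prepare_block <- function(block, tree_index, mask, window = 100L) {
  m <- block_char_matrix(block)
  refcols <- block_ref_columns(block)
  ref_len <- length(refcols)
  species <- rownames(m)
  ref <- block$ref
  ref_has_gap <- length(refcols) != block$width
  sub <- m[, refcols, drop = FALSE]
  species_codes <- matrix(
    encode_dna(as.vector(sub)), nrow = nrow(sub),
    dimnames = list(species, NULL)
  )
  species_codes[sub == "-"] <- 5L  # a gap can never match a base weight
  has_gap <- apply(m == "-", 1, any)
  raw <- {
    refbase <- sub[ref, ]
    member <- sweep(sub, 2, refbase, "==") & sub != "-" & sub != "N"
    member[ref, ] <- TRUE
    induced_lengths(tree_index, member) / tree_index$total
  }
  bins <- bin_conservation(smooth_profile(raw, window))
  allowed <- allowed_base_vector(mask, block$chrom, block$ref_start,
                                 block$ref_end)
  list(
    block = block, m = m, refcols = refcols, ref_len = ref_len,
    species = species, ref = ref,
    species_codes = species_codes,
    species_fast = !has_gap & !ref_has_gap,
    ref_has_gap = ref_has_gap,
    bins = bins, allowed = allowed
  )
}

# Candidate window offsets (1-based reference positions within the block)
# whose reference MATCH score passes the threshold and whose full window
# lies in allowed space. Returns list(offset, strand, score).
block_candidates <- function(bd, wts, threshold) {
  w <- wts$width
  if (bd$ref_len < w) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  codes <- bd$species_codes[bd$ref, ]
  csbad <- c(0L, cumsum(!bd$allowed))
  n <- bd$ref_len - w + 1L
  win_ok <- (csbad[(1:n) + w] - csbad[1:n]) == 0L
  out <- list()
  for (strand in c("+", "-")) {
    W <- if (strand == "+") wts$fwd else wts$rev
    sc <- scan_scores(codes, W, wts$smin, wts$smax)
    hit <- which(sc >= threshold & win_ok)
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        offset = hit, strand = strand, score = sc[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  do.call(rbind, out)
}

#' Species whose aligned sequence matches a motif at a window
#'
#' For a motif window anchored at a reference offset of a block, extracts
#' each species' gapless sequence over the spanned alignment columns and
#' scores it on the given strand. Species whose extracted sequence is not
#' exactly the motif width (due to gaps) or contains `N` are non-matching.
#' The reference species is included when its own score passes.
#'
#' @param block An [alignment_block()].
#' @param pwm A `pwm` object.
#' @param ref_offset 0-based offset of the window start among the block's
#'   reference bases.
#' @param strand `"+"` or `"-"`.
#' @param threshold MATCH threshold (default 0.8).
#' @return Character vector of matching species names.
#' @export
site_species_matches <- function(block, pwm, ref_offset, strand,
                                 threshold = 0.8) {
  w <- pwm$width
  refcols <- block_ref_columns(block)
  if (ref_offset < 0 || ref_offset + w > length(refcols)) {
    stop("motif window outside the block's reference row")
  }
  m <- block_char_matrix(block)
  wts <- pwm_weights(pwm)
  W <- if (strand == "+") wts$fwd else wts$rev
  cols <- refcols[ref_offset + 1L]:refcols[ref_offset + w]
  hits <- character(0)
  for (sp in rownames(m)) {
    chars <- m[sp, cols]
    chars <- chars[chars != "-"]
    if (length(chars) != w || any(!chars %in% c("A", "C", "G", "T"))) next
    sc <- score_at_offsets(encode_dna(chars), W, wts$smin, wts$smax, 1L)
    if (sc >= threshold) hits <- c(hits, sp)
  }
  hits
}

# Vectorised matching-species matrix for many candidate windows of one
# block (rows = candidates, columns = species). Gap-free rows are scored
# with the rolling engine; rows containing gaps fall back to per-window
# extraction.
candidate_match_matrix <- function(bd, wts, cand, threshold) {
  w <- wts$width
  nsp <- length(bd$species)
  res <- matrix(FALSE, nrow = nrow(cand), ncol = nsp,
                dimnames = list(NULL, bd$species))
  if (!nrow(cand)) return(res)
  res[, bd$ref] <- TRUE
  for (strand in unique(cand$strand)) {
    W <- if (strand == "+") wts$fwd else wts$rev
    rows <- which(cand$strand == strand)
    offs <- cand$offset[rows]
    for (sp in bd$species) {
      if (sp == bd$ref) next
      if (bd$species_fast[[sp]]) {
        sc <- score_at_offsets(bd$species_codes[sp, ], W,
                               wts$smin, wts$smax, offs)
        res[rows, sp] <- sc >= threshold
      } else {
        for (k in seq_along(offs)) {
          o <- offs[k]
          cols <- bd$refcols[o]:bd$refcols[o + w - 1L]
          chars <- bd$m[sp, cols]
          chars <- chars[chars != "-"]
          if (length(chars) != w ||
              any(!chars %in% c("A", "C", "G", "T"))) next
          sc <- score_at_offsets(encode_dna(chars), W,
                                 wts$smin, wts$smax, 1L)
          res[rows[k], sp] <- sc >= threshold
        }
      }
    }
  }
  res
}

#' Branch-length conservation (BBL) score of a matching-species set
#'
#' The branch length of the minimal subtree of the phylogeny connecting
#' the species in which the motif match is preserved; 0 when fewer than
#' two species match. This deterministic branch-length score is the
#' conservation statistic compared against the shuffled-motif null.
#'
#' @param tree A `phylo` object.
#' @param matching Character vector of matching species.
#' @param index Optional precomputed [tree_branch_index].
#' @return Branch length in substitutions/site.
#' @export
bbl_score <- function(tree, matching, index = NULL) {
  induced_subtree_length(tree, matching, index = index)
}

#' Draw a usable null motif by column shuffling
#'
#' A column shuffle of a motif with repeated consensus letters can
#' reproduce (or nearly reproduce) the original motif, in which case it
#' is not a null model at all: it would rediscover every real motif
#' instance. Shuffles whose MATCH score against the real motif's
#' consensus sequence (either strand) reaches the detection threshold
#' are therefore rejected and redrawn. If no acceptable shuffle exists
#' after `max_tries` draws (an extremely degenerate motif), the last
#' draw is returned with a warning.
#'
#' @param pwm A `pwm` object.
#' @param seed Integer seed; successive attempts perturb it
#'   deterministically.
#' @param threshold MATCH threshold used by the screen.
#' @param max_tries Maximum redraws.
#' @return A shuffled `pwm`.
#' @export
null_shuffle <- function(pwm, seed = NULL, threshold = 0.8,
                         max_tries = 100L) {
  cons <- pwm_consensus(pwm)
  for (t in seq_len(max_tries)) {
    s <- if (is.null(seed)) NULL else
      (as.integer(seed) + 104729L * (t - 1L)) %% .Machine$integer.max
    sh <- shuffle_columns(pwm, seed = s)
    self <- max(match_score(sh, cons), match_score(sh, revcomp(cons)))
    if (self < threshold) return(sh)
  }
  warning("motif ", pwm$id,
          " has no column shuffle distinct from itself; null may be weak")
  sh
}

#' Build the shuffled-motif null BBL distributions
#'
#' For each motif, a set of column-shuffled null motifs (CpG pairs kept
#' glued) is scanned over the allowed space of the alignment. Every window
#' whose reference sequence matches a shuffled motif at the MATCH
#' threshold contributes its BBL score to the 1% conservation bin of the
#' window's central base; distributions are pooled across shuffles.
#'
#' @param blocks List of [alignment_block()]s.
#' @param tree A `phylo` object.
#' @param pwms List of `pwm` objects.
#' @param mask A [genome_masks()] object.
#' @param n_shuffles Shuffled motifs per real motif (default 10).
#' @param seed Integer seed making the shuffles reproducible.
#' @param threshold MATCH threshold.
#' @param window Conservation smoothing window.
#' @param prepared Optional precomputed list of [prepare_block] results.
#' @return Object of class `tfbs_null`: per motif, 100 per-bin numeric
#'   vectors of null BBL scores.
#' @export
build_null <- function(blocks, tree, pwms, mask, n_shuffles = 10L,
                       seed = NULL, threshold = 0.8, window = 100L,
                       prepared = NULL) {
  index <- tree_branch_index(tree)
  if (is.null(prepared)) {
    prepared <- lapply(blocks, prepare_block, tree_index = index,
                       mask = mask, window = window)
  }
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  motifs <- list()
  for (mi in seq_along(pwms)) {
    pwm <- pwms[[mi]]
    bins <- vector("list", 100L)
    for (b in seq_len(100L)) bins[[b]] <- numeric(0)
    for (s in seq_len(n_shuffles)) {
      sh_seed <- if (is.null(base_seed)) NULL else
        (base_seed + 7919L * mi + s) %% .Machine$integer.max
      sh <- null_shuffle(pwm, seed = sh_seed, threshold = threshold)
      wts <- pwm_weights(sh)
      for (bd in prepared) {
        cand <- block_candidates(bd, wts, threshold)
        if (!nrow(cand)) next
        member <- candidate_match_matrix(bd, wts, cand, threshold)
        bbl <- induced_lengths(index, t(member))
        centre <- cand$offset + (pwm$width - 1L) %/% 2L
        bin <- bd$bins[centre]
        for (k in seq_len(nrow(cand))) {
          bx <- bin[k] + 1L
          bins[[bx]] <- c(bins[[bx]], bbl[k])
        }
      }
    }
    if (sum(lengths(bins)) == 0L) {
      stop("no null observations for motif ", pwm$id,
           ": increase n_shuffles or provide more alignment sequence")
    }
    motifs[[pwm$id]] <- lapply(bins, sort)
  }
  structure(
    list(motifs = motifs, n_shuffles = n_shuffles, threshold = threshold),
    class = "tfbs_null"
  )
}

#' @export
print.tfbs_null <- function(x, ...) {
  n <- vapply(x$motifs, function(b) sum(lengths(b)), numeric(1))
  cat(sprintf("<tfbs_null: %d motif(s), %s null scores (%d shuffles)>\n",
              length(x$motifs), paste(n, collapse = "/"), x$n_shuffles))
  invisible(x)
}

# Null BBL scores for a motif at a conservation bin. Sparse bins borrow
# from the nearest populated bins: the bin radius grows symmetrically
# until at least `min_n` observations are pooled (or the whole
# distribution is used). Errors when the motif has no null scores at all.
null_bin_scores <- function(null, motif_id, bin, min_n = 999L) {
  bins <- null$motifs[[motif_id]]
  if (is.null(bins)) stop("no null distribution for motif ", motif_id)
  counts <- lengths(bins)
  if (sum(counts) == 0L) {
    stop("empty null distribution for motif ", motif_id,
         ": increase n_shuffles or provide more alignment sequence")
  }
  centre <- bin + 1L
  for (r in 0:99) {
    sel <- seq(max(1L, centre - r), min(100L, centre + r))
    if (sum(counts[sel]) >= min_n || length(sel) == 100L ||
        (sel[1] == 1L && sel[length(sel)] == 100L)) {
      got <- unlist(bins[sel], use.names = FALSE)
      if (length(got) >= min_n || sum(counts) <= length(got)) return(got)
    }
  }
  unlist(bins, use.names = FALSE)
}

#' Empirical conservation p-value of a BBL score
#'
#' The probability that a shuffled-motif match in the same conservation
#' bin attains a BBL score at least as large as the observed one, with a
#' +1 pseudocount so the p-value is never exactly zero:
#' `p = (#\{null >= score\} + 1) / (N + 1)`.
#'
#' @param score Observed BBL score.
#' @param null_scores Numeric vector of null BBL scores (non-empty).
#' @return p-value in (0, 1\].
#' @export
empirical_p <- function(score, null_scores) {
  if (length(null_scores) == 0L) stop("empty null bin")
  (sum(null_scores >= score) + 1) / (length(null_scores) + 1)
}

#' Apply the conserved-site retention gates
#'
#' A prediction is retained only when its empirical conservation p-value
#' is at most `p_max`, it is preserved in at least `min_species` species
#' and those species span at least `min_bbl` substitutions/site.
#'
#' @param sites Conserved-site data.frame (columns `empirical_p`,
#'   `n_species`, `bbl`).
#' @param params [screen_params()] list.
#' @return The retained subset of `sites`.
#' @export
filter_conserved_sites <- function(sites, params = screen_params()) {
  keep <- sites$empirical_p <= params$p_max &
    sites$n_species >= params$min_species &
    sites$bbl >= params$min_bbl
  sites[keep, , drop = FALSE]
}

#' Predict conserved transcription factor binding sites
#'
#' Scans the reference rows of the alignment with each real motif over the
#' allowed (non-exon, non-repeat) space, collects the matching-species set
#' and BBL score of every window passing the MATCH threshold, assigns an
#' empirical p-value against the conservation-bin-matched shuffled-motif
#' null, and retains predictions passing all three gates (p-value,
#' species count, branch length).
#'
#' @inheritParams build_null
#' @param null A `tfbs_null` from [build_null()].
#' @param params [screen_params()] list.
#' @return data.frame of conserved sites with 0-based half-open
#'   coordinates: `chrom`, `start`, `end`, `strand`, `motif_id`,
#'   `ref_score`, `bbl`, `n_species`, `bin`, `empirical_p`, `score`
#'   (-log10 p) and `matching_species` (comma-separated).
#' @export
predict_sites <- function(blocks, tree, pwms, mask, null,
                          params = screen_params(), prepared = NULL) {
  index <- tree_branch_index(tree)
  if (is.null(prepared)) {
    prepared <- lapply(blocks, prepare_block, tree_index = index,
                       mask = mask, window = params$smooth_window)
  }
  rows <- list()
  null_cache <- new.env(parent = emptyenv())
  for (pwm in pwms) {
    wts <- pwm_weights(pwm)
    for (bd in prepared) {
      cand <- block_candidates(bd, wts, params$match_threshold)
      if (!nrow(cand)) next
      member <- candidate_match_matrix(bd, wts, cand,
                                       params$match_threshold)
      bbl <- induced_lengths(index, t(member))
      n_species <- rowSums(member)
      centre <- cand$offset + (pwm$width - 1L) %/% 2L
      bin <- bd$bins[centre]
      pvals <- vapply(seq_len(nrow(cand)), function(k) {
        key <- sprintf("%s|%d", pwm$id, bin[k])
        ns <- null_cache[[key]]
        if (is.null(ns)) {
          ns <- null_bin_scores(null, pwm$id, bin[k],
                                min_n = params$min_null)
          null_cache[[key]] <- ns
        }
        empirical_p(bbl[k], ns)
      }, numeric(1))
      start0 <- bd$block$ref_start + cand$offset - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = bd$block$chrom,
        start = start0,
        end = start0 + pwm$width,
        strand = cand$strand,
        motif_id = pwm$id,
        ref_score = cand$score,
        bbl = bbl,
        n_species = as.integer(n_species),
        bin = as.integer(bin),
        empirical_p = pvals,
        score = -log10(pvals),
        matching_species = vapply(seq_len(nrow(cand)), function(k) {
          paste(bd$species[member[k, ]], collapse = ",")
        }, character(1)),
        stringsAsFactors = FALSE
      )
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else empty_sites()
  sites <- filter_conserved_sites(sites, params)
  sites <- sites[order(sites$chrom, sites$start, sites$end, sites$strand,
                       sites$motif_id), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

empty_sites <- function() {
  data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), motif_id = character(0), ref_score = numeric(0),
    bbl = numeric(0), n_species = integer(0), bin = integer(0),
    empirical_p = numeric(0), score = numeric(0),
    matching_species = character(0), stringsAsFactors = FALSE
  )
}
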