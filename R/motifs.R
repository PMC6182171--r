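#' Construct a position weight matrix motif
#'
#' Columns are per-position base frequency vectors over A, C, G, T. Counts
#' or frequencies are accepted; a pseudocount is added to every cell and
#' columns renormalised so all frequencies are strictly positive (an
#' all-zero column becomes uniform). Adjacent CpG column pairs (consensus C
#' followed by consensus G) are annotated so that column shuffling can keep
#' them glued, preserving CpG dinucleotide structure in null motifs.
#'
#' @param mat 4-row numeric matrix (rows A, C, G, T) of counts or
#'   frequencies.
#' @param id Motif identifier.
#' @param name Optional transcription factor name.
#' @param pseudocount Value added to each cell before renormalisation
#'   (default 0.001).
#' @param cpg_pairs Optional integer vector of left indices of CpG column
#'   pairs, overriding consensus-based auto-annotation.
#' @return Object of class `pwm`.
#' @export
pwm_motif <- function(mat, id, name = id, pseudocount = 0.001,
                      cpg_pairs = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("motif matrix must have 4 rows (A, C, G, T)")
  if (any(mat < 0)) stop("negative motif counts")
  if (any(!is.finite(mat))) stop("non-finite motif counts")
  rownames(mat) <- c("A", "C", "G", "T")
  sums <- colSums(mat)
  freq <- mat
  pos <- sums > 0
  freq[, pos] <- sweep(mat[, pos, drop = FALSE], 2, sums[pos], "/")
  freq <- freq + pseudocount
  freq <- sweep(freq, 2, colSums(freq), "/")
  if (is.null(cpg_pairs)) {
    cons <- rownames(freq)[apply(freq, 2, which.max)]
    cpg_pairs <- integer(0)
    i <- 1L
    while (i < ncol(freq)) {
      if (cons[i] == "C" && cons[i + 1L] == "G") {
        cpg_pairs <- c(cpg_pairs, i)
        i <- i + 2L  # pairs must not overlap
      } else {
        i <- i + 1L
      }
    }
  } else {
    cpg_pairs <- as.integer(cpg_pairs)
    if (any(cpg_pairs < 1L) || any(cpg_pairs >= ncol(freq))) {
      stop("cpg_pairs out of range")
    }
    if (any(diff(sort(cpg_pairs)) < 2L)) stop("cpg_pairs overlap")
  }
  structure(
    list(id = id, name = name, mat = freq, width = ncol(freq),
         cpg_pairs = cpg_pairs),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm %s (%s), width %d, consensus %s>\n",
              x$id, x$name, x$width, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a motif (argmax base per column)
#' @param pwm A `pwm` object.
#' @return Character string.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$mat)[apply(pwm$mat, 2, which.max)], collapse = "")
}

#' Read a motif library
#'
#' Supports two common text dialects: JASPAR (4 base-labelled rows per
#' motif, `>` headers, optional brackets) and TRANSFAC-like
#' (column-per-line blocks introduced by a `P0 A C G T` header inside
#' `ID`/`//` records).
#'
#' @param path Path to the motif text file.
#' @param dialect `"jaspar"` or `"transfac"`.
#' @param pseudocount Passed to [pwm_motif()].
#' @return List of `pwm` objects.
#' @export
read_motifs <- function(path, dialect = c("jaspar", "transfac"),
                        pseudocount = 0.001) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "jaspar") read_jaspar(lines, pseudocount)
  else read_transfac(lines, pseudocount)
}

read_jaspar <- function(lines, pseudocount) {
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no '>' motif headers found")
  bounds <- c(heads, length(lines) + 1L)
  out <- list()
  for (i in seq_along(heads)) {
    hdr <- strsplit(sub("^>\\s*", "", lines[heads[i]]), "[[:space:]]+")[[1]]
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4L) stop("JASPAR motif must have 4 matrix rows")
    rows <- lapply(body, function(ln) {
      ln <- gsub("[][]", " ", ln)
      parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      if (parts[1] %in% c("A", "C", "G", "T")) parts <- parts[-1]
      vals <- suppressWarnings(as.numeric(parts))
      if (anyNA(vals)) stop("non-numeric motif matrix entry")
      vals
    })
    if (length(unique(lengths(rows))) != 1L) {
      stop("JASPAR motif rows of unequal width")
    }
    mat <- do.call(rbind, rows)
    out[[i]] <- pwm_motif(mat, id = hdr[1],
                          name = if (length(hdr) > 1) hdr[2] else hdr[1],
                          pseudocount = pseudocount)
  }
  stats::setNames(out, vapply(out, `[[`, character(1), "id"))
}

read_transfac <- function(lines, pseudocount) {
  out <- list()
  id <- NULL; name <- NULL; mat_rows <- list(); in_matrix <- FALSE
  flush <- function() {
    if (is.null(id) && length(mat_rows) == 0L) return(NULL)
    if (length(mat_rows) == 0L) stop("TRANSFAC record without matrix: ", id)
    mat <- t(do.call(rbind, mat_rows))
    pwm_motif(mat, id = id %||% "motif", name = name %||% id %||% "motif",
              pseudocount = pseudocount)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (grepl("^ID\\b", ln)) {
      id <- strsplit(ln, "[[:space:]]+")[[1]][2]
    } else if (grepl("^NA\\b", ln)) {
      name <- strsplit(ln, "[[:space:]]+")[[1]][2]
    } else if (grepl("^P0\\b", ln) || grepl("^PO\\b", ln)) {
      hdr <- strsplit(ln, "[[:space:]]+")[[1]][-1]
      if (!identical(toupper(hdr[1:4]), c("A", "C", "G", "T"))) {
        stop("TRANSFAC P0 header must order columns A C G T")
      }
      in_matrix <- TRUE
    } else if (grepl("^[0-9]+\\b", ln) && in_matrix) {
      parts <- strsplit(ln, "[[:space:]]+")[[1]]
      vals <- suppressWarnings(as.numeric(parts[2:5]))
      if (anyNA(vals)) stop("TRANSFAC matrix line not length 4: ", ln)
      mat_rows[[length(mat_rows) + 1L]] <- vals
    } else if (grepl("^//", ln)) {
      m <- flush()
      if (!is.null(m)) out[[length(out) + 1L]] <- m
      id <- NULL; name <- NULL; mat_rows <- list(); in_matrix <- FALSE
    }
  }
  m <- flush()
  if (!is.null(m)) out[[length(out) + 1L]] <- m
  stats::setNames(out, vapply(out, `[[`, character(1), "id"))
}

#' Write motifs in JASPAR text format
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @param digits Significant digits for frequencies.
#' @return `path`, invisibly.
#' @export
write_motifs_jaspar <- function(pwms, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(signif(p$mat[b, ], digits), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Information content weight of each motif column
#'
#' `I(i) = sum_b f(i,b) * log2(4 f(i,b))` with the convention
#' `0 * log 0 = 0`; ranges from 0 (uniform column) to 2 bits (single
#' base). These weights emphasise informative columns in MATCH scoring.
#'
#' @param mat A `pwm` object or bare 4-row frequency matrix.
#' @return Numeric vector of per-column weights.
#' @export
information_weights <- function(mat) {
  if (inherits(mat, "pwm")) mat <- mat$mat
  lg <- ifelse(mat > 0, log2(4 * mat), 0)
  colSums(mat * lg)
}

#' MATCH similarity score of a sequence against a motif
#'
#' The information-weighted matrix similarity score
#' `S = sum_i I(i) f(i, b_i)`, min-max normalised per motif to
#' `(S - Smin) / (Smax - Smin)` so the consensus sequence scores 1 and the
#' anti-consensus 0. Sequences containing `N` score 0 by convention; a
#' degenerate motif with `Smax == Smin` also scores 0.
#'
#' @param pwm A `pwm` object.
#' @param seq DNA string of exactly the motif width.
#' @return Score in \[0, 1\].
#' @export
match_score <- function(pwm, seq) {
  stopifnot(inherits(pwm, "pwm"), is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(chars) != pwm$width) {
    stop("sequence length ", length(chars), " != motif width ", pwm$width)
  }
  if (!all(chars %in% c("A", "C", "G", "T"))) return(0)
  iw <- information_weights(pwm)
  f <- pwm$mat[cbind(match(chars, rownames(pwm$mat)), seq_len(pwm$width))]
  s <- sum(iw * f)
  smin <- sum(iw * apply(pwm$mat, 2, min))
  smax <- sum(iw * apply(pwm$mat, 2, max))
  if (smax <= smin) return(0)
  (s - smin) / (smax - smin)
}

#' Shuffle motif columns, preserving CpG pairs
#'
#' Produces a null-model motif whose columns are a random permutation of
#' the input columns in which every annotated CpG pair stays adjacent and
#' in C-then-G order. The multiset of columns is unchanged, so base
#' composition and information content are preserved while positional
#' structure is destroyed.
#'
#' @param pwm A `pwm` object.
#' @param seed Optional integer seed for a reproducible shuffle (the
#'   caller's RNG stream is left untouched).
#' @return A new `pwm` object.
#' @export
shuffle_columns <- function(pwm, seed = NULL) {
  units <- list()
  i <- 1L
  while (i <= pwm$width) {
    if (i %in% pwm$cpg_pairs) {
      units[[length(units) + 1L]] <- c(i, i + 1L)
      i <- i + 2L
    } else {
      units[[length(units) + 1L]] <- i
      i <- i + 1L
    }
  }
  perm <- with_seed(seed, sample(length(units)))
  ord <- unlist(units[perm])
  newmat <- pwm$mat[, ord, drop = FALSE]
  # recover CpG pair positions in the shuffled motif
  sizes <- lengths(units)[perm]
  starts <- cumsum(c(1L, sizes[-length(sizes)]))
  new_pairs <- starts[sizes == 2L]
  out <- pwm
  out$mat <- newmat
  out$cpg_pairs <- as.integer(new_pairs)
  out
}

#' Scan a sequence for motif matches on both strands
#'
#' Scores every window of motif width on the forward sequence and (via the
#' reverse complement) the reverse strand, reporting windows whose MATCH
#' score reaches the threshold. Offsets are 0-based window starts on the
#' given (forward) sequence for both strands.
#'
#' @param pwm A `pwm` object.
#' @param seq DNA string to scan.
#' @param threshold Minimum MATCH score (default 0.8).
#' @param strands Strands to scan, subset of `c("+", "-")`.
#' @return data.frame with `offset` (0-based), `strand`, `score`.
#' @export
scan_window <- function(pwm, seq, threshold = 0.8, strands = c("+", "-")) {
  codes <- encode_dna(seq)
  w <- pwm_weights(pwm)
  out <- list()
  if (length(codes) >= pwm$width) {
    if ("+" %in% strands) {
      sc <- scan_scores(codes, w$fwd, w$smin, w$smax)
      hit <- which(sc >= threshold)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          offset = hit - 1L, strand = "+", score = sc[hit])
      }
    }
    if ("-" %in% strands) {
      sc <- scan_scores(codes, w$rev, w$smin, w$smax)
      hit <- which(sc >= threshold)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          offset = hit - 1L, strand = "-", score = sc[hit])
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$offset, res$strand), , drop = FALSE]
}
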