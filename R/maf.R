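#' Construct an alignment block
#'
#' A reference-anchored gapped alignment block: one row per species over the
#' alphabet `A,C,G,T,N,-`, all rows the same column count, with 0-based
#' half-open reference coordinates on the forward strand.
#'
#' @param chrom Reference chromosome name.
#' @param ref_start 0-based reference start of the block.
#' @param rows Named character vector of gapped row sequences; names are
#'   species, the first element is the reference species.
#' @param ref Reference species name (defaults to the first row).
#' @param row_start,row_size,row_strand,row_src_size Optional per-row source
#'   coordinates as in MAF `s` lines (named vectors); reconstructed
#'   defaults are used when omitted.
#' @return An object of class `alignment_block`.
#' @export
alignment_block <- function(chrom, ref_start, rows, ref = names(rows)[1],
                            row_start = NULL, row_size = NULL,
                            row_strand = NULL, row_src_size = NULL) {
  stopifnot(is.character(rows), length(rows) >= 1L, !is.null(names(rows)))
  if (anyDuplicated(names(rows))) stop("duplicate species in block")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment block: rows have unequal column counts")
  }
  if (!ref %in% names(rows)) stop("reference species not among rows")
  ungapped <- vapply(rows, function(s) nchar(gsub("-", "", s, fixed = TRUE)),
                     integer(1))
  if (is.null(row_size)) row_size <- ungapped
  if (is.null(row_start)) {
    row_start <- stats::setNames(rep(0L, length(rows)), names(rows))
    row_start[ref] <- as.integer(ref_start)
  }
  if (is.null(row_strand)) {
    row_strand <- stats::setNames(rep("+", length(rows)), names(rows))
  }
  if (is.null(row_src_size)) {
    row_src_size <- stats::setNames(rep(NA_integer_, length(rows)),
                                    names(rows))
  }
  structure(
    list(
      chrom = chrom,
      ref_start = as.integer(ref_start),
      ref_end = as.integer(ref_start) + ungapped[[ref]],
      width = widths[[1]],
      ref = ref,
      rows = rows,
      row_start = row_start,
      row_size = row_size,
      row_strand = row_strand,
      row_src_size = row_src_size
    ),
    class = "alignment_block"
  )
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("<alignment_block %s:%d-%d, %d species, %d columns>\n",
              x$chrom, x$ref_start, x$ref_end, length(x$rows), x$width))
  invisible(x)
}

#' Species present in a set of alignment blocks
#' @param blocks List of `alignment_block`s.
#' @return Character vector of species names.
#' @export
alignment_species <- function(blocks) {
  unique(unlist(lapply(blocks, function(b) names(b$rows))))
}

#' Read a MAF multiple alignment
#'
#' Parses the standard `a`/`s`-line MAF dialect. Species names are taken as
#' the part of the `s`-line source before the first dot (`species.chrom`).
#' The first `s` line of each block is the reference row; blocks whose
#' reference row is on the minus strand are normalised to the forward
#' strand (all rows reverse-complemented, coordinates flipped). Reference
#' coordinates are exposed 0-based half-open.
#'
#' @param path Path to a MAF file.
#' @return List of [alignment_block()]s in file order.
#' @export
read_maf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  blocks <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || length(cur) == 0L) return(NULL)
    parse_maf_block(cur)
  }
  for (ln in lines) {
    if (grepl("^a( |$)", ln)) {
      b <- flush(cur)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      cur <- character(0)
    } else if (grepl("^s ", ln)) {
      if (is.null(cur)) stop("MAF 's' line before any 'a' line")
      cur <- c(cur, ln)
    }
    # i/q/e lines and blanks are ignored
  }
  b <- flush(cur)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}

parse_maf_block <- function(slines) {
  fields <- strsplit(trimws(slines), "[[:space:]]+")
  bad <- vapply(fields, length, integer(1)) != 7L
  if (any(bad)) stop("malformed MAF 's' line: ", slines[which(bad)[1]])
  src <- vapply(fields, `[[`, character(1), 2)
  start <- as.integer(vapply(fields, `[[`, character(1), 3))
  size <- as.integer(vapply(fields, `[[`, character(1), 4))
  strand <- vapply(fields, `[[`, character(1), 5)
  src_size <- as.integer(vapply(fields, `[[`, character(1), 6))
  text <- vapply(fields, `[[`, character(1), 7)
  if (!all(strand %in% c("+", "-"))) {
    stop("unknown strand code in MAF block: ",
         paste(setdiff(strand, c("+", "-")), collapse = ","))
  }
  species <- sub("\\..*$", "", src)
  chrom <- sub("^[^.]*\\.", "", src)
  if (length(unique(nchar(text))) != 1L) {
    stop("ragged MAF block: rows of unequal length")
  }
  if (strand[1] == "-") {
    # normalise to reference forward strand
    text <- revcomp(text)
    start <- src_size - start - size
    strand <- chartr("+-", "-+", strand)
    strand[1] <- "+"
  }
  alignment_block(
    chrom = chrom[1],
    ref_start = start[1],
    rows = stats::setNames(text, species),
    ref = species[1],
    row_start = stats::setNames(start, species),
    row_size = stats::setNames(size, species),
    row_strand = stats::setNames(strand, species),
    row_src_size = stats::setNames(src_size, species)
  )
}

#' Write alignment blocks as MAF
#'
#' @param blocks List of [alignment_block()]s.
#' @param path Output file path.
#' @param chroms Optional named vector giving each non-reference species'
#'   chromosome name (defaults to the reference chromosome).
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path, chroms = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("a score=0.0", con)
    for (sp in names(b$rows)) {
      chrom <- if (!is.null(chroms) && sp %in% names(chroms)) {
        chroms[[sp]]
      } else {
        b$chrom
      }
      writeLines(sprintf(
        "s %s.%s %d %d %s %d %s",
        sp, chrom, b$row_start[[sp]], b$row_size[[sp]], b$row_strand[[sp]],
        if (is.na(b$row_src_size[[sp]])) b$row_size[[sp]] else b$row_src_size[[sp]],
        b$rows[[sp]]
      ), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

# Split block rows into a species-by-column character matrix (cached
# implicitly by callers that need it repeatedly).
block_char_matrix <- function(block) {
  m <- do.call(rbind, strsplit(toupper(unname(block$rows)), "", fixed = TRUE))
  rownames(m) <- names(block$rows)
  m
}

# Column indices (1-based within the block) of the reference row's
# non-gap positions.
block_ref_columns <- function(block) {
  which(strsplit(block$rows[[block$ref]], "", fixed = TRUE)[[1]] != "-")
}
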