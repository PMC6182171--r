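#' Read a BED3 file
#'
#' @param path Path to a BED file (first three columns used; comment and
#'   track lines ignored). Coordinates remain 0-based half-open.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "[[:space:]]+")
  df <- data.frame(
    chrom = vapply(fields, `[[`, character(1), 1),
    start = as.integer(vapply(fields, `[[`, character(1), 2)),
    end = as.integer(vapply(fields, `[[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
  if (any(df$end < df$start)) stop("BED interval with end < start in ", path)
  df
}

#' Write a BED3 data.frame
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome sizes file
#' @param path Path to a `chrom<TAB>size` text file.
#' @return Named integer vector of chromosome sizes.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("chrom", "size"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$size), df$chrom)
}

#' Assemble genomic masks and the allowed search space
#'
#' Binding-site prediction is restricted to regions of the reference genome
#' containing neither an exon nor a repeat element; the allowed space is
#' the complement of their union. Assembly gaps are kept separately and
#' used when discarding erosion calls.
#'
#' @param chrom_sizes Named vector of chromosome sizes.
#' @param exons,repeats,gaps BED data.frames (0-based half-open) or `NULL`.
#' @return Object of class `genome_mask` with `exons`, `repeats`, `gaps`
#'   and `allowed` GRanges plus `chrom_sizes`.
#' @export
genome_masks <- function(chrom_sizes, exons = NULL, repeats = NULL,
                         gaps = NULL) {
  stopifnot(!is.null(names(chrom_sizes)))
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  as_gr <- function(df) {
    df <- df %||% empty
    if (nrow(df)) {
      if (!all(df$chrom %in% names(chrom_sizes))) {
        stop("mask interval on unknown chromosome")
      }
      if (any(df$start < 0) ||
          any(df$end > chrom_sizes[df$chrom])) {
        stop("mask interval outside chromosome bounds")
      }
    }
    GenomicRanges::reduce(bed_to_gr(df))
  }
  ex <- as_gr(exons)
  rp <- as_gr(repeats)
  gp <- as_gr(gaps)
  genome <- GenomicRanges::GRanges(
    names(chrom_sizes),
    IRanges::IRanges(1L, unname(as.integer(chrom_sizes)))
  )
  allowed <- GenomicRanges::setdiff(genome, GenomicRanges::union(ex, rp))
  structure(
    list(exons = ex, repeats = rp, gaps = gp, allowed = allowed,
         chrom_sizes = chrom_sizes),
    class = "genome_mask"
  )
}

#' @export
print.genome_mask <- function(x, ...) {
  cat(sprintf(
    "<genome_mask %d chrom(s); allowed %d bp of %d bp (%.1f%%)>\n",
    length(x$chrom_sizes),
    sum(GenomicRanges::width(x$allowed)),
    sum(as.numeric(x$chrom_sizes)),
    100 * sum(GenomicRanges::width(x$allowed)) / sum(as.numeric(x$chrom_sizes))
  ))
  invisible(x)
}

# Logical vector over [start, end) on `chrom`: TRUE where the base lies in
# the allowed space of `mask`.
allowed_base_vector <- function(mask, chrom, start, end) {
  n <- end - start
  out <- logical(n)
  hit <- GenomicRanges::restrict(
    x = mask$allowed[GenomicRanges::seqnames(mask$allowed) == chrom],
    start = start + 1L, end = end
  )
  if (length(hit)) {
    for (i in seq_along(hit)) {
      out[(GenomicRanges::start(hit)[i] - start):(GenomicRanges::end(hit)[i] - start)] <- TRUE
    }
  }
  out
}
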