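# GREAT-style basal-plus-extension region/gene enrichment.

#' Read a gene-model table
#'
#' Expects a BED-like TSV with columns `chrom`, `tss`, `strand`,
#' `gene_id` (header optional); `tss` is the 0-based canonical
#' transcription start position.
#'
#' @param path File path.
#' @return data.frame with `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_genes <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("gene_id", first)
  df <- utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!header) names(df) <- c("chrom", "tss", "strand", "gene_id")[seq_along(df)]
  df$tss <- as.integer(df$tss)
  df[, c("gene_id", "chrom", "tss", "strand")]
}

#' Read a GMT gene-set file
#' @param path GMT path (`term_id<TAB>name<TAB>gene1<TAB>gene2...`).
#' @return data.frame with `term_id`, `name` and a `genes` list-column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    term_id = vapply(fields, `[[`, character(1), 1),
    name = vapply(fields, `[[`, character(1), 2),
    genes = I(lapply(fields, function(f) unique(f[-(1:2)]))),
    stringsAsFactors = FALSE
  )
}

#' Write gene sets as GMT
#' @param terms data.frame as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(seq_len(nrow(terms)), function(i) {
    paste(c(terms$term_id[i], terms$name[i], terms$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Build basal-plus-extension regulatory domains
#'
#' Each gene receives a strand-aware basal domain (`basal_up` bases
#' upstream and `basal_down` downstream of the TSS; default 5 kb / 1 kb)
#' clipped to its chromosome, then an extended domain grown in each
#' direction by up to `max_extension` (default 1 Mb) but stopping at the
#' nearest neighbouring basal domain boundary and never shrinking below
#' its own basal domain.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `tss` (0-based),
#'   `strand`.
#' @param chrom_sizes Named vector of chromosome sizes.
#' @param basal_up,basal_down,max_extension Rule distances in bases.
#' @return data.frame with basal and extended 0-based half-open intervals
#'   per gene.
#' @export
build_domains <- function(genes, chrom_sizes, basal_up = 5000L,
                          basal_down = 1000L, max_extension = 1000000L) {
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (!all(genes$chrom %in% names(chrom_sizes))) {
    stop("gene on unknown chromosome")
  }
  if (any(genes$tss < 0) || any(genes$tss >= chrom_sizes[genes$chrom])) {
    stop("TSS outside chromosome bounds")
  }
  plus <- genes$strand == "+"
  basal_start <- ifelse(plus, genes$tss - basal_up, genes$tss - basal_down)
  basal_end <- ifelse(plus, genes$tss + basal_down, genes$tss + basal_up)
  basal_start <- pmax(0L, as.integer(basal_start))
  basal_end <- pmin(unname(chrom_sizes[genes$chrom]), as.integer(basal_end))
  out <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, tss = genes$tss,
    strand = genes$strand, basal_start = basal_start,
    basal_end = basal_end, ext_start = basal_start, ext_end = basal_end,
    stringsAsFactors = FALSE
  )
  for (ch in unique(out$chrom)) {
    sel <- which(out$chrom == ch)
    sel <- sel[order(out$tss[sel])]
    bs <- out$basal_start[sel]; be <- out$basal_end[sel]
    n <- length(sel)
    prev_max_end <- c(-Inf, cummax(be))[seq_len(n)]
    next_min_start <- rev(c(Inf, cummin(rev(bs))))[-1L]
    ext_start <- pmax(bs - max_extension,
                      pmin(prev_max_end, bs), 0)
    ext_end <- pmin(be + max_extension,
                    pmax(next_min_start, be),
                    unname(chrom_sizes[ch]))
    out$ext_start[sel] <- as.integer(ext_start)
    out$ext_end[sel] <- as.integer(ext_end)
  }
  out
}

#' Associate regions with genes through regulatory domains
#'
#' A region is associated with every gene whose extended regulatory
#' domain contains the region's midpoint.
#'
#' @param regions BED-like data.frame (`chrom`, `start`, `end`).
#' @param domains [build_domains()] output.
#' @return data.frame with `region` (row index into `regions`) and
#'   `gene_id`, one row per association.
#' @export
associate_regions <- function(regions, domains) {
  if (!nrow(regions)) {
    return(data.frame(region = integer(0), gene_id = character(0)))
  }
  mid <- (regions$start + regions$end) %/% 2L
  q <- GenomicRanges::GRanges(regions$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
  d <- GenomicRanges::GRanges(domains$chrom,
                              IRanges::IRanges(domains$ext_start + 1L,
                                               domains$ext_end))
  ov <- GenomicRanges::findOverlaps(q, d)
  data.frame(
    region = S4Vectors::queryHits(ov),
    gene_id = domains$gene_id[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE
  )
}

#' Region-based binomial enrichment test
#'
#' Each query region is a Bernoulli trial with success probability equal
#' to the fraction of the genome annotated with the term; the p-value is
#' the upper binomial tail `P(X >= k)` and the fold enrichment is
#' `k / (n p)`.
#'
#' @param n Number of query regions.
#' @param k Number of regions hitting the term.
#' @param p Term's annotated genome fraction.
#' @return List with `p_value` and `fold`.
#' @export
binomial_region_test <- function(n, k, p) {
  if (p < 0 || p > 1) stop("genome fraction must be in [0, 1]")
  if (p == 0 && k > 0) stop("term hits with zero genome fraction")
  p_value <- if (k <= 0) 1 else stats::pbinom(k - 1, n, p,
                                              lower.tail = FALSE)
  fold <- if (p > 0 && n > 0) k / (n * p) else NA_real_
  list(p_value = p_value, fold = fold)
}

#' Gene-based hypergeometric enrichment test
#'
#' Upper-tail hypergeometric probability of observing at least `k` term
#' genes among the `n` genes hit by the query regions, drawn from a
#' universe of `N` genes of which `K` carry the term.
#'
#' @param N Universe size.
#' @param K Term gene count within the universe.
#' @param n Number of distinct genes hit by regions.
#' @param k Number of term genes hit.
#' @return p-value.
#' @export
hypergeom_gene_test <- function(N, K, n, k) {
  if (K > N || n > N || k > min(K, n)) stop("inconsistent counts")
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Step-up BH q-values, monotone in p-rank.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' GREAT-style enrichment of a region set over an ontology
#'
#' Builds regulatory domains, associates regions to genes by midpoint,
#' and for every ontology term computes the region-based binomial test
#' (against the term's annotated genome fraction) and the gene-based
#' hypergeometric test, with BH correction across the tested terms. Terms
#' are tested only when their gene set intersected with the universe (all
#' genes with domains) has between `min_term_genes` and `max_term_genes`
#' members.
#'
#' @param regions BED-like data.frame of query regions.
#' @param genes Gene models (see [build_domains()]).
#' @param terms Ontology data.frame ([read_gmt()] layout).
#' @param chrom_sizes Named chromosome sizes.
#' @param params [screen_params()] list.
#' @return data.frame of per-term results (one row per tested term).
#' @export
great_enrichment <- function(regions, genes, terms, chrom_sizes,
                             params = screen_params()) {
  domains <- build_domains(genes, chrom_sizes,
                           basal_up = params$basal_up,
                           basal_down = params$basal_down,
                           max_extension = params$max_extension)
  assoc <- associate_regions(regions, domains)
  genome_size <- sum(as.numeric(chrom_sizes))
  n_regions <- nrow(regions)
  universe <- domains$gene_id
  hit_genes <- unique(assoc$gene_id)
  dom_gr <- GenomicRanges::GRanges(
    domains$chrom, IRanges::IRanges(domains$ext_start + 1L, domains$ext_end))
  names(dom_gr) <- domains$gene_id
  keep <- vapply(terms$genes, function(g) {
    ng <- length(intersect(g, universe))
    ng >= params$min_term_genes && ng <= params$max_term_genes
  }, logical(1))
  tested <- terms[keep, , drop = FALSE]
  res <- lapply(seq_len(nrow(tested)), function(i) {
    tg <- intersect(tested$genes[[i]], universe)
    frac <- sum(GenomicRanges::width(GenomicRanges::reduce(
      dom_gr[names(dom_gr) %in% tg]))) / genome_size
    region_hits <- sum(vapply(split(assoc$gene_id, assoc$region),
                              function(g) any(g %in% tg), logical(1)))
    bt <- binomial_region_test(n_regions, region_hits, frac)
    k_genes <- length(intersect(hit_genes, tg))
    hp <- hypergeom_gene_test(length(universe), length(tg),
                              length(hit_genes), k_genes)
    data.frame(
      term_id = tested$term_id[i], name = tested$name[i],
      n_term_genes = length(tg), n_regions = n_regions,
      region_hits = region_hits, genome_frac = frac, fold = bt$fold,
      binom_p = bt$p_value, n_hit_genes = length(hit_genes),
      term_gene_hits = k_genes, hyper_p = hp,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(res)) do.call(rbind, res) else data.frame()
  if (nrow(out)) {
    out$region_q <- bh_fdr(out$binom_p)
    out$gene_q <- bh_fdr(out$hyper_p)
  }
  out
}

#' Rank significantly enriched terms
#'
#' Applies the published significance gates — region-based fold
#' enrichment of at least `fold_min` and FDR at most `q_max` on both the
#' region-based and gene-based tests — and sorts the survivors by
#' region-based q-value (ties broken by larger fold).
#'
#' @param results [great_enrichment()] output.
#' @param params [screen_params()] list.
#' @return Filtered, sorted data.frame with a `significant` column.
#' @export
rank_terms <- function(results, params = screen_params()) {
  if (!nrow(results)) return(results)
  sig <- results$fold >= params$fold_min &
    results$region_q <= params$q_max &
    results$gene_q <= params$q_max
  out <- results[sig, , drop = FALSE]
  out <- out[order(out$region_q, -out$fold), , drop = FALSE]
  out$significant <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
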