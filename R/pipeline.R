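# End-to-end orchestration of the screen, plus file-based stages backing
# the command-line interface.

#' Run the full independently-eroded-binding-site screen
#'
#' Chains every stage of the method: build the shuffled-motif null,
#' predict conserved binding sites, call eroded sites per target lineage
#' against its outgroups, intersect the lineages into independently
#' eroded sites, rank the top-k (with ties) and remove overlaps, tabulate
#' erosion mechanisms, run GREAT-style enrichment over the ontology, and
#' run the permutation overlap test against the feature track.
#'
#' @param world A [generate_world()] world; or `NULL` to pass components
#'   explicitly.
#' @param blocks,tree,pwms,mask,outgroup_spec,genes,terms,features,chrom_sizes
#'   Individual inputs (ignored when `world` is given). `outgroup_spec`
#'   is a named list: target species -> character vector of outgroups.
#' @param gaps Optional assembly-gap BED data.frame.
#' @param params [screen_params()] list.
#' @param seed Integer seed driving the motif shuffles and permutations.
#' @param with_permutation Run the permutation overlap test stage
#'   (default `TRUE`; skipping it saves time when only the enrichment
#'   ranking is of interest).
#' @return List with `null`, `conserved`, `eroded` (named per-target
#'   list), `independent`, `top`, `mech_table`, `enrichment`,
#'   `ranked_terms`, `permtest`, `params`.
#' @export
erosion_screen <- function(world = NULL, blocks = NULL, tree = NULL,
                           pwms = NULL, mask = NULL, outgroup_spec = NULL,
                           genes = NULL, terms = NULL, features = NULL,
                           chrom_sizes = NULL, gaps = NULL,
                           params = screen_params(), seed = 1L,
                           with_permutation = TRUE) {
  if (!is.null(world)) {
    blocks <- world$blocks; tree <- world$tree; pwms <- world$pwms
    mask <- world$mask; outgroup_spec <- world$outgroup_spec
    genes <- genes %||% world$genes; terms <- terms %||% world$terms
    features <- features %||% world$features
    chrom_sizes <- chrom_sizes %||% world$chrom_sizes
  }
  stopifnot(!is.null(blocks), !is.null(tree), !is.null(pwms),
            !is.null(mask), !is.null(outgroup_spec))
  index <- tree_branch_index(tree)
  prepared <- lapply(blocks, prepare_block, tree_index = index,
                     mask = mask, window = params$smooth_window)
  null <- build_null(blocks, tree, pwms, mask,
                     n_shuffles = params$n_shuffles, seed = seed,
                     threshold = params$match_threshold,
                     window = params$smooth_window, prepared = prepared)
  conserved <- predict_sites(blocks, tree, pwms, mask, null,
                             params = params, prepared = prepared)
  eroded <- lapply(names(outgroup_spec), function(tg) {
    call_eroded(conserved, tg, outgroup_spec[[tg]], tree, blocks,
                gaps = gaps)
  })
  names(eroded) <- names(outgroup_spec)
  independent <- intersect_independent(eroded)
  top <- dedup_overlaps(rank_top_k(independent, k = params$top_k))
  mech <- mechanism_table(top)
  enrichment <- ranked <- data.frame()
  if (!is.null(genes) && !is.null(terms) && !is.null(chrom_sizes)) {
    enrichment <- great_enrichment(top, genes, terms, chrom_sizes,
                                   params = params)
    ranked <- rank_terms(enrichment, params = params)
  }
  permtest <- NULL
  if (with_permutation && !is.null(features) && nrow(top)) {
    permtest <- permutation_overlap_test(
      top, features, mask$allowed, m = params$n_permutations,
      seed = if (is.null(seed)) NULL else seed + 1L)
  }
  list(null = null, conserved = conserved, eroded = eroded,
       independent = independent, top = top, mech_table = mech,
       enrichment = enrichment, ranked_terms = ranked,
       permtest = permtest, params = params)
}

## ---- file-based stage runner (CLI backend) -------------------------------

write_tsv <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    flat <- vapply(params, function(v) paste(format(v), collapse = ","),
                   character(1))
    writeLines(sprintf("# %s=%s", names(flat), flat), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

write_null_tsv <- function(null, path) {
  rows <- list()
  for (mid in names(null$motifs)) {
    bins <- null$motifs[[mid]]
    for (b in seq_along(bins)) {
      if (length(bins[[b]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif_id = mid, bin = b - 1L, bbl = bins[[b]])
      }
    }
  }
  write_tsv(do.call(rbind, rows), path,
            params = list(n_shuffles = null$n_shuffles,
                          threshold = null$threshold))
  invisible(path)
}

read_null_tsv <- function(path) {
  df <- read_tsv(path)
  motifs <- lapply(split(df, df$motif_id), function(d) {
    bins <- vector("list", 100L)
    for (b in seq_len(100L)) bins[[b]] <- numeric(0)
    for (bb in unique(d$bin)) {
      bins[[bb + 1L]] <- sort(d$bbl[d$bin == bb])
    }
    bins
  })
  structure(list(motifs = motifs, n_shuffles = NA_integer_,
                 threshold = NA_real_),
            class = "tfbs_null")
}

stage_inputs <- function(config, needed) {
  miss <- needed[!vapply(needed, function(k) {
    !is.null(config[[k]]) && file.exists(config[[k]])
  }, logical(1))]
  if (length(miss)) {
    stop("missing input file(s) for stage: ",
         paste(sprintf("%s (%s)", miss,
                       vapply(miss, function(k)
                         config[[k]] %||% "unset", character(1))),
               collapse = ", "))
  }
}

load_screen_inputs <- function(config) {
  stage_inputs(config, c("maf", "tree", "motifs", "chrom_sizes"))
  chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
  mask <- genome_masks(
    chrom_sizes,
    exons = if (!is.null(config$exons)) read_bed(config$exons),
    repeats = if (!is.null(config$repeats)) read_bed(config$repeats),
    gaps = if (!is.null(config$gaps)) read_bed(config$gaps)
  )
  list(
    blocks = read_maf(config$maf),
    tree = read_species_tree(config$tree),
    pwms = read_motifs(config$motifs,
                       dialect = config$motif_dialect %||% "jaspar"),
    mask = mask, chrom_sizes = chrom_sizes
  )
}

config_params <- function(config) {
  keys <- intersect(names(config), names(screen_params()))
  do.call(screen_params, config[keys])
}

#' Run one pipeline stage against files
#'
#' File-based counterpart of [erosion_screen()] used by the command-line
#' interface: each stage reads standard-format inputs named in `config`,
#' runs the corresponding package functions and writes TSV outputs (with
#' parameters recorded as `#` header lines) into `config$out_dir`.
#'
#' Stages: `simulate` (write a synthetic world), `conserve` (null +
#' conserved-site prediction), `erode` (per-target eroded sites),
#' `intersect`, `rank` (top-k + overlap dedup), `classify` (mechanism
#' table), `enrich`, `permtest`, and `all` (everything in order).
#'
#' @param stage Stage name (see above).
#' @param config Named list: input paths (`maf`, `tree`, `motifs`,
#'   `exons`, `repeats`, `gaps`, `genes`, `ontology`, `features`,
#'   `chrom_sizes`), `targets` (named list target -> outgroups),
#'   `out_dir`, `seed`, plus any [screen_params()] override.
#' @return Invisibly, a list of the stage's in-memory results.
#' @export
run_stage <- function(stage = c("simulate", "conserve", "erode",
                                "intersect", "rank", "classify",
                                "enrich", "permtest", "all"),
                      config) {
  stage <- match.arg(stage)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_params(config)
  seed <- config$seed %||% 1L
  pth <- function(f) file.path(out_dir, f)

  if (stage == "simulate") {
    world <- generate_world(world_config(seed = seed))
    paths <- write_world(world, out_dir)
    return(invisible(list(world = world, paths = paths)))
  }

  if (stage == "conserve") {
    inp <- load_screen_inputs(config)
    null <- build_null(inp$blocks, inp$tree, inp$pwms, inp$mask,
                       n_shuffles = params$n_shuffles, seed = seed,
                       threshold = params$match_threshold,
                       window = params$smooth_window)
    conserved <- predict_sites(inp$blocks, inp$tree, inp$pwms, inp$mask,
                               null, params = params)
    write_null_tsv(null, pth("null.tsv"))
    write_tsv(conserved, pth("conserved.tsv"), params = params)
    return(invisible(list(null = null, conserved = conserved)))
  }

  if (stage == "erode") {
    stage_inputs(config, c("maf", "tree"))
    if (!file.exists(pth("conserved.tsv"))) {
      stop("missing input file(s) for stage: conserved.tsv ",
           "(run the 'conserve' stage first)")
    }
    conserved <- read_tsv(pth("conserved.tsv"))
    blocks <- read_maf(config$maf)
    tree <- read_species_tree(config$tree)
    gaps <- if (!is.null(config$gaps)) read_bed(config$gaps)
    eroded <- lapply(names(config$targets), function(tg) {
      df <- call_eroded(conserved, tg, config$targets[[tg]], tree,
                        blocks, gaps = gaps)
      write_tsv(df, pth(sprintf("eroded_%s.tsv", tg)))
      df
    })
    names(eroded) <- names(config$targets)
    return(invisible(list(eroded = eroded)))
  }

  if (stage == "intersect") {
    files <- file.path(out_dir, sprintf("eroded_%s.tsv",
                                        names(config$targets)))
    if (!all(file.exists(files))) {
      stop("missing input file(s) for stage: ",
           paste(basename(files[!file.exists(files)]), collapse = ", "))
    }
    ind <- intersect_independent(lapply(files, read_tsv))
    write_tsv(ind, pth("independent.tsv"))
    return(invisible(list(independent = ind)))
  }

  if (stage == "rank") {
    if (!file.exists(pth("independent.tsv"))) {
      stop("missing input file(s) for stage: independent.tsv")
    }
    ind <- read_tsv(pth("independent.tsv"))
    top <- dedup_overlaps(rank_top_k(ind, k = params$top_k))
    write_tsv(top, pth("top.tsv"), params = params["top_k"])
    return(invisible(list(top = top)))
  }

  if (stage == "classify") {
    if (!file.exists(pth("top.tsv"))) {
      stop("missing input file(s) for stage: top.tsv")
    }
    top <- read_tsv(pth("top.tsv"))
    tab <- mechanism_table(top)
    write_tsv(data.frame(class = names(tab), count = as.integer(tab)),
              pth("mechanisms.tsv"))
    return(invisible(list(mech_table = tab)))
  }

  if (stage == "enrich") {
    stage_inputs(config, c("genes", "ontology", "chrom_sizes"))
    if (!file.exists(pth("top.tsv"))) {
      stop("missing input file(s) for stage: top.tsv")
    }
    top <- read_tsv(pth("top.tsv"))
    res <- great_enrichment(top, read_genes(config$genes),
                            read_gmt(config$ontology),
                            read_chrom_sizes(config$chrom_sizes),
                            params = params)
    write_tsv(res, pth("enrichment.tsv"), params = params)
    write_tsv(rank_terms(res, params = params), pth("significant.tsv"))
    return(invisible(list(enrichment = res)))
  }

  if (stage == "permtest") {
    stage_inputs(config, c("features", "chrom_sizes"))
    if (!file.exists(pth("top.tsv"))) {
      stop("missing input file(s) for stage: top.tsv")
    }
    top <- read_tsv(pth("top.tsv"))
    chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
    mask <- genome_masks(
      chrom_sizes,
      exons = if (!is.null(config$exons)) read_bed(config$exons),
      repeats = if (!is.null(config$repeats)) read_bed(config$repeats)
    )
    pt <- permutation_overlap_test(top, read_bed(config$features),
                                   mask$allowed,
                                   m = params$n_permutations,
                                   seed = seed + 1L)
    write_tsv(data.frame(observed = pt$observed, m = pt$m, b = pt$b,
                         p = pt$p, fold = pt$fold,
                         perm_mean = pt$perm_mean),
              pth("permtest.tsv"))
    return(invisible(list(permtest = pt)))
  }

  # all: run the in-memory pipeline over the files
  inp <- load_screen_inputs(config)
  stage_inputs(config, c("genes", "ontology", "features"))
  res <- erosion_screen(
    blocks = inp$blocks, tree = inp$tree, pwms = inp$pwms,
    mask = inp$mask, outgroup_spec = config$targets,
    genes = read_genes(config$genes), terms = read_gmt(config$ontology),
    features = read_bed(config$features), chrom_sizes = inp$chrom_sizes,
    gaps = if (!is.null(config$gaps)) read_bed(config$gaps),
    params = params, seed = seed
  )
  write_null_tsv(res$null, pth("null.tsv"))
  write_tsv(res$conserved, pth("conserved.tsv"), params = params)
  for (tg in names(res$eroded)) {
    write_tsv(res$eroded[[tg]], pth(sprintf("eroded_%s.tsv", tg)))
  }
  write_tsv(res$independent, pth("independent.tsv"))
  write_tsv(res$top, pth("top.tsv"))
  write_tsv(data.frame(class = names(res$mech_table),
                       count = as.integer(res$mech_table)),
            pth("mechanisms.tsv"))
  write_tsv(res$enrichment, pth("enrichment.tsv"))
  write_tsv(res$ranked_terms, pth("significant.tsv"))
  if (!is.null(res$permtest)) {
    pt <- res$permtest
    write_tsv(data.frame(observed = pt$observed, m = pt$m, b = pt$b,
                         p = pt$p, fold = pt$fold,
                         perm_mean = pt$perm_mean),
              pth("permtest.tsv"))
  }
  invisible(res)
}
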