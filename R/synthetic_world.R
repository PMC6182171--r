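# Deterministic miniature comparative-genomics world with planted
# conserved binding sites and planted independent erosion near the genes
# of one "trait" ontology term, so that every stage of the screen (and
# the screen end-to-end) can be validated against known ground truth.

#' Synthetic-world configuration
#'
#' Defaults define the standard validation world: 10 species related by a
#' fixed tree (total branch length 8.2 substitutions/site) containing two
#' independent target clades (`target1`/`outgroup1`,
#' `target2`/`outgroup2`), a 250 kb single-chromosome reference genome
#' tiled by 5 kb alignment blocks, 50 genes, a 25-term toy ontology whose
#' 12-gene trait term attracts 80% of the independently eroded sites, and
#' 190 planted motif instances: 60 conserved everywhere, 25 eroded in
#' each single target, and 80 independently eroded with a
#' (0.6, 0.3, 0.1) mixture of both-mismatch / mixed / both-deletion
#' mechanisms. Background sequence evolves neutrally (Jukes-Cantor
#' substitutions per branch, no background indels).
#'
#' @param seed Master seed; the same seed reproduces the world exactly.
#' @param ... Named overrides of any default listed above.
#' @return A `world_config` list.
#' @export
world_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    tree_text = paste0(
      "((ref:0.6,sister:0.7):0.3,",
      "((target1:0.5,outgroup1:0.5):0.4,",
      "((target2:0.5,outgroup2:0.5):0.4,",
      "((farA:0.6,farB:0.7):0.3,(farC:0.6,farD:0.7):0.3):0.2):0.2):0.2);"),
    ref = "ref",
    outgroup_spec = list(target1 = "outgroup1", target2 = "outgroup2"),
    chrom = "chr1",
    genome_length = 480000L,
    block_size = 10000L,
    n_genes = 80L,
    gene_spacing = 6000L,
    n_terms = 25L,
    term_size_range = c(10L, 14L),
    trait_size = 12L,
    n_conserved = 60L,
    n_t1_only = 25L,
    n_t2_only = 25L,
    n_independent = 80L,
    trait_fraction = 0.8,
    mech_mix = c(mismatch = 0.6, mixed = 0.3, deletion = 0.1),
    n_motifs = 3L,
    motif_width = 9L,
    sharp_freq = 0.85,
    soft_cols = c(4L, 7L),
    n_repeats = 30L,
    repeat_len = 300L,
    exon_len = 300L,
    n_random_features = 40L,
    feature_len = 500L,
    site_margin = 60L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown world_config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (sum(cfg$mech_mix) > 1 + 1e-9) stop("mechanism mix must sum to <= 1")
  structure(cfg, class = "world_config")
}

BASES <- c("A", "C", "G", "T")

code_to_char <- function(codes) {
  out <- c("-", BASES)[codes + 1L]
  out
}

jc_mutate <- function(codes, bl) {
  p <- 0.75 * (1 - exp(-4 * bl / 3))
  hit <- which(stats::runif(length(codes)) < p)
  if (length(hit)) {
    codes[hit] <- ((codes[hit] - 1L +
                      sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
  }
  codes
}

# Evolve the root sequence down the tree; returns a species-by-position
# integer matrix (1..4 = A..T).
evolve_leaves <- function(tree, genome_length) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- sample.int(4L, genome_length, replace = TRUE)
  edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
  # preorder: parents always appear before their children in ape's edge
  # matrix when traversed from the root; use a simple queue
  todo <- which(tree$edge[, 1] == root)
  while (length(todo)) {
    e <- todo[1]; todo <- todo[-1]
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    seqs[[child]] <- jc_mutate(seqs[[parent]], tree$edge.length[e])
    todo <- c(todo, which(tree$edge[, 1] == child))
  }
  out <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(out) <- tree$tip.label
  out
}

# Disrupt a planted motif instance in one target row by substitutions at
# informative columns until its MATCH score drops below the threshold.
disrupt_row <- function(leafmat, target, pwm, start0, strand,
                        threshold = 0.8) {
  w <- pwm$width
  iw <- information_weights(pwm)
  worst <- apply(pwm$mat, 2, which.min)
  cols <- order(iw, decreasing = TRUE)
  pos <- start0 + 1L
  n_edit <- 0L
  for (j in cols) {
    gpos <- if (strand == "+") pos + j - 1L else pos + w - j
    bad <- if (strand == "+") worst[j] else (5L - worst[j])
    leafmat[target, gpos] <- bad
    n_edit <- n_edit + 1L
    if (n_edit >= 2L) {
      seq <- paste(BASES[leafmat[target, pos:(pos + w - 1L)]], collapse = "")
      if (strand == "-") seq <- revcomp(seq)
      if (match_score(pwm, seq) < threshold) break
    }
  }
  leafmat
}

#' Generate the synthetic comparative-genomics world
#'
#' Builds, deterministically from the seed, every input the screen
#' consumes — species tree, reference-anchored alignment blocks, motif
#' library, exon/repeat masks, gene models, toy ontology (with a marked
#' trait term), a feature track concentrated on trait-gene promoters —
#' plus a ground-truth table of every planted site with its category and
#' per-target erosion mechanism. Planted sites are exact motif consensus
#' in all species; target-lineage erosion is implemented either as
#' motif-breaking substitutions (verified to score below the MATCH
#' threshold) or as whole-site deletion of the target row.
#'
#' @param config A [world_config()].
#' @return A `synthetic_world` list with components `tree`, `blocks`,
#'   `pwms`, `mask`, `genes`, `terms`, `trait_term`, `features`,
#'   `chrom_sizes`, `truth`, `outgroup_spec`, `config`.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(cfg) {
  tree <- read_species_tree(cfg$tree_text)
  chrom <- cfg$chrom
  G <- cfg$genome_length
  chrom_sizes <- stats::setNames(G, chrom)
  W <- cfg$motif_width

  ## genes, exons, repeats -------------------------------------------------
  n_genes <- cfg$n_genes
  tss <- as.integer(cfg$gene_spacing %/% 2 +
                      cfg$gene_spacing * (seq_len(n_genes) - 1L) +
                      sample(-100:100, n_genes, replace = TRUE))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = chrom, tss = tss, strand = strand, stringsAsFactors = FALSE
  )
  exons <- data.frame(
    chrom = chrom,
    start = ifelse(strand == "+", tss, tss - cfg$exon_len),
    end = ifelse(strand == "+", tss + cfg$exon_len, tss),
    stringsAsFactors = FALSE
  )
  forbidden <- cbind(tss - 1700L, tss + 500L)  # keep repeats off promoters
  repeats <- matrix(NA_integer_, 0, 2)
  guard <- 0L
  while (nrow(repeats) < cfg$n_repeats && guard < 10000L) {
    guard <- guard + 1L
    s <- sample.int(G - cfg$repeat_len, 1L) - 1L
    e <- s + cfg$repeat_len
    if (any(s < forbidden[, 2] & e > forbidden[, 1])) next
    repeats <- rbind(repeats, c(s, e))
  }
  repeats <- data.frame(chrom = chrom, start = repeats[, 1],
                        end = repeats[, 2], stringsAsFactors = FALSE)
  mask <- genome_masks(chrom_sizes, exons = exons, repeats = repeats)

  ## ontology --------------------------------------------------------------
  trait_genes <- sort(sample(genes$gene_id, cfg$trait_size))
  n_other <- cfg$n_terms - 1L
  other_sets <- lapply(seq_len(n_other), function(i) {
    sz <- sample(seq(cfg$term_size_range[1], cfg$term_size_range[2]), 1L)
    sort(sample(genes$gene_id, sz))
  })
  trait_pos <- sample.int(cfg$n_terms, 1L)
  ids <- sprintf("T%02d", seq_len(cfg$n_terms))
  sets <- vector("list", cfg$n_terms)
  nm <- character(cfg$n_terms)
  oi <- 1L
  for (i in seq_len(cfg$n_terms)) {
    if (i == trait_pos) {
      sets[[i]] <- trait_genes; nm[i] <- "trait program"
    } else {
      sets[[i]] <- other_sets[[oi]]; nm[i] <- sprintf("background term %d", oi)
      oi <- oi + 1L
    }
  }
  terms <- data.frame(term_id = ids, name = nm, genes = I(sets),
                      stringsAsFactors = FALSE)
  trait_term <- ids[trait_pos]

  ## motif library ---------------------------------------------------------
  # consensus sequences are drawn so that no motif's letter multiset can
  # be rearranged into (or near) another motif's consensus on either
  # strand: this emulates a curated non-redundant library, and keeps one
  # motif's shuffled nulls from rediscovering another motif's planted
  # instances
  base_counts <- function(cons) tabulate(cons, 4L)
  multiset_dist <- function(a, b) sum(pmax(a - b, 0))
  consensi <- list()
  tries <- 0L
  while (length(consensi) < cfg$n_motifs) {
    tries <- tries + 1L
    # the joint constraints can become infeasible for a given pair of
    # accepted consensi; relax them stepwise after repeated failure so
    # sampling always terminates (in practice the first rung suffices)
    if (tries <= 3000L) {
      min_d <- 3L; min_distinct <- 3L; max_mult <- 4L
    } else if (tries <= 6000L) {
      min_d <- 3L; min_distinct <- 2L; max_mult <- 5L
    } else if (tries <= 9000L) {
      min_d <- 2L; min_distinct <- 2L; max_mult <- 6L
    } else {
      min_d <- 0L; min_distinct <- 1L; max_mult <- W
    }
    cand <- sample.int(4L, W, replace = TRUE)
    cc <- base_counts(cand)
    # curated libraries exclude low-complexity motifs; highly repetitive
    # consensi are also near-invariant under column shuffling
    if (sum(cc > 0) < min_distinct || max(cc) > max_mult) next
    ccr <- rev(cc)  # complement multiset (A<->T, C<->G)
    ok <- all(vapply(consensi, function(prev) {
      pc <- base_counts(prev)
      multiset_dist(cc, pc) >= min_d && multiset_dist(ccr, pc) >= min_d
    }, logical(1)))
    if (ok) {
      consensi[[length(consensi) + 1L]] <- cand
      tries <- 0L
    }
  }
  pwms <- lapply(seq_len(cfg$n_motifs), function(j) {
    cons <- consensi[[j]]
    mat <- matrix(0, 4, W, dimnames = list(BASES, NULL))
    for (i in seq_len(W)) {
      if (i %in% cfg$soft_cols) {
        rest <- setdiff(1:4, cons[i])
        mat[cons[i], i] <- 0.4
        mat[rest, i] <- c(0.3, 0.2, 0.1)
      } else {
        mat[, i] <- (1 - cfg$sharp_freq) / 3
        mat[cons[i], i] <- cfg$sharp_freq
      }
    }
    pwm_motif(mat, id = sprintf("M%d", j), name = sprintf("TF%d", j))
  })
  names(pwms) <- vapply(pwms, `[[`, character(1), "id")

  ## site plan -------------------------------------------------------------
  category <- c(rep("conserved", cfg$n_conserved),
                rep("t1_only", cfg$n_t1_only),
                rep("t2_only", cfg$n_t2_only),
                rep("independent", cfg$n_independent))
  n_sites <- length(category)
  n_ind <- cfg$n_independent
  n_mm <- round(cfg$mech_mix[["mismatch"]] * n_ind)
  n_mx <- round(cfg$mech_mix[["mixed"]] * n_ind)
  n_dl <- n_ind - n_mm - n_mx
  ind_mech1 <- c(rep("mismatch", n_mm),
                 rep(c("mismatch", "deletion"), length.out = n_mx),
                 rep("deletion", n_dl))
  ind_mech2 <- c(rep("mismatch", n_mm),
                 rep(c("deletion", "mismatch"), length.out = n_mx),
                 rep("deletion", n_dl))
  single_mech <- function(n) rep(c("mismatch", "deletion"), length.out = n)

  n_trait <- round(cfg$trait_fraction * n_ind)
  trait_rows <- genes[genes$gene_id %in% trait_genes, ]
  # deterministic non-overlapping slots in the strand-aware upstream
  # window [200, 1300] bp from each trait TSS (inside the basal domain,
  # clear of exons and block edges)
  slot_of <- integer(nrow(trait_rows))
  place_trait <- function(k) {
    gi <- ((k - 1L) %% nrow(trait_rows)) + 1L
    slot <- slot_of[gi]
    slot_of[gi] <<- slot + 1L
    g <- trait_rows[gi, ]
    # slots stay within ~800 bp of the TSS so a site midpoint falls in
    # the basal domain of its own gene only (gene spacing 6 kb, basal
    # reach 5 kb)
    off <- 200L + 110L * slot + sample.int(6L, 1L) - 1L
    s <- if (g$strand == "+") g$tss - off - W else g$tss + off
    list(start = as.integer(s), gene = g$gene_id)
  }

  allowed_vec <- allowed_base_vector(mask, chrom, 0L, G)
  occ <- logical(G)
  bs <- cfg$block_size
  ok_uniform <- function(s) {
    e <- s + W
    if (s < 30L || e > G - 30L) return(FALSE)
    if (s %% bs < cfg$site_margin || (e - 1L) %% bs > bs - cfg$site_margin) {
      return(FALSE)
    }
    if (s %/% bs != (e - 1L) %/% bs) return(FALSE)
    if (!all(allowed_vec[(s - 1L):(e + 2L)])) return(FALSE)
    if (any(occ[(s - 19L):(e + 20L)])) return(FALSE)
    TRUE
  }

  plan <- data.frame(
    site_id = sprintf("S%03d", seq_len(n_sites)),
    chrom = chrom, start = NA_integer_, end = NA_integer_,
    strand = sample(c("+", "-"), n_sites, replace = TRUE),
    motif_id = rep(names(pwms), length.out = n_sites),
    category = category,
    mech_target1 = NA_character_, mech_target2 = NA_character_,
    gene_id = NA_character_, trait_directed = FALSE,
    stringsAsFactors = FALSE
  )
  ind_idx <- which(category == "independent")
  plan$mech_target1[ind_idx] <- ind_mech1
  plan$mech_target2[ind_idx] <- ind_mech2
  plan$mech_target1[category == "t1_only"] <- single_mech(cfg$n_t1_only)
  plan$mech_target2[category == "t2_only"] <- single_mech(cfg$n_t2_only)
  plan$trait_directed[ind_idx[seq_len(n_trait)]] <- TRUE

  trait_k <- 0L
  # trait-directed sites first: their promoter slots are collision-free
  # by construction, so slot indices stay within the basal-only zone
  for (i in order(!plan$trait_directed)) {
    placed <- FALSE
    for (try in seq_len(5000L)) {
      if (plan$trait_directed[i]) {
        trait_k <- trait_k + 1L
        pt <- place_trait(trait_k)
        s <- pt$start
        if (!ok_uniform(s)) next
        plan$gene_id[i] <- pt$gene
      } else {
        s <- sample.int(G - W, 1L) - 1L
        if (!ok_uniform(s)) next
      }
      plan$start[i] <- s
      plan$end[i] <- s + W
      occ[(s + 1L):(s + W)] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place planted site ", plan$site_id[i],
                      ": placement density infeasible")
  }

  ## sequences -------------------------------------------------------------
  leafmat <- evolve_leaves(tree, G)
  for (i in seq_len(n_sites)) {
    pwm <- pwms[[plan$motif_id[i]]]
    cons <- pwm_consensus(pwm)
    seqchr <- if (plan$strand[i] == "+") cons else revcomp(cons)
    codes <- encode_dna(seqchr)
    pos <- (plan$start[i] + 1L):(plan$end[i])
    leafmat[, pos] <- matrix(codes, nrow = nrow(leafmat), ncol = W,
                             byrow = TRUE)
  }
  # target-lineage erosion (0 encodes an alignment gap)
  apply_erosion <- function(leafmat, target, mech, i) {
    pos <- (plan$start[i] + 1L):(plan$end[i])
    if (is.na(mech)) return(leafmat)
    if (mech == "deletion") {
      leafmat[target, pos] <- 0L
      leafmat
    } else {
      disrupt_row(leafmat, target, pwms[[plan$motif_id[i]]],
                  plan$start[i], plan$strand[i])
    }
  }
  t1 <- names(cfg$outgroup_spec)[1]
  t2 <- names(cfg$outgroup_spec)[2]
  for (i in seq_len(n_sites)) {
    leafmat <- apply_erosion(leafmat, t1, plan$mech_target1[i], i)
    leafmat <- apply_erosion(leafmat, t2, plan$mech_target2[i], i)
  }

  ## alignment blocks ------------------------------------------------------
  species <- c(cfg$ref, setdiff(tree$tip.label, cfg$ref))
  offsets <- stats::setNames(rep(0L, length(species)), species)
  blocks <- list()
  for (b0 in seq(0L, G - 1L, by = bs)) {
    pos <- (b0 + 1L):min(G, b0 + bs)
    rows <- character(length(species))
    row_start <- integer(length(species))
    row_size <- integer(length(species))
    for (si in seq_along(species)) {
      codes <- leafmat[species[si], pos]
      rows[si] <- paste(code_to_char(codes), collapse = "")
      row_start[si] <- offsets[[species[si]]]
      row_size[si] <- sum(codes != 0L)
      offsets[[species[si]]] <- offsets[[species[si]]] + row_size[si]
    }
    blocks[[length(blocks) + 1L]] <- alignment_block(
      chrom = chrom, ref_start = b0,
      rows = stats::setNames(rows, species), ref = cfg$ref,
      row_start = stats::setNames(row_start, species),
      row_size = stats::setNames(row_size, species),
      row_strand = stats::setNames(rep("+", length(species)), species),
      row_src_size = stats::setNames(rep(G, length(species)), species)
    )
  }

  ## feature track ---------------------------------------------------------
  feat <- data.frame(
    chrom = chrom,
    start = pmax(0L, trait_rows$tss - 1500L),
    end = pmin(G, trait_rows$tss + 500L),
    stringsAsFactors = FALSE
  )
  rand_start <- sample.int(G - cfg$feature_len, cfg$n_random_features) - 1L
  feat <- rbind(feat, data.frame(chrom = chrom, start = rand_start,
                                 end = rand_start + cfg$feature_len))
  features <- gr_to_bed(GenomicRanges::reduce(bed_to_gr(feat)))

  structure(
    list(
      tree = tree, tree_text = cfg$tree_text, blocks = blocks,
      pwms = pwms, mask = mask, genes = genes, terms = terms,
      trait_term = trait_term, features = features,
      chrom_sizes = chrom_sizes, truth = plan,
      outgroup_spec = cfg$outgroup_spec, ref = cfg$ref, config = cfg
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world: %d species, %d bp, %d blocks, %d planted sites (%d independently eroded)>\n",
    length(x$tree$tip.label), x$config$genome_length, length(x$blocks),
    nrow(x$truth), sum(x$truth$category == "independent")))
  invisible(x)
}

#' Write a synthetic world to disk in standard formats
#'
#' Emits exactly the formats the pipeline consumes: newick, MAF, JASPAR
#' motifs, BED masks and features, a gene TSV, a GMT ontology, chromosome
#' sizes and the ground-truth TSV.
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    tree = file.path(dir, "species.nwk"),
    maf = file.path(dir, "alignment.maf"),
    motifs = file.path(dir, "motifs.jaspar"),
    exons = file.path(dir, "exons.bed"),
    repeats = file.path(dir, "repeats.bed"),
    gaps = file.path(dir, "gaps.bed"),
    genes = file.path(dir, "genes.tsv"),
    ontology = file.path(dir, "ontology.gmt"),
    features = file.path(dir, "features.bed"),
    chrom_sizes = file.path(dir, "chrom.sizes"),
    truth = file.path(dir, "truth.tsv")
  )
  writeLines(world$tree_text, paths["tree"])
  write_maf(world$blocks, paths["maf"])
  write_motifs_jaspar(world$pwms, paths["motifs"])
  write_bed(gr_to_bed(world$mask$exons), paths["exons"])
  write_bed(gr_to_bed(world$mask$repeats), paths["repeats"])
  write_bed(gr_to_bed(world$mask$gaps), paths["gaps"])
  utils::write.table(world$genes[, c("chrom", "tss", "strand", "gene_id")],
                     paths["genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(world$terms, paths["ontology"])
  write_bed(world$features, paths["features"])
  writeLines(sprintf("%s\t%d", names(world$chrom_sizes),
                     world$chrom_sizes), paths["chrom_sizes"])
  utils::write.table(world$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Compare screen output against the planted ground truth
#'
#' Matches predictions to planted sites by motif identity and interval
#' overlap, and summarises per-category recall, precision of the final
#' top set, the rank of the planted trait term in the enrichment output,
#' and the per-target mechanism confusion counts.
#'
#' @param result An [erosion_screen()] result list.
#' @param world The [generate_world()] world it was run on.
#' @return List with `recall` (per category), `precision_top`,
#'   `trait_rank`, `mechanism_confusion` and `n_top`.
#' @export
evaluate_recovery <- function(result, world) {
  truth <- world$truth
  overlap_hit <- function(pred, tr) {
    if (!nrow(pred)) return(logical(nrow(tr)))
    vapply(seq_len(nrow(tr)), function(i) {
      any(pred$motif_id == tr$motif_id[i] & pred$chrom == tr$chrom[i] &
            pred$start < tr$end[i] & pred$end > tr$start[i])
    }, logical(1))
  }
  cats <- c("conserved", "t1_only", "t2_only", "independent")
  recall <- vapply(cats, function(cc) {
    tr <- truth[truth$category == cc, , drop = FALSE]
    pred <- switch(cc,
      conserved = result$conserved,
      t1_only = result$eroded[[1]],
      t2_only = result$eroded[[2]],
      independent = result$top
    )
    if (!nrow(tr)) return(NA_real_)
    mean(overlap_hit(pred, tr))
  }, numeric(1))
  top <- result$top
  tr_ind <- truth[truth$category == "independent", , drop = FALSE]
  precision_top <- if (nrow(top)) {
    mean(vapply(seq_len(nrow(top)), function(i) {
      any(tr_ind$motif_id == top$motif_id[i] &
            tr_ind$start < top$end[i] & tr_ind$end > top$start[i])
    }, logical(1)))
  } else NA_real_
  ranked <- result$ranked_terms
  trait_rank <- if (nrow(ranked) && world$trait_term %in% ranked$term_id) {
    which(ranked$term_id == world$trait_term)[1]
  } else NA_integer_
  # mechanism confusion over matched independent sites
  mech_cols <- grep("^mechanism_", names(top), value = TRUE)
  conf <- NULL
  if (length(mech_cols) == 2L && nrow(top)) {
    key <- site_key(top)
    tkey <- site_key(tr_ind)
    hit <- match(tkey, key)
    ok <- !is.na(hit)
    if (any(ok)) {
      conf <- table(
        truth = paste(tr_ind$mech_target1, tr_ind$mech_target2)[ok],
        predicted = paste(top[[mech_cols[1]]], top[[mech_cols[2]]])[hit[ok]]
      )
    }
  }
  list(recall = recall, precision_top = precision_top,
       trait_rank = trait_rank, mechanism_confusion = conf,
       n_top = nrow(top))
}
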