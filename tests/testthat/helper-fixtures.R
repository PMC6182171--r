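# Shared fixtures: small trees, blocks and worlds built in code.

toy_tree <- function() {
  read_species_tree("((A:0.1,B:0.2):0.3,C:0.4);")
}

ref_tree <- function() {
  read_species_tree("(((ref:0.1,A:0.1):0.1,B:0.2):0.1,C:0.3);")
}

# a block whose rows are all identical to the given reference sequence
uniform_block <- function(seq, species = c("ref", "A", "B", "C"),
                          chrom = "chr1", start = 0L) {
  rows <- stats::setNames(rep(seq, length(species)), species)
  alignment_block(chrom, start, rows, ref = species[1])
}

toy_pwm <- function(width = 6L, seed = 42L, sharp = 0.85) {
  with_seed <- erosionscan:::with_seed
  with_seed(seed, {
    cons <- sample(1:4, width, replace = TRUE)
    mat <- matrix((1 - sharp) / 3, 4, width)
    mat[cbind(cons, seq_len(width))] <- sharp
    pwm_motif(mat, id = "toy", pseudocount = 0.001)
  })
}

# reduced synthetic world for unit-level pipeline checks (fast);
# memoised per seed — callers treat worlds as read-only
.tiny_cache <- new.env(parent = emptyenv())
tiny_world <- function(seed = 7L) {
  key <- as.character(seed)
  if (!is.null(.tiny_cache[[key]])) return(.tiny_cache[[key]])
  .tiny_cache[[key]] <- tiny_world_impl(seed)
  .tiny_cache[[key]]
}

tiny_world_impl <- function(seed) {
  generate_world(world_config(
    seed = seed, genome_length = 160000L, block_size = 8000L,
    n_genes = 26L, gene_spacing = 6000L, n_terms = 8L,
    trait_size = 10L, term_size_range = c(10L, 12L),
    n_conserved = 12L, n_t1_only = 6L, n_t2_only = 6L,
    n_independent = 24L, n_motifs = 2L,
    n_repeats = 10L, n_random_features = 10L
  ))
}

# unmasked whole-genome mask over a single small chromosome
open_mask <- function(size = 10000L, chrom = "chr1") {
  genome_masks(stats::setNames(as.integer(size), chrom))
}

# independent brute-force MATCH score used as an oracle in several files
brute_match_score <- function(pwm, seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  iw <- numeric(pwm$width)
  for (i in seq_len(pwm$width)) {
    f <- pwm$mat[, i]
    iw[i] <- sum(ifelse(f > 0, f * log2(4 * f), 0))
  }
  s <- 0; smin <- 0; smax <- 0
  for (i in seq_len(pwm$width)) {
    s <- s + iw[i] * pwm$mat[chars[i], i]
    smin <- smin + iw[i] * min(pwm$mat[, i])
    smax <- smax + iw[i] * max(pwm$mat[, i])
  }
  unname((s - smin) / (smax - smin))
}

all_kmers <- function(w) {
  grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), w))
  apply(grid, 1, paste, collapse = "")
}
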