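test_that("matching species are scored on their gapless aligned sequence", {
  tr <- ref_tree()
  p <- toy_pwm(width = 6, seed = 1)
  cons <- pwm_consensus(p)
  # every row identical to consensus -> all species match
  blk <- uniform_block(cons)
  expect_setequal(site_species_matches(blk, p, 0L, "+"),
                  c("ref", "A", "B", "C"))
  # a disrupting double substitution excludes that species
  anti <- rownames(p$mat)[apply(p$mat, 2, which.min)]
  broken <- strsplit(cons, "")[[1]]
  broken[1:2] <- anti[1:2]
  broken <- paste(broken, collapse = "")
  expect_lt(match_score(p, broken), 0.8)
  blk2 <- alignment_block("chr1", 0L,
                          c(ref = cons, A = cons, B = broken, C = cons))
  expect_setequal(site_species_matches(blk2, p, 0L, "+"),
                  c("ref", "A", "C"))
  # an all-gap row is excluded
  blk3 <- alignment_block("chr1", 0L,
                          c(ref = cons, A = cons,
                            B = strrep("-", 6), C = cons))
  expect_false("B" %in% site_species_matches(blk3, p, 0L, "+"))
  expect_error(site_species_matches(blk3, p, 3L, "+"), "outside")
})

test_that("BBL equals the induced branch length of the matching set", {
  tr <- toy_tree()
  expect_equal(bbl_score(tr, c("A", "B", "C")), total_branch_length(tr))
  expect_equal(bbl_score(tr, "A"), 0)
  expect_equal(bbl_score(tr, c("A", "C")), 0.8)
})

test_that("empirical p-values use the +1 permutation convention", {
  expect_equal(empirical_p(10, rep(1, 999)), 1 / 1000)
  expect_equal(empirical_p(0, rep(1, 999)), 1)
  nulls <- seq_len(101)  # median 51; 51 values >= 51
  expect_equal(empirical_p(51, nulls), (51 + 1) / 102)
  expect_error(empirical_p(1, numeric(0)), "empty")
  # non-increasing in the observed score
  set.seed(4)
  nulls <- rnorm(200)
  ps <- vapply(sort(rnorm(50)), empirical_p, numeric(1),
               null_scores = nulls)
  expect_true(all(diff(ps) <= 0))
})

test_that("the three retention gates reject violating sites", {
  sites <- data.frame(
    empirical_p = c(5e-4, 5e-4, 5e-4, 2e-3),
    n_species = c(6L, 4L, 6L, 6L),
    bbl = c(3.5, 3.5, 2.9, 3.5)
  )
  kept <- filter_conserved_sites(sites)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$n_species, 6L)
  # boundary values pass: p = 1e-3, 5 species, bbl = 3.0 exactly
  edge <- data.frame(empirical_p = 1e-3, n_species = 5L, bbl = 3.0)
  expect_equal(nrow(filter_conserved_sites(edge)), 1L)
})

test_that("null distributions are reproducible and bounded", {
  w <- tiny_world()
  sub <- w$blocks[1:6]
  n1 <- build_null(sub, w$tree, w$pwms[1], w$mask, n_shuffles = 3,
                   seed = 5)
  n2 <- build_null(sub, w$tree, w$pwms[1], w$mask, n_shuffles = 3,
                   seed = 5)
  expect_identical(n1$motifs, n2$motifs)
  v <- unlist(n1$motifs[[1]])
  expect_gt(length(v), 0)
  expect_true(all(v >= 0))
  expect_true(all(v <= total_branch_length(w$tree) + 1e-9))
})

test_that("shuffled and real motifs score alike on unstructured alignments", {
  # an alignment with no planted conservation: the real motif has no
  # advantage over its shuffles, so candidate BBL means agree
  tr <- tiny_world()$tree
  set.seed(31)
  seqs <- replicate(length(tr$tip.label),
                    paste(sample(c("A", "C", "G", "T"), 8000,
                                 replace = TRUE), collapse = ""))
  names(seqs) <- tr$tip.label
  seqs <- c(seqs["ref"], seqs[setdiff(names(seqs), "ref")])
  blk <- alignment_block("chr1", 0L, seqs, ref = "ref")
  mask <- open_mask(8000)
  p <- toy_pwm(width = 6, seed = 21, sharp = 0.6)
  idx <- tree_branch_index(tr)
  bd <- erosionscan:::prepare_block(blk, idx, mask, 100L)
  grab <- function(pwm) {
    wts <- erosionscan:::pwm_weights(pwm)
    cand <- erosionscan:::block_candidates(bd, wts, 0.8)
    m <- erosionscan:::candidate_match_matrix(bd, wts, cand, 0.8)
    erosionscan:::induced_lengths(idx, t(m))
  }
  real <- grab(p)
  nulls <- unlist(lapply(1:8, function(s)
    grab(shuffle_columns(p, seed = s))))
  expect_gt(length(real), 10)
  expect_gt(length(nulls), 50)
  expect_lt(abs(mean(real) - mean(nulls)), 0.5)
})

test_that("sparse conservation bins borrow from their neighbours", {
  bins <- lapply(1:100, function(i) numeric(0))
  bins[[10]] <- c(1, 2, 3)
  bins[[40]] <- rep(0.5, 2000)
  null <- structure(list(motifs = list(M = bins)), class = "tfbs_null")
  got <- erosionscan:::null_bin_scores(null, "M", 9, min_n = 5)
  expect_true(all(c(1, 2, 3) %in% got))
  expect_gte(length(got), 5)
  empty <- structure(list(motifs = list(M = lapply(1:100, function(i)
    numeric(0)))), class = "tfbs_null")
  expect_error(erosionscan:::null_bin_scores(empty, "M", 50), "empty")
})
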