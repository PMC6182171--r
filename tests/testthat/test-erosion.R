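# small catalogs built directly; the species tree is the default world's
erosion_tree <- function() {
  read_species_tree(world_config()$tree_text)
}

catalog_row <- function(start, matching, motif = "M1", strand = "+",
                        p = 1e-3, bbl = 7, end = start + 9L) {
  data.frame(
    chrom = "chr1", start = start, end = end, strand = strand,
    motif_id = motif, ref_score = 1, bbl = bbl,
    n_species = length(strsplit(matching, ",")[[1]]), bin = 30L,
    empirical_p = p, score = -log10(p), matching_species = matching,
    stringsAsFactors = FALSE
  )
}

# one covering block whose target row controls gap/mechanism behaviour
cover_block <- function(target_row, width = 30L) {
  rows <- c(ref = strrep("A", width), outgroup1 = strrep("A", width),
            target1 = target_row)
  alignment_block("chr1", 0L, rows, ref = "ref")
}

test_that("erosion requires outgroup presence and target absence", {
  tr <- erosion_tree()
  blocks <- list(cover_block(strrep("C", 30)))
  sites <- rbind(
    catalog_row(0L, "ref,target1,outgroup1,farA,farB"),   # target present
    catalog_row(10L, "ref,outgroup1,farA,farB,sister"),   # eroded
    catalog_row(20L, "ref,farA,farB,farC,sister")         # no outgroup
  )
  er <- call_eroded(sites, "target1", "outgroup1", tr, blocks)
  expect_equal(er$start, 10L)
  expect_equal(er$target, "target1")
  expect_equal(er$mechanism, "mismatch")
  expect_false(any(er$gap_overlap))
  expect_error(call_eroded(sites, "nosuch", "outgroup1", tr, blocks),
               "absent from tree")
  expect_error(call_eroded(sites, "target1", "target1", tr, blocks),
               "outgroup")
})

test_that("calls overlapping target assembly gaps are discarded", {
  tr <- erosion_tree()
  site <- catalog_row(5L, "ref,outgroup1,farA,farB,sister")
  n_block <- cover_block(paste0(strrep("C", 5), strrep("N", 10),
                                strrep("C", 15)))
  expect_equal(nrow(call_eroded(site, "target1", "outgroup1", tr,
                                list(n_block))), 0L)
  # same site, clean target row but an annotated gap interval
  clean <- cover_block(strrep("C", 30))
  gaps <- data.frame(chrom = "chr1", start = 10L, end = 12L)
  expect_equal(nrow(call_eroded(site, "target1", "outgroup1", tr,
                                list(clean), gaps = gaps)), 0L)
  # gap elsewhere leaves the call intact
  gaps2 <- data.frame(chrom = "chr1", start = 20L, end = 25L)
  expect_equal(nrow(call_eroded(site, "target1", "outgroup1", tr,
                                list(clean), gaps = gaps2)), 1L)
})

test_that("mechanism is mismatch iff any target base aligns", {
  blk <- alignment_block(
    "chr1", 0L,
    c(ref = "AAAAA", target1 = "ACG-T"))
  site <- list(chrom = "chr1", start = 0L, end = 5L)
  expect_equal(classify_mechanism(site, list(blk), "target1"), "mismatch")
  blk2 <- alignment_block(
    "chr1", 0L, c(ref = "AAAAA", target1 = "-----"))
  expect_equal(classify_mechanism(site, list(blk2), "target1"), "deletion")
  # species absent from every covering block
  blk3 <- alignment_block("chr1", 0L, c(ref = "AAAAA", farA = "AAAAA"))
  expect_equal(classify_mechanism(site, list(blk3), "target1"), "deletion")
  # a single aligned base is still a mismatch
  blk4 <- alignment_block(
    "chr1", 0L, c(ref = "AAAAA", target1 = "----G"))
  expect_equal(classify_mechanism(site, list(blk4), "target1"), "mismatch")
})

test_that("independent sites are those eroded in every target", {
  e1 <- rbind(catalog_row(0L, "ref,outgroup1"),
              catalog_row(20L, "ref,outgroup1"),
              catalog_row(40L, "ref,outgroup1"))
  e1$target <- "target1"
  e1$mechanism <- c("mismatch", "deletion", "mismatch")
  e1$gap_overlap <- FALSE
  e2 <- rbind(catalog_row(20L, "ref,outgroup2"),
              catalog_row(60L, "ref,outgroup2"))
  e2$target <- "target2"
  e2$mechanism <- c("mismatch", "deletion")
  e2$gap_overlap <- FALSE
  ind <- intersect_independent(list(e1, e2))
  expect_equal(ind$start, 20L)
  expect_equal(ind$mechanism_target1, "deletion")
  expect_equal(ind$mechanism_target2, "mismatch")
  expect_error(intersect_independent(list(e1)), "two")
  # three-target mode: a site eroded in only 2 of 3 is excluded
  e3 <- catalog_row(40L, "ref,outgroup1")
  e3$target <- "target3"; e3$mechanism <- "mismatch"; e3$gap_overlap <- FALSE
  expect_equal(nrow(intersect_independent(list(e1, e2, e3))), 0L)
})

test_that("top-k ranking keeps ties at the cutoff", {
  sites <- catalog_row(0L, "ref")
  sites <- sites[rep(1, 5), ]
  sites$start <- seq(0L, 80L, by = 20L)
  sites$end <- sites$start + 9L
  sites$empirical_p <- c(1e-5, 1e-4, 1e-3, 1e-3, 1e-2)
  top <- rank_top_k(sites, k = 3)
  expect_equal(nrow(top), 4L)  # 3 + 1 tie at the cutoff p
  expect_equal(max(top$empirical_p), 1e-3)
  expect_equal(nrow(rank_top_k(sites, k = 10)), 5L)
  allsame <- sites; allsame$empirical_p <- 1e-4
  expect_equal(nrow(rank_top_k(allsame, k = 2)), 5L)
  expect_error(rank_top_k(sites, k = 0), "at least 1")
})

test_that("overlap dedup keeps the most significant site greedily", {
  two <- catalog_row(0L, "ref")[rep(1, 2), ]
  two$start <- c(0L, 5L); two$end <- c(9L, 14L)
  two$empirical_p <- c(1e-5, 1e-4)
  kept <- dedup_overlaps(two)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$empirical_p, 1e-5)
  # chain A-B-C where A and C do not overlap: keep A and C
  chain <- catalog_row(0L, "ref")[rep(1, 3), ]
  chain$start <- c(0L, 6L, 12L); chain$end <- c(9L, 15L, 21L)
  chain$empirical_p <- c(1e-6, 1e-3, 1e-5)
  kept <- dedup_overlaps(chain)
  expect_setequal(kept$start, c(0L, 12L))
  # disjoint sites all kept
  disj <- catalog_row(0L, "ref")[rep(1, 3), ]
  disj$start <- c(0L, 20L, 40L); disj$end <- disj$start + 9L
  expect_equal(nrow(dedup_overlaps(disj)), 3L)
})

test_that("greedy dedup equals the exhaustive simulation oracle", {
  oracle <- function(df) {
    ord <- order(df$empirical_p, -df$bbl, df$chrom, df$start)
    kept <- list()
    for (i in ord) {
      ok <- TRUE
      for (j in seq_along(kept)) {
        k <- kept[[j]]
        if (df$start[i] < k[2] && df$end[i] > k[1]) { ok <- FALSE; break }
      }
      if (ok) kept[[length(kept) + 1L]] <- c(df$start[i], df$end[i])
    }
    sort(vapply(kept, `[[`, numeric(1), 1))
  }
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(2:20, 1)
    df <- catalog_row(0L, "ref")[rep(1, n), ]
    df$start <- sample(0:60, n)
    df$end <- df$start + sample(5:15, n, replace = TRUE)
    df$empirical_p <- 10^-sample(2:6, n, replace = TRUE)
    df$bbl <- runif(n, 3, 8)
    got <- dedup_overlaps(df)
    expect_identical(sort(got$start), as.integer(oracle(df)))
    # maximality: every removed site overlaps some kept site
    removed <- df[!paste(df$start, df$end) %in%
                    paste(got$start, got$end), , drop = FALSE]
    if (nrow(removed)) {
      for (i in seq_len(nrow(removed))) {
        expect_true(any(removed$start[i] < got$end &
                          removed$end[i] > got$start))
      }
    }
  }
})

test_that("mechanism counts partition the independent set", {
  ind <- data.frame(
    mechanism_target1 = c("mismatch", "mismatch", "deletion", "deletion"),
    mechanism_target2 = c("mismatch", "deletion", "mismatch", "deletion")
  )
  tab <- mechanism_table(ind)
  expect_equal(unname(tab), c(1L, 2L, 1L))
  expect_equal(sum(tab), nrow(ind))
})
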