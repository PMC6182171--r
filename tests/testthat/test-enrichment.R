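chrom1 <- c(chr1 = 10000000L)

test_that("basal domains follow the strand-aware 5kb/1kb rule", {
  g <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                  tss = c(100000L, 100000L), strand = c("+", "-"))
  d <- build_domains(g[1, ], chrom1)
  expect_equal(c(d$basal_start, d$basal_end), c(95000L, 101000L))
  d2 <- build_domains(g[2, ], chrom1)
  expect_equal(c(d2$basal_start, d2$basal_end), c(99000L, 105000L))
  expect_error(build_domains(data.frame(gene_id = c("a", "a"),
                                        chrom = "chr1", tss = c(1L, 2L),
                                        strand = "+"), chrom1),
               "duplicate")
})

test_that("extension reaches 1Mb or stops at the neighbouring basal domain", {
  g <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                  tss = c(2000000L, 5000000L), strand = "+")
  d <- build_domains(g, chrom1)
  # 3 Mb apart: both extend their full 1 Mb toward each other
  expect_equal(d$ext_end[1], d$basal_end[1] + 1000000L)
  expect_equal(d$ext_start[2], d$basal_start[2] - 1000000L)
  # close neighbours: extension stops at the neighbouring basal boundary
  g2 <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                   tss = c(2000000L, 2010000L), strand = "+")
  d2 <- build_domains(g2, chrom1)
  expect_equal(d2$ext_end[1], d2$basal_start[2])
  expect_equal(d2$ext_start[2], d2$basal_end[1])
})

test_that("extended domains never shrink below basal on random gene sets", {
  set.seed(13)
  for (rep in 1:10) {
    n <- 30
    g <- data.frame(
      gene_id = sprintf("g%02d", 1:n), chrom = "chr1",
      tss = sort(sample.int(9000000L, n)),
      strand = sample(c("+", "-"), n, replace = TRUE)
    )
    d <- build_domains(g, chrom1)
    expect_true(all(d$ext_start <= d$basal_start))
    expect_true(all(d$ext_end >= d$basal_end))
    expect_true(all(d$ext_start >= d$basal_start - 1000000L))
    expect_true(all(d$ext_end <= d$basal_end + 1000000L))
    # an extension never crosses a non-overlapping neighbour's basal domain
    o <- order(d$tss)
    for (i in seq_len(n - 1)) {
      a <- o[i]; b <- o[i + 1]
      if (d$basal_end[a] <= d$basal_start[b]) {
        expect_lte(d$ext_end[a], d$basal_start[b])
        expect_gte(d$ext_start[b], d$basal_end[a])
      }
    }
  }
})

test_that("regions associate with genes by domain midpoint", {
  g <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                  tss = c(2000000L, 2004000L), strand = "+")
  d <- build_domains(g, chrom1)
  # midpoint inside both overlapping basal domains
  r <- data.frame(chrom = "chr1", start = 1999900L, end = 2000100L)
  a <- associate_regions(r, d)
  expect_setequal(a$gene_id, c("a", "b"))
  # far outside every domain
  r2 <- data.frame(chrom = "chr1", start = 8000000L, end = 8000100L)
  expect_equal(nrow(associate_regions(r2, d)), 0L)
  # inside a single domain
  r3 <- data.frame(chrom = "chr1", start = 2004900L, end = 2005100L)
  expect_equal(associate_regions(r3, d)$gene_id, "b")
})

test_that("binomial region test matches exact tail enumeration", {
  bt <- binomial_region_test(10, 5, 0.5)
  expect_equal(bt$p_value, 0.623046875)
  expect_equal(bt$fold, 1)
  expect_equal(binomial_region_test(10, 0, 0.3)$p_value, 1)
  bt2 <- binomial_region_test(1, 1, 0.01)
  expect_equal(bt2$p_value, 0.01)
  expect_equal(bt2$fold, 100)
  expect_error(binomial_region_test(10, 2, 0), "zero genome fraction")
  expect_error(binomial_region_test(10, 2, 1.5), "\\[0, 1\\]")
  # enumeration oracle over all k for several n, p
  for (n in c(5, 12)) {
    for (p in c(0.1, 0.5, 0.9)) {
      for (k in 0:n) {
        exact <- sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
        expect_equal(binomial_region_test(n, k, p)$p_value,
                     min(1, exact), tolerance = 1e-12)
      }
    }
  }
})

test_that("hypergeometric gene test matches direct combinatorics", {
  expect_equal(hypergeom_gene_test(10, 2, 2, 2), 1 / 45)
  expect_equal(hypergeom_gene_test(10, 2, 2, 0), 1)
  expect_equal(hypergeom_gene_test(10, 10, 4, 4), 1)
  expect_error(hypergeom_gene_test(10, 11, 2, 2), "inconsistent")
  for (N in c(8, 12)) {
    for (K in c(2, 5)) {
      for (n in c(3, 6)) {
        for (k in 0:min(K, n)) {
          kk <- k:min(K, n)
          exact <- sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
          expect_equal(hypergeom_gene_test(N, K, n, k), min(1, exact),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("BH q-values follow the step-up recursion", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  p <- runif(40)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("term ranking applies the fold and double-FDR gates", {
  res <- data.frame(
    term_id = c("t1", "t2", "t3", "t4"),
    fold = c(2.85, 1.9, 3.0, 2.5),
    region_q = c(1e-4, 1e-9, 0.04, 0.2),
    gene_q = c(1e-3, 1e-9, 0.2, 0.01)
  )
  out <- rank_terms(res)
  expect_equal(out$term_id, "t1")  # t2 fails fold, t3 gene_q, t4 region_q
})

test_that("permutation overlap test honours its conventions", {
  allowed <- data.frame(chrom = "chr1", start = 0L, end = 100000L)
  # features covering all allowed space: fold 1, p 1
  feat <- allowed
  reg <- data.frame(chrom = "chr1", start = c(10L, 500L, 900L),
                    end = c(60L, 550L, 950L))
  pt <- permutation_overlap_test(reg, feat, allowed, m = 50, seed = 1)
  expect_equal(pt$p, 1)
  expect_equal(pt$fold, 1)
  expect_equal(pt$observed, 3L)
  # reproducibility under a fixed seed
  feat2 <- data.frame(chrom = "chr1", start = 0L, end = 5000L)
  a <- permutation_overlap_test(reg, feat2, allowed, m = 200, seed = 42)
  b <- permutation_overlap_test(reg, feat2, allowed, m = 200, seed = 42)
  expect_equal(a$p, b$p)
  expect_equal(a$perm_mean, b$perm_mean)
  # p floor is 1/(m+1)
  expect_gte(a$p, 1 / 201)
  # infeasible placement errors
  expect_error(
    permutation_overlap_test(
      data.frame(chrom = "chr1", start = 0L, end = 90000L),
      feat2, data.frame(chrom = "chr1", start = c(0L, 50000L),
                        end = c(40000L, 90000L)), m = 5, seed = 1),
    "allowed")
})

test_that("permuted placements stay inside allowed space, disjoint", {
  allowed <- data.frame(chrom = "chr1",
                        start = c(0L, 3000L), end = c(1000L, 4000L))
  iv_len <- c(1000, 1000); iv_off <- c(0, 1000)
  set.seed(6)
  for (rep in 1:20) {
    lens <- sample(20:200, 8, replace = TRUE)
    starts <- erosionscan:::place_regions(lens, iv_len, iv_off, 1000)
    ends <- starts + lens
    o <- order(starts)
    expect_true(all(starts[o][-1] >= ends[o][-8]))
    # each region fits one concatenated interval
    iv <- findInterval(starts, iv_off)
    expect_true(all(ends <= (iv_off + iv_len)[iv]))
  }
})
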