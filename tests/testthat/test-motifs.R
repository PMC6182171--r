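test_that("JASPAR and TRANSFAC dialects load the same motif", {
  jf <- tempfile()
  writeLines(c(
    ">M1 TFX",
    "A [ 8 0 1 ]",
    "C [ 0 8 1 ]",
    "G [ 1 1 8 ]",
    "T [ 1 1 0 ]"
  ), jf)
  tf <- tempfile()
  writeLines(c(
    "ID M1",
    "NA TFX",
    "P0 A C G T",
    "01 8 0 1 1",
    "02 0 8 1 1",
    "03 1 1 8 0",
    "//"
  ), tf)
  a <- read_motifs(jf, "jaspar")[["M1"]]
  b <- read_motifs(tf, "transfac")[["M1"]]
  expect_equal(a$mat, b$mat)
  expect_equal(pwm_consensus(a), "ACG")
  # frequencies sum to 1 and are strictly positive after the pseudocount
  expect_equal(unname(colSums(a$mat)), rep(1, 3))
  expect_true(all(a$mat > 0))
})

test_that("zero-count columns become uniform and bad input errors", {
  p <- pwm_motif(matrix(c(0, 0, 0, 0, 5, 0, 0, 0), 4), "z")
  expect_equal(unname(p$mat[, 1]), rep(0.25, 4))
  expect_error(pwm_motif(matrix(-1, 4, 2), "bad"), "negative")
  expect_error(pwm_motif(matrix(1, 3, 2), "bad"), "4 rows")
})

test_that("information weights span 0 (uniform) to 2 (fixed) bits", {
  m <- matrix(c(1, 0, 0, 0,
                0.25, 0.25, 0.25, 0.25,
                0.5, 0.5, 0, 0), 4)
  expect_equal(unname(information_weights(m)), c(2, 0, 1))
})

test_that("MATCH scores are min-max normalised information-weighted sums", {
  p <- toy_pwm(width = 5)
  cons <- pwm_consensus(p)
  anti <- paste(rownames(p$mat)[apply(p$mat, 2, which.min)], collapse = "")
  expect_equal(match_score(p, cons), 1)
  expect_equal(match_score(p, anti), 0)
  expect_equal(match_score(p, "ANCGT"), 0)  # N convention
  expect_error(match_score(p, "ACG"), "width")

  # brute-force enumeration over every dinucleotide for a 2-column PWM
  p2 <- pwm_motif(matrix(c(.7, .1, .1, .1, .1, .7, .1, .1), 4), "p2",
                  pseudocount = 0)
  for (kmer in all_kmers(2)) {
    expect_equal(match_score(p2, kmer), brute_match_score(p2, kmer),
                 tolerance = 1e-12)
  }
})

test_that("column shuffles preserve the column multiset and CpG pairs", {
  m <- matrix(c(.1, .7, .1, .1,   # C
                .1, .1, .7, .1,   # G  -> CpG pair (1,2)
                .7, .1, .1, .1), 4)
  p <- pwm_motif(m, "cpg", pseudocount = 0)
  expect_identical(p$cpg_pairs, 1L)
  seen <- character(0)
  for (seed in 1:40) {
    s <- shuffle_columns(p, seed = seed)
    seen <- union(seen, pwm_consensus(s))
    # multiset of columns preserved
    expect_equal(s$mat[, order(apply(s$mat, 2, paste, collapse = ","))],
                 p$mat[, order(apply(p$mat, 2, paste, collapse = ","))])
    # CpG stays glued in C->G order
    expect_length(s$cpg_pairs, 1L)
    i <- s$cpg_pairs
    expect_equal(s$mat[, i], p$mat[, 1])
    expect_equal(s$mat[, i + 1L], p$mat[, 2])
  }
  # only two legal orders exist for a glued pair among 3 columns
  expect_setequal(seen, c("CGA", "ACG"))
  # determinism: same seed, same output
  expect_identical(shuffle_columns(p, seed = 9)$mat,
                   shuffle_columns(p, seed = 9)$mat)
})

test_that("free shuffles reach every permutation over many seeds", {
  # consensus A,G,C: no C-followed-by-G column pair, so nothing is glued
  p <- pwm_motif(matrix(c(.97, .01, .01, .01,
                          .01, .01, .97, .01,
                          .01, .97, .01, .01), 4), "agc",
                 pseudocount = 0)
  expect_length(p$cpg_pairs, 0L)
  seen <- vapply(1:200, function(s) pwm_consensus(shuffle_columns(p, s)),
                 character(1))
  expect_setequal(unique(seen),
                  c("ACG", "AGC", "CAG", "CGA", "GAC", "GCA"))
})

test_that("scanning finds consensus hits on both strands", {
  p <- toy_pwm(width = 6)
  cons <- pwm_consensus(p)
  hit <- scan_window(p, cons)
  expect_true(any(hit$offset == 0 & hit$strand == "+" &
                    abs(hit$score - 1) < 1e-12))
  rc <- erosionscan:::revcomp(cons)
  hit2 <- scan_window(p, rc)
  expect_true(any(hit2$offset == 0 & hit2$strand == "-" &
                    abs(hit2$score - 1) < 1e-12))
  # a window set with every score below threshold comes back empty
  anti <- paste(rownames(p$mat)[apply(p$mat, 2, which.min)], collapse = "")
  low <- scan_window(p, anti, threshold = 0.8)
  expect_equal(nrow(low), 0L)
})

test_that("a sequence and its reverse complement yield mirrored hits", {
  p <- toy_pwm(width = 5, seed = 3)
  set.seed(8)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  # threshold -1 returns every window, so the full score surfaces can be
  # compared (hit-set comparison at a threshold is brittle when a window
  # scores exactly at the cutoff)
  fwd <- scan_window(p, seq, threshold = -1)
  rev <- scan_window(p, erosionscan:::revcomp(seq), threshold = -1)
  mirror <- data.frame(
    offset = nchar(seq) - p$width - rev$offset,
    strand = chartr("+-", "-+", rev$strand),
    score = rev$score
  )
  o1 <- fwd[order(fwd$offset, fwd$strand), ]
  o2 <- mirror[order(mirror$offset, mirror$strand), ]
  expect_equal(o1$offset, o2$offset)
  expect_equal(o1$strand, o2$strand)
  expect_equal(o1$score, o2$score, tolerance = 1e-9)
})

test_that("scan hits agree with Biostrings matchPWM at the 80% cutoff", {
  skip_if_not_installed("Biostrings")
  p <- toy_pwm(width = 7, seed = 12)
  set.seed(99)
  seq <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  iw <- information_weights(p)
  W <- sweep(p$mat, 2, iw, "*")
  hits <- Biostrings::matchPWM(W, Biostrings::DNAString(seq),
                               min.score = "80%")
  ours <- scan_window(p, seq, threshold = 0.8, strands = "+")
  expect_setequal(BiocGenerics::start(hits) - 1L, ours$offset)
})
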