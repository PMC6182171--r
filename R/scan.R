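# Vectorised MATCH-score scanning engine.
#
# Sequences are encoded as integers (A=1, C=2, G=3, T=4, anything else 5).
# A motif is converted into a 5-by-width weight matrix W[b, i] = I(i) *
# f(i, b); row 5 is -Inf so windows containing N (or gaps) can never reach
# a positive threshold. The raw window score is a rolling sum of column
# lookups and is min-max normalised into the MATCH score.

encode_dna <- function(seq) {
  if (length(seq) == 1L && nchar(seq) > 1L) {
    seq <- strsplit(seq, "", fixed = TRUE)[[1]]
  }
  code <- match(toupper(seq), c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  code
}

pwm_weights <- function(pwm) {
  iw <- information_weights(pwm)
  w <- pwm$width
  fwd <- matrix(-Inf, nrow = 5L, ncol = w)
  fwd[1:4, ] <- sweep(pwm$mat, 2, iw, "*")
  # reverse-complement weights: scanning the forward sequence with `rev`
  # scores the reverse complement of each window against the motif
  rev <- matrix(-Inf, nrow = 5L, ncol = w)
  rev[1:4, ] <- fwd[4:1, w:1]
  smin <- sum(iw * apply(pwm$mat, 2, min))
  smax <- sum(iw * apply(pwm$mat, 2, max))
  list(fwd = fwd, rev = rev, smin = smin, smax = smax, width = w)
}

# Normalised MATCH scores of every window start in `codes` for one strand
# weight matrix. Returns length(codes) - width + 1 scores (possibly -Inf
# where a window contains N).
scan_scores <- function(codes, W, smin, smax) {
  w <- ncol(W)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (i in seq_len(w)) {
    s <- s + W[codes[i:(i + n - 1L)], i]
  }
  if (smax <= smin) return(rep(0, n))
  (s - smin) / (smax - smin)
}

# Normalised scores at specific 1-based offsets of `codes` (vectorised
# over offsets); used when only candidate windows need rescoring.
score_at_offsets <- function(codes, W, smin, smax, offsets) {
  w <- ncol(W)
  if (length(offsets) == 0L) return(numeric(0))
  idx <- outer(as.integer(offsets), 0:(w - 1L), "+")
  vals <- matrix(W[cbind(as.vector(codes[idx]), rep(seq_len(w), each = length(offsets)))],
                 nrow = length(offsets))
  s <- rowSums(vals)
  if (smax <= smin) return(rep(0, length(offsets)))
  (s - smin) / (smax - smin)
}
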