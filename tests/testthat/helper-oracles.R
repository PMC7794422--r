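# Independent brute-force oracles used to validate the interval algebra,
# the hockey-stick cutoff, the enrichment running sum, BH and the motif
# scanner. They deliberately avoid the code paths under test: everything
# here works on per-base membership arrays, explicit loops or regexes.

CHROM_LEN <- 100000L

random_intervals <- function(n_max = 50, chrom = "chrTest",
                             len = CHROM_LEN) {
  n <- sample.int(n_max, 1)
  start <- sample.int(len - 100L, n, replace = TRUE) - 1L
  width <- sample.int(2000L, n, replace = TRUE)
  data.frame(chrom = chrom, start = start,
             end = pmin(len, start + width), strand = ".",
             stringsAsFactors = FALSE)
}

# per-base membership array for one interval set (single chromosome)
membership <- function(df, len = CHROM_LEN) {
  m <- logical(len)
  for (i in seq_len(nrow(df))) m[(df$start[i] + 1):df$end[i]] <- TRUE
  m
}

# runs of TRUE -> 0-based half-open intervals
runs_to_intervals <- function(m, chrom = "chrTest") {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  sel <- which(r$values)
  data.frame(chrom = rep(chrom, length(sel)), start = starts[sel],
             end = ends[sel], strand = rep(".", length(sel)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# merge oracle: mark bases, bridge gaps <= min_gap by dilation
oracle_merge <- function(df, min_gap = 0, len = CHROM_LEN) {
  m <- membership(df, len)
  if (min_gap > 0) {
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    gap <- which(!r$values)
    for (g in gap) {
      interior <- starts[g] > 0 && ends[g] < len
      if (interior && r$lengths[g] <= min_gap)
        m[(starts[g] + 1):ends[g]] <- TRUE
    }
  }
  runs_to_intervals(m)
}

# consensus oracle: per-base depth of distinct sets >= k
oracle_consensus <- function(sets, k, len = CHROM_LEN) {
  depth <- integer(len)
  for (df in sets) depth <- depth + membership(df, len)
  runs_to_intervals(depth >= k)
}

# co-occupancy oracle: pairwise overlap-width scan
oracle_overlap_hits <- function(a, b, min_overlap = 1) {
  vapply(seq_len(nrow(a)), function(i) {
    any(pmin(a$end[i], b$end) - pmax(a$start[i], b$start) >=
          min_overlap)
  }, TRUE)
}

# hockey-stick oracle: explicit loop over every point's forward slope
oracle_hockey <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  if (s[n] == s[1]) return(Inf)
  cut <- Inf
  for (i in seq_len(n - 1)) {
    x1 <- (i - 1) / (n - 1); x2 <- i / (n - 1)
    y1 <- (s[i] - s[1]) / (s[n] - s[1])
    y2 <- (s[i + 1] - s[1]) / (s[n] - s[1])
    if ((y2 - y1) / (x2 - x1) > 1) { cut <- s[i]; break }
  }
  cut
}

# enrichment-score oracle: step-by-step running sum over the whole
# list; the extreme of larger magnitude wins, positive on exact ties
oracle_es <- function(scores, inset, weight_p = 1) {
  n <- length(scores)
  nh <- sum(inset)
  w <- abs(scores)^weight_p
  tot <- sum(w[inset])
  run <- 0
  hi <- 0
  lo <- 0
  for (i in seq_len(n)) {
    if (inset[i]) run <- run + (if (tot > 0) w[i] / tot else 1 / nh)
    else run <- run - 1 / (n - nh)
    hi <- max(hi, run)
    lo <- min(lo, run)
  }
  unname(if (hi >= -lo - 1e-12) hi else lo)  # positive wins near-ties
}

# quadratic-time BH reference: adj_i = min over {j : p_j >= p_i} of
# m * p_j / rank_j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    cand <- vapply(which(p >= p[i]), function(j)
      m * p[j] / sum(p <= p[j]), 0)
    min(1, cand)
  }, 0)
}

# sliding-window regex E-box oracle (overlapping matches via lookahead)
oracle_ebox_offsets <- function(seq) {
  m <- gregexpr("(?=CA[ACGT][ACGT]TG)", toupper(seq), perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

tiny_track <- function(values, bin = 10, units = "RPM") {
  signal_track(list(chr1 = values), bin_size = bin, units = units)
}
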