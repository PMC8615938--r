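# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the package: the aligner oracle
# enumerates every alignment recursively; the SOV oracle re-derives segments
# by character scanning and evaluates the published formula term by term.

# 4-letter test alphabet and a small substitution matrix with positive
# diagonal, mixed off-diagonal scores.
toy_alphabet <- c("A", "C", "G", "T")
toy_matrix <- matrix(
  c( 5, -1, -2, -1,
    -1,  6, -3, -2,
    -2, -3,  5, -1,
    -1, -2, -1,  4),
  4, 4, byrow = TRUE, dimnames = list(toy_alphabet, toy_alphabet))

# Exhaustive global alignment score: explore every monotone path of
# diagonal / gap-in-B / gap-in-A moves and keep the best total. Gap runs
# are charged incrementally (opening a run costs the length-1 gap cost,
# each extension costs `ext`), which prices a run of length L at
# open + ext*L (blast) or open + ext*(L-1) (emboss).
oracle_global_score <- function(a, b, S = toy_matrix, open = 11, ext = 2,
                                emboss = FALSE) {
  first <- if (emboss) open else open + ext
  n <- length(a); m <- length(b)
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (i == n && j == m) {
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i < n && j < m) rec(i + 1, j + 1, sc + S[a[i + 1], b[j + 1]], "D")
    if (i < n) rec(i + 1, j, sc - (if (last == "X") ext else first), "X")
    if (j < m) rec(i, j + 1, sc - (if (last == "Y") ext else first), "Y")
  }
  rec(0L, 0L, 0, "")
  best
}

# Exhaustive local alignment score: best global score over every pair of
# contiguous substrings, floored at 0 (the empty local alignment).
oracle_local_score <- function(a, b, S = toy_matrix, open = 11, ext = 2,
                               emboss = FALSE) {
  best <- 0
  n <- length(a); m <- length(b)
  for (i1 in seq_len(n)) for (i2 in i1:n)
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      sc <- oracle_global_score(a[i1:i2], b[j1:j2], S, open, ext, emboss)
      if (sc > best) best <- sc
    }
  best
}

# Character-scanning segmentation (no rle), honoring breaks.
oracle_segments <- function(s, breaks = integer()) {
  ch <- strsplit(s, "")[[1]]
  out <- list()
  st <- 1L
  for (k in seq_along(ch)) {
    if (k == length(ch) || ch[k + 1L] != ch[k] || (k %in% breaks)) {
      out[[length(out) + 1L]] <- list(state = ch[st], start = st, end = k,
                                      len = k - st + 1L)
      st <- k + 1L
    }
  }
  out
}

# Term-by-term SOV v'99: double loop over observed/predicted segments of
# each state; delta = min(maxov - minov, minov, floor(len1/2),
# floor(len2/2)); observed segments with no same-state overlap enter only
# the normalizer.
oracle_sov <- function(obs, pred, breaks = integer()) {
  so <- oracle_segments(obs, breaks)
  sp <- oracle_segments(pred, breaks)
  total <- 0
  N <- 0
  for (st in unique(vapply(so, `[[`, "", "state"))) {
    o_st <- Filter(function(s) s$state == st, so)
    p_st <- Filter(function(s) s$state == st, sp)
    for (s1 in o_st) {
      ov <- Filter(function(s2) s2$start <= s1$end && s2$end >= s1$start, p_st)
      if (length(ov) == 0L) {
        N <- N + s1$len
        next
      }
      for (s2 in ov) {
        minov <- min(s1$end, s2$end) - max(s1$start, s2$start) + 1L
        maxov <- max(s1$end, s2$end) - min(s1$start, s2$start) + 1L
        delta <- min(maxov - minov, minov,
                     floor(s1$len / 2), floor(s2$len / 2))
        total <- total + (minov + delta) / maxov * s1$len
        N <- N + s1$len
      }
    }
  }
  100 * total / N
}

# Random SSE strings: iid uniform codes, or segment-structured runs, for
# property tests.
random_sse <- function(len, states = c("H", "E", "C"), segmenty = FALSE) {
  if (!segmenty)
    return(paste(sample(states, len, replace = TRUE), collapse = ""))
  out <- character(0)
  while (length(out) < len) {
    st <- sample(states, 1L)
    out <- c(out, rep(st, sample.int(7L, 1L)))
  }
  paste(out[seq_len(len)], collapse = "")
}

random_records <- function(n, len_range = c(80L, 200L),
                           states = SSE_STATES8, p = rep(1 / 8, 8)) {
  recs <- lapply(seq_len(n), function(i) {
    len <- sample(seq.int(len_range[1L], len_range[2L]), 1L)
    protein_record(sprintf("r%04d", i),
                   paste(sample(setdiff(AA_ALPHABET20X_test, "X"), len,
                                replace = TRUE), collapse = ""),
                   paste(sample(states, len, replace = TRUE, prob = p),
                         collapse = ""))
  })
  names(recs) <- vapply(recs, `[[`, "", "id")
  recs
}

AA_ALPHABET20X_test <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
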