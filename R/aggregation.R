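# Run expr with a private, seeded RNG stream; the caller's RNG state is
# untouched. All randomness in the package flows through this.
with_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Size-weighted average of per-pair measures
#'
#' The aggregation rule for Q and SOV across protein pairs: a weighted mean
#' with the number of aligned equivalent residue pairs (n_e) of each protein
#' pair as the weight, so that small proteins are not over-represented
#' relative to large ones.
#'
#' @param values Numeric vector of per-pair measure values (percent).
#' @param weights Positive weights, same length (typically n_e).
#' @return The weighted mean.
#' @examples
#' weighted_mean(c(90, 80), c(100, 300))  # 82.5
#' @export
weighted_mean <- function(values, weights) {
  if (length(values) == 0L) stop("weighted mean of an empty set is undefined")
  if (length(values) != length(weights)) stop("values/weights length mismatch")
  if (any(weights <= 0)) stop("weights must be positive")
  sum(values * weights) / sum(weights)
}

#' Identity bin schemes
#'
#' The three ways pairs are grouped by percent sequence identity:
#' `"level"` bins are half-open intervals [e_j, e_{j+1}) over consecutive
#' edges, with a singleton bin at exactly 100 when 100 is the last edge and
#' an explicit underflow bin below the first edge; `"threshold"` bins are
#' cumulative (identity >= e_j, one bin per edge); `"cutoff"` bins are
#' cumulative from below (identity < e_j).
#'
#' The default level edges use the mixed widths of the benchmark tables:
#' 5-wide from 10 to 60, 10-wide from 60 to 100, plus the singleton 100.
#'
#' @param kind `"level"`, `"threshold"` or `"cutoff"`.
#' @param edges Strictly increasing percent values in [0, 100].
#' @return An object of class `identity_bin_scheme`.
#' @export
identity_bin_scheme <- function(kind = c("level", "threshold", "cutoff"),
                                edges = NULL) {
  kind <- match.arg(kind)
  if (is.null(edges))
    edges <- switch(kind,
                    level = c(seq(10, 60, by = 5), seq(70, 100, by = 10)),
                    threshold = ,
                    cutoff = c(seq(10, 60, by = 5), seq(70, 100, by = 10)))
  edges <- as.numeric(edges)
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
  if (any(edges < 0 | edges > 100)) stop("edges must lie in [0, 100]")
  structure(list(kind = kind, edges = edges), class = "identity_bin_scheme")
}

MEASURES <- c("q3", "q8", "sov3", "sov8")

bin_summary_row <- function(label, lo, hi, sub) {
  out <- data.frame(label = label, lo = lo, hi = hi,
                    n_pairs = nrow(sub), total_weight = sum(sub$n_e),
                    stringsAsFactors = FALSE)
  for (m in MEASURES)
    out[[m]] <- if (nrow(sub)) weighted_mean(sub[[m]], sub$n_e) else NA_real_
  out
}

#' Aggregate pair results by identity bin
#'
#' Groups scored pairs by percent identity according to an
#' [identity_bin_scheme()] and aggregates Q3/Q8/SOV3/SOV8 within each bin by
#' the n_e-weighted mean ([weighted_mean()]). Level bins partition the
#' scored pairs (including an underflow bin below the lowest edge and a
#' singleton bin at exactly 100); threshold and cutoff bins are cumulative
#' and overlap by construction. Pairs with undefined identity or flagged
#' unscorable are excluded and counted in the `"excluded"` attribute.
#'
#' @param pairs A pair table (one row per pair with columns `identity`,
#'   `n_e`, `q3`, `q8`, `sov3`, `sov8`), as written by the pipeline or
#'   built from [score_homolog_pair()] results.
#' @param scheme An [identity_bin_scheme()].
#' @return A data.frame with one row per bin: `scheme`, `label`, `lo`, `hi`,
#'   `n_pairs`, `total_weight`, and the four weighted means.
#' @export
bin_pair_results <- function(pairs, scheme = identity_bin_scheme("level")) {
  stopifnot(inherits(scheme, "identity_bin_scheme"))
  if (inherits(pairs, "pair_result")) pairs <- list(pairs)
  if (is.list(pairs) && !is.data.frame(pairs)) pairs <- pair_results_table(pairs)
  drop <- is.na(pairs$identity) | is.na(pairs$q3) |
    (if ("unscorable" %in% names(pairs)) pairs$unscorable else FALSE)
  excluded <- sum(drop)
  pairs <- pairs[!drop, , drop = FALSE]
  e <- scheme$edges
  rows <- list()
  if (scheme$kind == "level") {
    singleton100 <- e[length(e)] == 100
    if (any(pairs$identity < e[1L]))
      rows[[length(rows) + 1L]] <- bin_summary_row(
        paste0("<", e[1L]), -Inf, e[1L],
        pairs[pairs$identity < e[1L], , drop = FALSE])
    for (j in seq_len(length(e) - 1L)) {
      sub <- pairs[pairs$identity >= e[j] & pairs$identity < e[j + 1L], ,
                   drop = FALSE]
      rows[[length(rows) + 1L]] <-
        bin_summary_row(sprintf("%g-%g", e[j], e[j + 1L]), e[j], e[j + 1L], sub)
    }
    if (singleton100) {
      sub <- pairs[pairs$identity == 100, , drop = FALSE]
      rows[[length(rows) + 1L]] <- bin_summary_row("100", 100, 100, sub)
    }
  } else if (scheme$kind == "threshold") {
    for (t in e)
      rows[[length(rows) + 1L]] <- bin_summary_row(
        sprintf(">=%g", t), t, 100,
        pairs[pairs$identity >= t, , drop = FALSE])
  } else {
    for (t in e)
      rows[[length(rows) + 1L]] <- bin_summary_row(
        sprintf("<%g", t), -Inf, t,
        pairs[pairs$identity < t, , drop = FALSE])
  }
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(scheme = scheme$kind, stringsAsFactors = FALSE), out)
  attr(out, "excluded") <- excluded
  out
}

#' All-against-all scoring within a family
#'
#' Scores every unordered pair of family members exactly once (n(n-1)/2
#' results for n members), in deterministic (idA, idB) order by sorted id.
#' Pair identity keys are order-normalized, so no A/B duplicate can occur.
#'
#' @param family A list of [protein_record()] objects (>= 2 members; a
#'   smaller family yields an empty list with a warning).
#' @param aligner Passed to [score_homolog_pair()]: [alignment_params()], or
#'   a function `(recA, recB) -> correspondence` supplying external (e.g.
#'   true or structural) correspondences.
#' @param orientation SOV orientation (see [sov_score()]).
#' @return A list of `pair_result` objects.
#' @export
family_all_vs_all <- function(family, aligner = alignment_params(),
                              orientation = "symmetric_mean") {
  if (length(family) < 2L) {
    warning("family has fewer than 2 members; nothing to score")
    return(list())
  }
  ids <- vapply(family, `[[`, "", "id")
  family <- family[order(ids)]
  n <- length(family)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      a <- if (is.function(aligner)) aligner(family[[i]], family[[j]])
      else aligner
      out[[length(out) + 1L]] <-
        score_homolog_pair(family[[i]], family[[j]], a, orientation)
    }
  }
  out
}

#' Fold-level representative value
#'
#' Collapses all scorable pairs of one fold (across its families) to a
#' single value per measure by the size-weighted mean. The default weight is
#' each pair's aligned-residue count n_e (the weight of the averaging
#' equations); `weight = "mean_length"` uses the mean of the two chain
#' lengths instead.
#'
#' @param pairs Pair table or list of `pair_result`s belonging to one fold.
#' @param weight `"ne"` or `"mean_length"`.
#' @return One-row data.frame with `n_pairs` and the four measures, or
#'   `NULL` when no pair is scorable.
#' @export
fold_value <- function(pairs, weight = c("ne", "mean_length")) {
  weight <- match.arg(weight)
  if (is.list(pairs) && !is.data.frame(pairs)) pairs <- pair_results_table(pairs)
  pairs <- pairs[!pairs$unscorable & !is.na(pairs$q3), , drop = FALSE]
  if (nrow(pairs) == 0L) return(NULL)
  w <- if (weight == "ne") pairs$n_e else (pairs$lenA + pairs$lenB) / 2
  out <- data.frame(n_pairs = nrow(pairs))
  for (m in MEASURES) out[[m]] <- weighted_mean(pairs[[m]], w)
  out
}

#' Repeat statistics over random fold subsets
#'
#' Randomly partitions fold-level values into k near-equal subsets (seeded
#' shuffle), averages each subset (unweighted mean over folds), and reports
#' the mean and sample standard deviation (k - 1 denominator) across the k
#' subset means — the repeat-statistics construction used for the benchmark
#' error bars.
#'
#' @param fold_values Numeric vector, or a data.frame with one row per fold
#'   and one column per measure.
#' @param k Number of subsets (>= 2; also need at least k folds).
#' @param seed Integer seed controlling the partition.
#' @return A data.frame with one row per measure: `measure`, `k`, `mean`,
#'   `sd`.
#' @export
subset_statistics <- function(fold_values, k = 10L, seed = 1L) {
  if (is.numeric(fold_values)) fold_values <- data.frame(value = fold_values)
  n <- nrow(fold_values)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop(sprintf("need at least k = %d folds, have %d", k, n))
  assign_subset <- with_rng(seed, rep_len(seq_len(k), n)[sample.int(n)])
  rows <- lapply(names(fold_values), function(m) {
    subset_means <- vapply(seq_len(k), function(s)
      mean(fold_values[[m]][assign_subset == s]), numeric(1))
    data.frame(measure = m, k = k, mean = mean(subset_means),
               sd = stats::sd(subset_means), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

segs_from_chars <- function(ch) {
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  data.frame(state = r$values, start = ends - r$lengths + 1L, end = ends,
             length = r$lengths, stringsAsFactors = FALSE)
}

#' Random-pairing lower bound
#'
#' Scores a large sample of randomly paired, generally unrelated proteins to
#' mark the floor of the consistency measures: the score a predictor would
#' get by reproducing typical secondary-structure composition with no
#' signal. Pairs of distinct records are sampled uniformly with replacement.
#' Unequal lengths are handled by the `projection`: `"prefix"` pairs
#' position k with position k up to the shorter length; `"global_seq_align"`
#' takes the correspondence from the global affine-gap aligner. SOV uses the
#' symmetric mean orientation.
#'
#' @param records List of [protein_record()] objects (>= 2).
#' @param n_pairs Number of random pairs to score.
#' @param seed Integer seed.
#' @param projection `"prefix"` or `"global_seq_align"`.
#' @param params [alignment_params()] for the aligned projection.
#' @return A list with `means` (named: q3, q8, sov3, sov8), `hist` (a
#'   data.frame of 1-percent-wide bins: `measure`, `bin`, `count`),
#'   `n_pairs`, `projection`, `seed`.
#' @export
random_pair_null <- function(records, n_pairs, seed = 1L,
                             projection = c("prefix", "global_seq_align"),
                             params = alignment_params()) {
  projection <- match.arg(projection)
  if (length(records) < 2L) stop("need at least 2 records")
  if (n_pairs < 1L) stop("n_pairs must be >= 1")
  lens <- vapply(records, `[[`, integer(1), "length")
  if (all(lens == 0L)) stop("all records are empty")
  ch8 <- lapply(records, function(r) strsplit(r$sse8, "")[[1]])
  ch3 <- lapply(ch8, function(x) chartr("HGIEBSTC", "HHHEECCC",
                                        paste(x, collapse = "")))
  ch3 <- lapply(ch3, function(s) strsplit(s, "")[[1]])
  nrec <- length(records)
  ij <- with_rng(seed, {
    i <- sample.int(nrec, n_pairs, replace = TRUE)
    j <- sample.int(nrec - 1L, n_pairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    cbind(i, j)
  })
  scores <- matrix(NA_real_, n_pairs, 4L,
                   dimnames = list(NULL, MEASURES))
  for (p in seq_len(n_pairs)) {
    i <- ij[p, 1L]; j <- ij[p, 2L]
    if (projection == "prefix") {
      m <- min(lens[i], lens[j])
      if (m == 0L) next
      a8 <- ch8[[i]][seq_len(m)]; b8 <- ch8[[j]][seq_len(m)]
      a3 <- ch3[[i]][seq_len(m)]; b3 <- ch3[[j]][seq_len(m)]
    } else {
      al <- align_pair(records[[i]]$sequence, records[[j]]$sequence, params)
      corr <- equivalent_pairs(al)
      if (nrow(corr) == 0L) next
      a8 <- ch8[[i]][corr$pos_a]; b8 <- ch8[[j]][corr$pos_b]
      a3 <- ch3[[i]][corr$pos_a]; b3 <- ch3[[j]][corr$pos_b]
    }
    s8a <- segs_from_chars(a8); s8b <- segs_from_chars(b8)
    s3a <- segs_from_chars(a3); s3b <- segs_from_chars(b3)
    scores[p, ] <- c(100 * mean(a3 == b3), 100 * mean(a8 == b8),
                     (sov_eval(s3a, s3b) + sov_eval(s3b, s3a)) / 2,
                     (sov_eval(s8a, s8b) + sov_eval(s8b, s8a)) / 2)
  }
  ok <- !is.na(scores[, 1L])
  hist <- do.call(rbind, lapply(MEASURES, function(m) {
    b <- pmin(floor(scores[ok, m]), 100)
    tab <- table(factor(b, levels = 0:100))
    data.frame(measure = m, bin = 0:100, count = as.integer(tab),
               stringsAsFactors = FALSE)
  }))
  list(means = colMeans(scores[ok, , drop = FALSE]),
       sds = apply(scores[ok, , drop = FALSE], 2L, stats::sd),
       hist = hist, n_pairs = n_pairs, n_scored = sum(ok),
       projection = projection, seed = seed)
}
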