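#' Aligned SSE pair
#'
#' Two equal-length SSE strings over equivalent residues (from
#' [project_sse()] or constructed directly, e.g. for a prediction against
#' the true assignment of the same protein), with continuity breaks and
#' optional per-position annotations. All per-pair scores (Q, SOV,
#' per-state conservation) operate on this object.
#'
#' @param obs,pred Equal-length SSE strings; `obs` is the observed/reference
#'   side where an orientation matters.
#' @param breaks Integer positions (pair coordinates) after which continuity
#'   is broken; segments never span a break.
#' @param ann Optional named list of per-position annotation vectors.
#' @return An object of class `aligned_sse_pair`.
#' @export
aligned_sse_pair <- function(obs, pred, breaks = integer(), ann = list()) {
  if (nchar(obs) != nchar(pred))
    stop(sprintf("obs length %d != pred length %d", nchar(obs), nchar(pred)))
  n <- nchar(obs)
  breaks <- sort(unique(as.integer(breaks)))
  breaks <- breaks[breaks >= 1L & breaks < n]
  for (nm in names(ann))
    if (!is.null(ann[[nm]]) && length(ann[[nm]]) != n)
      stop(sprintf("annotation '%s' has length %d, expected %d",
                   nm, length(ann[[nm]]), n))
  structure(list(obs = obs, pred = pred, breaks = breaks, ann = ann, n = n),
            class = "aligned_sse_pair")
}

pair_states <- function(pair, states) {
  stopifnot(states %in% c(3L, 8L))
  if (states == 3L)
    list(obs = reduce_to_three(pair$obs), pred = reduce_to_three(pair$pred))
  else
    list(obs = pair$obs, pred = pair$pred)
}

#' Residue-level SSE consistency (Q measure)
#'
#' The percent secondary-structure consistency over aligned equivalent
#' residues: 100 x n_c / n_e, where n_e is the number of equivalent residue
#' pairs and n_c the number of those with identical SSE codes. With
#' `states = 3` both strings are reduced via [reduce_to_three()] first
#' (giving Q3); `states = 8` compares the raw 8-state codes (Q8). When one
#' side is a prediction of the other protein's structure this equals the
#' usual Q3/Q8 prediction accuracy.
#'
#' @param pair An [aligned_sse_pair()] with at least one position.
#' @param states 3 or 8.
#' @return Percent in [0, 100].
#' @examples
#' p <- aligned_sse_pair("HHHCHHHCHHHC", "HHHHHHHCHHHC")
#' q_score(p, 3)  # 91.7 (11 of 12 residues agree)
#' @export
q_score <- function(pair, states = 3L) {
  if (pair$n == 0L) stop("Q undefined for an empty pair (n_e = 0)")
  ss <- pair_states(pair, states)
  a <- strsplit(ss$obs, "")[[1]]
  b <- strsplit(ss$pred, "")[[1]]
  100 * sum(a == b) / pair$n
}

# Core SOV v'99 evaluator over two segmentations of the same coordinate
# axis. For each state, every overlapping (observed, predicted) segment
# pair contributes len(s1) * (minov + delta) / maxov, with
# delta = min(maxov - minov, minov, floor(len(s1)/2), floor(len(s2)/2));
# observed segments with no same-state overlap contribute only to the
# normalizer N.
sov_eval <- function(obs_segs, pred_segs) {
  total <- 0
  N <- 0
  for (st in unique(obs_segs$state)) {
    o <- obs_segs[obs_segs$state == st, , drop = FALSE]
    p <- pred_segs[pred_segs$state == st, , drop = FALSE]
    if (nrow(p) == 0L) {
      N <- N + sum(o$length)
      next
    }
    minov <- outer(o$end, p$end, pmin) - outer(o$start, p$start, pmax) + 1
    hit <- minov > 0
    maxov <- outer(o$end, p$end, pmax) - outer(o$start, p$start, pmin) + 1
    len1 <- matrix(o$length, nrow(o), nrow(p))
    len2 <- matrix(p$length, nrow(o), nrow(p), byrow = TRUE)
    delta <- pmin(maxov - minov, minov, len1 %/% 2, len2 %/% 2)
    terms <- (minov + delta) / maxov * len1
    total <- total + sum(terms[hit])
    no_hit <- rowSums(hit) == 0
    N <- N + sum(len1[hit]) + sum(o$length[no_hit])
  }
  if (N == 0) stop("SOV normalizer is zero")
  100 * total / N
}

#' Segment-overlap score (SOV, v'99 definition)
#'
#' Segment-based SSE agreement: same-state observed/predicted segment pairs
#' are rewarded by their overlap ratio with a bounded allowance delta, and
#' the score is normalized over observed segment lengths. Segments are the
#' maximal single-state runs of each string (split at continuity breaks,
#' never merged across unaligned stretches). The allowance uses integer
#' floor for the half-segment-length caps, the defining v'99 choice.
#'
#' For homolog pairs there is no natural observed/predicted role, so
#' `orientation = "symmetric_mean"` (the aggregation default) averages the
#' score over both role assignments; `"first_as_observed"` treats `obs` as
#' the reference, the convention for scoring a prediction.
#'
#' @param pair An [aligned_sse_pair()] with at least one position.
#' @param states 3 or 8.
#' @param orientation `"first_as_observed"` or `"symmetric_mean"`.
#' @return Percent in [0, 100].
#' @examples
#' p <- aligned_sse_pair("HHHCHHHCHHHC", "HHHHHHHCHHHC")
#' sov_score(p, 3, "first_as_observed")  # 70.2
#' @export
sov_score <- function(pair, states = 3L,
                      orientation = c("first_as_observed", "symmetric_mean")) {
  orientation <- match.arg(orientation)
  if (pair$n == 0L) stop("SOV undefined for an empty pair (n_e = 0)")
  ss <- pair_states(pair, states)
  so <- segmentize(ss$obs, pair$breaks)
  sp <- segmentize(ss$pred, pair$breaks)
  if (orientation == "first_as_observed") sov_eval(so, sp)
  else (sov_eval(so, sp) + sov_eval(sp, so)) / 2
}

#' Per-state conservation table
#'
#' For each SSE code of the chosen state set present in the observed string:
#' how many observed residues carry it (`n_obs`), how many of those are
#' conserved in the other string (`n_conserved`), and the conservation
#' percent. Codes absent from the observed string get no row.
#'
#' @param pair An [aligned_sse_pair()].
#' @param states 3 or 8.
#' @return A data.frame with columns `state`, `n_obs`, `n_conserved`,
#'   `percent`.
#' @export
per_state_conservation <- function(pair, states = 8L) {
  if (pair$n == 0L) stop("undefined for an empty pair")
  ss <- pair_states(pair, states)
  a <- strsplit(ss$obs, "")[[1]]
  b <- strsplit(ss$pred, "")[[1]]
  codes <- if (states == 3L) SSE_STATES3 else SSE_STATES8
  rows <- lapply(codes, function(st) {
    n_obs <- sum(a == st)
    if (n_obs == 0L) return(NULL)
    n_con <- sum(a == st & b == st)
    data.frame(state = st, n_obs = n_obs, n_conserved = n_con,
               percent = 100 * n_con / n_obs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Annotation-masked Q
#'
#' The Q measure restricted to a subset of aligned positions, for
#' conditioning consistency on per-residue properties such as solvent
#' accessibility or flexibility. `mask_rsa()` and `mask_bfactor()` build
#' standard masks from the pair's carried annotations: accessible means
#' RSA >= 0.25 on the annotation side (the usual accessibility threshold),
#' and high/low flexibility splits the normalized B-factor at a threshold.
#'
#' @param pair An [aligned_sse_pair()].
#' @param mask Logical vector, one value per pair position.
#' @param states 3 or 8.
#' @return A list with `percent` (masked Q) and `n_retained`.
#' @examples
#' p <- aligned_sse_pair("HHHCHHHCHHHC", "HHHHHHHCHHHC")
#' masked_q(p, c(rep(TRUE, 6), rep(FALSE, 6)), 3)$percent  # 83.3
#' @export
masked_q <- function(pair, mask, states = 3L) {
  if (length(mask) != pair$n)
    stop(sprintf("mask length %d != pair length %d", length(mask), pair$n))
  mask <- as.logical(mask)
  if (anyNA(mask)) stop("mask must be defined (non-NA) at every position")
  if (!any(mask)) stop("mask retains no positions; masked Q undefined")
  ss <- pair_states(pair, states)
  a <- strsplit(ss$obs, "")[[1]][mask]
  b <- strsplit(ss$pred, "")[[1]][mask]
  list(percent = 100 * sum(a == b) / sum(mask), n_retained = sum(mask))
}

#' @rdname masked_q
#' @param side `"a"` or `"b"`: which record's annotation drives the mask.
#' @param accessible If `TRUE`, retain accessible residues (RSA >=
#'   `threshold`); otherwise buried ones.
#' @param threshold RSA fraction (default 0.25) or normalized B-factor
#'   cutoff.
#' @export
mask_rsa <- function(pair, side = "a", accessible = TRUE, threshold = 0.25) {
  rsa <- pair$ann[[paste0("rsa_", side)]]
  if (is.null(rsa)) stop("pair carries no RSA annotation on side ", side)
  if (accessible) rsa >= threshold else rsa < threshold
}

#' @rdname masked_q
#' @param high If `TRUE`, retain positions with normalized B-factor >=
#'   `threshold`.
#' @export
mask_bfactor <- function(pair, side = "a", high = TRUE, threshold = 0) {
  bf <- pair$ann[[paste0("bfactor_", side)]]
  if (is.null(bf)) stop("pair carries no B-factor annotation on side ", side)
  if (high) bf >= threshold else bf < threshold
}

#' Score one homolog pair
#'
#' The full per-pair scoring step: obtain a residue correspondence (either
#' by running the built-in aligner with the given [alignment_params()], or
#' directly from a supplied [correspondence()], e.g. a structural
#' alignment), project the SSE strings, and compute identity, n_e, Q3, Q8,
#' SOV3, SOV8 and the per-state conservation table. A pair with an empty
#' correspondence is returned flagged `unscorable` rather than scored 0.
#'
#' @param recA,recB [protein_record()] objects.
#' @param aligner An [alignment_params()] object (sequence alignment is
#'   computed) or a [correspondence()] (used as-is; identity is then counted
#'   over the corresponding residues).
#' @param orientation SOV orientation, see [sov_score()]; homolog pairs
#'   default to the symmetric mean.
#' @return A list of class `pair_result`: ids, `identity`, `n_e`, `q3`,
#'   `q8`, `sov3`, `sov8`, `per_state` (8-state table), `unscorable` flag.
#' @export
score_homolog_pair <- function(recA, recB, aligner = alignment_params(),
                               orientation = c("symmetric_mean",
                                               "first_as_observed")) {
  orientation <- match.arg(orientation)
  if (inherits(aligner, "alignment_params")) {
    al <- align_pair(recA$sequence, recB$sequence, aligner,
                     idA = recA$id, idB = recB$id)
    corr <- equivalent_pairs(al)
    identity <- if (length(al$a_pos)) percent_identity(al) else NA_real_
  } else if (inherits(aligner, "correspondence")) {
    corr <- aligner
    identity <- if (nrow(corr)) {
      s1 <- substring(recA$sequence, corr$pos_a, corr$pos_a)
      s2 <- substring(recB$sequence, corr$pos_b, corr$pos_b)
      100 * sum(s1 == s2) / nrow(corr)
    } else NA_real_
  } else {
    stop("`aligner` must be alignment_params() or a correspondence")
  }
  if (nrow(corr) == 0L) {
    return(structure(list(idA = recA$id, idB = recB$id, identity = NA_real_,
                          n_e = 0L, q3 = NA_real_, q8 = NA_real_,
                          sov3 = NA_real_, sov8 = NA_real_, per_state = NULL,
                          lenA = recA$length, lenB = recB$length,
                          family_id = recA$family_id, fold_id = recA$fold_id,
                          unscorable = TRUE),
                     class = "pair_result"))
  }
  pair <- project_sse(corr, recA, recB)
  structure(list(idA = recA$id, idB = recB$id, identity = identity,
                 n_e = pair$n,
                 q3 = q_score(pair, 3L), q8 = q_score(pair, 8L),
                 sov3 = sov_score(pair, 3L, orientation),
                 sov8 = sov_score(pair, 8L, orientation),
                 per_state = per_state_conservation(pair, 8L),
                 lenA = recA$length, lenB = recB$length,
                 family_id = recA$family_id, fold_id = recA$fold_id,
                 unscorable = FALSE),
            class = "pair_result")
}

# Flatten pair_result objects into the documented one-row-per-pair table:
# idA, idB, identity, n_e, q3, q8, sov3, sov8, then per-state columns
# nobs_<code>, cons_<code>, pct_<code> for the eight states.
pair_results_table <- function(results) {
  rows <- lapply(results, function(r) {
    row <- data.frame(idA = r$idA, idB = r$idB, identity = r$identity,
                      n_e = r$n_e, q3 = r$q3, q8 = r$q8,
                      sov3 = r$sov3, sov8 = r$sov8,
                      lenA = r$lenA, lenB = r$lenB,
                      family_id = if (is.null(r$family_id)) NA_character_ else r$family_id,
                      fold_id = if (is.null(r$fold_id)) NA_character_ else r$fold_id,
                      unscorable = isTRUE(r$unscorable),
                      stringsAsFactors = FALSE)
    for (st in SSE_STATES8) {
      i <- if (!is.null(r$per_state)) match(st, r$per_state$state) else NA
      row[[paste0("nobs_", st)]] <- if (!is.na(i)) r$per_state$n_obs[i] else 0L
      row[[paste0("cons_", st)]] <- if (!is.na(i)) r$per_state$n_conserved[i] else 0L
      row[[paste0("pct_", st)]] <- if (!is.na(i)) r$per_state$percent[i] else NA_real_
    }
    row
  })
  do.call(rbind, rows)
}
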