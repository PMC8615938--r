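#' Segment-grammar parameters for synthetic proteins
#'
#' Synthetic proteins are drawn from a simple segment grammar: secondary
#' structure segments with state-specific length distributions, filled with
#' amino acids drawn from state-conditioned propensities. The defaults
#' emulate globular-protein composition — helix-rich with moderate strand
#' content — with residue-level state frequencies and typical segment
#' lengths (helices ~10 residues, strands and coil ~5); exact values are
#' configuration, not biological claims.
#'
#' @param state_frequencies Named numeric: target residue-level marginal
#'   frequency of each 8-state code (must sum to 1).
#' @param segment_length_means Named numeric: mean segment length per state.
#' @param min_segment_length Named integer: minimum segment length per state
#'   (`means >= mins >= 1`).
#' @param aa_propensities Matrix (states x 20 amino acids) of per-state
#'   amino-acid sampling weights; rows are renormalized.
#' @return An object of class `grammar_params`.
#' @export
grammar_params <- function(state_frequencies = NULL,
                           segment_length_means = NULL,
                           min_segment_length = NULL,
                           aa_propensities = NULL) {
  if (is.null(state_frequencies))
    state_frequencies <- c(H = 0.30, G = 0.04, I = 0.01, E = 0.21,
                           B = 0.01, S = 0.08, T = 0.11, C = 0.24)
  if (is.null(segment_length_means))
    segment_length_means <- c(H = 10, G = 3, I = 5, E = 5,
                              B = 1, S = 2, T = 3, C = 5)
  if (is.null(min_segment_length))
    min_segment_length <- c(H = 4, G = 3, I = 5, E = 2,
                            B = 1, S = 1, T = 2, C = 1)
  states <- names(state_frequencies)
  stopifnot(setequal(states, SSE_STATES8) || all(states %in% SSE_STATES8))
  state_frequencies <- state_frequencies / sum(state_frequencies)
  if (abs(sum(state_frequencies) - 1) > 1e-9)
    stop("state frequencies must sum to 1")
  m <- segment_length_means[states]
  lo <- min_segment_length[states]
  if (anyNA(m) || anyNA(lo)) stop("length parameters missing for some state")
  if (any(m < lo) || any(lo < 1))
    stop("need segment_length_means >= min_segment_length >= 1")
  if (is.null(aa_propensities)) {
    aa <- setdiff(AA_ALPHABET20X, "X")
    aa_propensities <- matrix(1, length(states), length(aa),
                              dimnames = list(states, aa))
    helix_formers <- strsplit("AELMQKR", "")[[1]]
    sheet_formers <- strsplit("VIFYWTC", "")[[1]]
    coil_formers <- strsplit("GPSND", "")[[1]]
    for (st in states) {
      pref <- switch(reduce_to_three(st),
                     H = helix_formers, E = sheet_formers, C = coil_formers)
      aa_propensities[st, pref] <- 3
    }
  }
  aa_propensities <- sweep(aa_propensities, 1, rowSums(aa_propensities), "/")
  structure(list(state_frequencies = state_frequencies,
                 segment_length_means = m, min_segment_length = lo,
                 aa_propensities = aa_propensities, states = states),
            class = "grammar_params")
}

# State-conditioned per-residue annotations: buried-prone strands/helices,
# exposed-prone coil; normalized B-factor elevated in coil.
sample_annotations <- function(states3, n = length(states3)) {
  rsa <- numeric(n)
  bf <- numeric(n)
  for (cl in c("H", "E", "C")) {
    k <- states3 == cl
    if (!any(k)) next
    rsa[k] <- switch(cl, H = stats::rbeta(sum(k), 2, 3),
                     E = stats::rbeta(sum(k), 1.2, 4),
                     C = stats::rbeta(sum(k), 2.5, 2.5))
    bf[k] <- stats::rnorm(sum(k),
                          mean = switch(cl, H = -0.2, E = -0.3, C = 0.35),
                          sd = 0.9)
  }
  list(rsa = rsa, bfactor_norm = bf)
}

sample_segment_length <- function(state, grammar) {
  m <- grammar$segment_length_means[[state]]
  lo <- grammar$min_segment_length[[state]]
  if (m <= lo) return(as.integer(lo))
  lo + stats::rgeom(1L, prob = 1 / (1 + m - lo))
}

#' Sample a synthetic protein
#'
#' Draws secondary-structure segments until the target length is reached
#' (the final segment is truncated at the boundary), then fills in amino
#' acids from the state-conditioned propensities and state-dependent RSA /
#' normalized B-factor annotations. Segment states are drawn with
#' probability proportional to frequency / mean segment length, so that the
#' residue-level state marginals match `state_frequencies`.
#'
#' @param grammar A [grammar_params()] object.
#' @param length Target residue count (at least the largest per-state
#'   minimum segment length).
#' @param seed Integer seed; the same seed reproduces the record exactly.
#' @param id,family_id,fold_id,class_label Labels stored on the record.
#' @return A [protein_record()].
#' @export
sample_protein <- function(grammar = grammar_params(), length, seed,
                           id = "synth", family_id = NA_character_,
                           fold_id = NA_character_,
                           class_label = NA_character_) {
  if (length < max(grammar$min_segment_length))
    stop("target length shorter than the largest minimum segment length")
  with_rng(seed, {
    seg_w <- grammar$state_frequencies / grammar$segment_length_means
    seg_w <- seg_w / sum(seg_w)
    sse <- character(0)
    while (base::length(sse) < length) {
      st <- sample(grammar$states, 1L, prob = seg_w)
      sse <- c(sse, rep(st, sample_segment_length(st, grammar)))
    }
    sse <- sse[seq_len(length)]
    aa <- vapply(sse, function(st)
      sample(colnames(grammar$aa_propensities), 1L,
             prob = grammar$aa_propensities[st, ]), "")
    ann <- sample_annotations(chartr("GIEB", "HHEE",
                                     chartr("ST", "CC", sse)))
    protein_record(id = id, sequence = paste(aa, collapse = ""),
                   sse8 = paste(sse, collapse = ""),
                   rsa = pmin(pmax(ann$rsa, 0), 1),
                   bfactor_norm = ann$bfactor_norm,
                   family_id = family_id, fold_id = fold_id,
                   class_label = class_label)
  })
}

#' Divergence parameters for synthetic homologs
#'
#' Controls how a homolog is derived from a parent record: sequence
#' divergence (substitution rate implied by `target_identity`, indels) is
#' parameterized independently of secondary-structure divergence (segment
#' boundary shifts and whole-segment state flips), so the aligner's
#' contribution to consistency loss can be isolated from genuine structural
#' difference.
#'
#' @param target_identity Expected percent identity over the true residue
#'   correspondence, in (0, 100].
#' @param indel_rate Per-residue probability of starting an indel.
#' @param indel_length_mean Mean indel length (geometric, minimum 1).
#' @param boundary_shift_prob Probability that an internal segment boundary
#'   of the homolog's SSE string moves.
#' @param max_boundary_shift Maximum boundary displacement in residues.
#' @param state_flip_prob Probability that a whole segment changes state.
#' @return An object of class `divergence_params`.
#' @export
divergence_params <- function(target_identity = 100, indel_rate = 0,
                              indel_length_mean = 1.5,
                              boundary_shift_prob = 0,
                              max_boundary_shift = 3,
                              state_flip_prob = 0) {
  stopifnot(target_identity > 0, target_identity <= 100,
            indel_rate >= 0, indel_rate <= 1,
            indel_length_mean >= 1,
            boundary_shift_prob >= 0, boundary_shift_prob <= 1,
            max_boundary_shift >= 1,
            state_flip_prob >= 0, state_flip_prob <= 1)
  structure(list(target_identity = target_identity, indel_rate = indel_rate,
                 indel_length_mean = indel_length_mean,
                 boundary_shift_prob = boundary_shift_prob,
                 max_boundary_shift = max_boundary_shift,
                 state_flip_prob = state_flip_prob),
            class = "divergence_params")
}

perturb_sse <- function(sse_chars, div, grammar) {
  n <- length(sse_chars)
  segs <- segs_from_chars(sse_chars)
  if (nrow(segs) > 1L && div$boundary_shift_prob > 0) {
    for (b in seq_len(nrow(segs) - 1L)) {
      if (stats::runif(1) >= div$boundary_shift_prob) next
      d <- sample.int(div$max_boundary_shift, 1L) * sample(c(-1L, 1L), 1L)
      pos <- segs$end[b]  # boundary after this position
      new_pos <- min(max(pos + d, segs$start[b]), segs$end[b + 1L] - 1L)
      if (new_pos > pos)        # right segment shrinks, left state expands
        sse_chars[(pos + 1L):new_pos] <- sse_chars[pos]
      else if (new_pos < pos)   # left segment shrinks, right state expands
        sse_chars[(new_pos + 1L):pos] <- sse_chars[pos + 1L]
      segs <- segs_from_chars(sse_chars)
      if (nrow(segs) <= b) break
    }
  }
  if (div$state_flip_prob > 0) {
    segs <- segs_from_chars(sse_chars)
    freq <- grammar$state_frequencies
    for (k in seq_len(nrow(segs))) {
      if (stats::runif(1) >= div$state_flip_prob) next
      others <- setdiff(names(freq), segs$state[k])
      new_st <- sample(others, 1L, prob = freq[others])
      sse_chars[segs$start[k]:segs$end[k]] <- new_st
    }
  }
  sse_chars
}

#' Derive a synthetic homolog
#'
#' Applies seeded divergence to a record: amino-acid substitutions at the
#' rate implied by `target_identity` (replacement drawn from the same
#' state's propensities, never the original residue), insertions and
#' deletions with recorded offsets, and SSE perturbation by boundary shifts
#' and segment state flips. Returns the diverged record together with the
#' exact residue correspondence, on which the measured identity approaches
#' `target_identity` in expectation.
#'
#' @param record Parent [protein_record()].
#' @param div A [divergence_params()] object.
#' @param seed Integer seed.
#' @param id Identifier for the derived record.
#' @param grammar [grammar_params()] supplying substitution propensities and
#'   flip-state frequencies.
#' @return A list with `record` (the homolog) and `corr` (the true
#'   [correspondence()], parent positions first).
#' @export
derive_homolog <- function(record, div, seed, id = paste0(record$id, "_h"),
                           grammar = grammar_params()) {
  stopifnot(inherits(div, "divergence_params"))
  with_rng(seed, {
    n <- record$length
    a_seq <- strsplit(record$sequence, "")[[1]]
    a_sse <- strsplit(record$sse8, "")[[1]]
    sub_p <- 1 - div$target_identity / 100
    prop <- grammar$aa_propensities
    draw_len <- function() 1L + stats::rgeom(1L, 1 / div$indel_length_mean)
    draw_aa <- function(st, not = NULL) {
      w <- prop[st, ]
      if (!is.null(not) && not %in% names(w)) w[not] <- 0
      sample(colnames(prop), 1L, prob = w)
    }
    b_seq <- character(0); b_sse <- character(0)
    pos_a <- integer(0); pos_b <- integer(0)
    i <- 1L
    while (i <= n) {
      u <- stats::runif(1)
      if (u < div$indel_rate / 2) {        # deletion in the homolog
        i <- i + draw_len()
        next
      }
      if (u < div$indel_rate) {            # insertion into the homolog
        L <- draw_len()
        b_seq <- c(b_seq, replicate(L, draw_aa(a_sse[i])))
        b_sse <- c(b_sse, rep(a_sse[i], L))
      }
      aa <- a_seq[i]
      if (stats::runif(1) < sub_p) aa <- draw_aa(a_sse[i], not = a_seq[i])
      b_seq <- c(b_seq, aa)
      b_sse <- c(b_sse, a_sse[i])
      pos_a <- c(pos_a, i)
      pos_b <- c(pos_b, length(b_seq))
      i <- i + 1L
    }
    if (length(b_seq) == 0L)
      stop("divergence parameters deleted the whole protein")
    b_sse <- perturb_sse(b_sse, div, grammar)
    ann <- list(rsa = NULL, bf = NULL)
    if (!is.null(record$rsa)) {
      states3 <- chartr("GIEB", "HHEE", chartr("ST", "CC", b_sse))
      fresh <- sample_annotations(states3)
      rsa <- fresh$rsa; bf <- fresh$bfactor_norm
      rsa[pos_b] <- record$rsa[pos_a]
      if (!is.null(record$bfactor_norm)) bf[pos_b] <- record$bfactor_norm[pos_a]
      ann <- list(rsa = pmin(pmax(rsa, 0), 1), bf = bf)
    }
    rec <- protein_record(id = id, sequence = paste(b_seq, collapse = ""),
                          sse8 = paste(b_sse, collapse = ""),
                          rsa = ann$rsa, bfactor_norm = ann$bf,
                          family_id = record$family_id,
                          fold_id = record$fold_id,
                          class_label = record$class_label)
    list(record = rec, corr = correspondence(pos_a, pos_b))
  })
}

#' Default benchmark schedule
#'
#' One row per identity level: the divergence applied to every member of the
#' level's families. The default spans close homologs (95% identity, nearly
#' identical structures) down to remote ones (25%, substantial segment
#' rearrangement), with SSE perturbation growing as identity falls — the
#' qualitative identity-consistency relationship the pipeline is built to
#' measure.
#'
#' @param n_families Families per level.
#' @param members_per_family Members per family (member 1 is the parent).
#' @param min_length,max_length Parent length range (residues).
#' @return A data.frame schedule for [generate_benchmark()].
#' @export
benchmark_schedule <- function(n_families = 3L, members_per_family = 4L,
                               min_length = 120L, max_length = 260L) {
  data.frame(
    target_identity = c(95, 85, 70, 55, 40, 25),
    indel_rate = c(0.004, 0.01, 0.02, 0.03, 0.04, 0.05),
    boundary_shift_prob = c(0.02, 0.06, 0.12, 0.20, 0.30, 0.40),
    state_flip_prob = c(0.00, 0.02, 0.04, 0.07, 0.10, 0.14),
    n_families = n_families, members_per_family = members_per_family,
    min_length = min_length, max_length = max_length)
}

#' Generate a synthetic homolog-family benchmark
#'
#' Builds SCOP-family-like homolog sets: for each schedule row (identity
#' level), `n_families` families are created by sampling a parent protein
#' from the grammar and deriving the remaining members from it with the
#' level's [divergence_params()]. Every family is its own fold (close
#' homolog groups). True correspondences are recorded for all member pairs
#' (pairs not involving the parent are composed through shared parent
#' positions). Deterministic under `seed`.
#'
#' @param schedule A data.frame as from [benchmark_schedule()].
#' @param seed Integer master seed.
#' @param grammar A [grammar_params()] object.
#' @return A list of class `synthetic_benchmark`: `records` (named list of
#'   [protein_record()]s), `pairs` (data.frame: `id_a`, `id_b`, `family_id`,
#'   `level`), `corrs` (named list of true [correspondence()]s keyed
#'   `"idA|idB"`), `schedule`, `seed`.
#' @export
generate_benchmark <- function(schedule = benchmark_schedule(), seed = 1L,
                               grammar = grammar_params()) {
  if (nrow(schedule) == 0L) stop("empty benchmark schedule")
  if (any(schedule$members_per_family < 2L))
    stop("members_per_family must be >= 2")
  records <- list()
  corrs <- list()
  pair_rows <- list()
  sub_seeds <- with_rng(seed, sample.int(.Machine$integer.max - 1L,
                                         sum(schedule$n_families *
                                               schedule$members_per_family) + nrow(schedule)))
  s_idx <- 0L
  next_seed <- function() {
    s_idx <<- s_idx + 1L
    sub_seeds[s_idx]
  }
  for (lv in seq_len(nrow(schedule))) {
    row <- schedule[lv, ]
    div <- divergence_params(target_identity = row$target_identity,
                             indel_rate = row$indel_rate,
                             boundary_shift_prob = row$boundary_shift_prob,
                             state_flip_prob = row$state_flip_prob)
    lengths <- with_rng(next_seed(),
                        sample(seq.int(row$min_length, row$max_length),
                               row$n_families, replace = TRUE))
    for (f in seq_len(row$n_families)) {
      fam <- sprintf("L%02d_F%02d", lv, f)
      ids <- sprintf("%s_M%d", fam, seq_len(row$members_per_family))
      parent <- sample_protein(grammar, lengths[f], next_seed(), id = ids[1L],
                               family_id = fam, fold_id = paste0("fold_", fam))
      members <- list(parent)
      to_parent <- list(correspondence(seq_len(parent$length),
                                       seq_len(parent$length)))
      for (m in seq.int(2L, row$members_per_family)) {
        h <- derive_homolog(parent, div, next_seed(), id = ids[m],
                            grammar = grammar)
        members[[m]] <- h$record
        to_parent[[m]] <- h$corr
      }
      cls <- family_class_label(parent)
      for (m in seq_along(members)) {
        members[[m]]$class_label <- cls
        records[[members[[m]]$id]] <- members[[m]]
      }
      for (i in seq_len(length(members) - 1L)) {
        for (j in seq.int(i + 1L, length(members))) {
          key <- paste(ids[i], ids[j], sep = "|")
          corrs[[key]] <- compose_through_parent(to_parent[[i]],
                                                 to_parent[[j]])
          pair_rows[[length(pair_rows) + 1L]] <-
            data.frame(id_a = ids[i], id_b = ids[j], family_id = fam,
                       level = row$target_identity,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(records = records, pairs = do.call(rbind, pair_rows),
                 corrs = corrs, schedule = schedule, seed = seed),
            class = "synthetic_benchmark")
}

# Pair (pos_in_i, pos_in_j) for parent positions present in both members.
compose_through_parent <- function(corr_i, corr_j) {
  shared <- intersect(corr_i$pos_a, corr_j$pos_a)
  correspondence(corr_i$pos_b[match(shared, corr_i$pos_a)],
                 corr_j$pos_b[match(shared, corr_j$pos_a)])
}

# Crude class call from 3-state content: all-alpha, all-beta, or mixed.
family_class_label <- function(rec) {
  ch <- strsplit(reduce_to_three(rec$sse8), "")[[1]]
  fh <- mean(ch == "H"); fe <- mean(ch == "E")
  if (fh >= 0.35 && fe < 0.10) "a"
  else if (fe >= 0.25 && fh < 0.15) "b"
  else if (fh >= fe) "c" else "d"
}

#' Look up the true correspondence of a benchmark pair
#'
#' @param bench A `synthetic_benchmark`.
#' @param id_a,id_b Member ids (any order; the stored orientation is
#'   returned, swapped if needed).
#' @return A [correspondence()] or an error if the pair is not recorded.
#' @export
true_correspondence <- function(bench, id_a, id_b) {
  key <- paste(id_a, id_b, sep = "|")
  if (!is.null(bench$corrs[[key]])) return(bench$corrs[[key]])
  key2 <- paste(id_b, id_a, sep = "|")
  if (!is.null(bench$corrs[[key2]])) {
    c0 <- bench$corrs[[key2]]
    o <- order(c0$pos_b)
    return(correspondence(c0$pos_b[o], c0$pos_a[o]))
  }
  stop("no true correspondence recorded for ", id_a, " / ", id_b)
}

#' @rdname true_correspondence
#' @return `true_corr_fun()` returns a function `(recA, recB) ->
#'   correspondence` suitable as the `aligner` of [family_all_vs_all()].
#' @export
true_corr_fun <- function(bench) {
  function(recA, recB) true_correspondence(bench, recA$id, recB$id)
}

#' Write a benchmark to disk
#'
#' Emits the TSV collection of member records, a TSV of true residue
#' correspondences (`id_a`, `id_b`, `pos_a`, `pos_b`), and a JSON manifest
#' of the generating schedule and seed. Byte-identical for identical inputs.
#'
#' @param bench A `synthetic_benchmark`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_collection(bench$records, file.path(dir, "collection.tsv"))
  corr_df <- do.call(rbind, lapply(names(bench$corrs), function(k) {
    ids <- strsplit(k, "|", fixed = TRUE)[[1]]
    cc <- bench$corrs[[k]]
    data.frame(id_a = ids[1], id_b = ids[2], pos_a = cc$pos_a,
               pos_b = cc$pos_b, stringsAsFactors = FALSE)
  }))
  utils::write.table(corr_df, file.path(dir, "true_correspondences.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(seed = bench$seed, schedule = bench$schedule,
                   n_records = length(bench$records),
                   n_pairs = nrow(bench$pairs))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
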