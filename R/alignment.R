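#' Alignment parameters
#'
#' Bundles the scoring scheme of the dynamic-programming aligners: a
#' substitution matrix, affine gap penalties (positive score units) and the
#' alignment mode. Defaults follow the benchmark convention used throughout
#' the package: BLOSUM62 with uniform gap opening/extension penalties 11/2.
#'
#' Two affine gap-cost conventions are supported for a gap of length L:
#' `"blast"` charges open + extend * L (so a length-1 gap costs 13 at the
#' defaults) and `"emboss"` charges open + extend * (L - 1).
#'
#' @param matrix Substitution matrix (numeric, named rows/cols) or `NULL`
#'   for BLOSUM62.
#' @param gap_open,gap_extend Positive gap penalties; `gap_open >=
#'   gap_extend >= 0` is required.
#' @param mode `"global"` (Needleman-Wunsch style, end to end) or `"local"`
#'   (Smith-Waterman style maximal segment).
#' @param gap_convention `"blast"` or `"emboss"` (see Details).
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(matrix = NULL, gap_open = 11, gap_extend = 2,
                             mode = c("global", "local"),
                             gap_convention = c("blast", "emboss")) {
  mode <- match.arg(mode)
  gap_convention <- match.arg(gap_convention)
  if (is.null(matrix)) matrix <- default_matrix()
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            identical(rownames(matrix), colnames(matrix)))
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("need gap_open >= gap_extend >= 0")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, mode = mode,
                 gap_convention = gap_convention),
            class = "alignment_params")
}

new_alignment <- function(idA, idB, seqA, seqB, a_pos, b_pos, score) {
  structure(list(idA = idA, idB = idB, seqA = seqA, seqB = seqB,
                 a_pos = a_pos, b_pos = b_pos, score = score),
            class = "sse_alignment")
}

#' @export
print.sse_alignment <- function(x, ...) {
  cat(sprintf("<alignment %s/%s: %d columns, n_e = %d, score = %g>\n",
              x$idA, x$idB, length(x$a_pos), alignment_ne(x), x$score))
  invisible(x)
}

#' Alignment column counts
#'
#' `alignment_ne()` counts columns with a residue on both sides (the number
#' of equivalent residue pairs n_e); `alignment_identical()` counts columns
#' whose residues are identical.
#'
#' @param al An alignment from [align_pair()] or [read_alignment()].
#' @return An integer count.
#' @export
alignment_ne <- function(al) sum(!is.na(al$a_pos) & !is.na(al$b_pos))

#' @rdname alignment_ne
#' @export
alignment_identical <- function(al) {
  keep <- !is.na(al$a_pos) & !is.na(al$b_pos)
  if (!any(keep)) return(0L)
  a <- substring(al$seqA, al$a_pos[keep], al$a_pos[keep])
  b <- substring(al$seqB, al$b_pos[keep], al$b_pos[keep])
  sum(a == b)
}

#' Align two amino-acid sequences
#'
#' Optimal affine-gap pairwise alignment by full dynamic programming (no
#' heuristic seeding). Global mode aligns the sequences end to end; local
#' mode returns the maximal-scoring local alignment, or an empty alignment
#' with score 0 when no positive-scoring pairing exists. Traceback is
#' deterministic: on score ties, a residue-residue column is preferred over
#' a gap in the second sequence, which is preferred over a gap in the first.
#'
#' @param seqA,seqB Non-empty amino-acid strings; every residue must be
#'   present in the substitution matrix.
#' @param params An [alignment_params()] object.
#' @param idA,idB Identifiers stored in the result.
#' @return An alignment object holding the column pairing (`a_pos`, `b_pos`,
#'   `NA` marking a gap) and the optimal `score`.
#' @examples
#' al <- align_pair("ACD", "AD")
#' al$score  # s(A,A) + s(D,D) - (11 + 2) = -3 with BLOSUM62 defaults
#' @export
align_pair <- function(seqA, seqB, params = alignment_params(),
                       idA = "A", idB = "B") {
  if (!inherits(params, "alignment_params"))
    stop("`params` must come from alignment_params()")
  if (!nzchar(seqA) || !nzchar(seqB)) stop("empty sequence")
  codes <- rownames(params$matrix)
  a <- match(strsplit(seqA, "")[[1]], codes)
  b <- match(strsplit(seqB, "")[[1]], codes)
  if (anyNA(a))
    stop("residue not in matrix: ", strsplit(seqA, "")[[1]][which(is.na(a))[1]])
  if (anyNA(b))
    stop("residue not in matrix: ", strsplit(seqB, "")[[1]][which(is.na(b))[1]])
  res <- .align_core(a, b, params$matrix, params$gap_open, params$gap_extend,
                     params$mode == "local",
                     params$gap_convention == "emboss")
  a_pos <- res$a_pos; a_pos[a_pos == 0L] <- NA_integer_
  b_pos <- res$b_pos; b_pos[b_pos == 0L] <- NA_integer_
  new_alignment(idA, idB, seqA, seqB, a_pos, b_pos, res$score)
}

#' Percent sequence identity of an alignment
#'
#' 100 x n_identical / denominator. The default denominator is the full
#' column count including gap columns (the BLAST reporting convention);
#' `denominator = "ne"` divides by the number of residue-residue columns
#' instead.
#'
#' @param al An alignment.
#' @param denominator `"columns"` or `"ne"`.
#' @return Percent identity in [0, 100].
#' @export
percent_identity <- function(al, denominator = c("columns", "ne")) {
  denominator <- match.arg(denominator)
  n_col <- length(al$a_pos)
  if (n_col == 0L) stop("percent identity undefined for an empty alignment")
  d <- if (denominator == "columns") n_col else alignment_ne(al)
  if (d == 0L) stop("no equivalent residue pairs in alignment")
  100 * alignment_identical(al) / d
}

#' Residue correspondences
#'
#' A correspondence is an ordered list of equivalent residue position pairs
#' (pos_a, pos_b), strictly increasing on both sides — the common currency
#' for sequence- and structure-derived alignments. `correspondence()`
#' validates and constructs one; `equivalent_pairs()` extracts it from an
#' alignment by dropping gap columns.
#'
#' @param pos_a,pos_b Integer vectors of equal length, strictly increasing.
#' @return A data.frame of class `correspondence` with columns `pos_a`,
#'   `pos_b`.
#' @export
correspondence <- function(pos_a, pos_b) {
  pos_a <- as.integer(pos_a); pos_b <- as.integer(pos_b)
  if (length(pos_a) != length(pos_b)) stop("pos_a and pos_b lengths differ")
  if (length(pos_a)) {
    bad <- which(diff(pos_a) <= 0 | diff(pos_b) <= 0)
    if (length(bad))
      stop(sprintf("correspondence not strictly increasing at row %d",
                   bad[1L] + 1L))
    if (any(pos_a < 1L) || any(pos_b < 1L)) stop("positions must be >= 1")
  }
  structure(data.frame(pos_a = pos_a, pos_b = pos_b),
            class = c("correspondence", "data.frame"))
}

#' @rdname correspondence
#' @param al An alignment.
#' @export
equivalent_pairs <- function(al) {
  keep <- !is.na(al$a_pos) & !is.na(al$b_pos)
  correspondence(al$a_pos[keep], al$b_pos[keep])
}

#' Read an external alignment or correspondence
#'
#' The channel for externally produced (e.g. structural) alignments:
#' `"aligned-fasta"` expects exactly two equal-length gapped records (`-`
#' gaps) and returns an alignment; `"tsv-pairs"` expects two integer columns
#' `pos_a`, `pos_b` (1-based) and returns a correspondence. Monotonicity is
#' enforced; the first offending row is named.
#'
#' @param path Input file.
#' @param format `"aligned-fasta"` or `"tsv-pairs"`.
#' @return An alignment or a [correspondence()].
#' @export
read_alignment <- function(path, format = c("aligned-fasta", "tsv-pairs")) {
  format <- match.arg(format)
  if (format == "tsv-pairs") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("pos_a", "pos_b") %in% names(df)))
      stop("tsv-pairs file needs columns pos_a, pos_b")
    return(correspondence(df$pos_a, df$pos_b))
  }
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 2L)
    stop("aligned-fasta must contain exactly two records, found ",
         length(recs))
  g1 <- strsplit(as.character(recs[[1]]), "")[[1]]
  g2 <- strsplit(as.character(recs[[2]]), "")[[1]]
  if (length(g1) != length(g2))
    stop(sprintf("gapped lengths differ: %d vs %d", length(g1), length(g2)))
  a_pos <- ifelse(g1 == "-", NA_integer_, cumsum(g1 != "-"))
  b_pos <- ifelse(g2 == "-", NA_integer_, cumsum(g2 != "-"))
  if (any(g1 == "-" & g2 == "-")) stop("all-gap column in aligned-fasta")
  ids <- sub("\\s.*$", "", names(recs))
  new_alignment(ids[1L], ids[2L],
                gsub("-", "", as.character(recs[[1]]), fixed = TRUE),
                gsub("-", "", as.character(recs[[2]]), fixed = TRUE),
                as.integer(a_pos), as.integer(b_pos), NA_real_)
}

#' Project SSE strings onto a residue correspondence
#'
#' Restricts the two records' SSE strings to the equivalent residues of a
#' correspondence, producing the equal-length pair on which Q and SOV are
#' computed. A continuity break is recorded between consecutive output
#' positions wherever either side skips one or more residues or crosses a
#' recorded chain break, so that segments are never merged across unaligned
#' stretches. Per-residue annotations (RSA, normalized B-factor) are carried
#' through.
#'
#' @param corr A [correspondence()].
#' @param recA,recB [protein_record()] objects.
#' @return An object of class `aligned_sse_pair`: fields `obs` and `pred`
#'   (equal-length 8-state strings for records A and B), `breaks`
#'   (positions, in pair coordinates, after which continuity is broken) and
#'   `ann` (per-position annotation vectors).
#' @export
project_sse <- function(corr, recA, recB) {
  if (nrow(corr)) {
    if (max(corr$pos_a) > recA$length)
      stop(sprintf("correspondence position %d out of bounds for '%s'",
                   max(corr$pos_a), recA$id))
    if (max(corr$pos_b) > recB$length)
      stop(sprintf("correspondence position %d out of bounds for '%s'",
                   max(corr$pos_b), recB$id))
  }
  n <- nrow(corr)
  if (n == 0L) return(aligned_sse_pair("", ""))
  sub1 <- function(s, i) substring(s, i, i)
  obs <- paste(sub1(recA$sse8, corr$pos_a), collapse = "")
  pred <- paste(sub1(recB$sse8, corr$pos_b), collapse = "")
  breaks <- integer()
  if (n > 1L) {
    skip <- diff(corr$pos_a) > 1L | diff(corr$pos_b) > 1L
    crossA <- vapply(seq_len(n - 1L), function(k)
      any(recA$breaks >= corr$pos_a[k] & recA$breaks < corr$pos_a[k + 1L]),
      logical(1))
    crossB <- vapply(seq_len(n - 1L), function(k)
      any(recB$breaks >= corr$pos_b[k] & recB$breaks < corr$pos_b[k + 1L]),
      logical(1))
    breaks <- which(skip | crossA | crossB)
  }
  ann <- list(
    rsa_a = if (!is.null(recA$rsa)) recA$rsa[corr$pos_a],
    rsa_b = if (!is.null(recB$rsa)) recB$rsa[corr$pos_b],
    bfactor_a = if (!is.null(recA$bfactor_norm)) recA$bfactor_norm[corr$pos_a],
    bfactor_b = if (!is.null(recB$bfactor_norm)) recB$bfactor_norm[corr$pos_b])
  aligned_sse_pair(obs, pred, breaks, ann)
}
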