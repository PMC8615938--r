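#' @useDynLib ssecons, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Secondary-structure alphabets
#'
#' The eight-state DSSP alphabet (H alpha-helix, G 3-10 helix, I pi-helix,
#' E extended strand, B isolated beta-bridge, S bend, T turn, C coil/other)
#' and the reduced three-state alphabet (H helix, E strand, C coil).
#'
#' @format Character vectors of state codes.
#' @export
SSE_STATES8 <- c("H", "G", "I", "E", "B", "S", "T", "C")

#' @rdname SSE_STATES8
#' @export
SSE_STATES3 <- c("H", "E", "C")

AA_ALPHABET20X <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Reduce an 8-state SSE string to 3 states
#'
#' Applies the standard reduction: helices H, G, I collapse to H; extended
#' strand E and isolated bridge B collapse to E; bend S, turn T and coil C
#' collapse to C. The map is total on the 8-letter alphabet and idempotent
#' on its image.
#'
#' @param sse8 Character vector of 8-state SSE strings.
#' @return Character vector of 3-state strings, same lengths.
#' @examples
#' reduce_to_three("HGIEBSTC")  # "HHHEECCC"
#' @export
reduce_to_three <- function(sse8) {
  stopifnot(is.character(sse8))
  bad <- regexpr("[^HGIEBSTC]", sse8)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    stop(sprintf("invalid SSE code '%s' at position %d of string %d",
                 substr(sse8[i], bad[i], bad[i]), bad[i], i))
  }
  chartr("HGIEBSTC", "HHHEECCC", sse8)
}

#' Construct a protein record
#'
#' A protein record couples an amino-acid sequence with its per-residue
#' 8-state SSE string and optional per-residue annotations (relative solvent
#' accessibility in [0,1], normalized B-factor) and SCOP-style grouping
#' labels. Chain discontinuities are recorded as the set of positions after
#' which the chain breaks.
#'
#' @param id Record identifier.
#' @param sequence Amino-acid string over the 20 standard residues plus X.
#' @param sse8 8-state SSE string, same length as `sequence`.
#' @param breaks Integer positions after which the chain is discontinuous.
#' @param rsa Optional numeric vector of per-residue RSA fractions in [0,1].
#' @param bfactor_norm Optional numeric vector of normalized B-factors.
#' @param family_id,fold_id,class_label Optional grouping labels.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, sse8, breaks = integer(),
                           rsa = NULL, bfactor_norm = NULL,
                           family_id = NA_character_, fold_id = NA_character_,
                           class_label = NA_character_) {
  n <- nchar(sequence)
  if (nchar(sse8) != n)
    stop(sprintf("record '%s': sequence length %d != sse8 length %d",
                 id, n, nchar(sse8)))
  bad <- regexpr("[^HGIEBSTC]", sse8)
  if (bad > 0)
    stop(sprintf("record '%s': invalid SSE code at position %d", id, bad))
  bad_aa <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET20X, collapse = "")),
                    sequence)
  if (bad_aa > 0)
    stop(sprintf("record '%s': invalid amino acid at position %d", id, bad_aa))
  breaks <- sort(unique(as.integer(breaks)))
  breaks <- breaks[breaks >= 1L & breaks < n]
  if (!is.null(rsa)) {
    if (length(rsa) != n)
      stop(sprintf("record '%s': rsa length %d != %d", id, length(rsa), n))
    if (any(!is.na(rsa) & (rsa < 0 | rsa > 1)))
      stop(sprintf("record '%s': rsa outside [0,1]", id))
  }
  if (!is.null(bfactor_norm) && length(bfactor_norm) != n)
    stop(sprintf("record '%s': bfactor length %d != %d",
                 id, length(bfactor_norm), n))
  structure(list(id = id, sequence = sequence, sse8 = sse8,
                 breaks = breaks, rsa = rsa, bfactor_norm = bfactor_norm,
                 family_id = family_id, fold_id = fold_id,
                 class_label = class_label, length = n),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record %s: %d residues%s%s>\n", x$id, x$length,
              if (length(x$breaks)) sprintf(", %d breaks", length(x$breaks)) else "",
              if (!is.na(x$family_id)) sprintf(", family %s", x$family_id) else ""))
  invisible(x)
}

#' Segment an SSE string into maximal single-state runs
#'
#' Returns the run-length segmentation of an SSE string: maximal runs of one
#' state, never spanning a recorded chain break. Segments tile the string;
#' adjacent segments differ in state unless separated by a break.
#'
#' @param sse A single SSE string (any state alphabet).
#' @param breaks Integer positions after which the chain is discontinuous.
#' @return A data.frame with columns `state`, `start`, `end`, `length`
#'   (1-based inclusive coordinates).
#' @examples
#' segmentize("HHHCHHHCHHHC")
#' @export
segmentize <- function(sse, breaks = integer()) {
  n <- nchar(sse)
  if (n == 0L)
    return(data.frame(state = character(), start = integer(),
                      end = integer(), length = integer(),
                      stringsAsFactors = FALSE))
  ch <- strsplit(sse, "")[[1]]
  r <- rle(ch)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  breaks <- breaks[breaks >= 1L & breaks < n]
  starts <- sort(unique(c(starts, as.integer(breaks) + 1L)))
  ends <- c(starts[-1L] - 1L, n)
  data.frame(state = ch[starts], start = starts, end = ends,
             length = ends - starts + 1L, stringsAsFactors = FALSE)
}

#' Parse classic DSSP output
#'
#' Reads the fixed-column text emitted by classic (pre-2015 layout) DSSP and
#' returns one record per chain. The SSE code is read from the summary
#' structure column (column 17); a blank code maps to C. Rows whose
#' amino-acid column holds `!` denote a chain discontinuity: no residue is
#' emitted and a break is recorded at the current position of the chain.
#' Lowercase amino-acid letters (DSSP's disulfide-bonded cysteines) are read
#' as C. The chain identifier (column 12) splits records.
#'
#' @param path Path to a DSSP output file, or a character vector of its lines.
#' @return A list of [protein_record()] objects, one per chain, ids
#'   `<chain>`.
#' @export
parse_dssp <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L)
    stop("not a classic DSSP file: header row '  #  RESIDUE' not found")
  data <- if (hdr[1L] >= length(lines)) character() else
    lines[seq.int(hdr[1L] + 1L, length(lines))]
  data <- data[nzchar(trimws(data))]
  if (length(data) == 0L) {
    warning("DSSP file contains no residue lines")
    return(list())
  }
  chains <- list()   # chain -> list(aa = chr vec, ss = chr vec, breaks = int)
  cur <- NA_character_
  for (k in seq_along(data)) {
    line <- data[k]
    if (nchar(line) < 14L)
      stop(sprintf("truncated DSSP data line %d", hdr[1L] + k))
    aa <- substr(line, 14L, 14L)
    if (aa == "!") {
      if (!is.na(cur) && length(chains[[cur]]$aa) > 0L)
        chains[[cur]]$breaks <- c(chains[[cur]]$breaks,
                                  length(chains[[cur]]$aa))
      next
    }
    if (nchar(line) < 17L)
      stop(sprintf("truncated DSSP data line %d", hdr[1L] + k))
    chain <- substr(line, 12L, 12L)
    ss <- substr(line, 17L, 17L)
    if (ss == " ") ss <- "C"
    if (grepl("[a-z]", aa)) aa <- "C"
    if (is.na(match(chain, names(chains))))
      chains[[chain]] <- list(aa = character(), ss = character(),
                              breaks = integer())
    cur <- chain
    chains[[cur]]$aa <- c(chains[[cur]]$aa, aa)
    chains[[cur]]$ss <- c(chains[[cur]]$ss, ss)
  }
  lapply(names(chains), function(ch) {
    x <- chains[[ch]]
    protein_record(id = ch,
                   sequence = paste(x$aa, collapse = ""),
                   sse8 = paste(x$ss, collapse = ""),
                   breaks = x$breaks)
  })
}

join_num <- function(x) paste(format(x, trim = TRUE, digits = 15), collapse = ",")

split_num <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Read and write protein collections
#'
#' The primary exchange format is a TSV with columns `id`, `family_id`,
#' `fold_id`, `class_label`, `sequence`, `sse8`, optional `breaks` and
#' optional per-residue `rsa` / `bfactor` columns holding comma-joined
#' values. The `fasta+sse` format is a pair of parallel FASTA files (amino
#' acids and SSE codes) keyed by identical ids. Records violating the
#' protein-record invariants are rejected individually; the reasons are
#' attached as the `"rejected"` attribute (a data.frame of id and reason)
#' and reported with a warning. A duplicated id rejects the whole file.
#'
#' @param path Path to the TSV file, or to the sequence FASTA for
#'   `format = "fasta+sse"`.
#' @param format `"tsv"` or `"fasta+sse"`.
#' @param sse_path Path to the SSE FASTA (required for `"fasta+sse"`).
#' @return A named list of [protein_record()] objects.
#' @export
read_collection <- function(path, format = c("tsv", "fasta+sse"),
                            sse_path = NULL) {
  format <- match.arg(format)
  if (format == "fasta+sse") {
    if (is.null(sse_path)) stop("fasta+sse format needs `sse_path`")
    seqs <- Biostrings::readBStringSet(path)
    sses <- Biostrings::readBStringSet(sse_path)
    ids_a <- sub("\\s.*$", "", names(seqs))
    ids_b <- sub("\\s.*$", "", names(sses))
    only <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
    if (length(only))
      stop("ids present in only one file: ", paste(only, collapse = ", "))
    if (anyDuplicated(ids_a)) stop("duplicate id: ", ids_a[duplicated(ids_a)][1L])
    df <- data.frame(id = ids_a,
                     sequence = as.character(seqs),
                     sse8 = as.character(sses)[match(ids_a, ids_b)],
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("id", "sequence", "sse8")
    if (!all(need %in% names(df)))
      stop("TSV collection must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(df$id))
      stop("duplicate id: ", df$id[duplicated(df$id)][1L])
  }
  opt <- function(col, i) if (col %in% names(df)) df[[col]][i] else NA_character_
  records <- list()
  rejected <- data.frame(id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch(
      protein_record(
        id = df$id[i], sequence = df$sequence[i], sse8 = df$sse8[i],
        breaks = if (!is.na(opt("breaks", i)) && nzchar(opt("breaks", i)))
          as.integer(strsplit(opt("breaks", i), ",")[[1]]) else integer(),
        rsa = split_num(opt("rsa", i)),
        bfactor_norm = split_num(opt("bfactor", i)),
        family_id = opt("family_id", i), fold_id = opt("fold_id", i),
        class_label = opt("class_label", i)),
      error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      rejected <- rbind(rejected, data.frame(id = df$id[i], reason = rec,
                                             stringsAsFactors = FALSE))
    } else {
      records[[rec$id]] <- rec
    }
  }
  if (nrow(rejected))
    warning(sprintf("%d record(s) rejected; see attr(, 'rejected')",
                    nrow(rejected)))
  attr(records, "rejected") <- rejected
  records
}

#' @rdname read_collection
#' @param records A list of [protein_record()] objects.
#' @export
write_collection <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) {
    data.frame(
      id = r$id,
      family_id = ifelse(is.na(r$family_id), "", r$family_id),
      fold_id = ifelse(is.na(r$fold_id), "", r$fold_id),
      class_label = ifelse(is.na(r$class_label), "", r$class_label),
      sequence = r$sequence, sse8 = r$sse8,
      breaks = paste(r$breaks, collapse = ","),
      rsa = if (is.null(r$rsa)) "" else join_num(r$rsa),
      bfactor = if (is.null(r$bfactor_norm)) "" else join_num(r$bfactor_norm),
      stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
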