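#' Substitution matrices
#'
#' `default_matrix()` returns the BLOSUM62 matrix (from \pkg{Biostrings}),
#' restricted to the twenty standard amino acids plus the ambiguity code X,
#' which is the default scoring scheme of [align_pair()].
#' `read_score_matrix()` reads a substitution matrix in the NCBI text layout
#' (a header row of residue codes, one labelled row per residue, `#` comments).
#'
#' @param path Path to a matrix file in NCBI text layout.
#' @return A numeric matrix with identical row and column names (residue
#'   one-letter codes).
#' @examples
#' m <- default_matrix()
#' m["A", "A"]  # 4
#' @export
default_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  keep <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "X")
  m[keep, keep]
}

#' @rdname default_matrix
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("matrix file has no data: ", path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  labels <- vapply(rows, `[[`, "", 1L)
  vals <- lapply(rows, function(r) as.numeric(r[-1L]))
  if (any(lengths(vals) != length(header)))
    stop("matrix row length does not match header in ", path)
  m <- do.call(rbind, vals)
  dimnames(m) <- list(labels, header)
  if (!identical(sort(rownames(m)), sort(colnames(m))))
    stop("matrix rows and columns disagree in ", path)
  m
}
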