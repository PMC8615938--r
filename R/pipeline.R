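write_csv_det <- function(df, path) {
  # fixed-format, locale-independent CSV so identical runs are
  # byte-identical
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num])
    df[[cn]] <- ifelse(is.na(df[[cn]]), "",
                       formatC(df[[cn]], digits = 10, format = "g"))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

write_manifest <- function(path, config, counts) {
  jsonlite::write_json(
    list(tool = "ssecons",
         version = as.character(utils::packageVersion("ssecons")),
         config = config, counts = counts),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

resolve_records <- function(records) {
  if (is.character(records)) records <- read_collection(records)
  if (inherits(records, "protein_record")) records <- list(records)
  records
}

#' Family all-vs-all analysis
#'
#' The family-stratified experimental design: score all member pairs within
#' each family (by the built-in aligner or supplied correspondences),
#' collapse pairs to fold-level values by the size-weighted mean, compute
#' repeat statistics over k random fold subsets, and bin all pairs by
#' identity. Writes `pairs.csv`, `bins.csv`, `repeats.csv` and
#' `manifest.json` into `out_dir`; repeated runs with identical inputs and
#' seed are byte-identical.
#'
#' @param records Named list of [protein_record()]s (or a path to a TSV
#'   collection); every record must carry a `family_id`.
#' @param aligner [alignment_params()], or a function `(recA, recB) ->
#'   correspondence` (e.g. [true_corr_fun()] for a synthetic benchmark, or
#'   a lookup of external structural alignments).
#' @param scheme [identity_bin_scheme()] for the bins table.
#' @param k Number of fold subsets for the repeat statistics (skipped, with
#'   a note in the manifest, when there are fewer folds than k).
#' @param seed Integer seed (controls the subset partition).
#' @param out_dir Output directory, created if needed.
#' @param orientation SOV orientation for pair scoring.
#' @param fold_weight Weight for [fold_value()]: `"ne"` or `"mean_length"`.
#' @return Invisibly, a list with `pairs` (data.frame), `bins`, `repeats`,
#'   `fold_values` and the exclusion counts.
#' @export
run_family_analysis <- function(records, aligner = alignment_params(),
                                scheme = identity_bin_scheme("level"),
                                k = 10L, seed = 1L, out_dir,
                                orientation = "symmetric_mean",
                                fold_weight = "ne") {
  records <- resolve_records(records)
  fam <- vapply(records, function(r) r$family_id, "")
  if (anyNA(fam))
    stop("records without family_id: ",
         paste(names(records)[is.na(fam)], collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  small_families <- 0L
  for (f in sort(unique(fam))) {
    members <- records[fam == f]
    if (length(members) < 2L) {
      small_families <- small_families + 1L
      next
    }
    results <- c(results, family_all_vs_all(members, aligner, orientation))
  }
  pairs <- pair_results_table(results)
  n_unscorable <- sum(pairs$unscorable)
  fold_ids <- sort(unique(pairs$fold_id[!pairs$unscorable]))
  fv <- do.call(rbind, lapply(fold_ids, function(fd)
    fold_value(pairs[pairs$fold_id %in% fd, , drop = FALSE],
               weight = fold_weight)))
  repeats <- NULL
  if (!is.null(fv) && nrow(fv) >= k)
    repeats <- subset_statistics(fv[, MEASURES], k = k, seed = seed)
  bins <- bin_pair_results(pairs, scheme)
  write_csv_det(pairs, file.path(out_dir, "pairs.csv"))
  write_csv_det(bins, file.path(out_dir, "bins.csv"))
  if (!is.null(repeats))
    write_csv_det(repeats, file.path(out_dir, "repeats.csv"))
  write_manifest(
    file.path(out_dir, "manifest.json"),
    config = list(analysis = "family_all_vs_all",
                  aligner = if (is.function(aligner)) "external_correspondence"
                  else paste0(aligner$mode, "/", aligner$gap_open, "/",
                              aligner$gap_extend, "/",
                              aligner$gap_convention),
                  scheme = scheme$kind, edges = scheme$edges, k = k,
                  seed = seed, orientation = orientation,
                  fold_weight = fold_weight),
    counts = list(n_records = length(records),
                  n_families = length(unique(fam)),
                  families_too_small = small_families,
                  n_pairs_scored = sum(!pairs$unscorable),
                  n_pairs_unscorable = n_unscorable,
                  n_folds = length(fold_ids),
                  pairs_excluded_from_bins = attr(bins, "excluded")))
  invisible(list(pairs = pairs, bins = bins, repeats = repeats,
                 fold_values = fv,
                 excluded = c(unscorable = n_unscorable,
                              small_families = small_families)))
}

#' Score an explicit pair list
#'
#' Scores exactly the listed record pairs. Each pair may name a
#' correspondence file (TSV pos_a/pos_b or aligned FASTA) from an external
#' aligner; otherwise the built-in aligner is used. Unparseable
#' correspondence files skip the pair (counted in the manifest); an
#' unresolvable record id is an error. Writes `pairs.csv`, `bins.csv` and
#' `manifest.json`.
#'
#' @param records Named list of [protein_record()]s or collection path.
#' @param pair_list data.frame with columns `id_a`, `id_b`, optional
#'   `corr_file` and `corr_format`.
#' @param aligner Fallback [alignment_params()].
#' @inheritParams run_family_analysis
#' @return Invisibly, list with `pairs`, `bins`, `n_skipped`.
#' @export
run_pair_list <- function(records, pair_list, aligner = alignment_params(),
                          scheme = identity_bin_scheme("level"), out_dir,
                          orientation = "symmetric_mean") {
  records <- resolve_records(records)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(pair_list) == 0L) warning("empty pair list")
  missing_ids <- setdiff(unique(c(pair_list$id_a, pair_list$id_b)),
                         names(records))
  if (length(missing_ids))
    stop("pair list references unknown ids: ",
         paste(missing_ids, collapse = ", "))
  results <- list()
  skipped <- 0L
  for (i in seq_len(nrow(pair_list))) {
    a <- records[[pair_list$id_a[i]]]
    b <- records[[pair_list$id_b[i]]]
    scorer <- aligner
    if ("corr_file" %in% names(pair_list) &&
        !is.na(pair_list$corr_file[i]) && nzchar(pair_list$corr_file[i])) {
      fmt <- if ("corr_format" %in% names(pair_list) &&
                 !is.na(pair_list$corr_format[i]))
        pair_list$corr_format[i] else "tsv-pairs"
      ext <- tryCatch(read_alignment(pair_list$corr_file[i], fmt),
                      error = function(e) NULL)
      if (is.null(ext)) {
        skipped <- skipped + 1L
        next
      }
      scorer <- if (inherits(ext, "sse_alignment")) equivalent_pairs(ext)
      else ext
    }
    results[[length(results) + 1L]] <-
      score_homolog_pair(a, b, scorer, orientation)
  }
  pairs <- if (length(results)) pair_results_table(results) else
    pair_results_table(list())
  bins <- if (length(results)) bin_pair_results(pairs, scheme) else NULL
  write_csv_det(pairs, file.path(out_dir, "pairs.csv"))
  if (!is.null(bins)) write_csv_det(bins, file.path(out_dir, "bins.csv"))
  write_manifest(file.path(out_dir, "manifest.json"),
                 config = list(analysis = "pair_list", scheme = scheme$kind,
                               orientation = orientation),
                 counts = list(n_listed = nrow(pair_list),
                               n_scored = length(results),
                               n_skipped_bad_correspondence = skipped))
  invisible(list(pairs = pairs, bins = bins, n_skipped = skipped))
}

#' Random-pairing lower bound run
#'
#' Wraps [random_pair_null()] over a record collection and writes the
#' null-distribution histogram (`null_hist.csv`), the per-measure means
#' (`null_summary.csv`) and a manifest recording the projection mode and
#' seed.
#'
#' @param records Named list of [protein_record()]s or collection path.
#' @param n_pairs Number of random pairs.
#' @param seed Integer seed.
#' @param projection `"prefix"` or `"global_seq_align"`.
#' @param out_dir Output directory.
#' @return Invisibly, the [random_pair_null()] result.
#' @export
run_lower_bound <- function(records, n_pairs = 10000L, seed = 1L,
                            projection = "prefix", out_dir) {
  records <- resolve_records(records)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  null <- random_pair_null(records, n_pairs, seed, projection)
  write_csv_det(null$hist, file.path(out_dir, "null_hist.csv"))
  write_csv_det(data.frame(measure = names(null$means),
                           mean = as.numeric(null$means),
                           sd = as.numeric(null$sds),
                           stringsAsFactors = FALSE),
                file.path(out_dir, "null_summary.csv"))
  write_manifest(file.path(out_dir, "manifest.json"),
                 config = list(analysis = "lower_bound", n_pairs = n_pairs,
                               seed = seed, projection = projection),
                 counts = list(n_records = length(records),
                               n_scored = null$n_scored))
  invisible(null)
}
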