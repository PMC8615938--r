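test_that("8-to-3 state reduction follows the standard map", {
  expect_identical(reduce_to_three("HGIEBSTC"), "HHHEECCC")
  expect_identical(reduce_to_three(""), "")
  expect_identical(reduce_to_three("CCCC"), "CCCC")
  # idempotent on its image, total on the 8-letter alphabet
  for (st in SSE_STATES8) {
    r <- reduce_to_three(st)
    expect_true(r %in% SSE_STATES3)
    expect_identical(reduce_to_three(r), r)
  }
  expect_error(reduce_to_three("HHXH"), "position 3")
})

test_that("segmentation yields maximal runs that tile the string", {
  s <- segmentize("HHHCHHHCHHHC")
  expect_equal(s$state, c("H", "C", "H", "C", "H", "C"))
  expect_equal(s$start, c(1L, 4L, 5L, 8L, 9L, 12L))
  expect_equal(s$end, c(3L, 4L, 7L, 8L, 11L, 12L))

  s2 <- segmentize("HHHH", breaks = 2L)
  expect_equal(s2$start, c(1L, 3L))
  expect_equal(s2$end, c(2L, 4L))

  expect_equal(segmentize("E")$state, "E")
  expect_equal(nrow(segmentize("")), 0L)

  set.seed(41)
  for (rep in 1:50) {
    str <- random_sse(sample.int(60L, 1L), SSE_STATES8)
    brk <- sample.int(nchar(str), sample(0:3, 1L))
    segs <- segmentize(str, brk)
    expect_equal(sum(segs$length), nchar(str))
    expect_equal(segs$start[-1L], segs$end[-nrow(segs)] + 1L)
    # reassembly reproduces the string
    expect_identical(
      paste(unlist(Map(function(st, l) rep(st, l), segs$state, segs$length)),
            collapse = ""), str)
    # adjacent same-state segments only across a break
    same <- which(segs$state[-1L] == segs$state[-nrow(segs)])
    expect_true(all(segs$end[same] %in% brk))
  }
})

test_that("classic DSSP parsing reads codes, breaks and chain splits", {
  f1 <- dssp_fixture(data.frame(chain = "A", aa = c("G", "A", "L"),
                                ss = c("H", "H", " ")))
  recs <- parse_dssp(f1)
  expect_length(recs, 1L)
  expect_identical(recs[[1]]$sse8, "HHC")
  expect_identical(recs[[1]]$sequence, "GAL")

  f2 <- dssp_fixture(data.frame(chain = "A", aa = c("A", "!", "V"),
                                ss = c("H", "", "E")))
  recs2 <- parse_dssp(f2)
  expect_length(recs2, 1L)
  expect_identical(recs2[[1]]$breaks, 1L)
  expect_identical(recs2[[1]]$sse8, "HE")

  f3 <- dssp_fixture(data.frame(chain = c("A", "A", "B", "B"),
                                aa = c("A", "C", "D", "E"),
                                ss = c("H", "H", "E", "E")))
  recs3 <- parse_dssp(f3)
  expect_length(recs3, 2L)
  expect_identical(vapply(recs3, `[[`, "", "id"), c("A", "B"))

  # disulfide-bonded cysteines appear as lowercase letters
  f4 <- dssp_fixture(data.frame(chain = "A", aa = c("a", "G"),
                                ss = c("E", "E")))
  expect_identical(parse_dssp(f4)[[1]]$sequence, "CG")

  trunc <- dssp_fixture(data.frame(chain = "A", aa = "A", ss = "H"))
  trunc[3] <- substr(trunc[3], 1, 10)
  expect_error(parse_dssp(trunc), "truncated")

  expect_warning(empty <- parse_dssp(dssp_fixture(
    data.frame(chain = character(), aa = character(), ss = character()))),
    "no residue")
  expect_length(empty, 0L)
})

test_that("TSV collection round-trips and rejects invariant violations", {
  recs <- list(
    x = protein_record("x", "ACDEF", "HHHCC", family_id = "f1",
                       fold_id = "d1", rsa = c(.1, .2, .3, .9, 1)),
    y = protein_record("y", "GHIKL", "EECCC", breaks = 2L))
  tsv <- tempfile(fileext = ".tsv")
  write_collection(recs, tsv)
  back <- read_collection(tsv)
  expect_length(back, 2L)
  expect_identical(back$x$sse8, recs$x$sse8)
  expect_identical(back$y$breaks, 2L)
  expect_equal(back$x$rsa, recs$x$rsa)
  expect_identical(back$x$family_id, "f1")

  # length-mismatched record is rejected individually, with a reason
  df <- utils::read.delim(tsv, colClasses = "character")
  df$sse8[2] <- "EECC"
  bad <- tempfile(fileext = ".tsv")
  utils::write.table(df, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(part <- read_collection(bad), "rejected")
  expect_length(part, 1L)
  expect_equal(nrow(attr(part, "rejected")), 1L)
  expect_match(attr(part, "rejected")$reason, "length")

  # duplicate id rejects the file
  df2 <- utils::read.delim(tsv, colClasses = "character")
  df2$id[2] <- "x"
  dup <- tempfile(fileext = ".tsv")
  utils::write.table(df2, dup, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_collection(dup), "duplicate id")
})

test_that("DSSP records round-trip through the collection format", {
  f <- dssp_fixture(data.frame(chain = c("A", "A", "A", "A"),
                               aa = c("M", "A", "!", "V"),
                               ss = c("H", "H", "", "E")))
  recs <- parse_dssp(f)
  tsv <- tempfile(fileext = ".tsv")
  write_collection(recs, tsv)
  back <- read_collection(tsv)
  expect_identical(back[[1]]$sequence, recs[[1]]$sequence)
  expect_identical(back[[1]]$sse8, recs[[1]]$sse8)
  expect_identical(back[[1]]$breaks, recs[[1]]$breaks)
})

test_that("parallel FASTA pair loads and cross-checks ids", {
  fa <- tempfile(fileext = ".fa"); fs <- tempfile(fileext = ".fa")
  writeLines(c(">p1", "ACDEF", ">p2", "GHIK"), fa)
  writeLines(c(">p1", "HHHCC", ">p2", "EEEC"), fs)
  recs <- read_collection(fa, "fasta+sse", sse_path = fs)
  expect_length(recs, 2L)
  expect_identical(recs$p2$sse8, "EEEC")

  writeLines(c(">p1", "HHHCC"), fs)
  expect_error(read_collection(fa, "fasta+sse", sse_path = fs), "p2")
})
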