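toy_params <- function(mode = "global", convention = "blast",
                       open = 11, ext = 2)
  alignment_params(matrix = toy_matrix, gap_open = open, gap_extend = ext,
                   mode = mode, gap_convention = convention)

test_that("self-alignment is the identity with the diagonal score", {
  al <- align_pair("ACDEFG", "ACDEFG")
  expect_equal(al$score, 4 + 9 + 6 + 5 + 6 + 6)  # BLOSUM62 diagonal
  expect_equal(alignment_identical(al), 6L)
  expect_equal(al$a_pos, 1:6)
  expect_equal(al$b_pos, 1:6)

  corr <- equivalent_pairs(al)
  expect_equal(corr$pos_a, 1:6)
  expect_equal(corr$pos_b, 1:6)
})

test_that("a forced single-residue gap is priced open + extend", {
  al <- align_pair("ACD", "AD")
  expect_equal(al$score, 4 + 6 - (11 + 2))
  expect_equal(al$a_pos, c(1L, 2L, 3L))
  expect_equal(al$b_pos, c(1L, NA, 2L))
  # brute-force confirmation over the BLOSUM62 submatrix
  m <- default_matrix()
  expect_equal(al$score,
               oracle_global_score(c("A", "C", "D"), c("A", "D"), m))
})

test_that("local mode floors at the empty alignment", {
  neg <- matrix(-1, 4, 4, dimnames = list(toy_alphabet, toy_alphabet))
  p <- alignment_params(matrix = neg, gap_open = 11, gap_extend = 2,
                        mode = "local")
  al <- align_pair("ACGT", "TGCA", p)
  expect_equal(al$score, 0)
  expect_length(al$a_pos, 0L)
})

test_that("DP scores match exhaustive enumeration on short pairs", {
  set.seed(7)
  for (rep in 1:30) {
    la <- sample.int(4L, 1L); lb <- sample.int(4L, 1L)
    a <- sample(toy_alphabet, la, replace = TRUE)
    b <- sample(toy_alphabet, lb, replace = TRUE)
    for (conv in c("blast", "emboss")) {
      alg <- align_pair(paste(a, collapse = ""), paste(b, collapse = ""),
                        toy_params("global", conv))
      expect_equal(alg$score,
                   oracle_global_score(a, b, emboss = conv == "emboss"),
                   info = sprintf("global %s %s/%s", conv,
                                  paste(a, collapse = ""),
                                  paste(b, collapse = "")))
      all_ <- align_pair(paste(a, collapse = ""), paste(b, collapse = ""),
                         toy_params("local", conv))
      expect_equal(all_$score,
                   oracle_local_score(a, b, emboss = conv == "emboss"),
                   info = sprintf("local %s %s/%s", conv,
                                  paste(a, collapse = ""),
                                  paste(b, collapse = "")))
    }
  }
})

test_that("alignment score and identity are symmetric in the inputs", {
  set.seed(11)
  for (rep in 1:20) {
    a <- paste(sample(toy_alphabet, sample(2:8, 1), TRUE), collapse = "")
    b <- paste(sample(toy_alphabet, sample(2:8, 1), TRUE), collapse = "")
    for (mode in c("global", "local")) {
      al_ab <- align_pair(a, b, toy_params(mode))
      al_ba <- align_pair(b, a, toy_params(mode))
      expect_equal(al_ab$score, al_ba$score)
      if (length(al_ab$a_pos) && length(al_ba$a_pos))
        expect_equal(percent_identity(al_ab), percent_identity(al_ba))
    }
  }
})

test_that("identity follows the declared denominator conventions", {
  al <- align_pair("ACDE", "ACDF")
  expect_equal(percent_identity(al), 75)
  expect_equal(percent_identity(align_pair("AAAA", "AAAA")), 100)

  # hand-built 3-column alignment with one gap column
  al3 <- list(idA = "x", idB = "y", seqA = "ACD", seqB = "AD",
              a_pos = c(1L, 2L, 3L), b_pos = c(1L, NA, 2L), score = 0)
  class(al3) <- "sse_alignment"
  expect_equal(percent_identity(al3), 100 * 2 / 3)
  expect_equal(percent_identity(al3, denominator = "ne"), 100)
  expect_equal(alignment_ne(al3), 2L)

  # appending identical residues never lowers global identity
  p <- toy_params("global")
  a <- "ACGT"; b <- "AGT"
  id0 <- percent_identity(align_pair(a, b, p))
  for (k in 1:4) {
    a <- paste0(a, "A"); b <- paste0(b, "A")
    id1 <- percent_identity(align_pair(a, b, p))
    expect_gte(id1 + 1e-9, id0)
    id0 <- id1
  }
})

test_that("degenerate aligner inputs are rejected", {
  expect_error(align_pair("", "ACD"), "empty")
  expect_error(align_pair("ACD", "AZD"), "not in matrix")
  expect_error(alignment_params(gap_open = 1, gap_extend = 2), "gap_open")
})

test_that("external alignments and correspondences load with validation", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "AC-D", ">s2", "ACED"), fa)
  al <- read_alignment(fa, "aligned-fasta")
  expect_equal(length(al$a_pos), 4L)
  expect_equal(alignment_ne(al), 3L)
  expect_equal(al$a_pos, c(1L, 2L, NA, 3L))

  writeLines(c(">s1", "AC-D", ">s2", "ACE"), fa)
  expect_error(read_alignment(fa, "aligned-fasta"), "lengths differ")

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("pos_a\tpos_b", "1\t1", "2\t3", "3\t2"), tsv)
  expect_error(read_alignment(tsv, "tsv-pairs"), "row 3")
  writeLines(c("pos_a\tpos_b", "1\t2", "2\t3"), tsv)
  corr <- read_alignment(tsv, "tsv-pairs")
  expect_s3_class(corr, "correspondence")
  expect_equal(nrow(corr), 2L)
})

test_that("SSE projection keeps residue support and records breaks", {
  ra <- protein_record("ra", "ACDEF", "HHHCC")
  rb <- protein_record("rb", "ACDEF", "HHHCC")
  pr <- project_sse(correspondence(1:5, 1:5), ra, rb)
  expect_identical(pr$obs, ra$sse8)
  expect_identical(pr$pred, rb$sse8)
  expect_length(pr$breaks, 0L)

  # a skip on either side inserts a continuity break
  pr2 <- project_sse(correspondence(c(1L, 3L), c(1L, 2L)), ra, rb)
  expect_equal(pr2$n, 2L)
  expect_equal(pr2$breaks, 1L)

  # crossing a recorded chain break also breaks continuity
  rc <- protein_record("rc", "ACDEF", "HHHCC", breaks = 2L)
  pr3 <- project_sse(correspondence(1:5, 1:5), rc, rb)
  expect_equal(pr3$breaks, 2L)

  expect_equal(project_sse(correspondence(integer(), integer()), ra, rb)$n, 0L)
  expect_error(project_sse(correspondence(c(1L, 6L), c(1L, 2L)), ra, rb),
               "out of bounds")

  # annotations ride along
  rr <- protein_record("rr", "ACDEF", "HHHCC", rsa = seq(0, 1, length.out = 5))
  pr4 <- project_sse(correspondence(c(2L, 4L), c(1L, 2L)), rr, rb)
  expect_equal(pr4$ann$rsa_a, rr$rsa[c(2L, 4L)])
})

test_that("self-alignment yields the full identity correspondence", {
  set.seed(13)
  for (rep in 1:10) {
    s <- paste(sample(toy_alphabet, sample(3:12, 1), TRUE), collapse = "")
    corr <- equivalent_pairs(align_pair(s, s, toy_params()))
    expect_equal(corr$pos_a, seq_len(nchar(s)))
    expect_equal(corr$pos_b, seq_len(nchar(s)))
  }
})
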