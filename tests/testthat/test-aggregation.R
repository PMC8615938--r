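fake_pairs <- function(identity, q3 = 90, n_e = 100) {
  data.frame(idA = sprintf("a%03d", seq_along(identity)),
             idB = sprintf("b%03d", seq_along(identity)),
             identity = identity, n_e = n_e, q3 = q3, q8 = q3 - 5,
             sov3 = q3 - 2, sov8 = q3 - 7,
             lenA = 120L, lenB = 150L,
             family_id = "f", fold_id = "d", unscorable = FALSE,
             stringsAsFactors = FALSE)
}

test_that("weighted mean follows the aligned-residue weighting", {
  expect_equal(weighted_mean(c(90, 80), c(100, 300)), 82.5)
  expect_equal(weighted_mean(c(90, 80, 70), rep(7, 3)), 80)
  expect_equal(weighted_mean(42, 5), 42)
  expect_error(weighted_mean(numeric(), numeric()), "empty")
  expect_error(weighted_mean(c(1, 2), c(1, 0)), "positive")
  set.seed(3)
  for (rep in 1:20) {
    v <- runif(sample(2:10, 1), 0, 100)
    w <- sample.int(500L, length(v))
    wm <- weighted_mean(v, w)
    expect_gte(wm, min(v)); expect_lte(wm, max(v))
  }
})

test_that("level bins use half-open intervals with a singleton at 100", {
  pairs <- fake_pairs(c(30, 34.99, 35, 29.9, 100, 9.5, 97))
  bins <- bin_pair_results(pairs, identity_bin_scheme("level"))
  get <- function(lab) bins[bins$label == lab, ]
  expect_equal(get("30-35")$n_pairs, 2L)   # 30.0 and 34.99
  expect_equal(get("35-40")$n_pairs, 1L)
  expect_equal(get("25-30")$n_pairs, 1L)   # 29.9
  expect_equal(get("100")$n_pairs, 1L)     # exactly 100, apart from 90-100
  expect_equal(get("90-100")$n_pairs, 1L)  # 97
  expect_equal(get("<10")$n_pairs, 1L)     # explicit underflow
  # level bins partition the scored pairs
  expect_equal(sum(bins$n_pairs), nrow(pairs))
})

test_that("threshold and cutoff bins are cumulative and nested", {
  pairs <- fake_pairs(c(29.9, 30, 45, 80, 99))
  thr <- bin_pair_results(pairs, identity_bin_scheme("threshold", c(30, 45)))
  expect_equal(thr$n_pairs[thr$label == ">=30"], 4L)  # 29.9 excluded
  expect_equal(thr$n_pairs[thr$label == ">=45"], 3L)
  cut <- bin_pair_results(pairs, identity_bin_scheme("cutoff", c(30, 45)))
  expect_equal(cut$n_pairs[cut$label == "<30"], 1L)   # 29.9 included
  expect_equal(cut$n_pairs[cut$label == "<45"], 2L)
  # membership nesting: lower threshold is a superset
  thr2 <- bin_pair_results(pairs,
                           identity_bin_scheme("threshold", c(10, 30, 60, 90)))
  expect_true(all(diff(thr2$n_pairs) <= 0))
  cut2 <- bin_pair_results(pairs,
                           identity_bin_scheme("cutoff", c(10, 30, 60, 90)))
  expect_true(all(diff(cut2$n_pairs) >= 0))
})

test_that("bin aggregation weights by n_e and excludes undefined pairs", {
  pairs <- fake_pairs(c(50, 52), q3 = c(90, 80), n_e = c(100, 300))
  bins <- bin_pair_results(pairs, identity_bin_scheme("level", c(50, 55)))
  expect_equal(bins$q3[bins$label == "50-55"], 82.5)
  pairs2 <- rbind(pairs, fake_pairs(NA_real_))
  pairs2$unscorable[3] <- TRUE
  bins2 <- bin_pair_results(pairs2, identity_bin_scheme("level", c(50, 55)))
  expect_equal(attr(bins2, "excluded"), 1L)
  expect_equal(sum(bins2$n_pairs), 2L)
})

test_that("family all-vs-all scores each unordered pair once", {
  set.seed(31)
  fam <- lapply(1:4, function(i)
    sample_protein(length = 60, seed = 100 + i, id = sprintf("m%d", i),
                   family_id = "fam1"))
  res <- family_all_vs_all(fam, alignment_params())
  expect_length(res, 6L)
  keys <- vapply(res, function(r) paste(sort(c(r$idA, r$idB)), collapse = "|"), "")
  expect_equal(anyDuplicated(keys), 0L)

  twin <- list(fam[[1]], fam[[1]])
  twin[[2]]$id <- "copy"
  res2 <- family_all_vs_all(twin)
  expect_length(res2, 1L)
  expect_equal(res2[[1]]$q3, 100)
  expect_equal(res2[[1]]$sov8, 100)

  expect_warning(res3 <- family_all_vs_all(fam[1]), "fewer than 2")
  expect_length(res3, 0L)
})

test_that("fold values are size-weighted over scorable pairs", {
  pairs <- fake_pairs(c(50, 60), q3 = c(90, 80), n_e = c(100, 300))
  fv <- fold_value(pairs)
  expect_equal(fv$q3, 82.5)
  expect_equal(fv$n_pairs, 2L)
  # the alternative weighting uses mean chain length
  pairs$lenA <- c(100L, 500L); pairs$lenB <- c(100L, 500L)
  fv2 <- fold_value(pairs, weight = "mean_length")
  expect_equal(fv2$q3, (90 * 100 + 80 * 500) / 600)
  pairs$unscorable <- TRUE
  expect_null(fold_value(pairs))
})

test_that("subset statistics are seeded, sampled-sd summaries", {
  same <- data.frame(q3 = rep(88, 40))
  rs <- subset_statistics(same, k = 10, seed = 2)
  expect_equal(rs$mean, 88)
  expect_equal(rs$sd, 0)

  vals <- data.frame(q3 = runif(95, 60, 100))
  r1 <- subset_statistics(vals, k = 10, seed = 7)
  r2 <- subset_statistics(vals, k = 10, seed = 7)
  expect_identical(r1, r2)
  r3 <- subset_statistics(vals, k = 10, seed = 8)
  expect_false(isTRUE(all.equal(r1$sd, r3$sd)))

  expect_error(subset_statistics(data.frame(q3 = 1:5), k = 10), "at least")

  # sampling theory: sd of k-subset means ~ sigma / sqrt(n/k)
  set.seed(43)
  sds <- replicate(60, {
    fv <- data.frame(q3 = rnorm(100, 80, 6))
    subset_statistics(fv, k = 10, seed = sample.int(1e6, 1))$sd
  })
  expect_equal(mean(sds), 6 / sqrt(10), tolerance = 0.12)
})

test_that("random pairing of identical records scores 100 everywhere", {
  rec <- protein_record("one", "ACDEFGHIKL", "HHHHEEEECC")
  recs <- list(one = rec, two = rec)
  recs$two$id <- "two"
  null <- random_pair_null(recs, 50, seed = 9)
  expect_true(all(abs(null$means - 100) < 1e-9))
  expect_equal(sum(null$hist$count), 4 * 50)
})

test_that("the null sampler is seed-reproducible and order-invariant", {
  set.seed(1)
  recs <- random_records(40, c(60L, 120L))
  n1 <- random_pair_null(recs, 200, seed = 5)
  n2 <- random_pair_null(recs, 200, seed = 5)
  expect_identical(n1$means, n2$means)
  n3 <- random_pair_null(recs, 200, seed = 6)
  expect_false(identical(n1$means, n3$means))
})

test_that("aligned-projection null runs on small inputs", {
  set.seed(2)
  recs <- random_records(6, c(30L, 50L))
  null <- random_pair_null(recs, 10, seed = 3,
                           projection = "global_seq_align")
  expect_true(all(null$means >= 0 & null$means <= 100))
  expect_equal(null$projection, "global_seq_align")
})
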