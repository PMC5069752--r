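test_that("mint_set satisfies its structural invariants", {
  ids <- mint_set(200, n = 6, seed = 5)
  expect_s3_class(ids, "cualid_set")
  expect_equal(nrow(ids), 200L)
  expect_true(all(nchar(ids$cualid) == 6L))
  expect_false(anyDuplicated(ids$cualid) > 0)
  # every CualID is the suffix of its own UUID
  expect_identical(ids$cualid, derive_cualid(ids$uuid, 6))
  # pairwise separation, checked by brute force over all pairs
  expect_gte(pairwise_min_distance(ids, "levenshtein"), 3)
  expect_gte(pairwise_min_distance(ids, "hamming"), 3)
})

test_that("levenshtein distances agree with the dynamic-programming oracle", {
  ids <- mint_set(25, n = 5, seed = 8)$cualid
  pairs <- utils::combn(ids, 2)
  for (i in seq_len(ncol(pairs))) {
    expect_identical(levenshtein(pairs[1, i], pairs[2, i]),
                     as.integer(lev_dp(pairs[1, i], pairs[2, i])))
  }
})

test_that("mint_set is deterministic under a fixed seed", {
  a <- mint_set(100, n = 4, seed = 123)
  b <- mint_set(100, n = 4, seed = 123)
  expect_identical(a$uuid, b$uuid)
  expect_identical(a$cualid, b$cualid)
  expect_false(identical(a$uuid, mint_set(100, n = 4, seed = 124)$uuid))
})

test_that("mint_set leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(mint_set(10, n = 6, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("impossible requests fail with informative errors", {
  expect_error(mint_set(16^4 + 1, n = 4), class = "cualid_capacity_error")
  # a min_distance beyond the string length: nothing can join the first ID
  expect_error(mint_set(50, n = 4, min_distance = 9, seed = 1,
                        max_attempts = 60),
               class = "cualid_progress_error")
})

test_that("pairwise_min_distance matches hand-computed values", {
  expect_identical(pairwise_min_distance(c("5ed2c4", "4af925"), "hamming"), 6)
  expect_identical(pairwise_min_distance("5ed2c4"), Inf)
  expect_error(pairwise_min_distance(c("5ed2c4", "ff5ed2c4"), "hamming"),
               class = "cualid_metric_error")
  ids <- mint_set(30, n = 6, seed = 2)$cualid
  pairs <- utils::combn(ids, 2)
  expect_equal(pairwise_min_distance(ids, "hamming"),
               min(vapply(seq_len(ncol(pairs)), function(i) {
                 hamming_by_hand(pairs[1, i], pairs[2, i])
               }, numeric(1))))
})

test_that("suffix comparisons scale quadratically with set size", {
  # at length 8 the space is sparse enough that rejections are negligible,
  # so accepted-set comparisons approach k(k-1)/2
  c100 <- attr(mint_set(100, n = 8, seed = 31), "comparisons")
  c200 <- attr(mint_set(200, n = 8, seed = 31), "comparisons")
  expect_gt(c200 / c100, 4 * 0.8)
  expect_lt(c200 / c100, 4 * 1.2)
})

test_that("mapping files round-trip through write_mapping/read_mapping", {
  ids <- mint_set(20, n = 6, seed = 77)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mapping(ids, path)
  lines <- readLines(path)
  expect_identical(lines[1], "uuid\tcualid")
  back <- read_mapping(path)
  expect_identical(back$uuid, ids$uuid)
  expect_identical(back$cualid, ids$cualid)
})

test_that("read_mapping reports malformed files with a line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tname", "a\tb"), path)
  expect_error(read_mapping(path), "line 1", class = "cualid_mapping_error")
  writeLines(c("uuid\tcualid", "a\tb", "too\tmany\tfields"), path)
  expect_error(read_mapping(path), "line 3", class = "cualid_mapping_error")
})
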