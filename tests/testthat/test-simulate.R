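test_that("apply_error implements each transcription error type", {
  expect_identical(apply_error("5ed2c4", "substitution", 1, "a"), "aed2c4")
  expect_identical(apply_error("5ed2c4", "transposition", 1), "e5d2c4")
  expect_identical(apply_error("5ed2c4", "omission", 2), "5d2c4")
  expect_identical(apply_error("5ed2c4", "insertion", 7, "f"), "5ed2c4f")
  expect_identical(apply_error("5ed2c4", "duplication", 3), "5edd2c4")
  expect_error(apply_error("5ed2c4", "omission", 7),
               class = "cualid_arg_error")
  expect_error(apply_error("5ed2c4", "substitution", 1),
               class = "cualid_arg_error")
})

test_that("single errors sit within the expected edit radius", {
  set.seed(61)
  hex <- c(as.character(0:9), letters[1:6])
  for (i in 1:200) {
    src <- random_hex(sample(4:12, 1))
    len <- nchar(src)
    type <- sample(c("substitution", "transposition", "omission",
                     "insertion", "duplication"), 1)
    pos <- switch(type,
      insertion = sample.int(len + 1L, 1),
      transposition = sample.int(len - 1L, 1),
      sample.int(len, 1))
    repl <- switch(type,
      substitution = sample(setdiff(hex, substr(src, pos, pos)), 1),
      insertion = sample(hex, 1),
      NULL)
    out <- apply_error(src, type, pos, repl)
    d <- lev_dp(src, out)
    if (type == "omission") expect_identical(d, 1L)
    expect_lte(d, 2L)  # transpositions cost two unit edits, the rest one
  }
})

test_that("introduce_errors compounds sequentially within the edit budget", {
  set.seed(62)
  for (i in 1:100) {
    src <- random_hex(6)
    n_err <- sample(1:3, 1)
    out <- introduce_errors(src, n_err)
    expect_lte(lev_dp(src, out), 2L * n_err)
    expect_gte(nchar(out), 6L - n_err)
    expect_lte(nchar(out), 6L + n_err)
  }
  expect_error(introduce_errors("5ed2c4", 0), class = "cualid_arg_error")
})

test_that("uncorrupted queries produce no errors of either kind", {
  ids <- mint_set(50, n = 6, seed = 63)
  res <- fix_batch(ids$cualid, ids)
  expect_true(all(res$status == "exact"))
  expect_identical(res$cualid, ids$cualid)
})

test_that("run_condition returns valid fractions with combined = FN + FP", {
  res <- run_condition(6, 50, 10, 2, iterations = 4, seed = 64)
  for (col in c("fn_mean", "fp_mean", "combined_mean")) {
    expect_gte(res[[col]], 0)
    expect_lte(res[[col]], 1)
  }
  expect_equal(res$combined_mean, res$fn_mean + res$fp_mean,
               tolerance = 1e-12)
  expect_error(run_condition(6, 10, 11, 1), class = "cualid_arg_error")
})

test_that("run_grid is deterministic and reduces to run_condition", {
  a <- run_grid(lengths = 6, errored_counts = 5, errors_per_id = 2,
                set_size = 30, iterations = 3, seed = 65)
  b <- run_condition(6, 30, 5, 2, iterations = 3, seed = 65)
  expect_identical(a, b)
  c2 <- run_grid(lengths = c(4, 6), errored_counts = c(2, 5),
                 errors_per_id = 1:2, set_size = 30, iterations = 3,
                 seed = 66)
  c3 <- run_grid(lengths = c(4, 6), errored_counts = c(2, 5),
                 errors_per_id = 1:2, set_size = 30, iterations = 3,
                 seed = 66)
  expect_identical(c2, c3)
  expect_equal(c2$combined_mean, c2$fn_mean + c2$fp_mean, tolerance = 1e-12)
})
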