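known6 <- published_table$cualid6

test_that("fix_id resolves the published length-6 identifiers", {
  res <- fix_id("5ed2c4", known6)
  expect_identical(res$status, "exact")
  expect_identical(res$cualid, "5ed2c4")
  # a duplicated 'd': highest ratio 12/13 against the source, well clear
  # of the others (both below 0.4 by brute force)
  res <- fix_id("5edd2c4", known6)
  expect_identical(res$status, "corrected")
  expect_identical(res$cualid, "5ed2c4")
  expect_equal(res$score, 12 / 13)
  # shares no more than one character with any known ID
  res <- fix_id("ffffff", known6)
  expect_identical(res$status, "unresolved")
  expect_true(is.na(res$cualid))
  expect_lt(res$score, 0.6)
})

test_that("queries are normalized before matching", {
  res <- fix_id("  5ED2C4\t", known6)
  expect_identical(res$status, "exact")
  expect_identical(res$cualid, "5ed2c4")
})

test_that("matches are withheld on ties and below the cutoff", {
  # both candidates share the 5-block "abc12": an exact ratio tie
  res <- fix_id("abc12f", c("abc123", "abc124"))
  expect_identical(res$status, "ambiguous")
  expect_true(is.na(res$cualid))
  # matched fields are populated only for exact/corrected outcomes
  for (q in c("abc12f", "ffffff", "5ed2c4")) {
    r <- fix_id(q, c(known6, "abc123", "abc124"))
    expect_identical(is.na(r$cualid),
                     !r$status %in% c("exact", "corrected"))
  }
})

test_that("a valid known ID is never rewritten", {
  ids <- mint_set(100, n = 6, seed = 14)$cualid
  for (q in ids[seq(1, 100, by = 7)]) {
    r <- fix_id(q, ids)
    expect_identical(r$status, "exact")
    expect_identical(r$cualid, q)
  }
})

test_that("fix_batch downgrades multiply-hit targets and reports them", {
  res <- fix_batch("5ed2c4", known6)
  expect_identical(res$status, "exact")
  expect_length(attr(res, "duplicates"), 0)

  res <- fix_batch(c("5ed2c4", "5ed2c4"), known6)
  expect_identical(res$status, rep("duplicate_target", 2))
  expect_true(all(is.na(res$cualid)))
  expect_identical(attr(res, "duplicates"), "5ed2c4")

  # one exact and one corrected hit on the same target conflict too
  res <- fix_batch(c("4af925", "4af92"), known6)
  expect_identical(res$status, rep("duplicate_target", 2))
  expect_identical(attr(res, "duplicates"), "4af925")
})

test_that("fix reports round-trip with the duplicate section", {
  path <- withr::local_tempfile(fileext = ".tsv")
  res <- fix_batch(c("5ed2c4", "5ed2c4", "0434f6"), known6)
  write_fix_report(res, path)
  lines <- readLines(path)
  expect_identical(lines[1], "query\tstatus\tcualid\tuuid\tscore")
  expect_identical(lines[length(lines)], "#duplicate\t5ed2c4")
})

test_that("single substitutions are almost always recovered and never misassigned", {
  # The gestalt matcher is not a perfect single-error decoder: a query can
  # tie between two near-shifted IDs, and greedy block matching can
  # fragment the alignment to the true source (e.g. 312319 -> 319319
  # scores only 0.5).  Both failure modes withhold the match; what must
  # never happen is assignment to the wrong identifier.
  failures <- 0L
  total <- 0L
  for (seed in 1:5) {
    ids <- mint_set(100, n = 6, seed = seed)$cualid
    for (src in ids) {
      chars <- strsplit(src, "", fixed = TRUE)[[1]]
      for (pos in 1:6) {
        for (repl in setdiff(c(as.character(0:9), letters[1:6]),
                             chars[pos])) {
          query <- apply_error(src, "substitution", pos, repl)
          res <- fix_id(query, ids)
          total <- total + 1L
          ok <- res$status == "corrected" && res$cualid == src
          if (!ok) {
            failures <- failures + 1L
            # withheld, not fabricated
            expect_true(res$status %in% c("ambiguous", "unresolved"))
          }
        }
      }
    }
  }
  expect_identical(total, 5L * 100L * 6L * 15L)
  expect_gte(1 - failures / total, 0.99)
})

test_that("each transcription error type is recovered at >= 99%", {
  set.seed(30)
  sets <- lapply(1:5, function(s) mint_set(100, n = 6, seed = s)$cualid)
  hex <- c(as.character(0:9), letters[1:6])
  for (type in c("substitution", "transposition", "omission", "insertion",
                 "duplication")) {
    recovered <- 0L
    trials <- 1000L
    for (i in seq_len(trials)) {
      ids <- sets[[(i - 1L) %% 5L + 1L]]
      src <- sample(ids, 1)
      len <- nchar(src)
      pos <- switch(type,
        insertion = sample.int(len + 1L, 1),
        transposition = sample.int(len - 1L, 1),
        sample.int(len, 1))
      repl <- switch(type,
        substitution = sample(setdiff(hex, substr(src, pos, pos)), 1),
        insertion = sample(hex, 1),
        NULL)
      query <- apply_error(src, type, pos, repl)
      res <- fix_id(query, ids)
      if (res$status %in% c("exact", "corrected") && res$cualid == src) {
        recovered <- recovered + 1L
      }
    }
    expect_gte(recovered / trials, 0.99)
  }
})

test_that("the alternative Levenshtein strategy resolves unique neighbours", {
  ids <- mint_set(100, n = 6, seed = 41)$cualid
  src <- ids[10]
  query <- apply_error(src, "omission", 3)
  res <- fix_id(query, ids, method = "levenshtein")
  expect_identical(res$status, "corrected")
  expect_identical(res$cualid, src)
  res <- fix_id("ffffffffffff", ids, method = "levenshtein")
  expect_identical(res$status, "unresolved")
})

test_that("degenerate correction inputs are rejected", {
  expect_error(fix_id("abcd", character(0)), class = "cualid_arg_error")
  expect_error(fix_id("   ", known6), class = "cualid_empty_error")
})
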