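# Independent oracles used across the suite.  Each re-derives a quantity
# the package computes, by a route the package does not share.

# Unit-cost Levenshtein distance by the textbook dynamic program.
lev_dp <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  m <- length(x)
  n <- length(y)
  prev <- 0:n
  for (i in seq_len(m)) {
    cur <- c(i, integer(n))
    for (j in seq_len(n)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[n + 1L]
}

# Hamming distance by direct positionwise comparison.
hamming_by_hand <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(x) == length(y))
  sum(x != y)
}

# Number of agreeing positions (the positionwise view that misses
# frame-shifted similarity).
positional_matches <- function(a, b) {
  nchar(a) - hamming_by_hand(a, b)
}

# Monte-Carlo birthday collision: fraction of trials in which k uniform
# draws from the 16^n suffix space contain a repeat.
mc_duplicate_fraction <- function(k, n, trials, chunk = 20000L) {
  S <- as.integer(16^n)
  hits <- 0L
  done <- 0L
  while (done < trials) {
    m <- min(chunk, trials - done)
    draws <- matrix(sample.int(S, m * k, replace = TRUE), nrow = m)
    hits <- hits + sum(apply(draws, 1L, anyDuplicated) > 0L)
    done <- done + m
  }
  hits / trials
}

# Code 128 code set B checksum recomputed from the symbology's printable
# character sequence rather than from byte arithmetic.
code128b_oracle_checksum <- function(text) {
  charset <- paste0(" !\"#$%&'()*+,-./0123456789:;<=>?@",
                    "ABCDEFGHIJKLMNOPQRSTUVWXYZ[\\]^_`",
                    "abcdefghijklmnopqrstuvwxyz{|}~")
  chars <- strsplit(charset, "", fixed = TRUE)[[1L]]
  vals <- match(strsplit(text, "", fixed = TRUE)[[1L]], chars) - 1L
  stopifnot(!anyNA(vals))
  (104L + sum(seq_along(vals) * vals)) %% 103L
}

# Gestalt similarity ratios computed by Python difflib.SequenceMatcher
# (the reference gestalt matcher), frozen here as (a, b, ratio) triples.
difflib_reference <- local({
  rows <- list(
    c("12345678", "23456789", "0.875"),
    c("5edd2c4", "5ed2c4", "0.9230769230769231"),
    c("4af92", "4af925", "0.9090909090909091"),
    c("c123b1612", "dd272d", "0.26666666666666666"),
    c("71c1", "7149d", "0.4444444444444444"),
    c("39536b", "3216fdaeeb97", "0.2222222222222222"),
    c("29fae9", "23d5a4f", "0.3076923076923077"),
    c("2aabfe228f", "219e", "0.2857142857142857"),
    c("b0eb53f1", "6947ccf25e", "0.1111111111111111"),
    c("84d8dbc742", "54770f58904d", "0.2727272727272727"),
    c("a41ecccc3fc1", "626e53a13", "0.2857142857142857"),
    c("3b02", "6c48bb", "0.2"),
    c("3feff9243a8", "f506b", "0.125"),
    c("0928b5", "b7a767c76fb0", "0.1111111111111111"),
    c("f86b", "ebb2737f", "0.16666666666666666"),
    c("6f0fb23", "c6f5da2ce", "0.375"),
    c("55404e4fb4", "40034", "0.4"),
    c("608697a8d4", "1bed440", "0.23529411764705882"),
    c("0454f31af31", "76813e", "0.11764705882352941"),
    c("2ea68ef786e4", "d3ce", "0.125"),
    c("7d26934b4", "84e73", "0.2857142857142857"),
    c("575dcad6ba", "2b0aee0ca92", "0.19047619047619047"),
    c("32881", "584d8c4", "0.3333333333333333"),
    c("fa2815d28028", "27283e0ad841", "0.25"),
    c("3581569969e5", "8b08100", "0.21052631578947367"),
    c("6f7e3dfc967a", "64cb14028d51", "0.16666666666666666"),
    c("9791e", "558e08baa7", "0.13333333333333333"))
  data.frame(a = vapply(rows, `[`, "", 1L),
             b = vapply(rows, `[`, "", 2L),
             ratio = as.numeric(vapply(rows, `[`, "", 3L)),
             stringsAsFactors = FALSE)
})

# The three published UUID / CualID rows used throughout the tests.
published_table <- data.frame(
  uuid = c("3cd7e2b8-70ea-41f1-ae99-fea5ff5ed2c4",
           "24c715bc-b0e1-4808-b55f-e2645d4af925",
           "3c094f4a-a1eb-4a78-bc74-c4e05b0434f6"),
  cualid6 = c("5ed2c4", "4af925", "0434f6"),
  cualid8 = c("ff5ed2c4", "5d4af925", "5b0434f6"),
  stringsAsFactors = FALSE)

random_hex <- function(len) {
  paste(sample(c(as.character(0:9), letters[1:6]), len, replace = TRUE),
        collapse = "")
}
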