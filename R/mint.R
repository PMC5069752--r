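#' Mint a distance-constrained set of (UUID, CualID) pairs
#'
#' Mints `count` fresh version-4 UUIDs whose length-`n` CualID suffixes
#' are pairwise separated by a Levenshtein (edit) distance of at least
#' `min_distance` (default 3).  Separation is what makes the short IDs
#' correctable: any single-character transcription slip leaves the
#' corrupted string strictly closer to its source than to every other ID
#' in the run.  For equal-length strings the Levenshtein distance never
#' exceeds the Hamming distance, so the default also guarantees pairwise
#' Hamming distance of at least 3.
#'
#' Construction is rejection sampling: mint a UUID, derive its suffix,
#' and discard the whole UUID whenever the suffix comes too close to any
#' already-accepted suffix (a fresh suffix is never re-derived from a
#' rejected UUID, so every CualID remains a true suffix of its own UUID).
#' Each candidate is compared against all accepted suffixes, so minting
#' `k` identifiers costs on the order of `k^2` comparisons; expect
#' 100,000-ID runs to be slow.
#'
#' @param count number of identifiers to mint.
#' @param n CualID length (4 to 12).
#' @param min_distance minimum pairwise Levenshtein distance (>= 1).
#' @param seed optional integer seed; identical inputs then reproduce the
#'   identical ordered set.  `NULL` draws from the session RNG.
#' @param max_attempts candidate budget before giving up (the suffix
#'   space can become too crowded for a given `n`/`min_distance`).
#' @return a `cualid_set`: a data frame with columns `uuid` and `cualid`,
#'   in minting order, carrying attributes `n`, `min_distance`, `seed`,
#'   `attempts` (candidates drawn) and `comparisons` (suffix-suffix
#'   distance evaluations).
#' @examples
#' ids <- mint_set(5, n = 6, seed = 42)
#' ids
#' pairwise_min_distance(ids)
#' @export
mint_set <- function(count, n = 6L, min_distance = 3L, seed = NULL,
                     max_attempts = 1000 * count) {
  if (!is.numeric(count) || length(count) != 1L || is.na(count) || count < 1) {
    cualid_error("`count` must be a single positive integer",
                 "cualid_arg_error")
  }
  count <- as.integer(count)
  if (!is.numeric(min_distance) || min_distance < 1) {
    cualid_error("`min_distance` must be >= 1", "cualid_arg_error")
  }
  if (count > 16^n) {
    cualid_error(
      sprintf("cannot mint %d distinct length-%d CualIDs: only 16^%d = %s exist",
              count, n, n, format(16^n, big.mark = ",", scientific = FALSE)),
      "cualid_capacity_error")
  }
  with_seed(seed, {
    uuids <- character(count)
    cids <- character(count)
    accepted <- 0L
    attempts <- 0L
    comparisons <- 0
    while (accepted < count) {
      if (attempts >= max_attempts) {
        cualid_error(
          sprintf(paste0(
            "gave up after %d candidates with %d/%d accepted; the length-%d ",
            "suffix space is too crowded for min_distance = %d -- ",
            "increase `n` or `max_attempts`"),
            attempts, accepted, count, n, min_distance),
          "cualid_progress_error")
      }
      u <- mint_uuid(1L)
      attempts <- attempts + 1L
      cid <- derive_cualid(u, n)
      if (accepted > 0L) {
        comparisons <- comparisons + accepted
        d <- utils::adist(cid, cids[seq_len(accepted)])
        if (min(d) < min_distance) next
      }
      accepted <- accepted + 1L
      uuids[accepted] <- u
      cids[accepted] <- cid
    }
    structure(
      data.frame(uuid = uuids, cualid = cids, stringsAsFactors = FALSE),
      n = as.integer(n), min_distance = as.integer(min_distance),
      seed = seed, attempts = attempts, comparisons = comparisons,
      class = c("cualid_set", "data.frame"))
  })
}

#' @export
print.cualid_set <- function(x, ...) {
  cat(sprintf(
    "<cualid_set> %d identifiers, CualID length %d, min pairwise distance %d\n",
    nrow(x), attr(x, "n"), attr(x, "min_distance")))
  print.data.frame(utils::head(x, 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Minimum pairwise distance within a set of CualIDs
#'
#' Exact minimum over all unordered pairs, by brute force.  Serves as the
#' verification oracle for the separation that [mint_set()] promises.
#'
#' @param ids a `cualid_set` or a character vector of IDs.
#' @param metric `"levenshtein"` (unit-cost edit distance) or `"hamming"`
#'   (differing positions; requires equal-length strings).
#' @return the minimum distance as a number; `Inf` for a singleton set,
#'   which has no pairs.
#' @export
pairwise_min_distance <- function(ids, metric = c("levenshtein", "hamming")) {
  metric <- match.arg(metric)
  if (inherits(ids, "cualid_set")) ids <- ids$cualid
  if (length(ids) == 0L) {
    cualid_error("`ids` must be nonempty", "cualid_arg_error")
  }
  if (length(ids) == 1L) return(Inf)
  if (metric == "levenshtein") {
    d <- utils::adist(ids)
    return(min(d[upper.tri(d)]))
  }
  lens <- nchar(ids)
  if (length(unique(lens)) != 1L) {
    cualid_error("hamming distance requires equal-length strings",
                 "cualid_metric_error")
  }
  chm <- do.call(rbind, strsplit(ids, "", fixed = TRUE))
  k <- nrow(chm)
  best <- Inf
  for (i in seq_len(k - 1L)) {
    rest <- chm[(i + 1L):k, , drop = FALSE]
    diffs <- rowSums(rest != matrix(chm[i, ], nrow(rest), ncol(chm),
                                    byrow = TRUE))
    best <- min(best, diffs)
    if (best == 0) break
  }
  best
}

#' Write a minted set to a mapping file
#'
#' Tab-separated, UTF-8, with header `uuid<TAB>cualid` and one record per
#' line, lowercase hex.  This file is the "known identifiers" input to
#' [fix_batch()] and the `fix` CLI subcommand.
#'
#' @param ids a `cualid_set` (or data frame with `uuid`, `cualid`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(ids, path) {
  utils::write.table(ids[, c("uuid", "cualid")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a mapping file written by [write_mapping()]
#'
#' @param path mapping TSV path.
#' @return data frame with columns `uuid` and `cualid`.
#' @export
read_mapping <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L || !identical(lines[1L], "uuid\tcualid")) {
    cualid_error(
      sprintf("%s: line 1: expected header 'uuid\\tcualid'", path),
      "cualid_mapping_error")
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L]
    cualid_error(
      sprintf("%s: line %d: expected 2 tab-separated fields, found %d",
              path, bad + 1L, nf[bad]),
      "cualid_mapping_error")
  }
  data.frame(uuid = tolower(vapply(fields, `[`, "", 1L)),
             cualid = tolower(vapply(fields, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}
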