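normalize_id <- function(x) tolower(trimws(x))

new_correction <- function(query, status, cualid = NA_character_,
                           uuid = NA_character_, score = NA_real_) {
  data.frame(query = query, status = status, cualid = cualid,
             uuid = uuid, score = score, stringsAsFactors = FALSE)
}

lookup_uuid <- function(cualid, map) {
  if (is.null(map) || is.na(cualid)) return(NA_character_)
  hit <- match(cualid, map$cualid)
  if (is.na(hit)) NA_character_ else map$uuid[hit]
}

#' Resolve one possibly mistranscribed CualID
#'
#' Matches a query against the known CualIDs of a minting run.  The query
#' is normalized (lowercased, surrounding whitespace stripped); an exact
#' member of `known` is returned as-is (`status = "exact"` — correction
#' never rewrites a valid ID).  Otherwise the gestalt similarity
#' ([similarity_ratio()]) against every known ID decides:
#' a unique maximum at or above `cutoff` yields `"corrected"`; a tied
#' maximum yields `"ambiguous"`; a maximum below `cutoff` yields
#' `"unresolved"`.  Ties and sub-cutoff scores deliberately withhold the
#' match — for sample tracking, failing to resolve an ID (a false
#' negative) is far less costly than silently resolving it to the wrong
#' sample (a false positive).
#'
#' `method = "levenshtein"` switches to nearest-neighbour resolution by
#' edit distance: a unique nearest known ID within `max_distance` wins.
#' With the default minting separation (pairwise distance >= 3) this
#' provably recovers any single-character error; the gestalt default
#' matches what a human reading the ID would expect and handles
#' frame-shifting errors on longer IDs better.
#'
#' @param query one string to resolve.
#' @param known character vector of known CualIDs (or a `cualid_set` /
#'   mapping data frame, in which case matched UUIDs are reported too).
#' @param cutoff minimum acceptable gestalt ratio (default 0.6).
#' @param method `"gestalt"` (default) or `"levenshtein"`.
#' @param max_distance for `method = "levenshtein"`: largest acceptable
#'   edit distance (default 2, the correctable radius at minting
#'   separation 3).
#' @return one-row data frame: `query`, `status` (one of `exact`,
#'   `corrected`, `unresolved`, `ambiguous`), `cualid`, `uuid`, `score`.
#'   `cualid`/`uuid` are `NA` unless the status is `exact` or
#'   `corrected`; `score` is the gestalt ratio of the best candidate (or
#'   `1 - d/max(nchar)` under the Levenshtein method).
#' @examples
#' known <- c("5ed2c4", "4af925", "0434f6")
#' fix_id("5edd2c4", known)  # duplicated 'd' -> corrected to "5ed2c4"
#' @export
fix_id <- function(query, known, cutoff = 0.6,
                   method = c("gestalt", "levenshtein"), max_distance = 2L) {
  method <- match.arg(method)
  map <- NULL
  if (is.data.frame(known)) {
    map <- known
    known <- known$cualid
  }
  if (length(known) == 0L) {
    cualid_error("`known` must be nonempty", "cualid_arg_error")
  }
  if (length(query) != 1L) {
    cualid_error("`query` must be a single string (see fix_batch)",
                 "cualid_arg_error")
  }
  known <- normalize_id(known)
  q <- normalize_id(query)
  if (!nzchar(q)) {
    cualid_error("empty query after normalization", "cualid_empty_error")
  }
  if (q %in% known) {
    return(new_correction(q, "exact", q, lookup_uuid(q, map), 1))
  }
  if (method == "gestalt") {
    scores <- similarity_ratio(q, known)
    best <- max(scores)
    hits <- which(scores == best)
    if (best < cutoff) return(new_correction(q, "unresolved", score = best))
    if (length(hits) > 1L) return(new_correction(q, "ambiguous", score = best))
    new_correction(q, "corrected", known[hits], lookup_uuid(known[hits], map),
                   best)
  } else {
    d <- drop(utils::adist(q, known))
    best <- min(d)
    hits <- which(d == best)
    score <- 1 - best / max(nchar(q), nchar(known[hits[1L]]))
    if (best > max_distance) return(new_correction(q, "unresolved",
                                                   score = score))
    if (length(hits) > 1L) return(new_correction(q, "ambiguous",
                                                 score = score))
    new_correction(q, "corrected", known[hits], lookup_uuid(known[hits], map),
                   score)
  }
}

#' Resolve a batch of queries, reporting duplicated targets
#'
#' Applies [fix_id()] to every query, then enforces the duplicate rule:
#' a known CualID matched (exactly or by correction) by more than one
#' query cannot be trusted — which physical sample is which? — so all of
#' its matches are downgraded to `status = "duplicate_target"` and the ID
#' is listed in the duplicate report.
#'
#' @inheritParams fix_id
#' @param queries character vector of query IDs.
#' @return a `cualid_fix` data frame (one row per query, columns as in
#'   [fix_id()]) with attribute `duplicates`: the character vector of
#'   known CualIDs hit more than once.
#' @export
fix_batch <- function(queries, known, cutoff = 0.6,
                      method = c("gestalt", "levenshtein"),
                      max_distance = 2L) {
  method <- match.arg(method)
  res <- do.call(rbind, lapply(queries, fix_id, known = known,
                               cutoff = cutoff, method = method,
                               max_distance = max_distance))
  matched <- res$cualid[res$status %in% c("exact", "corrected")]
  dup <- sort(unique(matched[duplicated(matched)]))
  hit <- res$status %in% c("exact", "corrected") & res$cualid %in% dup
  res$status[hit] <- "duplicate_target"
  res$cualid[hit] <- NA_character_
  res$uuid[hit] <- NA_character_
  structure(res, duplicates = dup, class = c("cualid_fix", "data.frame"))
}

#' @export
print.cualid_fix <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  dup <- attr(x, "duplicates")
  if (length(dup)) {
    cat("duplicated targets (not resolvable):", paste(dup, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write a correction report
#'
#' TSV with header `query<TAB>status<TAB>cualid<TAB>uuid<TAB>score`; the
#' duplicate report is appended as comment lines of the form
#' `#duplicate<TAB><cualid>`.
#'
#' @param results a `cualid_fix` object from [fix_batch()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fix_report <- function(results, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(as.data.frame(results), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  for (d in attr(results, "duplicates")) {
    writeLines(paste0("#duplicate\t", d), con)
  }
  invisible(path)
}
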