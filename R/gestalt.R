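#' Gestalt (Ratcliff-Obershelp) similarity ratio
#'
#' Similarity between a query string and one or more candidates, computed
#' by recursively finding the longest contiguous matching block and then
#' matching the regions to its left and right.  The ratio is
#' `2 * M / (nchar(a) + nchar(b))` where `M` is the total length of all
#' matching blocks: 1 for identical strings, 0 when no character is
#' shared.
#'
#' This block-based similarity is better suited to transcription-error
#' correction than positionwise (Hamming) comparison because it tolerates
#' frame shifts: `"12345678"` and `"23456789"` disagree at every position
#' yet share the 7-character block `"2345678"`, scoring 0.875.
#'
#' The matcher is order-sensitive in edge cases (tie-breaking prefers
#' blocks earliest in `a`); the convention throughout the package is
#' `similarity_ratio(query, candidate)`.
#'
#' @param a the query string (length-1 character).
#' @param b candidate string(s).
#' @return numeric vector of ratios in `[0, 1]`, one per candidate.
#' @examples
#' similarity_ratio("12345678", "23456789")  # 0.875
#' @export
similarity_ratio <- function(a, b) {
  if (!is.character(a) || length(a) != 1L || is.na(a) ||
      !is.character(b) || length(b) < 1L || anyNA(b)) {
    cualid_error("`a` must be one string and `b` a character vector",
                 "cualid_arg_error")
  }
  if (!nzchar(a) || any(!nzchar(b))) {
    cualid_error("cannot compare empty strings", "cualid_empty_error")
  }
  gestalt_ratios_cpp(a, b)
}

#' Levenshtein (edit) distance
#'
#' Unit-cost edit distance: the minimum number of single-character
#' substitutions, insertions and deletions converting one string into the
#' other.  A thin wrapper around [utils::adist()], provided both as the
#' comparison oracle for the gestalt matcher and as the alternative
#' resolution strategy of [fix_id()].
#'
#' @param a,b character vectors.
#' @return for two scalars, a single integer; otherwise the
#'   `length(a) x length(b)` integer distance matrix.
#' @examples
#' levenshtein("12345678", "23456789")  # 2
#' @export
levenshtein <- function(a, b) {
  d <- utils::adist(a, b)
  if (length(d) == 1L) return(as.integer(d[1L]))
  storage.mode(d) <- "integer"
  d
}
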