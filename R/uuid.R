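#' @useDynLib cualid, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# data-masked ggplot2 aesthetics
utils::globalVariables(c("k", "probability", "n", "n_errored", "n_errors",
                         "frac", "sd"))

HEX_ALPHABET <- c(as.character(0:9), letters[1:6])

UUID_V4_REGEX <- paste0(
  "^[0-9a-f]{8}-[0-9a-f]{4}-4[0-9a-f]{3}-",
  "[89ab][0-9a-f]{3}-[0-9a-f]{12}$"
)

# classed condition helper so callers can test on error class
cualid_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cualid_error")))
}

# Run expr with a locally seeded RNG stream; the caller's RNG state is
# untouched.  seed = NULL uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1L)) {
    cualid_error("`seed` must be a single integer", "cualid_seed_error")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Mint random version-4 UUIDs
#'
#' Generates universally unique identifiers of UUID version 4: 32
#' hexadecimal characters (128 bits) in the canonical 8-4-4-4-12
#' hyphenated form.  122 bits are drawn from R's random number stream;
#' the remaining 6 bits are fixed so that the version nibble is `4` and
#' the variant nibble is one of `8`, `9`, `a`, `b`.  With over 10^36
#' possible values, collisions are negligible for any practical number of
#' samples, which is what makes decentralized (offline) minting safe.
#'
#' Randomness comes from the session RNG: call [set.seed()] first (or use
#' [mint_set()] with its `seed` argument) for reproducible identifiers.
#'
#' @param n number of UUIDs to mint.
#' @return character vector of `n` lowercase hyphenated UUIDs.
#' @examples
#' set.seed(1)
#' mint_uuid(3)
#' @export
mint_uuid <- function(n = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    cualid_error("`n` must be a single positive integer", "cualid_arg_error")
  }
  n <- as.integer(n)
  nib <- matrix(sample.int(16L, 32L * n, replace = TRUE) - 1L, nrow = n)
  nib[, 13L] <- 4L                    # version nibble
  nib[, 17L] <- 8L + nib[, 17L] %% 4L # variant nibble: 10xx bit pattern
  chars <- matrix(HEX_ALPHABET[nib + 1L], nrow = n)
  raw32 <- apply(chars, 1L, paste0, collapse = "")
  paste(substr(raw32, 1L, 8L), substr(raw32, 9L, 12L),
        substr(raw32, 13L, 16L), substr(raw32, 17L, 20L),
        substr(raw32, 21L, 32L), sep = "-")
}

#' Test whether strings are canonical version-4 UUIDs
#'
#' @param x character vector.
#' @return logical vector; `TRUE` where `x` is a lowercase hyphenated
#'   version-4 UUID (after normalizing case).
#' @export
is_uuid <- function(x) {
  grepl(UUID_V4_REGEX, tolower(trimws(x)))
}

#' Derive a CualID from a UUID
#'
#' A CualID is the human-transcribable companion of a UUID: the last `n`
#' hexadecimal characters of the UUID (hyphens removed).  Because the
#' final hyphenated group of a UUID holds 12 characters, any `n` up to 12
#' is a plain visual suffix of the printed UUID, so the mapping from
#' CualID back to UUID can be done by eye.
#'
#' @param uuid character vector of UUIDs (case-insensitive).
#' @param n CualID length, between 4 and 12 inclusive.
#' @return character vector of lowercase CualIDs.
#' @examples
#' derive_cualid("3cd7e2b8-70ea-41f1-ae99-fea5ff5ed2c4", 6)  # "5ed2c4"
#' @export
derive_cualid <- function(uuid, n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n != as.integer(n) ||
      n < 4 || n > 12) {
    cualid_error(
      sprintf("CualID length must be an integer between 4 and 12, got %s",
              deparse(substitute(n), nlines = 1L)),
      "cualid_length_error")
  }
  uuid <- tolower(trimws(uuid))
  bad <- !grepl("^[0-9a-f-]+$", uuid) | nchar(gsub("-", "", uuid)) != 32L
  if (any(bad)) {
    cualid_error(
      sprintf("not a 32-hex-character UUID: %s", uuid[bad][1L]),
      "cualid_uuid_error")
  }
  stripped <- gsub("-", "", uuid, fixed = TRUE)
  substr(stripped, 33L - as.integer(n), 32L)
}
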