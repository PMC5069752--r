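# Code 128 (ISO/IEC 15417) symbology tables.
#
# One entry per symbol value 0..106; each 6-digit string gives the module
# widths of the symbol's 3 bars and 3 spaces, alternating bar-first, and
# summing to 11 modules.  Value 103/104/105 are the Start A/B/C codes;
# 106 is the Stop pattern, which carries a 7th element (the 2-module
# termination bar) and spans 13 modules.
CODE128_PATTERNS <- c(
  "212222", "222122", "222221", "121223", "121322", "131222", "122213",
  "122312", "132212", "221213", "221312", "231212", "112232", "122132",
  "122231", "113222", "123122", "123221", "223211", "221132", "221231",
  "213212", "223112", "312131", "311222", "321122", "321221", "312212",
  "322112", "322211", "212123", "212321", "232121", "111323", "131123",
  "131321", "112313", "132113", "132311", "211313", "231113", "231311",
  "112133", "112331", "132131", "113123", "113321", "133121", "313121",
  "211331", "231131", "213113", "213311", "213131", "311123", "311321",
  "331121", "312113", "312311", "332111", "314111", "221411", "431111",
  "111224", "111422", "121124", "121421", "141122", "141221", "112214",
  "112412", "122114", "122411", "142112", "142211", "241211", "221114",
  "413111", "241112", "134111", "111242", "121142", "121241", "114212",
  "124112", "124211", "411212", "421112", "421211", "212141", "214121",
  "412121", "111143", "111341", "131141", "114113", "114311", "411113",
  "411311", "113141", "114131", "311141", "411131", "211412", "211214",
  "211232", "2331112")

CODE128_START_B <- 104L
CODE128_STOP <- 106L

code128_widths_of <- function(value) {
  as.integer(strsplit(CODE128_PATTERNS[value + 1L], "", fixed = TRUE)[[1L]])
}

# Code set B maps printable ASCII 32..127 to symbol values 0..95.
code128B_value <- function(chars) {
  v <- vapply(chars, function(ch) utf8ToInt(ch) - 32L, integer(1))
  unname(v)
}

#' Encode text as a Code 128 barcode
#'
#' Produces the symbol values and module widths of a Code 128 (code set
#' B) barcode: Start B, one symbol per character, the weighted mod-103
#' check symbol (start value plus the position-weighted sum of the data
#' values, modulo 103), and the Stop pattern.  Identifier text is
#' restricted to the hexadecimal alphabet plus the hyphen — everything a
#' CualID or hyphenated UUID can contain.
#'
#' @param text the string to encode (case-insensitive hex, `-` allowed).
#' @return a `code128` object: list with `text`, `values` (integer symbol
#'   values including start, check and stop) and `widths` (integer module
#'   widths, bar first, alternating bar/space).
#' @examples
#' code <- encode_code128("5ed2c4")
#' decode_code128(code$widths)
#' @export
encode_code128 <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    cualid_error("`text` must be one nonempty string", "cualid_arg_error")
  }
  text <- tolower(text)
  if (!grepl("^[0-9a-f-]+$", text)) {
    cualid_error(
      sprintf("unsupported character in %s: only hex digits and '-' can appear on a label", text),
      "cualid_char_error")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  data_values <- code128B_value(chars)
  check <- (CODE128_START_B +
              sum(seq_along(data_values) * data_values)) %% 103L
  values <- c(CODE128_START_B, data_values, check, CODE128_STOP)
  widths <- unlist(lapply(values, code128_widths_of))
  structure(list(text = text, values = as.integer(values),
                 widths = as.integer(widths)),
            class = "code128")
}

#' Decode Code 128 module widths back to text
#'
#' Inverse of [encode_code128()] for code set B symbols: splits the width
#' sequence into 11-module symbols, validates the start code, the Stop
#' pattern and the mod-103 check symbol, and maps the data symbols back
#' to characters.  Any corruption of a single module width is caught:
#' every valid symbol spans exactly 11 modules, so a width change either
#' produces an unknown pattern or desynchronizes the stop/check
#' structure.
#'
#' @param widths integer vector of module widths (as from
#'   `encode_code128(x)$widths`).
#' @return the decoded text.
#' @export
decode_code128 <- function(widths) {
  widths <- as.integer(widths)
  n <- length(widths)
  if (n < 19L || (n - 7L) %% 6L != 0L) {
    cualid_error("width sequence has no valid Code 128 structure",
                 "code128_decode_error")
  }
  n_symbols <- (n - 7L) %/% 6L
  values <- integer(n_symbols)
  for (i in seq_len(n_symbols)) {
    pat <- paste(widths[(6L * (i - 1L) + 1L):(6L * i)], collapse = "")
    hit <- match(pat, CODE128_PATTERNS[1:106])
    if (is.na(hit)) {
      cualid_error(sprintf("symbol %d: unknown module pattern %s", i, pat),
                   "code128_decode_error")
    }
    values[i] <- hit - 1L
  }
  stop_pat <- paste(widths[(n - 6L):n], collapse = "")
  if (!identical(stop_pat, CODE128_PATTERNS[CODE128_STOP + 1L])) {
    cualid_error("missing or corrupt stop pattern", "code128_decode_error")
  }
  if (values[1L] != CODE128_START_B) {
    cualid_error("not a code set B barcode", "code128_decode_error")
  }
  data_values <- values[-c(1L, n_symbols)]
  check <- values[n_symbols]
  expect <- (CODE128_START_B +
               sum(seq_along(data_values) * data_values)) %% 103L
  if (check != expect) {
    cualid_error(sprintf("checksum mismatch: read %d, computed %d",
                         check, expect), "code128_decode_error")
  }
  if (any(data_values > 95L)) {
    cualid_error("data symbol outside code set B", "code128_decode_error")
  }
  paste(vapply(data_values, function(v) intToUtf8(v + 32L), ""),
        collapse = "")
}
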