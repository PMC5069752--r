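ERROR_TYPES <- c("substitution", "transposition", "omission", "insertion",
                 "duplication")

#' Apply one transcription error deterministically
#'
#' The five error types a person transcribing an ID commonly makes:
#' substituting one character for another, transposing (swapping) two
#' adjacent characters, omitting a character, inserting a character, and
#' duplicating a character.  Positions are 1-based; for `insertion`,
#' `position` is where the new character lands (so `nchar(id) + 1`
#' appends).
#'
#' @param id the string to corrupt.
#' @param type one of `"substitution"`, `"transposition"`, `"omission"`,
#'   `"insertion"`, `"duplication"`.
#' @param position 1-based position of the error.
#' @param replacement the character written instead (required for
#'   substitution and insertion, unused otherwise).
#' @return the corrupted string.
#' @examples
#' apply_error("5ed2c4", "substitution", 1, "a")  # "aed2c4"
#' apply_error("5ed2c4", "duplication", 3)        # "5edd2c4"
#' @export
apply_error <- function(id, type, position, replacement = NULL) {
  type <- match.arg(type, ERROR_TYPES)
  len <- nchar(id)
  maxpos <- if (type == "insertion") len + 1L else
            if (type == "transposition") len - 1L else len
  if (!is.numeric(position) || position < 1L || position > maxpos) {
    cualid_error(sprintf("position %s out of bounds for %s on %d characters",
                         position, type, len), "cualid_arg_error")
  }
  if (type %in% c("substitution", "insertion") && is.null(replacement)) {
    cualid_error(sprintf("%s requires a replacement character", type),
                 "cualid_arg_error")
  }
  ch <- strsplit(id, "", fixed = TRUE)[[1L]]
  ch <- switch(type,
    substitution = { ch[position] <- replacement; ch },
    transposition = { ch[c(position, position + 1L)] <-
                        ch[c(position + 1L, position)]; ch },
    omission = ch[-position],
    insertion = append(ch, replacement, after = position - 1L),
    duplication = append(ch, ch[position], after = position))
  paste(ch, collapse = "")
}

#' Corrupt an ID with random transcription errors
#'
#' Applies `n_errors` errors in sequence.  At each step the type is
#' uniform over the five error types (transposition and omission are
#' excluded when the current string is a single character), the position
#' uniform over the valid positions for that type, and the written
#' character uniform over the hex alphabet — excluding, for a
#' substitution, the character actually present, so every substitution
#' really changes the string.  Errors compound: later positions are drawn
#' against the current, possibly length-shifted, string.
#'
#' @param id the CualID to corrupt.
#' @param n_errors number of errors to introduce (>= 1).
#' @return the corrupted string (its length may differ from the input's).
#' @export
introduce_errors <- function(id, n_errors = 1L) {
  if (!is.numeric(n_errors) || n_errors < 1L) {
    cualid_error("`n_errors` must be >= 1", "cualid_arg_error")
  }
  for (i in seq_len(n_errors)) {
    types <- if (nchar(id) >= 2L) ERROR_TYPES else
      c("substitution", "insertion", "duplication")
    type <- sample(types, 1L)
    len <- nchar(id)
    position <- switch(type,
      insertion = sample.int(len + 1L, 1L),
      transposition = sample.int(len - 1L, 1L),
      sample.int(len, 1L))
    replacement <- NULL
    if (type == "substitution") {
      current <- substr(id, position, position)
      replacement <- sample(setdiff(HEX_ALPHABET, current), 1L)
    } else if (type == "insertion") {
      replacement <- sample(HEX_ALPHABET, 1L)
    }
    id <- apply_error(id, type, position, replacement)
  }
  id
}

#' Simulate correction of transcription errors for one condition
#'
#' Measures how often error correction fails.  Per iteration: mint a
#' fresh distance-constrained set, corrupt a sample of its CualIDs with
#' [introduce_errors()], and resolve every corrupted query with
#' [fix_id()] against the set.  A query that comes back `unresolved` or
#' `ambiguous` is a *false negative* (the ID cannot be resolved and no
#' correction is returned); a query assigned to a different ID than its
#' source — whether by exact coincidence or by correction — is a *false
#' positive*.  Fractions are over the corrupted queries of the iteration;
#' the summary reports their mean and standard deviation across
#' iterations.  `combined` is FN + FP within each iteration.
#'
#' @param cualid_length CualID length to mint.
#' @param set_size identifiers per minted set.
#' @param n_errored_ids how many set members are corrupted (sampled
#'   without replacement; must not exceed `set_size`).
#' @param n_errors_per_id errors introduced into each corrupted ID.
#' @param iterations independent repeats (default 20).
#' @param cutoff gestalt acceptance cutoff passed to [fix_id()].
#' @param seed optional integer seed.
#' @param min_distance minting separation (default 3).
#' @return one-row data frame: `length`, `set_size`, `n_errored`,
#'   `n_errors`, `iterations`, `fn_mean`, `fn_sd`, `fp_mean`, `fp_sd`,
#'   `combined_mean`, `combined_sd`.
#' @export
run_condition <- function(cualid_length, set_size, n_errored_ids,
                          n_errors_per_id, iterations = 20L, cutoff = 0.6,
                          seed = NULL, min_distance = 3L) {
  if (n_errored_ids > set_size) {
    cualid_error("`n_errored_ids` must not exceed `set_size`",
                 "cualid_arg_error")
  }
  if (iterations < 1L) {
    cualid_error("`iterations` must be >= 1", "cualid_arg_error")
  }
  with_seed(seed, {
    fn <- fp <- numeric(iterations)
    for (it in seq_len(iterations)) {
      ids <- mint_set(set_size, n = cualid_length,
                      min_distance = min_distance)
      picked <- sample.int(set_size, n_errored_ids)
      is_fn <- is_fp <- logical(n_errored_ids)
      for (j in seq_along(picked)) {
        src <- ids$cualid[picked[j]]
        query <- introduce_errors(src, n_errors_per_id)
        res <- fix_id(query, ids$cualid, cutoff = cutoff)
        if (res$status %in% c("unresolved", "ambiguous")) {
          is_fn[j] <- TRUE
        } else if (res$cualid != src) {
          is_fp[j] <- TRUE
        }
      }
      fn[it] <- mean(is_fn)
      fp[it] <- mean(is_fp)
    }
    data.frame(length = cualid_length, set_size = set_size,
               n_errored = n_errored_ids, n_errors = n_errors_per_id,
               iterations = iterations,
               fn_mean = mean(fn), fn_sd = stats::sd(fn),
               fp_mean = mean(fp), fp_sd = stats::sd(fp),
               combined_mean = mean(fn + fp),
               combined_sd = stats::sd(fn + fp))
  })
}

#' Sweep the error-correction simulation over a factorial grid
#'
#' Full factorial sweep of [run_condition()] over CualID lengths, numbers
#' of corrupted IDs and errors per ID.  The default grid — lengths
#' `{4, 6, 8}`, corrupted counts `{1, 5, 10, 25}`, `{1, 2, 3}` errors per
#' ID, sets of 100, 20 iterations — spans the regimes of interest at desk
#' scale: from the comfortably correctable (one error on a length-6 ID)
#' to the saturated (three errors on a length-4 ID).
#'
#' @param lengths CualID lengths.
#' @param errored_counts numbers of corrupted IDs per iteration.
#' @param errors_per_id numbers of errors per corrupted ID.
#' @param set_size identifiers per minted set.
#' @param iterations repeats per condition.
#' @param cutoff gestalt acceptance cutoff.
#' @param seed optional integer seed; fixing it reproduces the table
#'   exactly.
#' @return data frame with one row per condition, columns as in
#'   [run_condition()].
#' @export
run_grid <- function(lengths = c(4L, 6L, 8L),
                     errored_counts = c(1L, 5L, 10L, 25L),
                     errors_per_id = 1:3,
                     set_size = 100L, iterations = 20L, cutoff = 0.6,
                     seed = NULL) {
  if (!length(lengths) || !length(errored_counts) || !length(errors_per_id)) {
    cualid_error("grids must be nonempty", "cualid_arg_error")
  }
  grid <- expand.grid(n_errors = errors_per_id, n_errored = errored_counts,
                      length = lengths)
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      run_condition(grid$length[i], set_size, grid$n_errored[i],
                    grid$n_errors[i], iterations = iterations,
                    cutoff = cutoff)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Plot simulation error fractions
#'
#' Three panels — false negatives, false positives, and their sum — with
#' the number of corrupted IDs on the x axis, one colour per error count,
#' one column per CualID length.
#'
#' @param grid_result output of [run_grid()].
#' @return a ggplot object.
#' @export
plot_error_grid <- function(grid_result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    cualid_error("plotting requires the ggplot2 package", "cualid_dep_error")
  }
  panels <- rbind(
    data.frame(grid_result[c("length", "n_errored", "n_errors")],
               panel = "false negatives", frac = grid_result$fn_mean,
               sd = grid_result$fn_sd),
    data.frame(grid_result[c("length", "n_errored", "n_errors")],
               panel = "false positives", frac = grid_result$fp_mean,
               sd = grid_result$fp_sd),
    data.frame(grid_result[c("length", "n_errored", "n_errors")],
               panel = "either", frac = grid_result$combined_mean,
               sd = grid_result$combined_sd))
  ggplot2::ggplot(panels,
                  ggplot2::aes(x = factor(n_errored), y = frac,
                               fill = factor(n_errors))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(frac - sd, 0), ymax = frac + sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25) +
    ggplot2::facet_grid(panel ~ length, scales = "free_y") +
    ggplot2::labs(x = "CualIDs with transcription errors",
                  y = "fraction of corrupted queries",
                  fill = "errors per ID") +
    ggplot2::theme_bw()
}
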