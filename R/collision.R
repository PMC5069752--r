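#' Probability of a duplicate CualID among unconstrained draws
#'
#' CualIDs are short, so unlike UUIDs they are not globally unique: if
#' `k` suffixes of length `n` were drawn uniformly and independently from
#' the `16^n` possibilities, the chance that at least two coincide is the
#' classic birthday problem,
#' `1 - prod(1 - i/S)` for `i = 0 .. k-1`, `S = 16^n`.
#' The product is evaluated in log space (`log1p`) so it is stable for
#' very small and very large probabilities alike.
#'
#' This models *unconstrained* draws — the risk the minting-time distance
#' filter exists to defeat.  Sets produced by [mint_set()] additionally
#' enforce a minimum pairwise distance, so their realized duplicate
#' probability is exactly zero; use this curve to choose a length at
#' which minting remains fast and correctable, not to estimate duplicates
#' in minted output.
#'
#' @param k number of identifiers drawn (vectorized).
#' @param n CualID length, 4 to 12.
#' @param alphabet_size alphabet cardinality (16 for hexadecimal).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @examples
#' duplicate_probability(100, 4)
#' @export
duplicate_probability <- function(k, n, alphabet_size = 16L) {
  if (!is.numeric(k) || length(k) < 1L || anyNA(k) || any(k < 1)) {
    cualid_error("`k` must be positive integer(s)", "cualid_arg_error")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 4 || n > 12) {
    cualid_error("`n` must be between 4 and 12", "cualid_length_error")
  }
  if (!is.numeric(alphabet_size) || alphabet_size < 2) {
    cualid_error("`alphabet_size` must be >= 2", "cualid_arg_error")
  }
  S <- alphabet_size^n
  kmax <- max(k)
  if (kmax > S) {
    # pigeonhole beyond k = S; compute the rest normally
    logq <- cumsum(log1p(-(seq_len(min(kmax, S)) - 1) / S))
    p <- ifelse(k > S, 1, -expm1(logq[pmin(k, S)]))
    return(p)
  }
  logq <- cumsum(log1p(-(seq_len(kmax) - 1) / S))
  -expm1(logq[k])
}

#' Birthday-problem approximation `1 - exp(-k(k-1)/2S)`
#'
#' The standard closed-form approximation, provided for cross-checking
#' [duplicate_probability()]; the package itself always uses the exact
#' product.
#'
#' @inheritParams duplicate_probability
#' @return numeric vector of approximate probabilities.
#' @export
duplicate_probability_approx <- function(k, n, alphabet_size = 16L) {
  S <- alphabet_size^n
  -expm1(-k * (k - 1) / (2 * S))
}

#' Duplicate-probability curve over lengths and study sizes
#'
#' Tabulates [duplicate_probability()] for each CualID length over a grid
#' of study sizes, suitable for plotting probability against `k` with one
#' series per length.  The probability is nondecreasing in `k` for fixed
#' `n` and nonincreasing in `n` for fixed `k`.
#'
#' @param lengths CualID lengths to tabulate.
#' @param max_k largest study size.
#' @param k_values optional explicit vector of study sizes; the default
#'   covers `1:max_k` densely up to 10,000 and log-spaced beyond.
#' @return data frame with columns `n`, `k`, `probability`.
#' @export
collision_curve <- function(lengths, max_k, k_values = NULL) {
  if (length(lengths) < 1L) {
    cualid_error("`lengths` must be nonempty", "cualid_arg_error")
  }
  if (is.null(k_values)) {
    k_values <- if (max_k <= 10000) seq_len(max_k) else {
      unique(c(1L, round(exp(seq(0, log(max_k), length.out = 2000L)))))
    }
  }
  k_values <- sort(unique(as.integer(k_values)))
  out <- do.call(rbind, lapply(as.integer(lengths), function(n) {
    data.frame(n = n, k = k_values,
               probability = duplicate_probability(k_values, n))
  }))
  rownames(out) <- NULL
  out
}

#' Recommended CualID length for a study size
#'
#' Step lookup over the recommended anchors: studies of up to 100, 1,000,
#' 10,000 and 100,000 samples get lengths 4, 5, 6 and 8 respectively
#' (the smallest anchor covering the study, i.e. rounding in the safe
#' direction).  Above 100,000 samples no anchor applies; size the ID
#' yourself with [duplicate_probability()] and mind that minting time
#' grows quadratically.
#'
#' @param n_samples expected number of samples (vectorized).
#' @return integer vector of recommended lengths.
#' @export
recommend_length <- function(n_samples) {
  if (!is.numeric(n_samples) || length(n_samples) < 1L || anyNA(n_samples) ||
      any(n_samples < 1)) {
    cualid_error("`n_samples` must be positive integer(s)",
                 "cualid_arg_error")
  }
  if (any(n_samples > 100000)) {
    cualid_error(paste0(
      "no recommended length above 100,000 samples; ",
      "use duplicate_probability() to size the identifier manually"),
      "cualid_range_error")
  }
  vapply(n_samples, function(x) {
    if (x <= 100) 4L else if (x <= 1000) 5L else if (x <= 10000) 6L else 8L
  }, integer(1))
}

#' Plot a duplicate-probability curve
#'
#' @param curve output of [collision_curve()].
#' @return a ggplot object.
#' @export
plot_collision_curve <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    cualid_error("plotting requires the ggplot2 package", "cualid_dep_error")
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = k, y = probability,
                                      colour = factor(n))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "identifiers drawn (k)",
                  y = "P(at least one duplicate)",
                  colour = "CualID length") +
    ggplot2::theme_bw()
}
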