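#' Shannon entropy of a clonotype frequency distribution
#'
#' Computes \eqn{H = -\sum_i p_i \log_2 p_i} in bits, the diversity measure
#' underlying the clonality index. Zero frequencies contribute nothing
#' (\eqn{0 \log 0 = 0}).
#'
#' @param frequencies Numeric vector of clonotype frequencies; must be
#'   non-negative and sum to 1 within `tol`.
#' @param tol Tolerance on the sum-to-one check.
#' @return Entropy in bits.
#' @export
#' @examples
#' shannon_entropy(rep(0.25, 4))  # 2 bits
shannon_entropy <- function(frequencies, tol = 1e-6) {
  if (!is.numeric(frequencies) || length(frequencies) == 0L) {
    stop_fmt("frequencies must be a non-empty numeric vector")
  }
  if (anyNA(frequencies) || any(frequencies < 0)) {
    stop_fmt("frequencies must be non-negative and non-missing")
  }
  s <- sum(frequencies)
  if (abs(s - 1) > tol) {
    stop_fmt("frequencies sum to %.8f, not 1 (tolerance %g)", s, tol)
  }
  p <- frequencies[frequencies > 0]
  -sum(p * log2(p))
}

#' Clonality index of a repertoire sample
#'
#' The clonality index is 1 minus the normalized Shannon entropy:
#' \eqn{H_{norm} = H / \log_2 N} with \eqn{N} the number of unique CDR3
#' amino-acid clonotypes. It ranges from 0 (maximal diversity, all
#' clonotypes equally frequent) to 1 (a completely oligoclonal sample),
#' and, being depth-normalized, is comparable across samples sequenced to
#' different depths. A single-clonotype sample has \eqn{H_{max} = 0}; the
#' index is defined as 1 there, the oligoclonal limit.
#'
#' @param x A `clonotype_table`, or a numeric vector of frequencies
#'   summing to 1.
#' @return An object of class `clonality_result` with fields `H`, `H_max`,
#'   `H_norm`, `clonality` and `n_unique`.
#' @export
#' @examples
#' clonality_index(c(0.5, 0.25, 0.25))
clonality_index <- function(x) {
  if (inherits(x, "clonotype_table")) {
    freqs <- x$table$frequency
  } else if (is.numeric(x)) {
    freqs <- x
  } else {
    stop_fmt("x must be a clonotype_table or a numeric frequency vector")
  }
  if (length(freqs) == 0L) stop_fmt("empty frequency vector")
  n <- length(freqs)
  H <- shannon_entropy(freqs)
  H_max <- log2(n)
  if (n == 1L) {
    H_norm <- 1  # convention: single clonotype is fully oligoclonal
    clon <- 1
  } else {
    H_norm <- H / H_max
    clon <- 1 - H_norm
  }
  structure(list(H = H, H_max = H_max, H_norm = H_norm,
                 clonality = clon, n_unique = n),
            class = "clonality_result")
}

#' @export
print.clonality_result <- function(x, ...) {
  cat(sprintf(
    "Clonality: %.4f  (H = %.4f bits, H_max = %.4f, N = %d)\n",
    x$clonality, x$H, x$H_max, x$n_unique))
  invisible(x)
}

# exact null distribution of the signed-rank sum W+ under random signs,
# on 2x-scaled ranks so average ranks at ties stay integral.
# Returns counts over W+*2 = 0..sum(ranks2); total 2^n. Convolution over
# rank terms -- identical to enumerating all 2^n sign assignments.
signed_rank_null_counts <- function(ranks) {
  ranks2 <- round(2 * ranks)
  if (max(abs(2 * ranks - ranks2)) > 1e-8) {
    stop_fmt("ranks are not half-integral")  # cannot happen for midranks
  }
  total <- sum(ranks2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] +
      f[1L:(total + 1L - r)]
    f <- g
  }
  f
}

#' Paired Wilcoxon signed-rank test with exact small-sample p-value
#'
#' Two-sided paired signed-rank test. Zero differences are dropped;
#' absolute differences are ranked with average ranks at ties; the
#' statistic is the smaller of the positive- and negative-rank sums. For
#' up to 25 effective pairs the p-value is exact over all \eqn{2^n} sign
#' assignments (computed by convolution of the rank terms, which
#' enumerates the same distribution without materialising the
#' assignments); beyond that a normal approximation with continuity
#' correction and tie-corrected variance is used.
#'
#' @param values_a,values_b Paired numeric vectors of equal length.
#' @return An object of classes `paired_signed_rank` and `htest` with the
#'   statistic `V` (min of the two rank sums), `p.value`, and fields
#'   `n_effective` and `method` (`"exact"` or `"normal_approx"` noted in
#'   the method string).
#' @export
#' @examples
#' paired_signed_rank(c(3, 4, 5, 6, 7), c(1, 2, 3, 4, 5))  # p = 0.0625
paired_signed_rank <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop_fmt("values_a and values_b must have equal length")
  }
  d <- values_a - values_b
  if (anyNA(d)) stop_fmt("missing values in paired differences")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop_fmt("all paired differences are zero: test undefined")
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w_min <- min(w_pos, w_neg)
  if (n <= 25L) {
    counts <- signed_rank_null_counts(r)
    # P(W+ <= w_min) on the 2x scale; null is symmetric so the two-sided
    # p doubles the lower tail at the smaller rank sum
    lower <- sum(counts[seq_len(round(2 * w_min) + 1L)]) / 2^n
    p <- min(1, 2 * lower)
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- n * (n + 1) / 4
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w_min - mu + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal_approx"
  }
  structure(list(
    statistic = c(V = w_min),
    p.value = p,
    n_effective = n,
    method = sprintf("Paired Wilcoxon signed-rank test (%s, two-sided)",
                     method),
    approx = method,
    W_pos = w_pos, W_neg = w_neg,
    data.name = deparse(substitute(values_a))
  ), class = c("paired_signed_rank", "htest"))
}
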