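#' Top-N clonotypes of a sample
#'
#' Ranks clonotypes by template count (ties broken by lexicographic CDR3,
#' ascending, so the ranking is deterministic under any input order) and
#' returns the top `n` together with the fraction of the sampled
#' repertoire they account for.
#'
#' @param table A `clonotype_table`.
#' @param n Number of clonotypes to return (default 50). Tables with
#'   fewer clonotypes return all of them.
#' @return An object of class `top_n_list`: list with `meta`,
#'   `n_requested`, `entries` (data frame `rank`, `cdr3_aa`, `v_call`,
#'   `j_call`, `templates`, `frequency`) and `repertoire_fraction`.
#' @export
top_n <- function(table, n = 50L) {
  stopifnot(inherits(table, "clonotype_table"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop_fmt("n must be a single integer >= 1")
  }
  tab <- table$table
  ord <- order(-tab$templates, tab$cdr3_aa)
  take <- utils::head(ord, n)
  entries <- tab[take, c("cdr3_aa", "v_call", "j_call", "templates",
                         "frequency"), drop = FALSE]
  entries <- cbind(rank = seq_len(nrow(entries)), entries)
  rownames(entries) <- NULL
  structure(list(meta = table$meta, n_requested = as.integer(n),
                 entries = entries,
                 repertoire_fraction = sum(entries$frequency)),
            class = "top_n_list")
}

#' @export
print.top_n_list <- function(x, ...) {
  cat(sprintf(
    "Top %d clonotypes of sample %s: %.1f%% of the sampled repertoire\n",
    nrow(x$entries), x$meta$sample_id, 100 * x$repertoire_fraction))
  print(utils::head(x$entries, 5))
  invisible(x)
}

as_cdr3_set <- function(x) {
  if (inherits(x, "top_n_list")) return(unique(x$entries$cdr3_aa))
  if (inherits(x, "clonotype_table")) return(unique(x$table$cdr3_aa))
  if (is.character(x)) return(unique(x))
  stop_fmt("cannot interpret object of class %s as a clonotype set",
           paste(class(x), collapse = "/"))
}

#' Venn partition of 2--4 clonotype sets
#'
#' Counts the elements falling in every intersection region of up to four
#' sets (as drawn in a Venn diagram). Region counts always sum to the size
#' of the union.
#'
#' @param ... Two to four clonotype sets: character vectors,
#'   `clonotype_table`s or `top_n_list`s, ideally named.
#' @return A data frame with one row per non-empty membership pattern:
#'   logical membership columns (one per set), `region` (e.g. `"A&B"`)
#'   and `count`; the union size is in attribute `union_size`.
#' @export
#' @examples
#' overlap(A = c("x", "y", "z"), B = c("y", "z", "w"))
overlap <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], c("clonotype_table", "top_n_list"))) {
    sets <- sets[[1]]
  }
  k <- length(sets)
  if (k < 2L || k > 4L) {
    stop_fmt("overlap() supports 2 to 4 sets, got %d", k)
  }
  sets <- lapply(sets, as_cdr3_set)
  if (any(lengths(sets) == 0L)) stop_fmt("sets must be non-empty")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- LETTERS[seq_len(k)]
  }
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, ncol = k,
                   dimnames = list(NULL, names(sets)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-2^k, , drop = FALSE]
  names(patterns) <- names(sets)
  pattern_key <- apply(patterns, 1, paste, collapse = ",")
  key <- apply(member, 1, paste, collapse = ",")
  counts <- table(factor(key, levels = pattern_key))
  out <- patterns
  out$region <- apply(patterns, 1, function(p)
    paste(names(sets)[as.logical(p)], collapse = "&"))
  out$count <- as.integer(counts)
  rownames(out) <- NULL
  attr(out, "union_size") <- length(universe)
  out
}

# vectorised Pearson chi-squared on 2x2 tables (clonotype vs rest x
# sample), 1 df; equals the squared pooled two-proportion z statistic
chi2_2x2 <- function(x1, n1, x2, n2, correct = FALSE) {
  # double arithmetic: the cross-product term overflows integer range
  a <- as.numeric(x1); b <- as.numeric(n1) - a
  c <- as.numeric(x2); d <- as.numeric(n2) - c
  N <- n1 + n2
  num <- abs(a * d - b * c)
  if (correct) num <- pmax(0, num - N / 2)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom > 0, N * num^2 / denom, 0)
  chi2
}

#' Two-proportion chi-squared comparison of one clonotype between samples
#'
#' Pearson chi-squared test (1 df, no continuity correction by default) on
#' the 2x2 table of clonotype vs rest-of-repertoire template counts in two
#' samples, with a direction call: `up` if the frequency is significantly
#' higher in sample 2, `down` if significantly lower, `no_change`
#' otherwise. A clonotype absent from both samples is `not_tested`. When
#' the clonotype is absent from exactly one sample the test is still
#' computed but flagged (`flag` column); with `strict_absent = TRUE` the
#' p-value is withheld instead (reported as `NA`, direction `not_tested`),
#' mirroring a "not determined" convention.
#'
#' All count arguments are vectorised.
#'
#' @param x1,n1 Clonotype and total template counts in sample 1.
#' @param x2,n2 Clonotype and total template counts in sample 2.
#' @param alpha Two-sided significance level for the direction call.
#' @param correct Apply Yates continuity correction.
#' @param strict_absent Withhold the test when the clonotype is absent
#'   from one sample.
#' @return Data frame with columns `x1`, `n1`, `x2`, `n2`, `freq1`,
#'   `freq2`, `chi2`, `p`, `direction`
#'   (`up`/`down`/`no_change`/`not_tested`), `flag` and `alpha`.
#' @export
#' @examples
#' compare_frequency(20, 100, 5, 100)  # significant decrease
compare_frequency <- function(x1, n1, x2, n2, alpha = 0.05,
                              correct = FALSE, strict_absent = FALSE) {
  len <- max(length(x1), length(x2))
  x1 <- rep_len(x1, len); x2 <- rep_len(x2, len)
  n1 <- rep_len(n1, len); n2 <- rep_len(n2, len)
  if (any(n1 <= 0) || any(n2 <= 0)) stop_fmt("totals must be positive")
  if (any(x1 < 0) || any(x2 < 0) || any(x1 > n1) || any(x2 > n2)) {
    stop_fmt("clonotype counts must satisfy 0 <= x <= n")
  }
  if (alpha <= 0 || alpha >= 1) stop_fmt("alpha must be in (0,1)")
  chi2 <- chi2_2x2(x1, n1, x2, n2, correct = correct)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  f1 <- x1 / n1; f2 <- x2 / n2
  direction <- ifelse(p < alpha & f2 > f1, "up",
               ifelse(p < alpha & f2 < f1, "down", "no_change"))
  flag <- rep("", len)
  flag[x1 == 0 & x2 > 0] <- "absent_sample_1"
  flag[x2 == 0 & x1 > 0] <- "absent_sample_2"
  both_zero <- x1 == 0 & x2 == 0
  chi2[both_zero] <- NA_real_
  p[both_zero] <- NA_real_
  direction[both_zero] <- "not_tested"
  flag[both_zero] <- "absent_both"
  if (strict_absent) {
    nd <- nzchar(flag) & !both_zero
    p[nd] <- NA_real_
    chi2[nd] <- NA_real_
    direction[nd] <- "not_tested"
  }
  data.frame(x1 = x1, n1 = n1, x2 = x2, n2 = n2,
             freq1 = f1, freq2 = f2, chi2 = chi2, p = p,
             direction = direction, flag = flag, alpha = alpha,
             stringsAsFactors = FALSE)
}

#' Track clonotype frequency changes between two samples
#'
#' Runs [compare_frequency()] for every clonotype of a universe (typically
#' a top-N list or a multi-sample intersection) across two clonotype
#' tables, and flags membership in each sample's top-N. No
#' multiple-testing correction is applied by default; `adjust = "BH"`
#' switches the direction call to Benjamini-Hochberg adjusted p-values.
#'
#' @param table_a,table_b `clonotype_table`s for the two samples (sample 1
#'   and sample 2 of the comparison; `up` means higher in `table_b`).
#' @param universe Character vector of CDR3 sequences to test (or an
#'   object coercible via a top-N list / clonotype table). Defaults to the
#'   intersection of the two tables' clonotypes. Members absent from both
#'   tables are dropped.
#' @param alpha Significance level.
#' @param n_top Top-N size used for the membership flags (default 50).
#' @param adjust `"none"` (default, each test at raw alpha) or `"BH"`.
#' @param strict_absent Passed to [compare_frequency()].
#' @return Data frame, one row per tested clonotype: `cdr3_aa`, the
#'   [compare_frequency()] columns, `p_adj` when `adjust = "BH"`, and
#'   logical `in_top_a`, `in_top_b`; sorted by direction (up, down,
#'   no_change, not_tested), then p.
#' @export
track <- function(table_a, table_b, universe = NULL, alpha = 0.05,
                  n_top = 50L, adjust = c("none", "BH"),
                  strict_absent = FALSE) {
  stopifnot(inherits(table_a, "clonotype_table"),
            inherits(table_b, "clonotype_table"))
  adjust <- match.arg(adjust)
  ta <- table_a$table; tb <- table_b$table
  if (is.null(universe)) {
    universe <- intersect(ta$cdr3_aa, tb$cdr3_aa)
  } else {
    universe <- as_cdr3_set(universe)
  }
  universe <- universe[universe %in% ta$cdr3_aa |
                         universe %in% tb$cdr3_aa]
  universe <- sort(unique(universe))
  if (length(universe) == 0L) {
    out <- data.frame(cdr3_aa = character(0))
    return(out)
  }
  xa <- stats::setNames(ta$templates, ta$cdr3_aa)[universe]
  xb <- stats::setNames(tb$templates, tb$cdr3_aa)[universe]
  xa[is.na(xa)] <- 0; xb[is.na(xb)] <- 0
  cmp <- compare_frequency(unname(xa), table_a$total_templates,
                           unname(xb), table_b$total_templates,
                           alpha = alpha, strict_absent = strict_absent)
  out <- cbind(cdr3_aa = universe, cmp, stringsAsFactors = FALSE)
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    testable <- !is.na(out$p_adj)
    out$direction[testable] <-
      ifelse(out$p_adj[testable] < alpha & out$freq2[testable] > out$freq1[testable], "up",
      ifelse(out$p_adj[testable] < alpha & out$freq2[testable] < out$freq1[testable], "down",
             "no_change"))
  }
  top_a <- top_n(table_a, n_top)$entries$cdr3_aa
  top_b <- top_n(table_b, n_top)$entries$cdr3_aa
  out$in_top_a <- out$cdr3_aa %in% top_a
  out$in_top_b <- out$cdr3_aa %in% top_b
  dir_rank <- match(out$direction, c("up", "down", "no_change",
                                     "not_tested"))
  out <- out[order(dir_rank, out$p, out$cdr3_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}
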