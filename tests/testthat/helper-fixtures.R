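# fixture builders and independent oracles shared across test files

make_records <- function(cdr3, templates = 1L, v = "TRBV05-1",
                         j = "TRBJ2-1", productive = TRUE) {
  data.frame(cdr3_aa = cdr3,
             v_call = rep_len(v, length(cdr3)),
             j_call = rep_len(j, length(cdr3)),
             templates = as.integer(rep_len(templates, length(cdr3))),
             productive = rep_len(productive, length(cdr3)),
             stringsAsFactors = FALSE)
}

# clonotype table straight from named counts
make_table <- function(counts, sample_id = "s1", compartment = "brain",
                       subject_id = sample_id, timepoint = "t1") {
  recs <- make_records(names(counts), templates = unname(counts))
  aggregate_clonotypes(recs, sample_meta(sample_id, subject_id,
                                         compartment, timepoint))
}

# brute-force recursive Levenshtein distance (memoised), independent of
# the package's dynamic programme
oracle_levenshtein <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(a, b) {
    if (nchar(a) == 0L) return(nchar(b))
    if (nchar(b) == 0L) return(nchar(a))
    key <- paste(a, b, sep = "\r")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    ta <- substr(a, 2L, nchar(a)); tb <- substr(b, 2L, nchar(b))
    cost <- substr(a, 1L, 1L) != substr(b, 1L, 1L)
    v <- min(rec(ta, tb) + cost, rec(ta, b) + 1L, rec(a, tb) + 1L)
    memo[[key]] <- v
    v
  }
  rec(a, b)
}

# exact two-sided signed-rank p by literal enumeration of all 2^n sign
# assignments (average ranks at ties), for small n
oracle_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_plus <- as.vector(signs %*% r)
  lower <- mean(w_plus <= w_obs)
  min(1, 2 * lower)
}

random_aa <- function(n, min_len = 1L, max_len = 8L,
                      alphabet = c("A", "C", "S")) {
  vapply(sample(seq(min_len, max_len), n, replace = TRUE), function(L) {
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
}

# all strings over an alphabet up to a length (including "")
all_strings <- function(alphabet, max_len) {
  out <- ""
  layer <- ""
  for (l in seq_len(max_len)) {
    layer <- as.vector(outer(layer, alphabet, paste0))
    out <- c(out, layer)
  }
  out
}
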