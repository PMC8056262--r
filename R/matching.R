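check_aa <- function(x, what) {
  bad <- !is_aa_string(x)
  if (any(bad)) {
    stop_fmt("%s contains non-amino-acid characters: %s", what,
             paste(utils::head(x[bad], 3), collapse = ", "))
  }
}

# distance-only Levenshtein, two-row dynamic programme (unit costs)
levenshtein <- function(a, b) {
  m <- nchar(a); n <- nchar(b)
  if (m == 0L) return(n)
  if (n == 0L) return(m)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  prev <- 0:n
  for (i in seq_len(m)) {
    cur <- numeric(n + 1L)
    cur[1L] <- i
    for (j in seq_len(n)) {
      cur[j + 1L] <- min(prev[j] + (av[i] != bv[j]),
                         prev[j + 1L] + 1,
                         cur[j] + 1)
    }
    prev <- cur
  }
  as.integer(prev[n + 1L])
}

#' Align a query CDR3 to a reference CDR3
#'
#' Computes the unit-cost Levenshtein distance between the two sequences
#' and a canonical optimal edit script describing the reference in terms
#' of the query, with three operation kinds matching the usual printed
#' rendering of near-matched CDR3 pairs:
#'
#' * `substitution` -- a reference residue differs from the aligned query
#'   residue (rendered lowercase in `annotation`);
#' * `deletion` -- the reference lacks a residue present in the query
#'   (rendered `-`);
#' * `insertion` -- the reference carries an extra residue absent from the
#'   query (rendered in square brackets).
#'
#' Among co-optimal alignments, the traceback canonically prefers
#' match/substitution over deletion over insertion, so the reported edit
#' script is unique. Applying the ops in order to the reference
#' reconstructs the query (see [apply_edit_ops()]).
#'
#' @param query Query CDR3 amino-acid sequence (uppercase; may be empty).
#' @param reference Reference CDR3 amino-acid sequence.
#' @return An object of class `cdr3_match`: list with `query`,
#'   `reference`, integer `distance`, `ops` (data frame `col`
#'   (alignment column), `position` (query position), `kind`, `from`,
#'   `to`), aligned strings `query_aln` / `ref_aln`, a one-line
#'   `annotation` rendering of the reference, and `metadata` (`NULL`
#'   unless attached by [match_viral()]).
#' @export
#' @examples
#' edit_align("CASSLVGGNTEAFF", "CASSLFGGNTEAFF")
edit_align <- function(query, reference) {
  stopifnot(is.character(query), length(query) == 1L,
            is.character(reference), length(reference) == 1L)
  check_aa(query, "query")
  check_aa(reference, "reference")
  q <- strsplit(query, "", fixed = TRUE)[[1]]
  r <- strsplit(reference, "", fixed = TRUE)[[1]]
  m <- length(q); n <- length(r)
  dp <- matrix(0L, m + 1L, n + 1L)
  dp[, 1L] <- 0:m
  dp[1L, ] <- 0:n
  if (m > 0L && n > 0L) {
    for (i in seq_len(m)) {
      for (j in seq_len(n)) {
        dp[i + 1L, j + 1L] <- min(dp[i, j] + (q[i] != r[j]),
                                  dp[i, j + 1L] + 1L,
                                  dp[i + 1L, j] + 1L)
      }
    }
  }
  # canonical traceback: diagonal (match/substitution) > up (deletion,
  # reference gap) > left (insertion, extra reference residue)
  i <- m; j <- n
  q_aln <- character(0); r_aln <- character(0)
  kind <- character(0); from <- character(0); to <- character(0)
  pos_q <- integer(0)
  while (i > 0L || j > 0L) {
    here <- dp[i + 1L, j + 1L]
    if (i > 0L && j > 0L &&
        here == dp[i, j] + (q[i] != r[j])) {
      q_aln <- c(q[i], q_aln); r_aln <- c(r[j], r_aln)
      if (q[i] != r[j]) {
        kind <- c("substitution", kind)
        from <- c(r[j], from); to <- c(q[i], to)
        pos_q <- c(i, pos_q)
      } else {
        kind <- c("", kind); from <- c("", from); to <- c("", to)
        pos_q <- c(i, pos_q)
      }
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && here == dp[i, j + 1L] + 1L) {
      q_aln <- c(q[i], q_aln); r_aln <- c("-", r_aln)
      kind <- c("deletion", kind)
      from <- c("-", from); to <- c(q[i], to)
      pos_q <- c(i, pos_q)
      i <- i - 1L
    } else {
      q_aln <- c("-", q_aln); r_aln <- c(r[j], r_aln)
      kind <- c("insertion", kind)
      from <- c(r[j], from); to <- c("-", to)
      pos_q <- c(i + 1L, pos_q)
      j <- j - 1L
    }
  }
  is_op <- nzchar(kind)
  ops <- data.frame(col = which(is_op),
                    position = pos_q[is_op],
                    kind = kind[is_op],
                    from = from[is_op],
                    to = to[is_op],
                    stringsAsFactors = FALSE)
  rownames(ops) <- NULL
  # rendered reference: match as-is, substitution lowercase, deletion '-',
  # insertion bracketed
  render <- r_aln
  sub_cols <- ops$col[ops$kind == "substitution"]
  ins_cols <- ops$col[ops$kind == "insertion"]
  render[sub_cols] <- tolower(render[sub_cols])
  render[ins_cols] <- paste0("[", render[ins_cols], "]")
  structure(list(
    query = query, reference = reference,
    distance = dp[m + 1L, n + 1L],
    ops = ops,
    query_aln = paste(q_aln, collapse = ""),
    ref_aln = paste(r_aln, collapse = ""),
    annotation = paste(render, collapse = ""),
    metadata = NULL
  ), class = "cdr3_match")
}

#' @export
print.cdr3_match <- function(x, ...) {
  cat(sprintf("CDR3 alignment, edit distance %d\n", x$distance))
  cat(sprintf("  query: %s\n", x$query_aln))
  cat(sprintf("  ref:   %s\n", x$ref_aln))
  cat(sprintf("  rendered reference: %s\n", x$annotation))
  if (nrow(x$ops) > 0L) {
    for (k in seq_len(nrow(x$ops))) {
      op <- x$ops[k, ]
      cat(sprintf("  %s at query position %d (%s -> %s)\n",
                  op$kind, op$position, op$from, op$to))
    }
  }
  if (!is.null(x$metadata)) {
    cat(sprintf("  matched: %s epitope %s (%s, %s)\n",
                x$metadata$cdr3_aa, x$metadata$epitope,
                x$metadata$antigen, x$metadata$species))
  }
  invisible(x)
}

#' Apply an edit script to a reference sequence
#'
#' Replays the edit operations of a [edit_align()] result on the reference
#' sequence, reconstructing the query. Used to verify edit-script
#' soundness.
#'
#' @param reference The reference sequence the ops were computed against.
#' @param ops The `ops` data frame of a `cdr3_match`.
#' @return The reconstructed query string.
#' @export
apply_edit_ops <- function(reference, ops) {
  r <- strsplit(reference, "", fixed = TRUE)[[1]]
  n_del <- sum(ops$kind == "deletion")
  L <- length(r) + n_del
  op_at <- stats::setNames(seq_len(nrow(ops)), ops$col)
  out <- character(0)
  ri <- 1L
  for (col in seq_len(L)) {
    k <- op_at[as.character(col)]
    if (!is.na(k)) {
      op <- ops[k, ]
      if (op$kind == "deletion") {
        out <- c(out, op$to)           # residue missing from reference
      } else if (op$kind == "insertion") {
        ri <- ri + 1L                  # drop the extra reference residue
      } else {
        out <- c(out, op$to)           # substitution
        ri <- ri + 1L
      }
    } else {
      out <- c(out, r[ri])
      ri <- ri + 1L
    }
  }
  paste(out, collapse = "")
}

#' Construct or read a public-clonotype reference
#'
#' A public-clonotype reference is a local snapshot mapping CDR3
#' amino-acid sequences to the number of distinct individuals in which
#' each was observed, standing in for an online repertoire-sharing
#' database search so that public/private calls are reproducible and
#' versionable by file checksum.
#'
#' @param cdr3_aa Character vector of CDR3 sequences.
#' @param subject_count Integer vector (>= 1) of per-sequence subject
#'   counts.
#' @param source_label Free-text provenance label.
#' @return An object of class `public_reference` (a data frame).
#' @export
public_reference <- function(cdr3_aa, subject_count,
                             source_label = "local") {
  stopifnot(length(cdr3_aa) == length(subject_count))
  if (any(subject_count < 1)) stop_fmt("subject_count must be >= 1")
  check_aa(cdr3_aa, "public reference cdr3_aa")
  df <- data.frame(cdr3_aa = toupper(cdr3_aa),
                   subject_count = as.integer(subject_count),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df$cdr3_aa), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("public_reference", "data.frame"),
            source_label = source_label)
}

#' @rdname public_reference
#' @param path TSV file with columns `cdr3_aa` and `subject_count`.
#' @export
read_public_reference <- function(path) {
  df <- read_tsv_plain(path)
  need <- c("cdr3_aa", "subject_count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop_fmt("public reference %s is missing column(s): %s", path,
             paste(missing_cols, collapse = ", "))
  }
  public_reference(df$cdr3_aa, df$subject_count, source_label = path)
}

# VDJdb export columns -> standard names
.vdjdb_columns <- c(cdr3_aa = "cdr3", epitope = "antigen.epitope",
                    antigen = "antigen.gene", species = "species",
                    mhc_allele = "mhc.a", v_call = "v.segm",
                    j_call = "j.segm")

#' Read a virus-specific CDR3 reference table
#'
#' Accepts either VDJdb-style export columns (`cdr3`, `antigen.epitope`,
#' `antigen.gene`, `species`, `mhc.a`, and optionally `v.segm`/`j.segm`)
#' or the standardized names (`cdr3_aa`, `epitope`, `antigen`, `species`,
#' `mhc_allele`, `v_call`, `j_call`).
#'
#' @param path TSV file path.
#' @return A data frame of class `viral_cdr3_table` with the standardized
#'   columns.
#' @export
read_viral_table <- function(path) {
  df <- read_tsv_plain(path)
  for (std in names(.vdjdb_columns)) {
    vdj <- .vdjdb_columns[[std]]
    if (!std %in% names(df) && vdj %in% names(df)) {
      names(df)[names(df) == vdj] <- std
    }
  }
  need <- c("cdr3_aa", "epitope", "antigen", "species")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop_fmt("viral table %s is missing column(s): %s", path,
             paste(missing_cols, collapse = ", "))
  }
  if (!"mhc_allele" %in% names(df)) df$mhc_allele <- ""
  if (!"v_call" %in% names(df)) df$v_call <- ""
  if (!"j_call" %in% names(df)) df$j_call <- ""
  df$mhc_allele[is.na(df$mhc_allele)] <- ""
  df$cdr3_aa <- toupper(df$cdr3_aa)
  if (any(!nzchar(df$cdr3_aa))) stop_fmt("empty cdr3_aa in %s", path)
  viral_cdr3_table(df)
}

#' @rdname read_viral_table
#' @param df Data frame with the standardized columns.
#' @export
viral_cdr3_table <- function(df) {
  need <- c("cdr3_aa", "epitope", "antigen", "species")
  stopifnot(all(need %in% names(df)))
  if (!"mhc_allele" %in% names(df)) df$mhc_allele <- ""
  if (!"v_call" %in% names(df)) df$v_call <- ""
  if (!"j_call" %in% names(df)) df$j_call <- ""
  check_aa(df$cdr3_aa, "viral cdr3_aa")
  rownames(df) <- NULL
  structure(df[, c("cdr3_aa", "epitope", "antigen", "species",
                   "mhc_allele", "v_call", "j_call")],
            class = c("viral_cdr3_table", "data.frame"))
}

#' Classify clonotypes as public or private
#'
#' A clonotype is public when its CDR3 amino-acid sequence appears in the
#' reference with a subject count of at least `min_subjects`; otherwise it
#' is private (patient-specific). Identity is by CDR3 amino-acid sequence
#' alone.
#'
#' @param cdr3_aa Character vector of query CDR3 sequences.
#' @param reference A [public_reference()].
#' @param min_subjects Minimum subject count to call a sequence public.
#' @return Character vector, `"public"` or `"private"`, one per query.
#' @export
classify_public <- function(cdr3_aa, reference, min_subjects = 1L) {
  stopifnot(inherits(reference, "public_reference"))
  counts <- stats::setNames(reference$subject_count, reference$cdr3_aa)
  found <- unname(counts[cdr3_aa])
  ifelse(!is.na(found) & found >= min_subjects, "public", "private")
}

#' Match a CDR3 against virus-specific reference clonotypes
#'
#' Aligns the query to every reference CDR3 and returns all hits within
#' `max_distance` edits, sorted by distance, then epitope, then reference
#' sequence (deterministic). An optional HLA filter restricts candidate
#' rows to the listed restricting alleles before matching, as when a
#' patient's typed alleles narrow the plausible epitope space.
#'
#' @param query Query CDR3 sequence.
#' @param table A `viral_cdr3_table`.
#' @param max_distance Maximum edit distance to report (default 2).
#' @param hla_filter Optional character vector of MHC allele strings; rows
#'   whose `mhc_allele` is not in the set are excluded.
#' @return Data frame of hits with the reference metadata columns plus
#'   `distance` and `annotation`; zero rows when nothing is close enough.
#'   The full `cdr3_match` objects are in attribute `matches`.
#' @export
match_viral <- function(query, table, max_distance = 2L,
                        hla_filter = NULL) {
  stopifnot(inherits(table, "viral_cdr3_table"))
  if (nrow(table) == 0L) stop_fmt("viral table is empty")
  check_aa(query, "query")
  cand <- table
  if (!is.null(hla_filter)) {
    cand <- cand[cand$mhc_allele %in% hla_filter, , drop = FALSE]
  }
  if (nrow(cand) > 0L) {
    d <- vapply(cand$cdr3_aa, levenshtein, integer(1), a = query)
    cand$distance <- d
    cand <- cand[cand$distance <= max_distance, , drop = FALSE]
  }
  if (nrow(cand) == 0L) {
    out <- cand
    out$distance <- integer(0)
    out$annotation <- character(0)
    attr(out, "matches") <- list()
    return(out)
  }
  cand <- cand[order(cand$distance, cand$epitope, cand$cdr3_aa), ,
               drop = FALSE]
  matches <- lapply(seq_len(nrow(cand)), function(k) {
    m <- edit_align(query, cand$cdr3_aa[k])
    m$metadata <- as.list(cand[k, c("cdr3_aa", "epitope", "antigen",
                                    "species", "mhc_allele")])
    m
  })
  cand$annotation <- vapply(matches, function(m) m$annotation,
                            character(1))
  rownames(cand) <- NULL
  attr(cand, "matches") <- matches
  cand
}

#' Annotate a top-N clonotype list with public/private and viral matches
#'
#' Labels every entry of a top-N list public or private against a local
#' reference and attaches the best virus-specific CDR3 match (if any
#' within `max_distance`). The summary reports the public/private split
#' and the most abundant public and private clonotype of the sample.
#'
#' @param top A [top_n()] result.
#' @param reference A [public_reference()].
#' @param viral Optional `viral_cdr3_table`.
#' @param max_distance Maximum edit distance for viral matches.
#' @param min_subjects Passed to [classify_public()].
#' @param hla_filter Passed to [match_viral()].
#' @return A list of class `annotated_top` with `table` (the entries plus
#'   `status`, `viral_cdr3`, `viral_distance`, `viral_epitope`,
#'   `viral_antigen`, `viral_species`, `viral_mhc`, `viral_annotation`)
#'   and `summary` (list: `n_public`, `n_private`, `public_fraction`,
#'   `top_public`, `top_private` rows).
#' @export
annotate_top_clonotypes <- function(top, reference, viral = NULL,
                                    max_distance = 2L,
                                    min_subjects = 1L,
                                    hla_filter = NULL) {
  stopifnot(inherits(top, "top_n_list"))
  tab <- top$entries
  tab$status <- classify_public(tab$cdr3_aa, reference,
                                min_subjects = min_subjects)
  tab$viral_cdr3 <- NA_character_
  tab$viral_distance <- NA_integer_
  tab$viral_epitope <- NA_character_
  tab$viral_antigen <- NA_character_
  tab$viral_species <- NA_character_
  tab$viral_mhc <- NA_character_
  tab$viral_annotation <- NA_character_
  if (!is.null(viral) && nrow(viral) > 0L) {
    for (k in seq_len(nrow(tab))) {
      hits <- match_viral(tab$cdr3_aa[k], viral,
                          max_distance = max_distance,
                          hla_filter = hla_filter)
      if (nrow(hits) > 0L) {
        tab$viral_cdr3[k] <- hits$cdr3_aa[1]
        tab$viral_distance[k] <- hits$distance[1]
        tab$viral_epitope[k] <- hits$epitope[1]
        tab$viral_antigen[k] <- hits$antigen[1]
        tab$viral_species[k] <- hits$species[1]
        tab$viral_mhc[k] <- hits$mhc_allele[1]
        tab$viral_annotation[k] <- hits$annotation[1]
      }
    }
  }
  pick_top <- function(status) {
    sub <- tab[tab$status == status, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    sub[which.max(sub$frequency), , drop = FALSE]
  }
  n_pub <- sum(tab$status == "public")
  summary <- list(
    sample_id = top$meta$sample_id,
    n_public = n_pub,
    n_private = nrow(tab) - n_pub,
    public_fraction = n_pub / nrow(tab),
    top_public = pick_top("public"),
    top_private = pick_top("private")
  )
  structure(list(table = tab, summary = summary),
            class = "annotated_top")
}

#' @export
print.annotated_top <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Sample %s: %d public / %d private in top %d (%.0f%% public)\n",
    s$sample_id, s$n_public, s$n_private, nrow(x$table),
    100 * s$public_fraction))
  if (!is.null(s$top_public)) {
    cat(sprintf("  most abundant public:  %s (%.3f%%)\n",
                s$top_public$cdr3_aa, 100 * s$top_public$frequency))
  }
  if (!is.null(s$top_private)) {
    cat(sprintf("  most abundant private: %s (%.3f%%)\n",
                s$top_private$cdr3_aa, 100 * s$top_private$frequency))
  }
  invisible(x)
}
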