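#' Sample metadata for a TCR repertoire sample
#'
#' Describes one sequenced repertoire sample: which subject it came from,
#' whether it was resected brain tissue or peripheral blood, and a free-text
#' timepoint label (for example a surgery case ID when the same subject was
#' operated on twice).
#'
#' @param sample_id Unique sample identifier.
#' @param subject_id Subject (patient) identifier.
#' @param compartment Either `"brain"` or `"blood"`.
#' @param timepoint Timepoint label, e.g. `"surgery1"`. Defaults to `"t1"`.
#' @return An object of class `sample_meta`.
#' @export
#' @examples
#' sample_meta("s1_brain", "s1", "brain", "surgery1")
sample_meta <- function(sample_id, subject_id = sample_id,
                        compartment = c("brain", "blood"),
                        timepoint = "t1") {
  compartment <- match.arg(compartment)
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            nzchar(sample_id))
  structure(list(sample_id = sample_id, subject_id = subject_id,
                 compartment = compartment, timepoint = timepoint),
            class = "sample_meta")
}

#' @export
print.sample_meta <- function(x, ...) {
  cat(sprintf("<sample %s: subject %s, %s, %s>\n",
              x$sample_id, x$subject_id, x$compartment, x$timepoint))
  invisible(x)
}

# column maps for the two supported export dialects
.dialect_columns <- list(
  airr = c(cdr3_aa = "junction_aa", v_call = "v_call", j_call = "j_call",
           templates = "duplicate_count", productive = "productive"),
  immunoseq = c(cdr3_aa = "amino_acid", v_call = "v_gene", j_call = "j_gene",
                templates = "templates", productive = "frame_type")
)

#' Read TCR beta-chain rearrangements from a TSV export
#'
#' Parses either an AIRR Rearrangement TSV (AIRR Community schema column
#' names) or an immunoSEQ-style export into a uniform rearrangement table.
#' In the immunoSEQ dialect a `frame_type` of `"In"` maps to
#' `productive = TRUE`. Rows with a missing template count default to 1
#' (with a warning), since a sequenced rearrangement implies at least one
#' template molecule.
#'
#' @param path Path to the TSV file.
#' @param dialect `"airr"` (columns `junction_aa`, `v_call`, `j_call`,
#'   `duplicate_count`, `productive`) or `"immunoseq"` (columns
#'   `amino_acid`, `v_gene`, `j_gene`, `templates`, `frame_type`).
#' @return A data frame with columns `cdr3_aa`, `v_call`, `j_call`,
#'   `templates` (integer) and `productive` (logical), one row per
#'   rearrangement.
#' @export
read_rearrangements <- function(path, dialect = c("airr", "immunoseq")) {
  dialect <- match.arg(dialect)
  raw <- read_tsv_plain(path)
  cols <- .dialect_columns[[dialect]]
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols) > 0L) {
    stop_fmt("%s file %s is missing required column(s): %s",
             dialect, path, paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    cdr3_aa = toupper(trimws(as.character(raw[[cols[["cdr3_aa"]]]]))),
    v_call = as.character(raw[[cols[["v_call"]]]]),
    j_call = as.character(raw[[cols[["j_call"]]]]),
    templates = suppressWarnings(as.integer(raw[[cols[["templates"]]]])),
    stringsAsFactors = FALSE
  )
  out$cdr3_aa[is.na(out$cdr3_aa)] <- ""
  out$v_call[is.na(out$v_call)] <- ""
  out$j_call[is.na(out$j_call)] <- ""
  if (dialect == "airr") {
    prod_raw <- raw[[cols[["productive"]]]]
    out$productive <- tolower(as.character(prod_raw)) %in%
      c("true", "t", "yes", "y", "1")
  } else {
    out$productive <- as.character(raw[[cols[["productive"]]]]) == "In"
  }
  n_missing <- sum(is.na(out$templates))
  if (n_missing > 0L) {
    warning(sprintf("%d row(s) with missing template count set to 1",
                    n_missing), call. = FALSE)
    out$templates[is.na(out$templates)] <- 1L
  }
  if (any(out$templates < 0L)) {
    stop_fmt("negative template counts in %s", path)
  }
  out
}

#' Write rearrangements as an AIRR Rearrangement TSV
#'
#' @param records Rearrangement data frame as returned by
#'   [read_rearrangements()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_airr <- function(records, path) {
  stopifnot(all(c("cdr3_aa", "v_call", "j_call", "templates",
                  "productive") %in% names(records)))
  out <- data.frame(
    junction_aa = records$cdr3_aa,
    v_call = records$v_call,
    j_call = records$j_call,
    duplicate_count = as.integer(records$templates),
    productive = ifelse(records$productive, "TRUE", "FALSE"),
    stringsAsFactors = FALSE
  )
  write_tsv_plain(out, path)
}

#' Curate CDR3 rearrangements
#'
#' Removes rearrangements that cannot be CDR3 amino-acid clonotypes. The
#' central rule follows standard repertoire practice: a valid CDR3 junction
#' begins with the third framework cysteine (IMGT position 104), so any
#' junction not starting with `C` is discarded. In addition, empty
#' junctions, junctions containing a stop codon (`*`) or out-of-frame
#' marker (`_`), and non-productive rearrangements are removed; each
#' removal is tallied under the first matching reason.
#'
#' @param records Rearrangement data frame (see [read_rearrangements()]).
#' @return A list with elements `kept` (the retained rows) and `report`, a
#'   named integer vector of removal counts by reason
#'   (`empty_junction`, `stop_codon`, `out_of_frame`, `non_productive`,
#'   `no_framework_cysteine`). `nrow(kept) + sum(report)` always equals
#'   `nrow(records)`; curation is idempotent.
#' @export
#' @examples
#' recs <- data.frame(cdr3_aa = c("CASSQELTGLAGYTF", "ASSQELTGLAGYTF"),
#'                    v_call = "", j_call = "", templates = 1L,
#'                    productive = TRUE)
#' curate(recs)$report
curate <- function(records) {
  reasons <- c("empty_junction", "stop_codon", "out_of_frame",
               "non_productive", "no_framework_cysteine")
  report <- stats::setNames(integer(length(reasons)), reasons)
  if (is.null(records) || nrow(records) == 0L) {
    kept <- records[integer(0), , drop = FALSE]
    return(list(kept = kept, report = report))
  }
  cdr3 <- records$cdr3_aa
  reason <- rep(NA_character_, nrow(records))
  reason[!nzchar(cdr3)] <- "empty_junction"
  flag <- function(cond, r) is.na(reason) & cond
  idx <- flag(grepl("*", cdr3, fixed = TRUE), "stop_codon")
  reason[idx] <- "stop_codon"
  idx <- flag(grepl("_", cdr3, fixed = TRUE), "out_of_frame")
  reason[idx] <- "out_of_frame"
  idx <- flag(!records$productive, "non_productive")
  reason[idx] <- "non_productive"
  idx <- flag(substr(cdr3, 1L, 1L) != "C", "no_framework_cysteine")
  reason[idx] <- "no_framework_cysteine"
  tab <- table(factor(reason, levels = reasons))
  report[names(tab)] <- as.integer(tab)
  kept <- records[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, report = report)
}

#' Aggregate curated rearrangements into a clonotype table
#'
#' A clonotype is defined by its CDR3 amino-acid sequence alone; template
#' counts of all rearrangements sharing a CDR3 are summed and converted to
#' frequencies. V and J gene calls are carried as annotation from the
#' highest-count contributing rearrangement. By default frequencies are
#' template-weighted (templates approximate cell counts in the assay); set
#' `weighted = FALSE` to count each rearrangement once instead.
#'
#' @param records Curated rearrangement data frame.
#' @param meta A [sample_meta()] object.
#' @param weighted Weight clonotypes by template counts (default) or count
#'   each rearrangement row once.
#' @return An object of class `clonotype_table`: a list with `meta`, a
#'   `table` data frame (`cdr3_aa`, `v_call`, `j_call`, `templates`,
#'   `frequency`; rows sorted by descending templates, ties broken by
#'   CDR3), `total_templates` and `n_unique`.
#' @export
aggregate_clonotypes <- function(records, meta, weighted = TRUE) {
  stopifnot(inherits(meta, "sample_meta"))
  if (is.null(records) || nrow(records) == 0L) {
    stop_fmt("cannot aggregate an empty record set (sample %s)",
             meta$sample_id)
  }
  w <- if (weighted) as.numeric(records$templates) else
    rep(1, nrow(records))
  if (sum(w) <= 0) {
    stop_fmt("zero total templates in sample %s", meta$sample_id)
  }
  templates <- tapply(w, records$cdr3_aa, sum)
  # representative V/J from the highest-count contributing rearrangement
  ord <- order(-w, records$v_call, records$j_call)
  first <- !duplicated(records$cdr3_aa[ord])
  rep_rows <- records[ord, , drop = FALSE][first, , drop = FALSE]
  rep_v <- stats::setNames(rep_rows$v_call, rep_rows$cdr3_aa)
  rep_j <- stats::setNames(rep_rows$j_call, rep_rows$cdr3_aa)
  cdr3 <- names(templates)
  tab <- data.frame(
    cdr3_aa = cdr3,
    v_call = unname(rep_v[cdr3]),
    j_call = unname(rep_j[cdr3]),
    templates = as.numeric(templates),
    stringsAsFactors = FALSE
  )
  total <- sum(tab$templates)
  tab$frequency <- tab$templates / total
  tab <- tab[order(-tab$templates, tab$cdr3_aa), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(meta = meta, table = tab,
                 total_templates = total, n_unique = nrow(tab)),
            class = "clonotype_table")
}

#' @export
print.clonotype_table <- function(x, n = 6L, ...) {
  cat(sprintf(
    "Clonotype table: sample %s (%s, subject %s, %s)\n",
    x$meta$sample_id, x$meta$compartment, x$meta$subject_id,
    x$meta$timepoint))
  cat(sprintf("  %d unique CDR3 clonotypes, %s templates\n",
              x$n_unique, format(x$total_templates, big.mark = ",")))
  print(utils::head(x$table, n))
  if (x$n_unique > n) cat(sprintf("  ... %d more rows\n", x$n_unique - n))
  invisible(x)
}

#' Write a clonotype table to TSV
#'
#' @param x A `clonotype_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_clonotype_table <- function(x, path) {
  stopifnot(inherits(x, "clonotype_table"))
  write_tsv_plain(x$table[, c("cdr3_aa", "v_call", "j_call",
                              "templates", "frequency")], path)
}

#' Read a clonotype table written by [write_clonotype_table()]
#'
#' Frequencies are recomputed from the template counts on read-back so the
#' sum-to-one invariant holds exactly.
#'
#' @param path TSV path.
#' @param meta A [sample_meta()] for the sample.
#' @return A `clonotype_table`.
#' @export
read_clonotype_table <- function(path, meta) {
  stopifnot(inherits(meta, "sample_meta"))
  tab <- read_tsv_plain(path)
  need <- c("cdr3_aa", "v_call", "j_call", "templates")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop_fmt("clonotype TSV %s is missing column(s): %s", path,
             paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0L) stop_fmt("clonotype TSV %s has no rows", path)
  tab$v_call <- as.character(tab$v_call)
  tab$j_call <- as.character(tab$j_call)
  tab$v_call[is.na(tab$v_call)] <- ""
  tab$j_call[is.na(tab$j_call)] <- ""
  total <- sum(tab$templates)
  if (total <= 0) stop_fmt("zero total templates in %s", path)
  tab$frequency <- tab$templates / total
  tab <- tab[order(-tab$templates, tab$cdr3_aa),
             c("cdr3_aa", "v_call", "j_call", "templates", "frequency")]
  rownames(tab) <- NULL
  structure(list(meta = meta, table = tab, total_templates = total,
                 n_unique = nrow(tab)),
            class = "clonotype_table")
}
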