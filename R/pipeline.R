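#' Run the full repertoire study pipeline
#'
#' Orchestrates the analysis end to end from a configuration: read and
#' curate every sample, aggregate clonotypes, compute per-sample
#' clonality and the paired brain-vs-blood signed-rank comparison,
#' extract top-N lists, classify public/private and match virus-specific
#' CDR3s (when reference databases are configured), test clonotype
#' frequency changes between compartments and across timepoints, count
#' top-N overlaps per subject, and (when an expression matrix is
#' configured) run the immune-signature stage. All outputs are written
#' as TSV plus one machine-readable JSON summary; re-running on
#' identical inputs is byte-identical. Reference-database checksums,
#' parameters and the seed are recorded in the run log.
#'
#' @param config Named list (or path to a YAML file) with fields:
#'   `samples` -- list of per-sample entries, each with `path`,
#'   `sample_id`, `subject_id`, `compartment` (`brain`/`blood`),
#'   `timepoint`; `dialect` (`airr`/`immunoseq`, default `airr`);
#'   optional `public_db`, `viral_db`, `expression`, `markers` paths;
#'   `top_n` (default 50), `alpha` (default 0.05), `max_distance`
#'   (default 2), `k_clusters` (default 3), `seed` (default 1),
#'   and `out_dir` (required).
#' @return An object of class `study_report` (list of result tables),
#'   invisibly; side effect: report files under `out_dir`.
#' @export
run_study <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_fmt("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_add <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  log_add("run_study: %d samples, dialect=%s, top_n=%d, alpha=%g, seed=%d",
          length(cfg$samples), cfg$dialect, cfg$top_n, cfg$alpha, cfg$seed)
  for (db in c("public_db", "viral_db", "expression", "markers")) {
    if (!is.null(cfg[[db]])) {
      log_add("%s: %s md5=%s", db, cfg[[db]],
              unname(tools::md5sum(cfg[[db]])))
    }
  }
  set.seed(cfg$seed)

  stage <- function(what, sample_id, expr) {
    tryCatch(expr, error = function(e) {
      stop_fmt("stage '%s' failed for sample '%s': %s", what, sample_id,
               conditionMessage(e))
    })
  }

  # --- ingest -------------------------------------------------------
  tables <- list()
  curation <- list()
  for (s in cfg$samples) {
    meta <- sample_meta(s$sample_id, s$subject_id, s$compartment,
                        s$timepoint)
    recs <- stage("read", s$sample_id,
                  read_rearrangements(s$path, dialect = cfg$dialect))
    cur <- stage("curate", s$sample_id, curate(recs))
    curation[[s$sample_id]] <- cur$report
    tables[[s$sample_id]] <- stage(
      "aggregate", s$sample_id,
      aggregate_clonotypes(cur$kept, meta))
    log_add("sample %s: %d records, %d removed, %d clonotypes",
            s$sample_id, nrow(recs), sum(cur$report),
            tables[[s$sample_id]]$n_unique)
  }
  curation_df <- data.frame(
    sample_id = names(curation),
    do.call(rbind, curation),
    stringsAsFactors = FALSE, row.names = NULL)

  # --- clonality ----------------------------------------------------
  clonality_df <- do.call(rbind, lapply(tables, function(tab) {
    cr <- clonality_index(tab)
    data.frame(sample_id = tab$meta$sample_id,
               subject_id = tab$meta$subject_id,
               compartment = tab$meta$compartment,
               timepoint = tab$meta$timepoint,
               n_unique = cr$n_unique,
               total_templates = tab$total_templates,
               H = cr$H, H_max = cr$H_max, H_norm = cr$H_norm,
               clonality = cr$clonality,
               stringsAsFactors = FALSE)
  }))
  rownames(clonality_df) <- NULL
  paired <- paired_clonality_test(clonality_df)
  if (!is.null(paired)) {
    log_add("paired brain vs blood clonality: V=%g, p=%.6g (%d pairs)",
            unname(paired$statistic), paired$p.value, paired$n_effective)
  }

  # --- top-N + annotation ------------------------------------------
  tops <- lapply(tables, top_n, n = cfg$top_n)
  top_df <- do.call(rbind, lapply(tops, function(tp) {
    cbind(sample_id = tp$meta$sample_id, tp$entries,
          stringsAsFactors = FALSE)
  }))
  rownames(top_df) <- NULL
  pub <- if (!is.null(cfg$public_db)) read_public_reference(cfg$public_db)
  viral <- if (!is.null(cfg$viral_db)) read_viral_table(cfg$viral_db)
  annotations <- NULL
  annotation_summary <- NULL
  if (!is.null(pub)) {
    ann <- lapply(tops, annotate_top_clonotypes, reference = pub,
                  viral = viral, max_distance = cfg$max_distance)
    annotations <- do.call(rbind, lapply(ann, function(a) {
      cbind(sample_id = a$summary$sample_id, a$table,
            stringsAsFactors = FALSE)
    }))
    rownames(annotations) <- NULL
    annotation_summary <- do.call(rbind, lapply(ann, function(a) {
      s <- a$summary
      data.frame(sample_id = s$sample_id, n_public = s$n_public,
                 n_private = s$n_private,
                 public_fraction = s$public_fraction,
                 top_public = if (is.null(s$top_public)) NA_character_
                              else s$top_public$cdr3_aa,
                 top_private = if (is.null(s$top_private)) NA_character_
                               else s$top_private$cdr3_aa,
                 stringsAsFactors = FALSE)
    }))
    rownames(annotation_summary) <- NULL
  }

  # --- tracking + overlaps -----------------------------------------
  pairs <- tracking_pairs(tables)
  tracking <- list()
  for (p in pairs) {
    cmp <- track(tables[[p$a]], tables[[p$b]], alpha = cfg$alpha,
                 n_top = cfg$top_n)
    if (nrow(cmp) > 0L) {
      tracking[[p$label]] <- cbind(comparison = p$label,
                                   sample_a = p$a, sample_b = p$b,
                                   cmp, stringsAsFactors = FALSE)
    }
  }
  tracking_df <- if (length(tracking) > 0L)
    do.call(rbind, tracking) else NULL
  if (!is.null(tracking_df)) rownames(tracking_df) <- NULL

  overlaps <- overlap_by_subject(tops)

  # --- expression signature ----------------------------------------
  signature <- NULL
  if (!is.null(cfg$expression)) {
    mat <- read_expression_matrix(cfg$expression, scale = "linear")
    mat <- log2_transform(mat)
    cl <- pca_cluster(mat, k = cfg$k_clusters)
    markers <- select_markers(mat, cl, target = cfg$k_clusters,
                              alpha = cfg$marker_alpha)
    z <- modified_z(mat)
    corr <- NULL
    if (!is.null(cfg$markers)) {
      ms <- read_marker_set(cfg$markers)
      tg <- names(ms)[ms == "tcell"]
      mg <- names(ms)[ms == "microglia"]
      if (length(intersect(tg, rownames(mat))) > 0L &&
          length(intersect(mg, rownames(mat))) > 0L) {
        sc <- signature_correlation(mat, tg, mg)
        corr <- data.frame(set_a = "tcell", set_b = "microglia",
                           r = sc$r, p = sc$p, n = sc$n,
                           stringsAsFactors = FALSE)
      }
    }
    signature <- list(
      clusters = data.frame(sample_id = names(cl$labels),
                            cluster = unname(cl$labels),
                            stringsAsFactors = FALSE),
      markers = markers, zscores = z, correlation = corr,
      n_pcs = cl$n_pcs)
    log_add("signature: %d samples in %d clusters (%d PCs), %d markers",
            length(cl$labels), cfg$k_clusters, cl$n_pcs, nrow(markers))
  }

  report <- structure(list(
    clonality = clonality_df,
    paired_clonality = paired,
    curation = curation_df,
    top_clonotypes = top_df,
    annotations = annotations,
    annotation_summary = annotation_summary,
    tracking = tracking_df,
    overlaps = overlaps,
    signature = signature,
    config = cfg
  ), class = "study_report")
  write_report(report, cfg$out_dir, log_lines)
  invisible(report)
}

validate_config <- function(config) {
  if (is.null(config$samples) || length(config$samples) == 0L) {
    stop_fmt("config must list at least one sample")
  }
  if (is.null(config$out_dir)) stop_fmt("config must set out_dir")
  cfg <- list(
    samples = config$samples,
    dialect = config$dialect %||% "airr",
    public_db = config$public_db,
    viral_db = config$viral_db,
    expression = config$expression,
    markers = config$markers,
    top_n = as.integer(config$top_n %||% 50L),
    alpha = config$alpha %||% 0.05,
    marker_alpha = config$marker_alpha %||% 1e-4,
    max_distance = as.integer(config$max_distance %||% 2L),
    k_clusters = as.integer(config$k_clusters %||% 3L),
    seed = as.integer(config$seed %||% 1L),
    out_dir = config$out_dir
  )
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop_fmt("alpha must be in (0,1)")
  ids <- vapply(cfg$samples, function(s) s$sample_id %||% "",
                character(1))
  if (any(!nzchar(ids)) || anyDuplicated(ids)) {
    stop_fmt("sample_id must be present and unique for every sample")
  }
  for (s in cfg$samples) {
    if (is.null(s$path) || !file.exists(s$path)) {
      stop_fmt("sample %s: input file not found: %s", s$sample_id,
               s$path %||% "<missing>")
    }
  }
  for (db in c("public_db", "viral_db", "expression", "markers")) {
    if (!is.null(cfg[[db]]) && !file.exists(cfg[[db]])) {
      stop_fmt("%s file not found: %s", db, cfg[[db]])
    }
  }
  cfg$samples <- lapply(cfg$samples, function(s) {
    list(path = s$path, sample_id = s$sample_id,
         subject_id = s$subject_id %||% s$sample_id,
         compartment = s$compartment %||% "brain",
         timepoint = s$timepoint %||% "t1")
  })
  cfg
}

# paired brain/blood clonality per subject+timepoint, when >= 2 complete
# pairs exist
paired_clonality_test <- function(clonality_df) {
  key <- paste(clonality_df$subject_id, clonality_df$timepoint)
  brain <- clonality_df[clonality_df$compartment == "brain", ]
  blood <- clonality_df[clonality_df$compartment == "blood", ]
  bk <- paste(brain$subject_id, brain$timepoint)
  lk <- paste(blood$subject_id, blood$timepoint)
  common <- intersect(bk, lk)
  if (length(common) < 2L) return(NULL)
  a <- brain$clonality[match(common, bk)]
  b <- blood$clonality[match(common, lk)]
  if (all(a == b)) return(NULL)
  paired_signed_rank(a, b)
}

tracking_pairs <- function(tables) {
  meta <- lapply(tables, function(t) t$meta)
  ids <- names(tables)
  pairs <- list()
  subjects <- unique(vapply(meta, function(m) m$subject_id, character(1)))
  for (subj in subjects) {
    mine <- ids[vapply(meta, function(m) m$subject_id == subj,
                       logical(1))]
    comp <- vapply(meta[mine], function(m) m$compartment, character(1))
    tp <- vapply(meta[mine], function(m) m$timepoint, character(1))
    # brain vs blood at each timepoint
    for (t in unique(tp)) {
      a <- mine[comp == "brain" & tp == t]
      b <- mine[comp == "blood" & tp == t]
      if (length(a) == 1L && length(b) == 1L) {
        pairs[[length(pairs) + 1L]] <- list(
          a = b, b = a,
          label = sprintf("%s_blood_vs_brain_%s", subj, t))
      }
    }
    # longitudinal within each compartment
    for (cc in unique(comp)) {
      have <- mine[comp == cc]
      tps <- sort(tp[comp == cc])
      if (length(have) == 2L) {
        o <- order(tp[comp == cc])
        pairs[[length(pairs) + 1L]] <- list(
          a = have[o[1]], b = have[o[2]],
          label = sprintf("%s_%s_%s_vs_%s", subj, cc, tps[1], tps[2]))
      }
    }
  }
  pairs
}

overlap_by_subject <- function(tops) {
  meta <- lapply(tops, function(t) t$meta)
  subjects <- unique(vapply(meta, function(m) m$subject_id, character(1)))
  out <- list()
  for (subj in subjects) {
    mine <- names(tops)[vapply(meta, function(m) m$subject_id == subj,
                               logical(1))]
    if (length(mine) < 2L || length(mine) > 4L) next
    sets <- lapply(tops[mine], function(t) t$entries$cdr3_aa)
    names(sets) <- mine
    ov <- overlap(sets)
    out[[subj]] <- data.frame(subject_id = subj,
                              region = ov$region, count = ov$count,
                              stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

write_report <- function(report, out_dir, log_lines) {
  wt <- function(df, name) {
    if (!is.null(df)) write_tsv_plain(df, file.path(out_dir, name))
  }
  wt(report$clonality, "clonality.tsv")
  wt(report$curation, "curation_report.tsv")
  wt(report$top_clonotypes, "top_clonotypes.tsv")
  wt(report$annotations, "top_annotations.tsv")
  wt(report$annotation_summary, "public_private_summary.tsv")
  wt(report$tracking, "tracking.tsv")
  wt(report$overlaps, "overlaps.tsv")
  if (!is.null(report$signature)) {
    wt(report$signature$clusters, "signature_clusters.tsv")
    wt(report$signature$markers, "signature_markers.tsv")
    wt(report$signature$correlation, "signature_correlation.tsv")
    z <- report$signature$zscores
    wt(data.frame(gene = rownames(z), z, check.names = FALSE),
       "signature_zscores.tsv")
  }
  summary <- list(
    n_samples = length(report$config$samples),
    clonality = report$clonality,
    paired_clonality = if (!is.null(report$paired_clonality)) list(
      statistic = unname(report$paired_clonality$statistic),
      p = report$paired_clonality$p.value,
      n_effective = report$paired_clonality$n_effective),
    public_private = report$annotation_summary,
    tracking_direction_counts = if (!is.null(report$tracking))
      as.list(table(report$tracking$direction)),
    overlaps = report$overlaps,
    signature_correlation = report$signature$correlation
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(NULL)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d samples\n", nrow(x$clonality)))
  cat("Clonality:\n")
  print(x$clonality[, c("sample_id", "compartment", "timepoint",
                        "n_unique", "clonality")])
  if (!is.null(x$paired_clonality)) {
    cat(sprintf("Paired brain vs blood clonality: p = %.4g\n",
                x$paired_clonality$p.value))
  }
  if (!is.null(x$tracking)) {
    cat("Tracking direction calls:\n")
    print(table(x$tracking$comparison, x$tracking$direction))
  }
  invisible(x)
}
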