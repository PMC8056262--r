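#' Simulation parameters for a synthetic TCR repertoire study
#'
#' Collects the knobs of the repertoire generator: the background
#' clone-size law, planted expanded clones, a public-sequence pool,
#' compartment-specific (brain) enrichment, longitudinal fold changes and
#' sequencing depth. Defaults emulate the regime observed in bulk TCRbeta
#' sequencing of inflamed tissue: a near-power-law background (Zipf
#' exponent just above 1) with a handful of expanded clones, so top-50
#' repertoire fractions span roughly 5--70% across settings.
#'
#' @param seed Integer seed driving all randomness of the subject.
#' @param n_background_clones Number of background clones.
#' @param clone_size_law List: `list(law = "zipf", s = 1.05)` or
#'   `list(law = "lognormal", mu = 0, sigma = 1)`.
#' @param n_expanded Number of planted expanded clones.
#' @param expanded_mass Total frequency mass of the expanded clones
#'   (in \[0, 1); split equally among them).
#' @param public_pool_size Size of the public-sequence pool.
#' @param public_spike_rate Fraction of clones whose CDR3 is drawn from
#'   the public pool.
#' @param n_brain_enriched Number of clones enriched in the brain
#'   compartment.
#' @param brain_enrichment Fold (>= 1) applied to those clones' masses in
#'   brain before renormalization.
#' @param longitudinal_folds Numeric vector of fold changes (> 0) applied
#'   at timepoint 2 to randomly chosen distinct clones, or a named vector
#'   keyed by CDR3 once sequences exist; `NULL` for a single timepoint.
#' @param n_timepoints 1 or 2.
#' @param depth Sequencing templates per sample.
#' @param cdr3_length_range Length range of simulated CDR3s.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_background_clones = 10000L,
                       clone_size_law = list(law = "zipf", s = 1.05),
                       n_expanded = 5L,
                       expanded_mass = 0.1,
                       public_pool_size = 500L,
                       public_spike_rate = 0.1,
                       n_brain_enriched = 20L,
                       brain_enrichment = 5,
                       longitudinal_folds = NULL,
                       n_timepoints = 1L,
                       depth = 1e5,
                       cdr3_length_range = c(8L, 16L)) {
  p <- list(seed = as.integer(seed),
            n_background_clones = as.integer(n_background_clones),
            clone_size_law = clone_size_law,
            n_expanded = as.integer(n_expanded),
            expanded_mass = expanded_mass,
            public_pool_size = as.integer(public_pool_size),
            public_spike_rate = public_spike_rate,
            n_brain_enriched = as.integer(n_brain_enriched),
            brain_enrichment = brain_enrichment,
            longitudinal_folds = longitudinal_folds,
            n_timepoints = as.integer(n_timepoints),
            depth = depth,
            cdr3_length_range = as.integer(cdr3_length_range))
  if (p$expanded_mass < 0 || p$expanded_mass >= 1) {
    stop_fmt("expanded_mass must be in [0, 1)")
  }
  if (p$public_spike_rate < 0 || p$public_spike_rate > 1) {
    stop_fmt("public_spike_rate must be in [0, 1]")
  }
  if (p$brain_enrichment < 1) stop_fmt("brain_enrichment must be >= 1")
  if (p$depth < 1) stop_fmt("depth must be >= 1")
  if (!is.null(p$longitudinal_folds) && any(p$longitudinal_folds <= 0)) {
    stop_fmt("longitudinal folds must be > 0")
  }
  if (!p$n_timepoints %in% c(1L, 2L)) {
    stop_fmt("n_timepoints must be 1 or 2")
  }
  if (p$n_expanded > 0L && p$expanded_mass > 0 &&
      p$n_expanded > p$n_background_clones) {
    stop_fmt("n_expanded exceeds the number of clones")
  }
  structure(p, class = "sim_params")
}

#' Simulate CDR3 amino-acid sequences
#'
#' Sequences are a framework cysteine `C`, random residues from the
#' 20-letter alphabet, and a terminal `F` (the canonical junction
#' boundary), with uniform lengths over `length_range`; every simulated
#' sequence passes [curate()] by construction.
#'
#' @param n Number of sequences (not necessarily distinct).
#' @param length_range Integer range of total CDR3 length (min 3).
#' @return Character vector of length `n`.
#' @export
simulate_cdr3 <- function(n, length_range = c(8L, 16L)) {
  if (length_range[1] < 3L || length_range[2] < length_range[1]) {
    stop_fmt("invalid CDR3 length range")
  }
  lens <- sample(seq(length_range[1], length_range[2]), n,
                 replace = TRUE)
  vapply(lens, function(L) {
    paste0("C", paste(sample(AA_ALPHABET, L - 2L, replace = TRUE),
                      collapse = ""), "F")
  }, character(1))
}

simulate_unique_cdr3 <- function(n, length_range) {
  out <- unique(simulate_cdr3(ceiling(n * 1.2) + 10L, length_range))
  while (length(out) < n) {
    out <- unique(c(out, simulate_cdr3(n, length_range)))
  }
  out[seq_len(n)]
}

# TRBV/TRBJ-style gene labels for simulated rearrangements
simulate_gene_calls <- function(n) {
  list(v = sprintf("TRBV%02d-1", sample(1:30, n, replace = TRUE)),
       j = sprintf("TRBJ%d-%d", sample(1:2, n, replace = TRUE),
                   sample(1:7, n, replace = TRUE)))
}

clone_masses <- function(law, n) {
  if (law$law == "zipf") {
    w <- seq_len(n)^(-law$s)
  } else if (law$law == "lognormal") {
    w <- stats::rlnorm(n, meanlog = law$mu, sdlog = law$sigma)
  } else {
    stop_fmt("unknown clone size law: %s", law$law)
  }
  w / sum(w)
}

#' Simulate a paired brain/blood subject with ground truth
#'
#' Generates one subject's TCRbeta repertoire: background clone masses
#' from the configured size law, planted expanded clones carrying
#' `expanded_mass`, public-pool sequences injected at
#' `public_spike_rate`, brain-compartment enrichment of selected clones,
#' an optional second timepoint with longitudinal fold changes, and a
#' multinomial template draw of `depth` per sample. All randomness is
#' driven by `params$seed`, so identical parameters give identical
#' output (including byte-identical AIRR files via [write_airr()]).
#'
#' @param params A [sim_params()] object.
#' @param dir Optional directory; when given, each sample is written as
#'   an AIRR TSV named `<sample_id>.tsv`.
#' @return List of class `sim_subject`:
#'   `samples` -- named list of rearrangement data frames (names like
#'   `brain_t1`, `blood_t1`, ...);
#'   `meta` -- named list of matching [sample_meta()] objects;
#'   `masses` -- per-compartment/timepoint true frequency vectors;
#'   `truth` -- data frame per clone (`cdr3_aa`, `base_mass`,
#'   `is_public`, `is_expanded`, `brain_enriched`, `longitudinal_fold`)
#'   plus the `public_pool` and `params`.
#' @export
simulate_subject <- function(params = sim_params(), dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_background_clones
  pool <- simulate_unique_cdr3(params$public_pool_size,
                               params$cdr3_length_range)
  # background sequences: unique and disjoint from the public pool, so
  # spiking pool draws (without replacement) keeps the repertoire unique
  cdr3 <- simulate_unique_cdr3(n + length(pool),
                               params$cdr3_length_range)
  cdr3 <- setdiff(cdr3, pool)
  while (length(cdr3) < n) {
    cdr3 <- setdiff(unique(c(cdr3, simulate_cdr3(n, params$cdr3_length_range))),
                    pool)
  }
  cdr3 <- cdr3[seq_len(n)]
  n_public <- min(round(params$public_spike_rate * n), length(pool))
  is_public <- rep(FALSE, n)
  if (n_public > 0L) {
    take <- sample(n, n_public)
    cdr3[take] <- sample(pool, n_public)
    is_public[take] <- TRUE
  }
  mass <- clone_masses(params$clone_size_law, n)
  mass <- sample(mass)  # random assignment of sizes to sequences
  is_expanded <- rep(FALSE, n)
  if (params$n_expanded > 0L && params$expanded_mass > 0) {
    idx <- sample(n, params$n_expanded)
    is_expanded[idx] <- TRUE
    mass[!is_expanded] <- mass[!is_expanded] /
      sum(mass[!is_expanded]) * (1 - params$expanded_mass)
    mass[idx] <- params$expanded_mass / params$n_expanded
  }
  brain_enriched <- rep(FALSE, n)
  if (params$n_brain_enriched > 0L && params$brain_enrichment > 1) {
    brain_enriched[sample(n, params$n_brain_enriched)] <- TRUE
  }
  blood_mass <- mass
  brain_mass <- mass
  brain_mass[brain_enriched] <- brain_mass[brain_enriched] *
    params$brain_enrichment
  brain_mass <- brain_mass / sum(brain_mass)
  folds <- rep(1, n)
  if (params$n_timepoints == 2L && !is.null(params$longitudinal_folds)) {
    lf <- params$longitudinal_folds
    if (!is.null(names(lf)) && all(nzchar(names(lf)))) {
      hit <- match(names(lf), cdr3)
      if (anyNA(hit)) stop_fmt("longitudinal fold names not in repertoire")
      folds[hit] <- unname(lf)
    } else {
      # unnamed folds are planted on established clones (expected count
      # >= 20 at the configured depth): longitudinal tracking follows
      # clones from top-N universes, i.e. clones large enough to be
      # observed at both timepoints
      eligible <- which(mass >= 20 / params$depth & !is_expanded)
      if (length(eligible) < length(lf)) {
        stop_fmt("fewer than %d clones large enough to plant folds on",
                 length(lf))
      }
      idx <- sample(eligible, length(lf))
      folds[idx] <- lf
    }
  }
  masses <- list(brain_t1 = brain_mass, blood_t1 = blood_mass)
  if (params$n_timepoints == 2L) {
    masses$brain_t2 <- brain_mass * folds / sum(brain_mass * folds)
    masses$blood_t2 <- blood_mass * folds / sum(blood_mass * folds)
  }
  genes <- simulate_gene_calls(n)
  subject_id <- sprintf("sim%03d", params$seed %% 1000L)
  samples <- list()
  meta <- list()
  for (nm in names(masses)) {
    counts <- as.vector(stats::rmultinom(1, size = params$depth,
                                         prob = masses[[nm]]))
    keep <- counts > 0L
    samples[[nm]] <- data.frame(
      cdr3_aa = cdr3[keep],
      v_call = genes$v[keep],
      j_call = genes$j[keep],
      templates = counts[keep],
      productive = TRUE,
      stringsAsFactors = FALSE
    )
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    meta[[nm]] <- sample_meta(
      sample_id = paste(subject_id, nm, sep = "_"),
      subject_id = subject_id,
      compartment = parts[1],
      timepoint = parts[2]
    )
  }
  truth <- data.frame(cdr3_aa = cdr3, base_mass = mass,
                      is_public = is_public,
                      is_expanded = is_expanded,
                      brain_enriched = brain_enriched,
                      longitudinal_fold = folds,
                      stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(samples)) {
      write_airr(samples[[nm]],
                 file.path(dir, paste0(meta[[nm]]$sample_id, ".tsv")))
    }
  }
  structure(list(samples = samples, meta = meta, masses = masses,
                 truth = truth, public_pool = pool, params = params),
            class = "sim_subject")
}

#' Simulate local public and virus-specific reference databases
#'
#' Builds the two reference tables the matching stage consumes, with
#' ground truth: the public reference contains exactly the subject's
#' public pool (each with a subject count >= 2) plus decoy sequences not
#' in the repertoire; the viral table contains rows derived from chosen
#' repertoire clones by 0--2 point edits (annotated with epitope, source
#' antigen, virus and restricting HLA allele drawn from a small catalog
#' of immunodominant epitopes) plus unrelated random rows.
#'
#' @param subject A [simulate_subject()] result.
#' @param n_decoys Decoy sequences added to the public reference.
#' @param n_viral_derived Number of viral rows derived from repertoire
#'   clones (the most abundant clones are used, so top lists hit them).
#' @param viral_edits Integer vector recycled over the derived rows:
#'   number of point substitutions applied to each (0 means an exact
#'   match is planted).
#' @param n_viral_unrelated Unrelated random viral rows.
#' @param seed Seed for this generator (independent of the subject's).
#' @return List with `public` (a [public_reference()]), `viral` (a
#'   `viral_cdr3_table`) and `truth` (data frame mapping each derived
#'   viral row to its source clone and planted edit count).
#' @export
simulate_reference_dbs <- function(subject, n_decoys = 100L,
                                   n_viral_derived = 5L,
                                   viral_edits = c(0L, 1L, 1L, 2L, 2L),
                                   n_viral_unrelated = 15L,
                                   seed = subject$params$seed + 1000L) {
  stopifnot(inherits(subject, "sim_subject"))
  set.seed(seed)
  lr <- subject$params$cdr3_length_range
  repertoire <- subject$truth$cdr3_aa
  decoys <- setdiff(simulate_unique_cdr3(n_decoys + 50L, lr), repertoire)
  decoys <- utils::head(decoys, n_decoys)
  pub <- public_reference(
    c(subject$public_pool, decoys),
    c(2L + stats::rpois(length(subject$public_pool), 20),
      1L + stats::rpois(length(decoys), 5)),
    source_label = "simulated public reference"
  )
  epitope_catalog <- data.frame(
    epitope = c("KLGGALQAK", "NLVPMVATV", "TPRVTGGGAM", "GLCTLVAML",
                "GILGFVFTL"),
    antigen = c("IE1", "pp65", "pp65", "BMLF1", "M"),
    species = c("HCMV", "HCMV", "HCMV", "EBV", "InfluenzaA"),
    mhc_allele = c("HLA-A*03", "HLA-A*02", "HLA-B*07", "HLA-A*02",
                   "HLA-A*02"),
    stringsAsFactors = FALSE
  )
  # derive viral rows from the subject's most abundant true clones
  ord <- order(-subject$truth$base_mass)
  src_idx <- ord[seq_len(min(n_viral_derived, length(ord)))]
  edits <- rep_len(as.integer(viral_edits), length(src_idx))
  derived <- character(length(src_idx))
  for (k in seq_along(src_idx)) {
    derived[k] <- mutate_cdr3(repertoire[src_idx[k]], edits[k])
  }
  cat_rows <- sample(nrow(epitope_catalog), length(src_idx),
                     replace = TRUE)
  unrelated <- setdiff(simulate_unique_cdr3(n_viral_unrelated + 50L, lr),
                       c(repertoire, derived))
  unrelated <- utils::head(unrelated, n_viral_unrelated)
  un_rows <- sample(nrow(epitope_catalog), length(unrelated),
                    replace = TRUE)
  viral <- viral_cdr3_table(data.frame(
    cdr3_aa = c(derived, unrelated),
    epitope = epitope_catalog$epitope[c(cat_rows, un_rows)],
    antigen = epitope_catalog$antigen[c(cat_rows, un_rows)],
    species = epitope_catalog$species[c(cat_rows, un_rows)],
    mhc_allele = epitope_catalog$mhc_allele[c(cat_rows, un_rows)],
    stringsAsFactors = FALSE
  ))
  truth <- data.frame(viral_cdr3 = derived,
                      source_cdr3 = repertoire[src_idx],
                      planted_edits = edits,
                      stringsAsFactors = FALSE)
  list(public = pub, viral = viral, truth = truth)
}

# apply k point substitutions at distinct interior positions (anchoring
# the framework C and terminal F), so the edit distance is exactly k for
# k <= interior length
mutate_cdr3 <- function(x, k) {
  if (k == 0L) return(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  interior <- 2:(length(ch) - 1L)
  pos <- sample(interior, min(k, length(interior)))
  for (p in pos) {
    ch[p] <- sample(setdiff(AA_ALPHABET, ch[p]), 1)
  }
  paste(ch, collapse = "")
}

#' Simulate a cell-type-mixture expression matrix
#'
#' Emulates an immune-infiltration gradient across tissue samples:
#' `value(g, s) = baseline(g) + load(g) * infiltration(s) + noise`,
#' where only T-cell / microglia / macrophage marker genes carry a
#' positive load. Samples are split evenly over the infiltration levels,
#' which define the planted cluster labels; because the T-cell and
#' microglia sets share the infiltration factor, their signature scores
#' are positively correlated by construction.
#'
#' @param n_samples Number of samples (default 53, a typical surgical
#'   cohort size for this kind of panel study).
#' @param n_genes Total genes including non-markers (default 577, a
#'   typical immunology panel size).
#' @param marker_counts Named integer vector: markers per cell class.
#' @param infiltration_levels Numeric levels (log2-expression units), one
#'   per planted cluster, ordered low to high; with the default
#'   `noise_sd = 1` the defaults give a 3-SD separation between
#'   neighbouring groups.
#' @param load Mean marker loading on the infiltration factor.
#' @param noise_sd Residual noise SD.
#' @param seed Seed.
#' @return List: `matrix` (log2-scale [expression_matrix()]), `truth`
#'   (list with per-sample `cluster` and `infiltration`, per-gene
#'   `gene_class` and `load`).
#' @export
simulate_expression <- function(n_samples = 53L, n_genes = 577L,
                                marker_counts = c(tcell = 60L,
                                                  microglia = 60L,
                                                  macrophage = 55L),
                                infiltration_levels = c(0, 3, 6),
                                load = 1,
                                noise_sd = 1,
                                seed = 1L) {
  set.seed(seed)
  if (length(infiltration_levels) < 2L) {
    stop_fmt("need at least two infiltration levels")
  }
  n_markers <- sum(marker_counts)
  if (n_markers > n_genes) stop_fmt("more markers than genes")
  classes <- c(rep(names(marker_counts), marker_counts),
               rep("unassigned", n_genes - n_markers))
  genes <- sprintf("G%04d", seq_len(n_genes))
  loads <- ifelse(classes == "unassigned", 0,
                  stats::runif(n_genes, 0.5 * load, 1.5 * load))
  baseline <- stats::runif(n_genes, 4, 10)
  k <- length(infiltration_levels)
  cluster <- sort(rep_len(seq_len(k), n_samples))
  infiltration <- infiltration_levels[cluster]
  values <- baseline + outer(loads, infiltration) +
    matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
           n_genes, n_samples)
  samples <- sprintf("S%03d", seq_len(n_samples))
  mat <- expression_matrix(values, genes = genes, samples = samples,
                           scale = "log2")
  list(matrix = mat,
       truth = list(cluster = stats::setNames(cluster, samples),
                    infiltration = stats::setNames(infiltration, samples),
                    gene_class = stats::setNames(classes, genes),
                    load = stats::setNames(loads, genes)))
}
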