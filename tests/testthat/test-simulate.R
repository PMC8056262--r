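test_that("simulated CDR3s are curation-valid by construction", {
  set.seed(0)
  seqs <- simulate_cdr3(10000)
  expect_true(all(substr(seqs, 1, 1) == "C"))
  expect_true(all(substr(seqs, nchar(seqs), nchar(seqs)) == "F"))
  recs <- make_records(seqs)
  expect_equal(nrow(curate(recs)$kept), length(seqs))

  lens <- nchar(seqs)
  expect_true(all(lens >= 8 & lens <= 16))
  gof <- chisq.test(table(factor(lens, levels = 8:16)))
  expect_gt(gof$p.value, 0.01)   # uniform over the configured range
})

test_that("identical parameters give byte-identical AIRR output", {
  p <- sim_params(seed = 23, n_background_clones = 500, depth = 2e3,
                  n_timepoints = 2, longitudinal_folds = c(4, 4))
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_subject(p, dir = d1)
  simulate_subject(p, dir = d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("planted masses are conserved and survive the IO round trip", {
  p <- sim_params(seed = 3, n_background_clones = 800, depth = 5e3)
  s <- simulate_subject(p)
  for (m in s$masses) expect_equal(sum(m), 1, tolerance = 1e-9)

  f <- tempfile(fileext = ".tsv")
  write_airr(s$samples$brain_t1, f)
  back <- curate(read_rearrangements(f, "airr"))
  expect_equal(sum(back$report), 0L)    # curation loses nothing
  expect_equal(sum(back$kept$templates), sum(s$samples$brain_t1$templates))
})

test_that("expanded clones carry the planted repertoire mass", {
  p <- sim_params(seed = 2, n_expanded = 5, expanded_mass = 0.5,
                  depth = 1e5)
  s <- simulate_subject(p)
  tab <- aggregate_clonotypes(curate(s$samples$blood_t1)$kept,
                              s$meta$blood_t1)
  expect_gt(clonality_index(tab)$clonality, 0.2)
  tp5 <- top_n(tab, 5)
  expect_equal(tp5$repertoire_fraction, 0.5, tolerance = 0.03)
  expect_setequal(tp5$entries$cdr3_aa,
                  s$truth$cdr3_aa[s$truth$is_expanded])
})

test_that("without planted effects both compartments sit at the background diversity floor", {
  p <- sim_params(seed = 12, n_background_clones = 10000L,
                  n_expanded = 0L, expanded_mass = 0,
                  n_brain_enriched = 0L, brain_enrichment = 1,
                  depth = 1e5)
  s <- simulate_subject(p)
  clon <- vapply(c("brain_t1", "blood_t1"), function(nm) {
    tab <- aggregate_clonotypes(curate(s$samples[[nm]])$kept, s$meta[[nm]])
    clonality_index(tab)$clonality
  }, numeric(1))
  # no compartment effect: brain and blood indistinguishable
  expect_lt(abs(clon["brain_t1"] - clon["blood_t1"]), 0.02)
  # planting expansion mass lifts clonality well above the floor
  p2 <- sim_params(seed = 12, n_background_clones = 10000L,
                   n_expanded = 5L, expanded_mass = 0.4,
                   n_brain_enriched = 0L, brain_enrichment = 1,
                   depth = 1e5)
  s2 <- simulate_subject(p2)
  tab2 <- aggregate_clonotypes(curate(s2$samples$blood_t1)$kept,
                               s2$meta$blood_t1)
  expect_gt(clonality_index(tab2)$clonality, clon["blood_t1"] + 0.05)
})

test_that("brain enrichment is recovered as up calls by tracking", {
  p <- sim_params(seed = 42, n_brain_enriched = 20, brain_enrichment = 10,
                  n_expanded = 0, expanded_mass = 0, depth = 1e5)
  s <- simulate_subject(p)
  brain <- aggregate_clonotypes(curate(s$samples$brain_t1)$kept,
                                s$meta$brain_t1)
  blood <- aggregate_clonotypes(curate(s$samples$blood_t1)$kept,
                                s$meta$blood_t1)
  enriched <- s$truth$cdr3_aa[s$truth$brain_enriched]
  res <- track(blood, brain, universe = enriched)
  expect_gte(sum(res$direction == "up"), 15)
})

test_that("simulated reference databases carry their ground truth", {
  s <- simulate_subject(sim_params(seed = 6, n_background_clones = 1000,
                                   depth = 1e4))
  dbs <- simulate_reference_dbs(s)
  calls <- classify_public(s$truth$cdr3_aa, dbs$public)
  expect_equal(calls == "public", s$truth$is_public)

  # planted near-matches are found at (at most) the planted edit count,
  # with equality at 0 and 1 edits
  for (k in seq_len(nrow(dbs$truth))) {
    d <- edit_align(dbs$truth$source_cdr3[k], dbs$truth$viral_cdr3[k])$distance
    expect_lte(d, dbs$truth$planted_edits[k])
    if (dbs$truth$planted_edits[k] <= 1L) {
      expect_equal(d, dbs$truth$planted_edits[k])
    }
    hits <- match_viral(dbs$truth$source_cdr3[k], dbs$viral,
                        max_distance = 2)
    expect_true(dbs$truth$viral_cdr3[k] %in% hits$cdr3_aa)
  }

  # without derived or decoy rows every non-public clone is private
  dbs0 <- simulate_reference_dbs(s, n_decoys = 0, n_viral_derived = 0,
                                 n_viral_unrelated = 3)
  calls0 <- classify_public(s$truth$cdr3_aa, dbs0$public)
  expect_equal(sum(calls0 == "private"), sum(!s$truth$is_public))
})

test_that("observed top-N mass converges to the planted mass with depth", {
  errs <- vapply(c(1e3, 1e4, 1e5), function(depth) {
    p <- sim_params(seed = 77, n_expanded = 5, expanded_mass = 0.4,
                    depth = depth)
    s <- simulate_subject(p)
    tab <- aggregate_clonotypes(curate(s$samples$blood_t1)$kept,
                                s$meta$blood_t1)
    abs(top_n(tab, 5)$repertoire_fraction - 0.4)
  }, numeric(1))
  expect_lt(errs[3], errs[1] + 0.01)
  expect_lt(errs[3], 0.02)
})

test_that("noiseless expression recovers planted clusters perfectly", {
  ex <- simulate_expression(n_samples = 15, n_genes = 300, seed = 5,
                            noise_sd = 1e-6,
                            infiltration_levels = c(0, 1, 2))
  cl <- pca_cluster(ex$matrix, k = 3)
  expect_equal(mclust::adjustedRandIndex(cl$labels, ex$truth$cluster), 1)
})

test_that("all-zero loads give only alpha-level marker false positives", {
  ex <- simulate_expression(n_samples = 30, n_genes = 1000, seed = 8,
                            load = 0, infiltration_levels = c(0, 3, 6))
  cl <- structure(list(labels = ex$truth$cluster, k = 3L),
                  class = "cluster_assignment")
  sel <- select_markers(ex$matrix, cl, target = 3, alpha = 1e-4)
  expect_lte(nrow(sel), 3L)   # expected count 0.05 false positives
})
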