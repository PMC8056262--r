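test_that("AIRR and immunoSEQ dialects parse into the same record schema", {
  airr <- tempfile(fileext = ".tsv")
  writeLines(c(
    "junction_aa\tv_call\tj_call\tduplicate_count\tproductive",
    "CASSLGF\tTRBV05-1\tTRBJ2-1\t7\tTRUE",
    "CASSQF\tTRBV06-2\tTRBJ1-1\t2\tTRUE",
    "CASSWF\tTRBV07-3\tTRBJ2-7\t1\tFALSE"), airr)
  recs <- read_rearrangements(airr, dialect = "airr")
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$templates, c(7L, 2L, 1L))
  expect_equal(recs$productive, c(TRUE, TRUE, FALSE))

  iseq <- tempfile(fileext = ".tsv")
  writeLines(c(
    "amino_acid\tv_gene\tj_gene\ttemplates\tframe_type",
    "CASSLG\tTCRBV05-01\tTCRBJ02-01\t7\tIn"), iseq)
  recs2 <- read_rearrangements(iseq, dialect = "immunoseq")
  expect_equal(recs2$cdr3_aa, "CASSLG")
  expect_equal(recs2$templates, 7L)
  expect_true(recs2$productive)
})

test_that("missing required columns are reported by name", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("junction_aa\tv_call\tj_call\tproductive",
               "CASSF\tTRBV1\tTRBJ1\tTRUE"), bad)
  expect_error(read_rearrangements(bad, "airr"), "duplicate_count")
})

test_that("missing template counts default to 1 with a warning", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("junction_aa\tv_call\tj_call\tduplicate_count\tproductive",
               "CASSF\tTRBV1\tTRBJ1\tNA\tTRUE",
               "CASSGF\tTRBV1\tTRBJ1\t4\tTRUE"), f)
  expect_warning(recs <- read_rearrangements(f, "airr"), "set to 1")
  expect_equal(recs$templates, c(1L, 4L))
})

test_that("AIRR round trip preserves simulated records", {
  set.seed(11)
  recs <- make_records(simulate_cdr3(100), templates = sample(1:50, 100,
                                                             replace = TRUE))
  f <- tempfile(fileext = ".tsv")
  write_airr(recs, f)
  back <- read_rearrangements(f, "airr")
  expect_equal(back, recs)
})

test_that("curation enforces the framework cysteine and tallies removals", {
  recs <- make_records(c("CASSQELTGLAGYTF", "ASSQELTGLAGYTF"))
  out <- curate(recs)
  expect_equal(out$kept$cdr3_aa, "CASSQELTGLAGYTF")
  expect_equal(unname(out$report["no_framework_cysteine"]), 1L)
  expect_equal(sum(out$report), 1L)

  mixed <- make_records(
    c("CASSF", "", "CAS*SF", "CAS_SF", "CASSGF", "XSSF"),
    productive = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  res <- curate(mixed)
  expect_equal(nrow(res$kept) + sum(res$report), nrow(mixed))
  expect_equal(unname(res$report[c("empty_junction", "stop_codon",
                                   "out_of_frame", "non_productive",
                                   "no_framework_cysteine")]),
               c(1L, 1L, 1L, 1L, 1L))
  expect_equal(res$kept$cdr3_aa, "CASSF")
})

test_that("curation is idempotent and handles empty input", {
  recs <- make_records(c("CASSF", "ASSF", "CAS*F"))
  once <- curate(recs)
  twice <- curate(once$kept)
  expect_equal(twice$kept, once$kept)
  expect_equal(sum(twice$report), 0L)

  empty <- curate(recs[integer(0), ])
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(sum(empty$report), 0L)

  all_valid <- curate(make_records(simulate_cdr3(10)))
  expect_equal(nrow(all_valid$kept), 10L)
})

test_that("aggregation merges identical CDR3s and conserves template mass", {
  recs <- data.frame(cdr3_aa = c("CASSF", "CASSF"),
                     v_call = c("TRBV1", "TRBV2"),
                     j_call = "TRBJ1", templates = c(3L, 2L),
                     productive = TRUE, stringsAsFactors = FALSE)
  tab <- aggregate_clonotypes(recs, sample_meta("s1"))
  expect_equal(tab$n_unique, 1L)
  expect_equal(tab$table$templates, 5)
  expect_equal(tab$table$frequency, 1.0)
  expect_equal(tab$table$v_call, "TRBV1")  # highest-count contributor

  recs2 <- make_records(c("CAF", "CCF", "CDF"), templates = c(1L, 1L, 2L))
  tab2 <- aggregate_clonotypes(recs2, sample_meta("s2"))
  expect_equal(sort(tab2$table$frequency), c(0.25, 0.25, 0.5))
  expect_equal(tab2$total_templates, sum(recs2$templates))

  single <- aggregate_clonotypes(make_records("CASSF"), sample_meta("s3"))
  expect_equal(single$table$frequency, 1.0)
})

test_that("aggregation rejects degenerate input and frequencies sum to 1", {
  expect_error(aggregate_clonotypes(make_records(character(0)),
                                    sample_meta("s1")), "empty")
  zero <- make_records("CASSF", templates = 0L)
  expect_error(aggregate_clonotypes(zero, sample_meta("s1")), "zero total")

  set.seed(3)
  recs <- make_records(simulate_cdr3(500),
                       templates = sample(1:100, 500, replace = TRUE))
  tab <- aggregate_clonotypes(recs, sample_meta("s1"))
  expect_equal(sum(tab$table$frequency), 1, tolerance = 1e-9)
  expect_equal(tab$n_unique, nrow(tab$table))
  expect_false(anyDuplicated(tab$table$cdr3_aa) > 0)
})

test_that("the same data in both dialects aggregates identically", {
  set.seed(5)
  recs <- make_records(simulate_cdr3(50),
                       templates = sample(1:20, 50, replace = TRUE))
  airr <- tempfile(fileext = ".tsv")
  write_airr(recs, airr)
  iseq <- tempfile(fileext = ".tsv")
  writeLines(c("amino_acid\tv_gene\tj_gene\ttemplates\tframe_type",
               sprintf("%s\t%s\t%s\t%d\t%s", recs$cdr3_aa, recs$v_call,
                       recs$j_call, recs$templates,
                       ifelse(recs$productive, "In", "Out"))), iseq)
  ta <- aggregate_clonotypes(curate(read_rearrangements(airr, "airr"))$kept,
                             sample_meta("x"))
  tb <- aggregate_clonotypes(
    curate(read_rearrangements(iseq, "immunoseq"))$kept, sample_meta("x"))
  expect_equal(ta$table, tb$table)
})

test_that("clonotype tables survive a write/read round trip", {
  tab <- make_table(c(CASSAF = 10, CASSCF = 5, CASSDF = 5, CASSEF = 1,
                      CASSGF = 4))
  f <- tempfile(fileext = ".tsv")
  write_clonotype_table(tab, f)
  back <- read_clonotype_table(f, tab$meta)
  expect_equal(back$table, tab$table)
  expect_equal(back$total_templates, tab$total_templates)

  # larger simulator output: frequencies re-sum to 1 on read-back
  s <- simulate_subject(sim_params(seed = 9, n_background_clones = 3000,
                                   depth = 2e4))
  big <- aggregate_clonotypes(curate(s$samples$blood_t1)$kept,
                              s$meta$blood_t1)
  write_clonotype_table(big, f)
  back2 <- read_clonotype_table(f, big$meta)
  expect_equal(sum(back2$table$frequency), 1, tolerance = 1e-9)
})
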