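test_that("top_n ranks by templates with lexicographic tie-break", {
  tab <- make_table(c(D = 10, B = 5, A = 5, C = 1))
  tp <- top_n(tab, 3)
  expect_equal(tp$entries$cdr3_aa, c("D", "A", "B"))
  expect_equal(tp$entries$rank, 1:3)

  small <- make_table(c(CAF = 3, CCF = 2, CDF = 1))
  all3 <- top_n(small, 50)
  expect_equal(nrow(all3$entries), 3L)
  expect_equal(all3$repertoire_fraction, 1.0)
})

test_that("top_n is deterministic under permuted input and captures skew", {
  set.seed(13)
  counts <- sample(1:200, 300, replace = TRUE)
  names(counts) <- replicate(300, paste(sample(LETTERS, 8), collapse = ""))
  t1 <- top_n(make_table(counts), 20)
  t2 <- top_n(make_table(sample(counts)), 20)
  expect_equal(t1$entries, t2$entries)

  s <- simulate_subject(sim_params(seed = 31, n_background_clones = 2000,
                                   depth = 2e4))
  tab <- aggregate_clonotypes(curate(s$samples$blood_t1)$kept,
                              s$meta$blood_t1)
  tp <- top_n(tab, 50)
  # a skewed repertoire concentrates far more mass in its top clones
  # than the uniform share
  expect_gt(tp$repertoire_fraction, 50 / tab$n_unique)
})

test_that("overlap computes Venn partitions that sum to the union", {
  dis <- overlap(A = c("A", "B"), B = "C")
  expect_equal(dis$count[dis$region == "A&B"], 0L)

  ov <- overlap(A = c("A", "B", "C"), B = c("B", "C", "D"))
  expect_equal(ov$count[ov$region == "A&B"], 2L)
  expect_equal(sum(ov$count), 4L)
  expect_equal(attr(ov, "union_size"), 4L)

  s <- simulate_subject(sim_params(seed = 17, n_background_clones = 1000,
                                   depth = 5e3, n_timepoints = 2,
                                   longitudinal_folds = rep(3, 5)))
  tops <- lapply(names(s$samples), function(nm) {
    tab <- aggregate_clonotypes(curate(s$samples[[nm]])$kept, s$meta[[nm]])
    top_n(tab, 50)$entries$cdr3_aa
  })
  names(tops) <- names(s$samples)
  ov4 <- overlap(tops)
  expect_equal(sum(ov4$count), attr(ov4, "union_size"))
  expect_equal(attr(ov4, "union_size"),
               length(unique(unlist(tops))))

  expect_error(overlap(A = "x", B = "y", C = "z", D = "w", E = "v"),
               "2 to 4")
})

test_that("compare_frequency reproduces the pooled-proportion chi-squared", {
  same <- compare_frequency(5, 100, 5, 100)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_equal(same$direction, "no_change")

  # oracle: pooled-proportion Pearson formula computed independently
  cmp <- compare_frequency(20, 100, 5, 100)
  p_pool <- 25 / 200
  z2 <- (0.2 - 0.05)^2 / (p_pool * (1 - p_pool) * (1 / 100 + 1 / 100))
  expect_equal(cmp$chi2, z2, tolerance = 1e-12)
  expect_equal(cmp$chi2, 10.28571, tolerance = 1e-5)
  expect_equal(cmp$p, 0.00134, tolerance = 1e-3)
  expect_equal(cmp$direction, "down")
})

test_that("chi-squared equals z-squared and matches stats oracles", {
  set.seed(6)
  for (rep in 1:50) {
    n1 <- sample(50:5000, 1); n2 <- sample(50:5000, 1)
    x1 <- sample(0:20, 1); x2 <- sample(0:20, 1)
    if (x1 + x2 == 0) x1 <- 1
    cmp <- compare_frequency(x1, n1, x2, n2)
    p_pool <- (x1 + x2) / (n1 + n2)
    z <- (x1 / n1 - x2 / n2) /
      sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
    expect_equal(cmp$chi2, z^2, tolerance = 1e-9)
    if (x1 > 0 && x2 > 0) {
      m <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2)
      ref <- suppressWarnings(chisq.test(m, correct = FALSE))
      expect_equal(cmp$chi2, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(cmp$p, ref$p.value, tolerance = 1e-9)
      pt <- suppressWarnings(prop.test(c(x1, x2), c(n1, n2),
                                       correct = FALSE))
      expect_equal(cmp$p, pt$p.value, tolerance = 1e-9)
    }
  }
})

test_that("compare_frequency is antisymmetric in the two samples", {
  set.seed(8)
  for (rep in 1:20) {
    x1 <- sample(0:50, 1); x2 <- sample(0:50, 1)
    if (x1 + x2 == 0) x2 <- 3
    a <- compare_frequency(x1, 1000, x2, 1200)
    b <- compare_frequency(x2, 1200, x1, 1000)
    expect_equal(a$chi2, b$chi2)
    expect_equal(a$p, b$p)
    flip <- c(up = "down", down = "up", no_change = "no_change",
              not_tested = "not_tested")
    expect_equal(unname(flip[a$direction]), b$direction)
  }
})

test_that("absence policy flags one-sided zeros and strict mode withholds p", {
  cmp <- compare_frequency(0, 1000, 30, 1000)
  expect_equal(cmp$direction, "up")
  expect_equal(cmp$flag, "absent_sample_1")
  expect_lt(cmp$p, 0.05)

  strict <- compare_frequency(0, 1000, 30, 1000, strict_absent = TRUE)
  expect_true(is.na(strict$p))
  expect_equal(strict$direction, "not_tested")

  none <- compare_frequency(0, 1000, 0, 1000)
  expect_equal(none$direction, "not_tested")
  expect_equal(none$flag, "absent_both")
  expect_true(is.na(none$chi2))
})

test_that("Yates correction reduces the statistic and matches chisq.test", {
  a <- compare_frequency(12, 300, 4, 280, correct = TRUE)
  m <- matrix(c(12, 288, 4, 276), 2)
  ref <- chisq.test(m, correct = TRUE)
  expect_equal(a$chi2, unname(ref$statistic), tolerance = 1e-9)
  b <- compare_frequency(12, 300, 4, 280)
  expect_lt(a$chi2, b$chi2)
})

test_that("track recovers a planted frequency change and flags top-N membership", {
  base <- c(CAAAF = 300, CABAF = 300, CACAF = 300)
  filler <- setNames(rep(10, 910), paste0("CF", sprintf("%03d", 1:910), "F"))
  t1 <- make_table(c(base, filler), sample_id = "a")
  tripled <- base; tripled["CABAF"] <- 900
  t2 <- make_table(c(tripled, filler), sample_id = "b")
  res <- track(t1, t2, universe = names(base))
  expect_equal(res$direction[res$cdr3_aa == "CABAF"], "up")
  expect_equal(res$direction[res$cdr3_aa == "CAAAF"], "no_change")
  expect_equal(res$direction[res$cdr3_aa == "CACAF"], "no_change")
  expect_true(all(res$in_top_a[res$cdr3_aa %in% names(base)]))

  idem <- track(t1, t1)
  expect_true(all(idem$direction == "no_change"))
})

test_that("BH adjustment is available but off by default", {
  set.seed(44)
  counts1 <- setNames(sample(50:150, 60), paste0("CX", sprintf("%02d", 1:60), "F"))
  counts2 <- counts1
  counts2[1:5] <- counts2[1:5] * 3
  ta <- make_table(counts1, "a")
  tb <- make_table(counts2, "b")
  raw <- track(ta, tb)
  adj <- track(ta, tb, adjust = "BH")
  expect_true("p_adj" %in% names(adj))
  expect_false("p_adj" %in% names(raw))
  expect_lte(sum(adj$direction %in% c("up", "down")),
             sum(raw$direction %in% c("up", "down")))
})
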