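test_that("exact branch matches enumeration on the textbook example", {
  res <- mannWhitneyU(c(1, 2), c(3, 4))
  expect_identical(res$u, 0)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  expect_true(res$exact)
  expect_equal(res$p, brute_exact_p(c(1, 2), c(3, 4)), tolerance = 1e-12)
})

test_that("a complete tie gives the midrank U and p = 1", {
  res <- mannWhitneyU(5, 5)
  expect_identical(res$u, 0.5)
  expect_identical(res$p, 1)
  expect_false(res$exact)  # tie forces the approximate branch
})

test_that("exact branch agrees with brute-force enumeration for all small sizes", {
  set.seed(61)
  for (n1 in 1:5) for (n2 in n1:(10 - n1)) {
    for (rep in 1:3) {
      g1 <- sample(seq_len(n1 + n2), n1)         # tie-free integer ranks
      g2 <- setdiff(seq_len(n1 + n2), g1)
      res <- mannWhitneyU(g1, g2)
      expect_true(res$exact)
      expect_identical(res$u, brute_u(g1, g2))
      expect_equal(res$p, brute_exact_p(g1, g2), tolerance = 1e-12,
                   label = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("U is antisymmetric in group order and shift-invariant", {
  set.seed(62)
  for (rep in 1:10) {
    g1 <- rnorm(sample(2:12, 1)); g2 <- rnorm(sample(2:12, 1))
    a <- mannWhitneyU(g1, g2); b <- mannWhitneyU(g2, g1)
    expect_equal(a$u + b$u, length(g1) * length(g2), tolerance = 1e-9)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    shifted <- mannWhitneyU(g1 + 17.3, g2 + 17.3)
    expect_equal(shifted$u, a$u)
    expect_equal(shifted$p, a$p, tolerance = 1e-12)
  }
  # antisymmetry holds with ties too (midranks)
  g1 <- c(1, 2, 2, 5); g2 <- c(2, 3, 3)
  a <- mannWhitneyU(g1, g2); b <- mannWhitneyU(g2, g1)
  expect_equal(a$u + b$u, 12)
})

test_that("approximate branch matches the reference implementation", {
  set.seed(63)
  for (rep in 1:5) {
    g1 <- rnorm(30); g2 <- rnorm(40)
    res <- mannWhitneyU(g1, g2)
    ref <- stats::wilcox.test(g1, g2, exact = FALSE, correct = TRUE)
    expect_equal(res$u, unname(ref$statistic))
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  }
  # with heavy ties (tie-corrected variance)
  g1 <- sample(1:4, 25, TRUE); g2 <- sample(1:5, 30, TRUE)
  res <- mannWhitneyU(g1, g2)
  ref <- stats::wilcox.test(g1, g2, exact = FALSE, correct = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
})

test_that("empty or NA groups are rejected", {
  expect_error(mannWhitneyU(numeric(0), 1:3), "non-empty")
  expect_error(mannWhitneyU(c(1, NA), 1:3), "non-empty")
})

test_that("Tukey box statistics follow the type-7 quantile convention", {
  b <- tukeyBoxStats(1:7)
  expect_identical(b$median, 4)
  expect_identical(b$q1, 2.5)
  expect_identical(b$q3, 5.5)
  expect_identical(b$whiskerLow, 1)
  expect_identical(b$whiskerHigh, 7)
  expect_length(b$outliers, 0L)
  # constant data collapse the box
  k <- tukeyBoxStats(rep(3.2, 9))
  expect_true(all(c(k$median, k$q1, k$q3, k$whiskerLow, k$whiskerHigh) == 3.2))
  expect_length(k$outliers, 0L)
  # a far point beyond the upper fence is an outlier
  o <- tukeyBoxStats(c(1:7, 100))
  expect_identical(o$outliers, 100)
  expect_lte(o$whiskerHigh, o$q3 + 1.5 * o$iqr)
  expect_error(tukeyBoxStats(numeric(0)), "no values")
})

test_that("cohorts with a plaque shift flag the shifted parameters", {
  coh <- generateCohort(40, c(plaque = 1.25), seed = 71)
  cmp <- compareSegments(cohortRecords(coh))
  expect_identical(nrow(cmp), 10L)
  row <- cmp[cmp$parameter == "plaque_area_um2", ]
  expect_true(row$significant)
  expect_true(row$u_statistic >= 0 && row$u_statistic <= row$n1 * row$n2)
  # media drawn identically should usually not be significant; check p sane
  expect_true(all(cmp$p_value > 0 & cmp$p_value <= 1))
})

test_that("single-record groups are computable and never significant", {
  recs <- list(
    morphometryFromAreas(1e5, 3e4, 2e5, 2e4, 1e4, "p", "proximal"),
    morphometryFromAreas(1.2e5, 3.5e4, 2.6e5, 2.4e4, 1.3e4, "d", "distal"))
  cmp <- compareSegments(recs)
  expect_true(all(is.finite(cmp$p_value)))
  expect_false(any(cmp$significant))
})

test_that("missing groups and Holm adjustment behave as documented", {
  recs <- list(morphometryFromAreas(1e5, 3e4, 2e5, sectionId = "p",
                                    segmentLabel = "proximal"))
  expect_error(compareSegments(recs), "non-empty")
  coh <- generateCohort(15, c(plaque = 1.5), seed = 72)
  cmp <- compareSegments(cohortRecords(coh), adjust = "holm")
  expect_true(all(cmp$p_adjusted >= cmp$p_value - 1e-12))
})
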