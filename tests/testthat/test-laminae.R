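test_that("two concentric annuli among blobs yield exactly two laminae", {
  n <- 200L; ctr <- c(100.5, 100.5)
  mask <- annulus_mask(n, ctr, 40, 45) | annulus_mask(n, ctr, 80, 85)
  # 50 scattered compact blobs sharing the orcein color
  set.seed(7)
  for (k in 1:50) {
    i <- sample(5:195, 1); j <- sample(5:195, 1)
    mask[i + (-1:1), j + (-1:1)] <- TRUE
  }
  ls <- detectLaminae(mask, minEnclosedArea = 500)
  expect_length(laminae(ls), 2L)
  # innermost encloses ~ pi * 40^2 (rasterization tolerance)
  expect_lt(rel_err_pct(innermost(ls)@enclosedArea, pi * 40^2), 2)
  expect_lt(rel_err_pct(outermost(ls)@enclosedArea, pi * 80^2), 2)
  expect_lt(innermost(ls)@meanThickness, 10)
})

test_that("an all-zeros mask raises the no-vessel condition with diagnostics", {
  err <- tryCatch(detectLaminae(matrix(FALSE, 10, 10)), error = identity)
  expect_s3_class(err, "plaquemorph_no_vessel")
  expect_identical(err$nComponents, 0L)
  # blobs alone (nothing encloses an interior) also report no vessel
  m <- matrix(FALSE, 30, 30); m[10:12, 10:12] <- TRUE
  err2 <- tryCatch(detectLaminae(m), error = identity)
  expect_s3_class(err2, "plaquemorph_no_vessel")
  expect_gte(err2$nComponents, 1L)
})

test_that("a small gap is bridged by morphological closing", {
  n <- 120L; ctr <- c(60.5, 60.5)
  ring <- annulus_mask(n, ctr, 40, 43)
  # cut a 3-px gap at the top of the ring
  ring[1:60, 59:61] <- ring[1:60, 59:61] & FALSE
  gap_cols <- 59:61
  expect_error(detectLaminae(ring, minEnclosedArea = 500, closingRadius = 0),
               "no vessel")
  ls <- detectLaminae(ring, minEnclosedArea = 500, closingRadius = 2)
  expect_length(laminae(ls), 1L)
  expect_lt(rel_err_pct(innermost(ls)@enclosedArea, pi * 40^2), 3)
})

test_that("media and internal partition the filled outer interior", {
  n <- 200L; ctr <- c(100.5, 100.5)
  mask <- annulus_mask(n, ctr, 40, 45) | annulus_mask(n, ctr, 80, 85)
  ls <- detectLaminae(mask, minEnclosedArea = 500)
  media <- mediaMask(ls)
  internal <- internalMask(ls)
  expect_lt(rel_err_pct(sum(media), pi * (85^2 - 40^2)), 2)
  expect_lt(rel_err_pct(sum(internal), pi * 40^2), 2)
  expect_false(any(media & internal))           # disjoint
  filled_outer <- bfs_fill(outermost(ls)@ringMask)
  expect_identical(media | internal, filled_outer)  # partition
  # innermost ring pixels belong to media, not internal
  expect_true(all(media[innermost(ls)@ringMask]))
  expect_false(any(internal[innermost(ls)@ringMask]))
})

test_that("a single lamina delimits no media unless the fallback is requested", {
  ring <- annulus_mask(120L, c(60.5, 60.5), 40, 44)
  ls <- detectLaminae(ring, minEnclosedArea = 500)
  expect_error(mediaMask(ls), "cannot delimit media")
  fallback <- mediaMask(ls, allowSingle = TRUE)
  # zero-width media: the ring pixels only
  expect_identical(fallback, innermost(ls)@ringMask)
  expect_false(any(fallback & internalMask(ls)))
})

test_that("thick filled structures are rejected by the thickness criterion", {
  # a filled disk with a small off-center hole encloses area but is thick
  n <- 160L
  m <- disk_mask(n, c(80.5, 80.5), 60) & !disk_mask(n, c(80.5, 80.5), 26)
  expect_error(detectLaminae(m, minEnclosedArea = 500, maxThickness = 15),
               "no vessel")
  ls <- detectLaminae(m, minEnclosedArea = 500, maxThickness = 60)
  expect_length(laminae(ls), 1L)
})

test_that("component labeling and hole filling match the BFS oracle exactly", {
  set.seed(13)
  for (rep in 1:6) {
    m <- matrix(runif(48 * 48) < 0.35, 48, 48)
    lab <- labelComponents(m)
    oracle <- bfs_label(m, eight = TRUE)
    expect_identical(max(lab), max(oracle))
    # same partition up to label naming: the label pairing is a bijection
    expect_identical(length(unique(paste(lab[m], oracle[m]))), max(oracle))
    expect_identical(fillHoles(m), bfs_fill(m))
  }
  # diagonal chains are single components (8-connectivity)
  d <- diag(8) > 0
  expect_identical(max(labelComponents(d)), 1L)
  expect_identical(max(bfs_label(d, eight = TRUE)), 1L)
})
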