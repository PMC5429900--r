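make_internal <- function(n) matrix(TRUE, n, n)

test_that("white regions split into lumen and lipid by erythrocyte content", {
  n <- 60L
  internal <- make_internal(n)
  white <- disk_mask(n, c(20, 20), 8) | disk_mask(n, c(45, 45), 8)
  ery <- matrix(FALSE, n, n)
  ery[16:20, 16:21] <- TRUE  # 30 erythrocyte pixels in the first blob
  white <- white & !ery
  res <- splitLumenLipid(internal, white, ery, minRbcPixels = 5)
  # the erythrocyte-bearing component plus its erythrocytes is lumen
  expect_true(all(res$lumen[ery]))
  expect_true(any(res$lumen[disk_mask(n, c(20, 20), 8)]))
  # the clean blob is lipid
  expect_identical(res$lipid, white & disk_mask(n, c(45, 45), 8))
  expect_false(any(res$lumen & res$lipid))
})

test_that("absence of white yields empty lumen and lipid, with a warning", {
  n <- 20L
  expect_warning(
    res <- splitLumenLipid(make_internal(n), matrix(FALSE, n, n),
                           matrix(FALSE, n, n)),
    "graze")
  expect_identical(sum(res$lumen) + sum(res$lipid), 0L)
})

test_that("a single erythrocyte-rich white component leaves lipid empty", {
  n <- 40L
  white <- disk_mask(n, c(20, 20), 10)
  ery <- disk_mask(n, c(20, 20), 3)
  white <- white & !ery
  res <- splitLumenLipid(make_internal(n), white, ery, minRbcPixels = 5)
  expect_identical(res$lumen, white | ery)
  expect_false(any(res$lipid))
})

test_that("pure-erythrocyte components are neither lumen nor lipid", {
  n <- 40L
  ery <- disk_mask(n, c(30, 30), 4)  # entrapped erythrocytes: no white
  expect_warning(
    res <- splitLumenLipid(make_internal(n), matrix(FALSE, n, n), ery,
                           minRbcPixels = 5),
    "graze")
  expect_false(any(res$lumen))
  expect_false(any(res$lipid))
})

test_that("raising minRbcPixels never grows the lumen", {
  n <- 80L
  set.seed(23)
  internal <- make_internal(n)
  white <- disk_mask(n, c(20, 20), 9) | disk_mask(n, c(55, 25), 7) |
    disk_mask(n, c(40, 60), 8)
  ery <- matrix(FALSE, n, n)
  ery[cbind(sample(15:25, 12, TRUE), sample(15:25, 12, TRUE))] <- TRUE
  ery[cbind(sample(50:60, 4, TRUE), sample(20:30, 4, TRUE))] <- TRUE
  prev <- Inf
  for (thr in c(1, 3, 5, 10, 20)) {
    res <- suppressWarnings(splitLumenLipid(internal, white & !ery, ery, thr))
    expect_lte(sum(res$lumen), prev)
    prev <- sum(res$lumen)
  }
})

test_that("plaque subtraction checks containment and basic arithmetic", {
  n <- 30L
  internal <- disk_mask(n, c(15, 15), 12)
  lumen <- disk_mask(n, c(15, 15), 5)
  expect_identical(plaquePixels(internal, lumen),
                   sum(internal) - sum(lumen))
  expect_identical(plaquePixels(internal, internal), 0L)
  bad <- matrix(TRUE, n, n)  # lumen not inside internal
  expect_error(plaquePixels(internal, bad), "invariant violation")
})

test_that("collagen is clipped to internal minus lumen", {
  n <- 40L
  internal <- disk_mask(n, c(20, 20), 15)
  lumen <- disk_mask(n, c(20, 20), 6)
  blue_out <- disk_mask(n, c(3, 3), 2)          # outside internal
  expect_false(any(collagenInPlaque(blue_out, internal, lumen)))
  blue_in <- disk_mask(n, c(20, 30), 3) & internal & !lumen
  got <- collagenInPlaque(blue_in, internal, lumen)
  expect_identical(got, blue_in)
  expect_true(all(internal[got]) && !any(lumen & got))
})

test_that("end-to-end recovery is within 2% (clean) and 5% (noisy)", {
  for (s in 1:3) {
    tr <- generateSection(sectionSpec(seed = s))
    seg <- segmentSection(tr$image)
    expect_lt(max(rel_err_pct(seg_areas(seg), truth_areas(tr$truth))), 2)
  }
  tr <- generateSection(sectionSpec(seed = 4, noiseSd = 8))
  seg <- segmentSection(tr$image)
  expect_lt(max(rel_err_pct(seg_areas(seg), truth_areas(tr$truth))), 5)
})

test_that("segmentation result masks obey the mask algebra on varied fixtures", {
  specs <- list(
    sectionSpec(seed = 11),
    sectionSpec(seed = 12, laminaBreaks = list(c(120, 2), NULL)),  # broken lamina
    sectionSpec(seed = 13, entrappedErythrocytes = 6L),
    sectionSpec(seed = 14, noiseSd = 8)
  )
  for (sp in specs) {
    seg <- segmentSection(generateSection(sp)$image)
    expect_true(validObject(seg))  # validity enforces the algebra
    expect_false(any(mediaMask(seg) & internalMask(seg)))
    expect_true(all(internalMask(seg)[lumenMask(seg)]))
    expect_gte(plaquePixelCount(seg), 0)
    cg <- collagenMask(seg)
    expect_true(all(internalMask(seg)[cg]) && !any(cg & lumenMask(seg)))
  }
})

test_that("a 90-degree rotation changes compartment areas by less than 1%", {
  tr <- generateSection(sectionSpec(seed = 21))
  img <- tr$image
  rot <- array(0L, c(dim(img)[2], dim(img)[1], 3))
  for (ch in 1:3) rot[, , ch] <- t(img[nrow(img):1, , ch])
  a1 <- seg_areas(segmentSection(img))
  a2 <- seg_areas(segmentSection(rot))
  expect_lt(max(rel_err_pct(a2, a1)), 1)
})

test_that("a blank image reports no vessel", {
  expect_error(segmentSection(array(255L, c(80, 80, 3))), "no vessel")
})

test_that("segmentation summary serializes pixel counts as JSON", {
  seg <- segmentSection(generateSection(sectionSpec(seed = 2))$image)
  js <- jsonlite::fromJSON(segmentationSummary(seg))
  expect_identical(js$pixels$media, sum(mediaMask(seg)))
  expect_identical(js$pixels$plaque, plaquePixelCount(seg))
  expect_length(js$laminae$enclosedArea, 2L)
})
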