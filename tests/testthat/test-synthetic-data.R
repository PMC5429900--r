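test_that("generation is bit-reproducible for a fixed spec", {
  sp <- sectionSpec(seed = 9, noiseSd = 8, entrappedErythrocytes = 3L)
  a <- generateSection(sp)
  b <- generateSection(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth@areasPx, b$truth@areasPx)
  # a different seed changes the render
  c <- generateSection(sectionSpec(seed = 10, noiseSd = 8))
  expect_false(identical(a$image, c$image))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(3)
  set.seed(123)
  invisible(generateSection(sectionSpec(seed = 5, noiseSd = 4)))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("zero collagen blobs give zero true collagen area", {
  tr <- generateSection(sectionSpec(seed = 2, collagenBlobs = 0L))
  expect_identical(tr$truth@areasPx[["collagen"]], 0)
  tr2 <- generateSection(sectionSpec(seed = 2, lipidVacuoles = 0L))
  expect_identical(tr2$truth@areasPx[["lipid"]], 0)
})

test_that("true media area matches the per-pixel radius oracle exactly", {
  sp <- sectionSpec(seed = 3, laminaRadii = list(c(40, 45), c(80, 85)),
                    lumenRadius = 20, lumenOffset = c(-5, 3), size = 200L,
                    collagenBlobs = 3L, collagenRadius = 6,
                    lipidVacuoles = 2L, lipidRadius = 5, erythrocytes = 10L)
  tr <- generateSection(sp)
  n <- sp@size; ctr <- sp@center
  oracle_media <- disk_mask(n, ctr, 85) & !(sqrt(outer(
    (seq_len(n) - ctr[1])^2, (seq_len(n) - ctr[2])^2, "+")) < 40)
  expect_identical(tr$truth@media, oracle_media)
  expect_lt(rel_err_pct(tr$truth@areasPx[["media"]], pi * (85^2 - 40^2)), 2)
  # lumen truth equals the offset disk
  expect_identical(tr$truth@lumen,
                   disk_mask(n, ctr + c(-5, 3), 20))
})

test_that("ground-truth masks always satisfy the segmentation algebra", {
  for (s in c(31, 32, 33)) {
    tr <- generateSection(sectionSpec(seed = s, entrappedErythrocytes = 4L,
                                      laminaBreaks = list(NULL, c(200, 3))))
    t <- tr$truth
    expect_true(validObject(t))
    expect_true(all(t@internal[t@lumen]))
    expect_false(any(t@media & t@internal))
    expect_false(any(t@lumen & t@lipid))
    expect_false(any(t@collagen & t@lumen))
    expect_identical(t@areasPx[["plaque"]],
                     t@areasPx[["internal"]] - t@areasPx[["lumen"]])
  }
})

test_that("infeasible geometry is rejected at spec construction", {
  expect_error(sectionSpec(laminaRadii = list(c(125, 128), c(127, 140))),
               "nested")
  expect_error(sectionSpec(lumenRadius = 130), "lumen")
  expect_error(sectionSpec(size = 200L), "fit")
})

test_that("cohort regeneration is reproducible and effects shift true areas", {
  a <- generateCohort(4, c(plaque = 1.2), seed = 5)
  b <- generateCohort(4, c(plaque = 1.2), seed = 5)
  pa <- sapply(a, function(s) s$truth@areasPx[["plaque"]])
  expect_identical(pa, sapply(b, function(s) s$truth@areasPx[["plaque"]]))
  expect_identical(sapply(a, `[[`, "group"),
                   rep(c("proximal", "distal"), each = 4))
  expect_error(generateCohort(3, c(fibrin = 2)), "unknown effect")
})

test_that("a +20% plaque effect shifts mean true plaque area by about 20%", {
  coh <- generateCohort(500, c(plaque = 1.2), seed = 6)
  plaque <- sapply(coh, function(s) s$truth@areasPx[["plaque"]])
  grp <- sapply(coh, `[[`, "group")
  ratio <- mean(plaque[grp == "distal"]) / mean(plaque[grp == "proximal"])
  expect_lt(abs(ratio - 1.2), 0.05)
  # no-effect cohorts differ only by sampling noise
  null <- generateCohort(5, seed = 7)
  expect_length(null, 10L)
})
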