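test_that("identical spec, config and seed give byte-identical cohorts", {
  spec <- tinySpec()
  a <- simulateCohort(spec, defaultErrorConfig(), nPatients = 3, seed = 9)
  b <- simulateCohort(spec, defaultErrorConfig(), nPatients = 3, seed = 9)
  for (i in 1:3) {
    expect_identical(a[[i]]@gt@voxels, b[[i]]@gt@voxels)
    expect_identical(a[[i]]@pred@voxels, b[[i]]@pred@voxels)
    expect_identical(a[[i]]@lesionTable, b[[i]]@lesionTable)
    expect_identical(a[[i]]@injectionLog, b[[i]]@injectionLog)
  }
  c3 <- simulateCohort(spec, defaultErrorConfig(), nPatients = 3, seed = 10)
  expect_false(identical(a[[1]]@gt@voxels, c3[[1]]@gt@voxels))
})

test_that("compartment maps render disjoint boxes with analytic voxel counts", {
  spec <- tinySpec()
  cmap <- buildCompartmentMap(spec)
  cp <- spec@compartments
  for (i in seq_len(nrow(cp))) {
    expected <- (cp$x1[i] - cp$x0[i]) * (cp$y1[i] - cp$y0[i]) *
      (cp$z1[i] - cp$z0[i])
    expect_equal(sum(voxels(cmap) == cp$compartment_id[i]), expected)
  }
  # single compartment filling the grid -> every voxel carries its id
  one <- PhantomSpec(c(8, 8, 8), c(3, 3, 3),
                     data.frame(compartment_id = 1, category = "T",
                                label = "lung", x0 = 0, x1 = 8, y0 = 0,
                                y1 = 8, z0 = 0, z1 = 8,
                                count_dist = "fixed", count_param = 0),
                     radiusRange = c(2, 4))
  expect_true(all(voxels(buildCompartmentMap(one)) == 1L))
  # zero compartments -> all background
  none <- PhantomSpec(c(8, 8, 8), c(3, 3, 3),
                      tinySpec()@compartments[0, ], radiusRange = c(2, 4))
  expect_true(all(voxels(buildCompartmentMap(none)) == 0L))
})

test_that("overlapping compartment boxes are a configuration error", {
  cp <- tinySpec()@compartments
  cp$x0[2] <- cp$x0[1]; cp$x1[2] <- cp$x1[1]
  cp$y0[2] <- cp$y0[1]; cp$y1[2] <- cp$y1[1]
  cp$z0[2] <- cp$z0[1]; cp$z1[2] <- cp$z1[1]
  expect_error(PhantomSpec(c(40, 40, 40), c(3, 3, 3), cp,
                           radiusRange = c(4, 9)), "overlap")
})

test_that("lesion counts follow the compartment plan", {
  # fixed count 0 everywhere -> empty masks
  spec0 <- tinySpec("fixed", counts = c(0, 0, 0, 0, 0))
  cases <- sampleGtCohort(spec0, 2, seed = 4)
  expect_true(all(vapply(cases, function(cs) sum(cs$gt@voxels), 1) == 0))
  # fixed count 3 in one compartment, many patients -> exactly 3n lesions
  spec3 <- tinySpec("fixed", counts = c(3, 0, 0, 0, 0))
  cases <- sampleGtCohort(spec3, 40, seed = 4)
  nComp <- vapply(cases, function(cs)
    nLesions(extractComponents(cs$gt)), integer(1))
  expect_identical(sum(nComp), 120L)
  expect_true(all(nComp == 3L))
})

test_that("zero-error injection reproduces the binarized ground truth", {
  cases <- sampleGtCohort(tinySpec(), 3, seed = 21)
  for (cs in cases) {
    inj <- injectErrors(cs, zeroErrorConfig(), seed = 1)
    expect_identical(inj$pred@voxels,
                     array(as.integer(cs$gt@voxels > 0), dim(cs$gt@voxels)))
    expect_equal(nrow(inj$injectionLog), 0L)
  }
})

test_that("unit deletion rate with no false positives empties the prediction", {
  cs <- sampleGtCohort(tinySpec(), 1, seed = 8)[[1]]
  inj <- injectErrors(cs, ErrorInjectionConfig(fnRate = c(T = 1, N = 1, M = 1)),
                      seed = 2)
  expect_true(all(inj$pred@voxels == 0L))
  nGt <- length(setdiff(unique(as.vector(cs$gt@voxels)), 0L))
  expect_equal(sum(inj$injectionLog$op == "delete"), nGt)
})

test_that("the injection log conserves lesion counts", {
  cohort <- simulateCohort(tinySpec(), defaultErrorConfig(),
                           nPatients = 10, seed = 13)
  for (b in cohort) {
    nGt <- length(setdiff(unique(as.vector(b@gt@voxels)), 0L))
    nDel <- sum(b@injectionLog$op %in% c("delete", "implicit_delete"))
    nFp <- sum(b@injectionLog$op == "fp")
    nMerge <- sum(b@injectionLog$op == "hilar_merge")
    predComp <- nLesions(extractComponents(b@pred, source = "predicted"))
    expect_equal(predComp, (nGt - nDel) - nMerge + nFp)
  }
})

test_that("erosion that annihilates a lesion is logged as an implicit deletion", {
  spec <- tinySpec("fixed", counts = c(1, 0, 0, 0, 0))
  spec@radiusRange <- c(4, 4.5)   # ~1-voxel-radius lesions at 3 mm spacing
  cs <- sampleGtCohort(spec, 1, seed = 3)[[1]]
  inj <- injectErrors(cs, ErrorInjectionConfig(erodeVoxels = 3L), seed = 5)
  expect_true(any(inj$injectionLog$op == "implicit_delete"))
  expect_true(all(inj$pred@voxels == 0L))
})

test_that("hilar merging fuses a primary with an N1 node into one component", {
  spec <- tinySpec("fixed", counts = c(1, 1, 0, 0, 0))  # one T, one hilar N
  cs <- sampleGtCohort(spec, 1, seed = 17)[[1]]
  inj <- injectErrors(cs, ErrorInjectionConfig(hilarMergeRate = 1), seed = 6)
  expect_true(any(inj$injectionLog$op == "hilar_merge"))
  gtSet <- extractComponents(cs$gt)
  predSet <- extractComponents(inj$pred, source = "predicted")
  expect_equal(nLesions(gtSet), 2L)
  expect_equal(nLesions(predSet), 1L)
  m <- matchLesions(gtSet, predSet)
  expect_equal(nrow(m@mergeEvents), 1L)
  expect_equal(m@mergeEvents$n_gt, 2L)
  expect_length(m@fnIds, 0L)   # merged lesions still count as detected
})

test_that("volume bias inflates surviving lesions multiplicatively", {
  spec <- tinySpec("fixed", counts = c(1, 0, 0, 0, 0))
  cs <- sampleGtCohort(spec, 1, seed = 19)[[1]]
  inj <- injectErrors(cs, ErrorInjectionConfig(volumeBias = 1.6), seed = 7)
  ratio <- sum(inj$pred@voxels > 0) / sum(cs$gt@voxels > 0)
  # rasterization keeps the realized factor near the requested one
  expect_gt(ratio, 1.25)
  expect_lt(ratio, 2.0)
})

test_that("phantom configuration files round trip through YAML and JSON", {
  spec <- tinySpec()
  cfg <- defaultErrorConfig()
  for (ext in c(".yaml", ".json")) {
    p <- tempfile(fileext = ext)
    writePhantomConfig(spec, cfg, nPatients = 4, p)
    back <- readPhantomConfig(p)
    expect_equal(back$nPatients, 4)
    expect_equal(back$spec@gridShape, spec@gridShape)
    expect_equal(back$spec@compartments$count_param,
                 spec@compartments$count_param)
    expect_equal(back$config@fnRate, cfg@fnRate)
    expect_equal(back$config@fpSpec$count_param, cfg@fpSpec$count_param)
  }
})
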