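test_that("connectivity controls component decomposition", {
  a <- array(0L, c(4, 4, 4))
  a[1, 1, 1] <- 1L
  a[2, 2, 2] <- 1L   # corner contact only
  v <- LabelVolume(a)
  expect_equal(nLesions(extractComponents(v, 26)), 1L)
  expect_equal(nLesions(extractComponents(v, 6)), 2L)
  b <- array(0L, c(4, 4, 4))
  b[1, 1, 1] <- 1L
  b[2, 2, 1] <- 1L   # edge contact
  v2 <- LabelVolume(b)
  expect_equal(nLesions(extractComponents(v2, 18)), 1L)
  expect_equal(nLesions(extractComponents(v2, 6)), 2L)

  expect_equal(nLesions(extractComponents(LabelVolume(array(0L, c(3, 3, 3))))), 0L)
})

test_that("touching instances with different labels stay separate lesions", {
  a <- array(0L, c(4, 4, 4))
  a[1:2, 1, 1] <- 1L
  a[3:4, 1, 1] <- 2L   # face contact between instances 1 and 2
  set <- extractComponents(LabelVolume(a), 26)
  expect_equal(nLesions(set), 2L)
  expect_setequal(lesionTable(set)$lesion_id, c("1", "2"))
})

test_that("component labelling agrees with an independent propagation oracle", {
  for (seed in 1:8) {
    mp <- randomMaskPair(seed, maxDim = 14L, density = 0.15)
    for (conn in c(6L, 26L)) {
      set <- extractComponents(LabelVolume(mp$gt), conn)
      ora <- oracleLabel(mp$gt, conn)
      expect_equal(nLesions(set), length(setdiff(unique(as.vector(ora)), 0L)),
                   info = sprintf("seed %d conn %d", seed, conn))
      # identical partitions: same multiset of component voxel sets
      pk <- sort(vapply(set@voxelIndex, function(v) paste(sort(v), collapse = ","), ""))
      ok <- sort(vapply(setdiff(unique(as.vector(ora)), 0L),
                        function(id) paste(sort(which(ora == id)), collapse = ","), ""))
      expect_identical(unname(pk), ok)
    }
  }
})

test_that("rasterized spheres recover analytic volumes and diameters", {
  spec <- tinySpec("fixed", counts = c(2, 2, 1, 1, 1))   # 7 spheres
  cs <- sampleGtCohort(spec, 1, seed = 31)[[1]]
  set <- measureDiameter(extractComponents(cs$gt))
  expect_equal(nLesions(set), 7L)
  tb <- merge(lesionTable(set), cs$lesionTable[, c("lesion_id", "radius_mm")],
              by = "lesion_id")
  for (i in seq_len(nrow(tb))) {
    r <- tb$radius_mm[i]
    analytic <- 4 / 3 * pi * r^3 / 1000
    shell <- 4 * pi * r^2 * sqrt(sum(spacing(cs$gt)^2)) / 1000
    expect_lt(abs(tb$volume_mL[i] - analytic), shell)
    expect_lt(abs(tb$diameter_mm[i] - 2 * r), sqrt(2) * max(spacing(cs$gt)))
  }
})

test_that("matching partitions lesions into TP, FN and FP", {
  a <- array(0L, c(6, 6, 6)); a[2:3, 2:3, 2:3] <- 1L
  va <- LabelVolume(a)
  gtSet <- extractComponents(va)
  predSame <- extractComponents(va, source = "predicted")
  m <- matchLesions(gtSet, predSame)
  expect_equal(nrow(m@tpPairs), 1L)
  expect_length(m@fnIds, 0L)
  expect_length(m@fpIds, 0L)

  b <- array(0L, c(6, 6, 6)); b[5:6, 5:6, 5:6] <- 1L
  m2 <- matchLesions(gtSet, extractComponents(LabelVolume(b), source = "predicted"))
  expect_equal(nrow(m2@tpPairs), 0L)
  expect_length(m2@fnIds, 1L)
  expect_length(m2@fpIds, 1L)
})

test_that("a bridging prediction detects both lesions as one merge event", {
  g <- array(0L, c(12, 4, 4))
  g[2:3, 2:3, 2:3] <- 1L
  g[9:10, 2:3, 2:3] <- 2L
  p <- array(0L, c(12, 4, 4))
  p[2:10, 2:3, 2:3] <- 1L
  gtSet <- extractComponents(LabelVolume(g))
  predSet <- extractComponents(LabelVolume(p), source = "predicted")
  m <- matchLesions(gtSet, predSet)
  # oracle: exhaustive pairwise overlap counting
  for (gid in c("1", "2")) {
    ov <- length(intersect(which(g == as.integer(gid)), which(p > 0)))
    expect_equal(m@tpPairs$overlap_voxels[m@tpPairs$gt_id == gid], ov)
  }
  expect_equal(nrow(m@mergeEvents), 1L)
  expect_equal(m@mergeEvents$n_gt, 2L)
  expect_length(m@fnIds, 0L)
  expect_length(m@fpIds, 0L)
})

test_that("match partition invariants hold on random fixtures", {
  for (seed in 1:12) {
    mp <- randomMaskPair(seed)
    gtSet <- extractComponents(LabelVolume(mp$gt))
    predSet <- extractComponents(LabelVolume(mp$pred), source = "predicted")
    m <- matchLesions(gtSet, predSet)
    gtIds <- lesionTable(gtSet)$lesion_id
    prIds <- lesionTable(predSet)$lesion_id
    matchedGt <- unique(m@tpPairs$gt_id)
    matchedPr <- unique(m@tpPairs$pred_id)
    expect_setequal(c(matchedGt, m@fnIds), gtIds)
    expect_length(intersect(matchedGt, m@fnIds), 0L)
    expect_setequal(c(matchedPr, m@fpIds), prIds)
    expect_length(intersect(matchedPr, m@fpIds), 0L)
  }
})

test_that("swapping gt and pred swaps FN and FP when no merges occur", {
  for (seed in 13:24) {
    mp <- randomMaskPair(seed, maxDim = 10L, density = 0.05)
    gtSet <- extractComponents(LabelVolume(mp$gt))
    predSet <- extractComponents(LabelVolume(mp$pred), source = "predicted")
    fwd <- matchLesions(gtSet, predSet)
    rev <- matchLesions(predSet, gtSet)
    if (nrow(fwd@mergeEvents) == 0 && nrow(rev@mergeEvents) == 0) {
      expect_setequal(fwd@fnIds, rev@fpIds)
      expect_setequal(fwd@fpIds, rev@fnIds)
    }
  }
})

test_that("predicted components inherit or acquire the right category", {
  # grid with two compartments: N-station (id 1) and M-organ (id 2)
  cmapArr <- array(0L, c(10, 4, 4))
  cmapArr[1:5, , ] <- 1L
  cmapArr[6:10, , ] <- 2L
  cmap <- LabelVolume(cmapArr)
  compartments <- data.frame(compartment_id = 1:2, category = c("N", "M"),
                             label = c("ipsilateral_hilar", "liver"))
  g <- array(0L, c(10, 4, 4)); g[2:3, 2:3, 2:3] <- 1L
  gtSet <- extractComponents(LabelVolume(g))
  gtSet@table$category <- "N"
  gtSet@table$station_or_organ <- "ipsilateral_hilar"

  # matched lesion inherits N; distant FP takes its compartment (M)
  p <- array(0L, c(10, 4, 4)); p[2:3, 2:3, 2:3] <- 1L; p[8:9, 2:3, 2:3] <- 1L
  predSet <- extractComponents(LabelVolume(p), source = "predicted")
  m <- matchLesions(gtSet, predSet)
  predSet <- assignCategory(predSet, m, cmap, compartments, gtSet)
  tb <- lesionTable(predSet)
  expect_equal(tb$category[tb$lesion_id == "1"], "N")
  expect_equal(tb$category[tb$lesion_id == "2"], "M")
  expect_equal(tb$station_or_organ[tb$lesion_id == "2"], "liver")
  expect_false(tb$annotated[tb$lesion_id == "2"])   # unannotated FP flagged

  # FP straddling both compartments 60/40 -> majority compartment wins
  p2 <- array(0L, c(10, 4, 4)); p2[3:7, 2, 2] <- 1L   # 3 voxels in 1, 2 in 2
  pred2 <- extractComponents(LabelVolume(p2), source = "predicted")
  m2 <- matchLesions(extractComponents(LabelVolume(array(0L, c(10, 4, 4)))), pred2)
  pred2 <- assignCategory(pred2, m2, cmap, compartments, gtSet)
  expect_equal(lesionTable(pred2)$category, "N")

  # FP entirely outside all compartments -> category M
  cmap0 <- LabelVolume(array(0L, c(10, 4, 4)))
  pred3 <- assignCategory(pred2, m2, cmap0, compartments, gtSet)
  expect_equal(lesionTable(pred3)$category, "M")
})

test_that("false-positive aetiology is taken from sidecar marker points", {
  cmap <- LabelVolume(array(1L, c(8, 8, 8)), spacing = c(2, 2, 2))
  compartments <- data.frame(compartment_id = 1, category = "M", label = "liver")
  g <- LabelVolume(array(0L, c(8, 8, 8)), spacing = c(2, 2, 2))
  p <- array(0L, c(8, 8, 8)); p[3:5, 3:5, 3:5] <- 1L
  predSet <- extractComponents(LabelVolume(p, spacing = c(2, 2, 2)),
                               source = "predicted")
  m <- matchLesions(extractComponents(g), predSet)
  sidecar <- validateSidecar(data.frame(
    lesion_id = "F1", category = "M", etiology_class = "physiologic",
    etiology = "brown_adipose_tissue",
    center_x_mm = 7, center_y_mm = 7, center_z_mm = 7))
  predSet <- assignCategory(predSet, m, cmap, compartments,
                            extractComponents(g), sidecar)
  tb <- lesionTable(predSet)
  expect_equal(tb$etiology_class, "physiologic")
  expect_equal(tb$etiology, "brown_adipose_tissue")
  expect_true(tb$annotated)
})

test_that("axial diameters follow the voxel-width convention", {
  one <- array(0L, c(6, 6, 6)); one[3, 3, 3] <- 1L
  s1 <- measureDiameter(extractComponents(LabelVolume(one, spacing = c(2, 2, 2))))
  expect_equal(lesionTable(s1)$diameter_mm, 2)

  line <- array(0L, c(12, 6, 6)); line[2:11, 3, 3] <- 1L
  s2 <- measureDiameter(extractComponents(LabelVolume(line, spacing = c(2, 2, 2))))
  expect_equal(lesionTable(s2)$diameter_mm, 20)

  # diameter is in-plane: a 10-voxel z-column still measures one voxel width
  col <- array(0L, c(6, 6, 12)); col[3, 3, 2:11] <- 1L
  s3 <- measureDiameter(extractComponents(LabelVolume(col, spacing = c(2, 2, 2))))
  expect_equal(lesionTable(s3)$diameter_mm, 2)
})
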