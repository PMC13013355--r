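#' @include staging.R
NULL

# Synthetic phantom cohorts: spherical lesions placed in disjoint
# axis-aligned compartment boxes (one box per nodal station or organ),
# then derailed by controllable error operators that emulate the
# characteristic failure modes of whole-body PET/CT segmentation models:
# deleted lesions (false negatives), taxonomy-tagged spurious components
# (false positives), per-lesion boundary dilation/erosion, a volume bias
# and hilar T-N1 merging. Spheres are used deliberately: diameter and
# volume are then analytically known, which makes oracle tests possible.

N1_STATIONS <- c("ipsilateral_hilar", "ipsilateral_peribronchial",
                 "ipsilateral_intrapulmonary")
INVASION_FLAGS_T4 <- c("mediastinum", "great_vessels", "vertebral_body")

#' Default phantom specification
#'
#' A whole-body-like 64x64x80 grid at 3 mm isotropic spacing with nine
#' disjoint compartments: one primary-tumour box (fixed one lesion per
#' patient), four nodal-station boxes (N1 hilar, two N2 stations, one
#' contralateral N3 station) and four metastatic-site boxes
#' (contralateral lung, liver, adrenal, bone). Poisson means are set so
#' cohorts average about 1.4 T, 2.8 N and 1.9 M lesions per patient,
#' matching the per-patient lesion load of a large treatment-naive
#' NSCLC staging cohort.
#'
#' @return a validated [PhantomSpec-class].
#' @export
defaultPhantomSpec <- function() {
  cp <- data.frame(
    compartment_id = 1:9,
    category = c("T", "T", "N", "N", "N", "N", "M", "M", "M"),
    label = c("lung", "lung", "ipsilateral_hilar", "ipsilateral_mediastinal",
              "subcarinal", "contralateral_mediastinal", "contralateral_lung",
              "liver", "adrenal_gland"),
    x0 = c(4, 4, 30, 40, 40, 48, 56, 8, 44),
    x1 = c(28, 28, 38, 46, 46, 54, 62, 40, 56),
    y0 = c(8, 34, 16, 16, 16, 16, 8, 8, 8),
    y1 = c(32, 56, 48, 48, 48, 48, 56, 48, 40),
    z0 = c(36, 36, 40, 40, 26, 40, 36, 8, 8),
    z1 = c(68, 68, 64, 64, 38, 64, 68, 24, 20),
    count_dist = c("fixed", "poisson", "poisson", "poisson", "poisson",
                   "poisson", "poisson", "poisson", "poisson"),
    count_param = c(1, 0.4, 0.9, 0.9, 0.5, 0.5, 0.35, 0.6, 0.6),
    stringsAsFactors = FALSE)
  PhantomSpec(gridShape = c(64, 64, 80), voxelSpacing = c(3, 3, 3),
              compartments = cp, radiusRange = c(4, 9),
              invasionProbability = 0.1)
}

#' Default error-injection configuration
#'
#' Per-category deletion rates, per-patient false-positive class means
#' and the hilar merge rate are calibrated to the aggregate error
#' counts of a published expert re-reading of a 306-patient NSCLC
#' cohort (e.g. 14 missed of 425 T lesions, 196 M-category false
#' positives of which 58 physiologic / 70 benign / 68 pathologic, and a
#' hilar T-N1 convergence in 11.1% of cases). Boundary perturbation and
#' volume bias default to zero/one.
#'
#' @return a validated [ErrorInjectionConfig-class].
#' @export
defaultErrorConfig <- function() {
  fp <- data.frame(
    category = c("T", "T", "N", "M", "M", "M"),
    etiology_class = c("pathologic", "pathologic", "benign",
                       "physiologic", "benign", "pathologic"),
    etiology = c("pulmonary_inflammation", "dystelectasis",
                 "unspecific_lymph_node", "physiologic_uptake",
                 "benign_lesion", "pathologic_non_oncologic"),
    count_dist = "poisson",
    count_param = c(18 / 306, 4 / 306, 37 / 306, 58 / 306, 70 / 306, 68 / 306),
    stringsAsFactors = FALSE)
  ErrorInjectionConfig(
    fnRate = c(T = 14 / 425, N = 25 / 853, M = 30 / 578),
    fpSpec = fp, dilateVoxels = 0L, erodeVoxels = 0L,
    hilarMergeRate = 0.111, volumeBias = 1)
}

#' @rdname defaultErrorConfig
#' @export
zeroErrorConfig <- function() ErrorInjectionConfig()

#' Render the compartment map of a phantom specification
#'
#' Each voxel carries 0 (background) or the id of the compartment box
#' containing it; boxes are validated to be pairwise disjoint.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [LabelVolume-class] of compartment ids.
#' @export
buildCompartmentMap <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  arr <- array(0L, dim = spec@gridShape)
  cp <- spec@compartments
  for (i in seq_len(nrow(cp))) {
    arr[(cp$x0[i] + 1):cp$x1[i], (cp$y0[i] + 1):cp$y1[i],
        (cp$z0[i] + 1):cp$z1[i]] <- as.integer(cp$compartment_id[i])
  }
  LabelVolume(arr, spacing = spec@voxelSpacing)
}

# linear voxel indices of a rasterized sphere (centre and radius in mm;
# voxel centres at (index - 0.5) * spacing, 1-based indices)
#' @keywords internal
#' @noRd
rasterizeSphere <- function(center, r, dims, sp) {
  lo <- pmax(1L, floor((center - r) / sp - 0.5) + 1L)
  hi <- pmin(dims, ceiling((center + r) / sp + 0.5))
  if (any(lo > hi)) return(integer())
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  cx <- (xs - 0.5) * sp[1] - center[1]
  cy <- (ys - 0.5) * sp[2] - center[2]
  cz <- (zs - 0.5) * sp[3] - center[3]
  d2 <- outer(outer(cx^2, cy^2, "+"), cz^2, "+")
  keep <- which(d2 <= r^2)
  if (!length(keep)) return(integer())
  co <- arrayInd(keep, c(length(xs), length(ys), length(zs)))
  as.integer((zs[co[, 3]] - 1) * dims[1] * dims[2] +
             (ys[co[, 2]] - 1) * dims[1] + xs[co[, 1]])
}

# draw a centre uniformly inside box i (mm), sphere fully inside the box
#' @keywords internal
#' @noRd
drawCenter <- function(cp, i, r, sp) {
  lo <- c(cp$x0[i], cp$y0[i], cp$z0[i]) * sp + r
  hi <- c(cp$x1[i], cp$y1[i], cp$z1[i]) * sp - r
  lo + stats::runif(3) * pmax(hi - lo, 0)
}

#' Sample a ground-truth phantom cohort
#'
#' Draws, for each patient, the per-compartment lesion count (fixed or
#' Poisson), places spherical lesions with radii uniform in the
#' configured mm range fully inside their compartment boxes and without
#' contact between lesions (bounded rejection sampling; a compartment
#' too small for a requested lesion raises a placement error), and
#' rasterizes them into an instance-labelled mask. Primary (T) lesions
#' carry a T4-relevant invasion flag with the configured probability.
#' Each patient draws from an independent random stream derived from
#' the master seed by a fixed offset, so identical `(spec, seed)` give
#' byte-identical cohorts.
#'
#' @param spec a [PhantomSpec-class].
#' @param nPatients number of patients (>= 1).
#' @param seed integer master seed.
#' @return list of cases; each case is a list with elements `patient_id`,
#'   `gt` (instance [LabelVolume-class]), `compartmentMap`,
#'   `lesionTable`, and `spec`.
#' @export
sampleGtCohort <- function(spec, nPatients, seed) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  if (nPatients < 1) stop("nPatients must be >= 1")
  cmap <- buildCompartmentMap(spec)
  cp <- spec@compartments
  sp <- spec@voxelSpacing
  dims <- spec@gridShape
  lapply(seq_len(nPatients), function(pi) {
    set.seed(patientSeed(seed, pi, salt = 1L))
    arr <- array(0L, dim = dims)
    rows <- list()
    centers <- matrix(numeric(), ncol = 3)
    radii <- numeric()
    margin <- 2 * max(sp)
    lid <- 0L
    for (i in seq_len(nrow(cp))) {
      nles <- if (cp$count_dist[i] == "fixed") as.integer(cp$count_param[i])
              else stats::rpois(1, cp$count_param[i])
      for (k in seq_len(nles)) {
        placed <- FALSE
        for (try in 1:200) {
          r <- stats::runif(1, spec@radiusRange[1], spec@radiusRange[2])
          cen <- drawCenter(cp, i, r, sp)
          ok <- !nrow(centers) ||
            all(sqrt(colSums((t(centers) - cen)^2)) > radii + r + margin)
          if (ok) { placed <- TRUE; break }
        }
        if (!placed)
          stop(sprintf("placement error: compartment %s cannot host another %.1f mm lesion",
                       cp$label[i], r))
        lid <- lid + 1L
        vox <- rasterizeSphere(cen, r, dims, sp)
        arr[vox] <- lid
        centers <- rbind(centers, cen)
        radii <- c(radii, r)
        inv <- NA_character_
        if (cp$category[i] == "T" && stats::runif(1) < spec@invasionProbability)
          inv <- sample(INVASION_FLAGS_T4, 1)
        rows[[lid]] <- data.frame(
          lesion_id = as.character(lid), source = "ground_truth",
          category = cp$category[i], station_or_organ = cp$label[i],
          compartment_id = cp$compartment_id[i],
          radius_mm = r, diameter_mm = 2 * r,
          center_x_mm = cen[1], center_y_mm = cen[2], center_z_mm = cen[3],
          invasion = inv, etiology_class = "tumour",
          etiology = NA_character_, stringsAsFactors = FALSE)
      }
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      cbind(emptyLesionTable()[, c("lesion_id", "source", "category",
                                   "station_or_organ")],
            data.frame(compartment_id = integer(), radius_mm = numeric(),
                       diameter_mm = numeric(), center_x_mm = numeric(),
                       center_y_mm = numeric(), center_z_mm = numeric(),
                       invasion = character(), etiology_class = character(),
                       etiology = character()))
    list(patient_id = sprintf("P%03d", pi),
         gt = LabelVolume(arr, spacing = sp),
         compartmentMap = cmap, lesionTable = tab, spec = spec)
  })
}

# one 6-connected binary dilation / erosion step on a logical array
#' @keywords internal
#' @noRd
morphStep <- function(a, dilate = TRUE) {
  d <- dim(a)
  out <- a
  comb <- if (dilate) `|` else `&`
  shift <- function(ax, by) {
    s <- array(if (dilate) FALSE else TRUE, dim = d)
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    n <- d[ax]
    if (by > 0) { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
    else { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
    s[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    s
  }
  for (ax in 1:3) for (by in c(-1, 1))
    out <- comb(out, shift(ax, by))
  out
}

#' @keywords internal
#' @noRd
morphLesion <- function(vox, dims, dilate = 0L, erode = 0L) {
  if ((dilate == 0L && erode == 0L) || !length(vox)) return(vox)
  pad <- dilate + erode + 1L
  co <- arrayInd(vox, dims)
  lo <- pmax(1L, apply(co, 2, min) - pad)
  hi <- pmin(dims, apply(co, 2, max) + pad)
  sub <- array(FALSE, dim = hi - lo + 1L)
  sub[cbind(co[, 1] - lo[1] + 1L, co[, 2] - lo[2] + 1L, co[, 3] - lo[3] + 1L)] <- TRUE
  for (i in seq_len(erode)) sub <- morphStep(sub, dilate = FALSE)
  for (i in seq_len(dilate)) sub <- morphStep(sub, dilate = TRUE)
  w <- which(sub)
  if (!length(w)) return(integer())
  cs <- arrayInd(w, dim(sub))
  as.integer((cs[, 3] + lo[3] - 2) * dims[1] * dims[2] +
             (cs[, 2] + lo[2] - 2) * dims[1] + (cs[, 1] + lo[1] - 1))
}

#' Inject segmentation errors into a phantom case
#'
#' Builds the predicted mask from the ground truth by (in order)
#' deleting lesions per-category at the configured false-negative rate,
#' re-rendering survivors under the volume bias, applying per-lesion
#' erosion then dilation (an erosion that annihilates a lesion is
#' logged as an implicit deletion, never silently dropped), optionally
#' fusing one surviving primary tumour with one surviving hilar (N1)
#' node through a bridging corridor, and adding taxonomy-tagged
#' false-positive spheres placed without contact with any true lesion.
#' Every operation is recorded in the injection log with the lesion ids
#' involved.
#'
#' @param case one case from [sampleGtCohort()].
#' @param config an [ErrorInjectionConfig-class].
#' @param seed integer seed for this case's error stream.
#' @return list with `pred` (binary [LabelVolume-class]),
#'   `injectionLog` and `fpTable` (metadata rows of injected FPs).
#' @export
injectErrors <- function(case, config, seed) {
  stopifnot(is(config, "ErrorInjectionConfig"))
  validObject(config)
  set.seed(seed)
  spec <- case$spec
  dims <- dim(case$gt@voxels)
  sp <- case$gt@spacing
  gtArr <- case$gt@voxels
  tab <- case$lesionTable
  log <- list()
  addLog <- function(op, lesion_id = NA, category = NA, etiology_class = NA,
                     etiology = NA, detail = NA) {
    log[[length(log) + 1L]] <<- data.frame(
      op = op, lesion_id = as.character(lesion_id),
      category = as.character(category),
      etiology_class = as.character(etiology_class),
      etiology = as.character(etiology), detail = as.character(detail),
      stringsAsFactors = FALSE)
  }

  # 1. deletions
  surv <- character()
  for (i in seq_len(nrow(tab))) {
    if (stats::runif(1) < config@fnRate[[tab$category[i]]]) {
      addLog("delete", tab$lesion_id[i], tab$category[i], detail = "fn_rate")
    } else surv <- c(surv, tab$lesion_id[i])
  }

  # 2. render survivors (volume bias, then erosion/dilation)
  pred <- array(FALSE, dim = dims)
  bias <- config@volumeBias
  for (id in surv) {
    row <- tab[tab$lesion_id == id, ]
    vox <- if (bias == 1) which(gtArr == as.integer(id))
    else rasterizeSphere(c(row$center_x_mm, row$center_y_mm, row$center_z_mm),
                         row$radius_mm * bias^(1 / 3), dims, sp)
    if (bias != 1)
      addLog("volume_bias", id, row$category, detail = sprintf("factor=%g", bias))
    vox <- morphLesion(vox, dims, dilate = config@dilateVoxels,
                       erode = config@erodeVoxels)
    if (config@erodeVoxels > 0 || config@dilateVoxels > 0)
      addLog(if (config@dilateVoxels > 0 && config@erodeVoxels == 0) "dilate"
             else if (config@erodeVoxels > 0 && config@dilateVoxels == 0) "erode"
             else "morph", id, row$category,
             detail = sprintf("dilate=%d erode=%d", config@dilateVoxels,
                              config@erodeVoxels))
    if (!length(vox)) {
      addLog("implicit_delete", id, row$category, detail = "erosion_annihilated")
      surv <- setdiff(surv, id)
      next
    }
    pred[vox] <- TRUE
  }

  # 3. hilar merge: bridge one surviving T lesion to one surviving N1 node
  corridor <- NULL
  if (config@hilarMergeRate > 0 && stats::runif(1) < config@hilarMergeRate) {
    sv <- tab[tab$lesion_id %in% surv, , drop = FALSE]
    tIds <- sv$lesion_id[sv$category == "T"]
    nIds <- sv$lesion_id[sv$category == "N" & sv$station_or_organ %in% N1_STATIONS]
    if (length(tIds) && length(nIds)) {
      tId <- if (length(tIds) == 1) tIds else sample(tIds, 1)
      nId <- if (length(nIds) == 1) nIds else sample(nIds, 1)
      a <- unlist(tab[tab$lesion_id == tId,
                      c("center_x_mm", "center_y_mm", "center_z_mm")])
      b <- unlist(tab[tab$lesion_id == nId,
                      c("center_x_mm", "center_y_mm", "center_z_mm")])
      rc <- 1.2 * max(sp)
      corridor <- list(a = a, b = b, r = rc)
      # rasterize a cylinder of radius rc around segment a-b
      lo <- pmax(1L, floor((pmin(a, b) - rc) / sp) + 1L)
      hi <- pmin(dims, ceiling((pmax(a, b) + rc) / sp))
      xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
      gridpts <- as.matrix(expand.grid(x = (xs - 0.5) * sp[1],
                                       y = (ys - 0.5) * sp[2],
                                       z = (zs - 0.5) * sp[3]))
      ab <- b - a
      tpar <- pmin(1, pmax(0, (sweep(gridpts, 2, a) %*% ab) / sum(ab^2)))
      nearest <- sweep(tpar %*% t(ab), 2, a, "+")
      d2 <- rowSums((gridpts - nearest)^2)
      sel <- which(d2 <= rc^2)
      co <- arrayInd(sel, c(length(xs), length(ys), length(zs)))
      lin <- (zs[co[, 3]] - 1) * dims[1] * dims[2] +
             (ys[co[, 2]] - 1) * dims[1] + xs[co[, 1]]
      pred[lin] <- TRUE
      addLog("hilar_merge", tId, "T", detail = sprintf("merged_with=%s", nId))
    }
  }

  # 4. false positives, placed clear of every true lesion and the corridor
  fpRows <- list()
  cp <- spec@compartments
  margin <- (2 + config@dilateVoxels) * max(sp)
  allCenters <- as.matrix(tab[, c("center_x_mm", "center_y_mm", "center_z_mm")])
  allRadii <- tab$radius_mm
  fpN <- 0L
  fs <- config@fpSpec
  for (i in seq_len(nrow(fs))) {
    n <- if (fs$count_dist[i] == "fixed") as.integer(fs$count_param[i])
         else stats::rpois(1, fs$count_param[i])
    boxes <- which(cp$category == fs$category[i])
    if (!length(boxes)) next
    for (k in seq_len(n)) {
      placed <- FALSE
      for (try in 1:200) {
        bi <- if (length(boxes) == 1) boxes else sample(boxes, 1)
        r <- stats::runif(1, spec@radiusRange[1], spec@radiusRange[2])
        cen <- drawCenter(cp, bi, r, sp)
        ok <- !nrow(allCenters) ||
          all(sqrt(colSums((t(allCenters) - cen)^2)) > allRadii + r + margin)
        if (ok && !is.null(corridor)) {
          ab <- corridor$b - corridor$a
          tt <- min(1, max(0, sum((cen - corridor$a) * ab) / sum(ab^2)))
          ok <- sqrt(sum((corridor$a + tt * ab - cen)^2)) >
            corridor$r + r + margin
        }
        if (ok) { placed <- TRUE; break }
      }
      if (!placed) {
        addLog("fp_skipped", NA, fs$category[i], fs$etiology_class[i],
               fs$etiology[i], "no_room")
        next
      }
      fpN <- fpN + 1L
      fid <- paste0("F", fpN)
      vox <- rasterizeSphere(cen, r, dims, sp)
      pred[vox] <- TRUE
      allCenters <- rbind(allCenters, cen)
      allRadii <- c(allRadii, r)
      addLog("fp", fid, fs$category[i], fs$etiology_class[i], fs$etiology[i],
             sprintf("compartment=%s", cp$label[bi]))
      fpRows[[fpN]] <- data.frame(
        lesion_id = fid, source = "injected_fp", category = fs$category[i],
        station_or_organ = cp$label[bi], compartment_id = cp$compartment_id[bi],
        radius_mm = r, diameter_mm = 2 * r,
        center_x_mm = cen[1], center_y_mm = cen[2], center_z_mm = cen[3],
        invasion = NA_character_, etiology_class = fs$etiology_class[i],
        etiology = fs$etiology[i], stringsAsFactors = FALSE)
    }
  }

  logDf <- if (length(log)) do.call(rbind, log) else
    data.frame(op = character(), lesion_id = character(),
               category = character(), etiology_class = character(),
               etiology = character(), detail = character(),
               stringsAsFactors = FALSE)
  fpTab <- if (length(fpRows)) do.call(rbind, fpRows) else NULL
  list(pred = LabelVolume(array(as.integer(pred), dim = dims), spacing = sp),
       injectionLog = logDf, fpTable = fpTab)
}

#' Simulate a complete phantom cohort
#'
#' Chains [sampleGtCohort()] and [injectErrors()] into a list of
#' [CaseBundle-class]s. The error stream of each patient is derived
#' from the same master seed by a fixed offset, independent of the
#' placement stream.
#'
#' @param spec a [PhantomSpec-class]; default [defaultPhantomSpec()].
#' @param config an [ErrorInjectionConfig-class]; default
#'   [defaultErrorConfig()].
#' @param nPatients cohort size.
#' @param seed integer master seed.
#' @return list of [CaseBundle-class]s.
#' @examples
#' \donttest{
#' cohort <- simulateCohort(nPatients = 2, seed = 7)
#' cohort[[1]]
#' }
#' @export
simulateCohort <- function(spec = defaultPhantomSpec(),
                           config = defaultErrorConfig(),
                           nPatients = 10, seed = 1) {
  cases <- sampleGtCohort(spec, nPatients, seed)
  lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    inj <- injectErrors(cs, config, seed = patientSeed(seed, i, salt = 2L))
    tab <- cs$lesionTable
    if (!is.null(inj$fpTable)) tab <- rbind(tab, inj$fpTable)
    new("CaseBundle", patientId = cs$patient_id, gt = cs$gt, pred = inj$pred,
        compartmentMap = cs$compartmentMap, lesionTable = tab,
        injectionLog = inj$injectionLog)
  })
}

#' Sidecar table of a simulated case
#'
#' Converts a [CaseBundle-class]'s lesion table into the canonical
#' sidecar schema: ground-truth rows carry category, station/organ and
#' invasion flags; injected false-positive rows carry their aetiology
#' class/label and a world-space marker point so the evaluator can
#' attach the annotation to the matching predicted component without
#' reading the injection log.
#'
#' @param bundle a [CaseBundle-class].
#' @return validated sidecar data.frame.
#' @export
caseSidecar <- function(bundle) {
  tab <- bundle@lesionTable
  sc <- data.frame(
    lesion_id = tab$lesion_id, category = tab$category,
    station_or_organ = tab$station_or_organ, invasion = tab$invasion,
    etiology_class = tab$etiology_class, etiology = tab$etiology,
    diameter_mm = NA_real_,
    center_x_mm = tab$center_x_mm, center_y_mm = tab$center_y_mm,
    center_z_mm = tab$center_z_mm, stringsAsFactors = FALSE)
  validateSidecar(sc)
}

# ---------------------------------------------------------------------------
# Config round trip (YAML or JSON)

#' Write / read a phantom configuration file
#'
#' Serializes a [PhantomSpec-class] and [ErrorInjectionConfig-class]
#' (plus cohort size) to YAML or JSON, and reads it back validated.
#'
#' @param spec a [PhantomSpec-class].
#' @param config an [ErrorInjectionConfig-class].
#' @param nPatients cohort size stored in the file.
#' @param path `.yaml`/`.yml` or `.json` path.
#' @return `writePhantomConfig()`: `path`; `readPhantomConfig()`: list
#'   with `spec`, `config`, `nPatients`.
#' @export
writePhantomConfig <- function(spec, config, nPatients, path) {
  x <- list(
    n_patients = nPatients,
    phantom = list(grid_shape = spec@gridShape,
                   voxel_spacing = spec@voxelSpacing,
                   radius_range_mm = spec@radiusRange,
                   invasion_probability = spec@invasionProbability,
                   compartments = spec@compartments),
    errors = list(fn_rate = as.list(config@fnRate),
                  fp_spec = config@fpSpec,
                  dilate_voxels = config@dilateVoxels,
                  erode_voxels = config@erodeVoxels,
                  hilar_merge_rate = config@hilarMergeRate,
                  volume_bias = config@volumeBias))
  if (tolower(tools::file_ext(path)) %in% c("yaml", "yml")) {
    x$phantom$compartments <- lapply(seq_len(nrow(spec@compartments)),
                                     function(i) as.list(spec@compartments[i, ]))
    x$errors$fp_spec <- lapply(seq_len(nrow(config@fpSpec)),
                               function(i) as.list(config@fpSpec[i, ]))
    yaml::write_yaml(x, path, precision = 12L)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' @rdname writePhantomConfig
#' @export
readPhantomConfig <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  x <- if (tolower(tools::file_ext(path)) %in% c("yaml", "yml"))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  cpRaw <- x$phantom$compartments
  cp <- if (is.data.frame(cpRaw)) cpRaw else
    do.call(rbind, lapply(cpRaw, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  fsRaw <- x$errors$fp_spec
  fs <- if (is.data.frame(fsRaw)) fsRaw
        else if (length(fsRaw)) do.call(rbind, lapply(fsRaw, function(r)
          as.data.frame(r, stringsAsFactors = FALSE)))
        else emptyFpSpec()
  spec <- PhantomSpec(gridShape = unlist(x$phantom$grid_shape),
                      voxelSpacing = unlist(x$phantom$voxel_spacing),
                      compartments = cp,
                      radiusRange = unlist(x$phantom$radius_range_mm),
                      invasionProbability = x$phantom$invasion_probability)
  config <- ErrorInjectionConfig(
    fnRate = unlist(x$errors$fn_rate), fpSpec = fs,
    dilateVoxels = x$errors$dilate_voxels, erodeVoxels = x$errors$erode_voxels,
    hilarMergeRate = x$errors$hilar_merge_rate,
    volumeBias = x$errors$volume_bias)
  list(spec = spec, config = config, nPatients = x$n_patients)
}
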