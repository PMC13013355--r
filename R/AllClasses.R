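#' @include utils.R
NULL

# Category scales used throughout the package. T/N/M levels follow the
# 9th-edition vocabulary (N2 split into N2a/N2b; M1c for multiple
# extrathoracic lesions); UICC stage groups are ordinal IA1 < ... < IVB.

#' Ordered category levels
#'
#' Level sets for T/N/M categories, the UICC stage scale, the lesion
#' compartment categories and the false-positive aetiology taxonomy.
#' `uiccLevels()` is the ordinal scale on which stage migration and
#' decision boundaries are defined.
#'
#' @return character vector of levels, in increasing order where the
#'   scale is ordinal.
#' @examples
#' uiccLevels()
#' @export
uiccLevels <- function() c("IA1", "IA2", "IA3", "IB", "IIA", "IIB",
                           "IIIA", "IIIB", "IIIC", "IVA", "IVB")

#' @rdname uiccLevels
#' @export
tLevels <- function() c("Tx", "T1mi", "T1a", "T1b", "T1c", "T2a", "T2b", "T3", "T4")

#' @rdname uiccLevels
#' @export
nLevels <- function() c("N0", "N1", "N2a", "N2b", "N3")

#' @rdname uiccLevels
#' @export
mLevels <- function() c("M0", "M1a", "M1b", "M1c")

#' @rdname uiccLevels
#' @export
categoryLevels <- function() c("T", "N", "M")

#' @rdname uiccLevels
#' @export
etiologyLevels <- function() c("tumour", "physiologic", "benign", "pathologic")

# ---------------------------------------------------------------------------
# LabelVolume

#' LabelVolume: a 3D integer label grid with geometry
#'
#' Carrier for segmentation masks: a 3D array of non-negative integers
#' (0 = background; positive values are instance labels or 1 for binary
#' masks) together with voxel spacing in mm, world origin in mm and the
#' axis orientation code of the canonical frame. All package internals
#' operate in voxel space after asserting that paired volumes share grid
#' shape and spacing; volumes read from disk are reoriented to the
#' canonical `"RAS"` convention first.
#'
#' @slot voxels 3D integer array.
#' @slot spacing numeric length-3, mm per voxel along each axis (> 0).
#' @slot origin numeric length-3, world-space mm offset of voxel (0,0,0).
#' @slot orientation character scalar, axis convention (canonically "RAS").
#' @export
setClass("LabelVolume",
  representation(voxels = "array", spacing = "numeric",
                 origin = "numeric", orientation = "character"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), orientation = "RAS"))

setValidity("LabelVolume", function(object) {
  msgs <- character()
  if (length(dim(object@voxels)) != 3L)
    msgs <- c(msgs, "voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msgs <- c(msgs, "spacing must be 3 strictly positive numbers")
  if (length(object@origin) != 3L)
    msgs <- c(msgs, "origin must have length 3")
  v <- object@voxels
  if (!(is.integer(v) || (is.numeric(v) && all(v == round(v)))))
    msgs <- c(msgs, "voxel values must be integers")
  else if (any(v < 0)) msgs <- c(msgs, "voxel values must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a LabelVolume
#'
#' @param voxels 3D integer array (0 background).
#' @param spacing numeric(3), mm per axis.
#' @param origin numeric(3), mm world offset; default zeros.
#' @param orientation axis convention label; default "RAS".
#' @return A [LabelVolume-class] object.
#' @examples
#' v <- LabelVolume(array(0L, c(4, 4, 4)), spacing = c(2, 2, 2))
#' spacing(v)
#' @export
LabelVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        orientation = "RAS") {
  storage.mode(voxels) <- "integer"
  new("LabelVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation)
}

#' @rdname LabelVolume
#' @param x,object a `LabelVolume`.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname LabelVolume
#' @export
setMethod("voxels", "LabelVolume", function(x) x@voxels)

#' @rdname LabelVolume
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname LabelVolume
#' @export
setMethod("spacing", "LabelVolume", function(x) x@spacing)

#' @rdname LabelVolume
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname LabelVolume
#' @export
setMethod("origin", "LabelVolume", function(x) x@origin)

#' Voxel volume in mm^3 / volume conversion helpers
#'
#' @param x a `LabelVolume` or numeric spacing vector.
#' @return `voxelVolumeMm3()`: scalar mm^3 per voxel.
#' @export
voxelVolumeMm3 <- function(x) {
  sp <- if (is(x, "LabelVolume")) x@spacing else as.numeric(x)
  prod(sp)
}

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  fg <- sum(object@voxels > 0)
  cat(sprintf("LabelVolume %dx%dx%d voxels, spacing %s mm, %s foreground voxel(s), %d label(s)\n",
              d[1], d[2], d[3], paste(format(object@spacing), collapse = "x"),
              format(fg), length(setdiff(unique(as.vector(object@voxels)), 0L))))
})

# ---------------------------------------------------------------------------
# LesionSet

#' LesionSet: connected components of a label volume
#'
#' One row per lesion (connected component of a positive label) with its
#' voxel count, volume in mL and, once computed, axial diameter, T/N/M
#' category, station/organ and aetiology. Voxel membership is kept as
#' linear indices into the source grid so that matching and category
#' assignment stay exact.
#'
#' @slot table data.frame with columns `lesion_id`, `source`
#'   ("ground_truth"/"predicted"), `voxel_count`, `volume_mL` and the
#'   annotation columns `diameter_mm`, `category`, `station_or_organ`,
#'   `invasion`, `etiology_class`, `etiology`, `annotated`.
#' @slot voxelIndex named list of integer vectors (linear voxel indices).
#' @slot dim integer(3) grid shape.
#' @slot spacing numeric(3) mm.
#' @export
setClass("LesionSet",
  representation(table = "data.frame", voxelIndex = "list",
                 dim = "integer", spacing = "numeric"))

setValidity("LesionSet", function(object) {
  tb <- object@table
  msgs <- character()
  need <- c("lesion_id", "source", "voxel_count", "volume_mL")
  if (!all(need %in% names(tb)))
    msgs <- c(msgs, paste("table must contain columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(tb$lesion_id)) msgs <- c(msgs, "lesion_id must be unique")
    if (nrow(tb) != length(object@voxelIndex))
      msgs <- c(msgs, "one voxel index vector per lesion required")
    if (nrow(tb) && any(tb$voxel_count < 1))
      msgs <- c(msgs, "every lesion must contain at least one voxel")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname LesionSet-class
#' @param object a `LesionSet`.
#' @export
setGeneric("lesionTable", function(object) standardGeneric("lesionTable"))
#' @rdname LesionSet-class
#' @export
setMethod("lesionTable", "LesionSet", function(object) object@table)

#' @rdname LesionSet-class
#' @export
setGeneric("nLesions", function(object) standardGeneric("nLesions"))
#' @rdname LesionSet-class
#' @export
setMethod("nLesions", "LesionSet", function(object) nrow(object@table))

setMethod("show", "LesionSet", function(object) {
  cat(sprintf("LesionSet of %d lesion(s) (%s), grid %s\n",
              nrow(object@table),
              if (nrow(object@table)) object@table$source[1] else "empty",
              paste(object@dim, collapse = "x")))
  if (nrow(object@table))
    print(utils::head(object@table[, c("lesion_id", "voxel_count", "volume_mL",
                                       "category", "station_or_organ")], 8))
})

# ---------------------------------------------------------------------------
# MatchResult

#' MatchResult: TP/FN/FP partition of lesions for one case
#'
#' Records which predicted components overlap which ground-truth lesions.
#' Every ground-truth lesion is either detected (appears in `tpPairs`) or
#' a false negative; every predicted component is either matched or a
#' false positive. A predicted component overlapping more than one
#' ground-truth lesion is a merge event: it detects all of them but
#' counts once on the prediction side.
#'
#' @slot tpPairs data.frame `gt_id`, `pred_id`, `overlap_voxels`.
#' @slot fnIds character, undetected ground-truth lesion ids.
#' @slot fpIds character, unmatched predicted component ids.
#' @slot mergeEvents data.frame `pred_id`, `n_gt`, `gt_ids` (";"-joined).
#' @export
setClass("MatchResult",
  representation(tpPairs = "data.frame", fnIds = "character",
                 fpIds = "character", mergeEvents = "data.frame"))

setValidity("MatchResult", function(object) {
  msgs <- character()
  if (!all(c("gt_id", "pred_id", "overlap_voxels") %in% names(object@tpPairs)))
    msgs <- c(msgs, "tpPairs must have gt_id, pred_id, overlap_voxels")
  else {
    if (length(intersect(unique(object@tpPairs$gt_id), object@fnIds)))
      msgs <- c(msgs, "a ground-truth lesion cannot be both matched and FN")
    if (length(intersect(unique(object@tpPairs$pred_id), object@fpIds)))
      msgs <- c(msgs, "a predicted component cannot be both matched and FP")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: %d detected gt lesion(s), %d FN, %d FP, %d merge event(s)\n",
              length(unique(object@tpPairs$gt_id)), length(object@fnIds),
              length(object@fpIds), nrow(object@mergeEvents)))
})

# ---------------------------------------------------------------------------
# PhantomSpec / ErrorInjectionConfig / CaseBundle

#' PhantomSpec: geometry and sampling plan for synthetic cohorts
#'
#' Defines the voxel grid, the axis-aligned compartment boxes (each tied
#' to a T/N/M category and a station or organ label), how many spherical
#' lesions to draw per compartment (fixed count or Poisson mean), the
#' lesion radius range in mm and the probability that a primary tumour
#' carries a T4-relevant invasion flag. Compartment boxes are 0-based,
#' half-open voxel intervals, so a box volume is
#' `(x1-x0)*(y1-y0)*(z1-z0)` voxels.
#'
#' @slot gridShape integer(3) voxels per axis.
#' @slot voxelSpacing numeric(3) mm per axis.
#' @slot compartments data.frame with columns `compartment_id`,
#'   `category` (T/N/M), `label` (station or organ),
#'   `x0,x1,y0,y1,z0,z1` (0-based half-open voxel bounds),
#'   `count_dist` ("fixed"/"poisson"), `count_param`.
#' @slot radiusRange numeric(2) lesion radius min/max in mm.
#' @slot invasionProbability fraction of primary (T) lesions flagged as
#'   invading a T4-relevant structure.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSpacing = "numeric",
                 compartments = "data.frame", radiusRange = "numeric",
                 invasionProbability = "numeric"))

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1))
    msgs <- c(msgs, "gridShape must be 3 positive integers")
  if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
    msgs <- c(msgs, "voxelSpacing must be 3 positive numbers")
  cp <- object@compartments
  need <- c("compartment_id", "category", "label", "x0", "x1", "y0", "y1",
            "z0", "z1", "count_dist", "count_param")
  if (!all(need %in% names(cp))) {
    msgs <- c(msgs, paste("compartments must contain:", paste(need, collapse = ", ")))
    return(msgs)
  }
  if (nrow(cp)) {
    if (anyDuplicated(cp$compartment_id)) msgs <- c(msgs, "compartment_id must be unique")
    if (!all(cp$category %in% categoryLevels()))
      msgs <- c(msgs, "compartment category must be one of T, N, M")
    if (any(cp$x1 <= cp$x0 | cp$y1 <= cp$y0 | cp$z1 <= cp$z0))
      msgs <- c(msgs, "compartment boxes must have positive extent")
    if (any(cp$x0 < 0 | cp$y0 < 0 | cp$z0 < 0) ||
        any(cp$x1 > object@gridShape[1] | cp$y1 > object@gridShape[2] |
            cp$z1 > object@gridShape[3]))
      msgs <- c(msgs, "compartment boxes must lie inside the grid")
    if (!all(cp$count_dist %in% c("fixed", "poisson")))
      msgs <- c(msgs, "count_dist must be 'fixed' or 'poisson'")
    if (any(cp$count_param < 0)) msgs <- c(msgs, "count_param must be non-negative")
    # pairwise disjoint boxes
    if (nrow(cp) > 1) {
      for (i in seq_len(nrow(cp) - 1)) for (j in (i + 1):nrow(cp)) {
        ov <- cp$x0[i] < cp$x1[j] && cp$x0[j] < cp$x1[i] &&
              cp$y0[i] < cp$y1[j] && cp$y0[j] < cp$y1[i] &&
              cp$z0[i] < cp$z1[j] && cp$z0[j] < cp$z1[i]
        if (ov) msgs <- c(msgs, sprintf("compartment boxes %s and %s overlap",
                                        cp$compartment_id[i], cp$compartment_id[j]))
      }
    }
    # radius range must fit inside the smallest compartment box
    ext <- pmin((cp$x1 - cp$x0) * object@voxelSpacing[1],
                (cp$y1 - cp$y0) * object@voxelSpacing[2],
                (cp$z1 - cp$z0) * object@voxelSpacing[3])
    if (length(object@radiusRange) == 2L && 2 * object@radiusRange[2] > min(ext))
      msgs <- c(msgs, "maximum lesion diameter exceeds the smallest compartment box")
  }
  if (length(object@radiusRange) != 2L || any(object@radiusRange <= 0) ||
      object@radiusRange[1] > object@radiusRange[2])
    msgs <- c(msgs, "radiusRange must be increasing and positive")
  if (object@invasionProbability < 0 || object@invasionProbability > 1)
    msgs <- c(msgs, "invasionProbability must be in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' @rdname PhantomSpec-class
#' @param gridShape,voxelSpacing,compartments,radiusRange,invasionProbability
#'   see slot documentation.
#' @return a validated `PhantomSpec`.
#' @export
PhantomSpec <- function(gridShape, voxelSpacing, compartments,
                        radiusRange = c(4, 9), invasionProbability = 0.1) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSpacing = as.numeric(voxelSpacing),
      compartments = as.data.frame(compartments),
      radiusRange = as.numeric(radiusRange),
      invasionProbability = as.numeric(invasionProbability))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: grid %s @ %s mm, %d compartment(s), radii %.1f-%.1f mm\n",
              paste(object@gridShape, collapse = "x"),
              paste(format(object@voxelSpacing), collapse = "x"),
              nrow(object@compartments),
              object@radiusRange[1], object@radiusRange[2]))
})

#' ErrorInjectionConfig: failure modes applied to a ground-truth case
#'
#' Controls how a synthetic prediction is derailed from its ground truth:
#' per-category false-negative (deletion) probabilities, a plan of
#' taxonomy-tagged false-positive components, per-lesion boundary
#' dilation/erosion in voxels, the probability of fusing a primary
#' tumour with an adjacent hilar (N1) node into one predicted component,
#' and a multiplicative volume bias applied to surviving lesions.
#'
#' @slot fnRate named numeric, deletion probability per category (T/N/M).
#' @slot fpSpec data.frame `category`, `etiology_class` (physiologic /
#'   benign / pathologic), `etiology` label, `count_dist`, `count_param`
#'   (per-patient count distribution).
#' @slot dilateVoxels,erodeVoxels non-negative integer boundary
#'   perturbation applied to every surviving lesion.
#' @slot hilarMergeRate probability in \[0,1\] of one T-N1 merge per case.
#' @slot volumeBias multiplicative volume factor (> 0) for surviving
#'   lesions (1 = unbiased).
#' @export
setClass("ErrorInjectionConfig",
  representation(fnRate = "numeric", fpSpec = "data.frame",
                 dilateVoxels = "integer", erodeVoxels = "integer",
                 hilarMergeRate = "numeric", volumeBias = "numeric"))

setValidity("ErrorInjectionConfig", function(object) {
  msgs <- character()
  if (!all(categoryLevels() %in% names(object@fnRate)))
    msgs <- c(msgs, "fnRate must be named with T, N, M")
  if (any(object@fnRate < 0 | object@fnRate > 1))
    msgs <- c(msgs, "fnRate values must be in [0,1]")
  fs <- object@fpSpec
  need <- c("category", "etiology_class", "etiology", "count_dist", "count_param")
  if (!all(need %in% names(fs)))
    msgs <- c(msgs, paste("fpSpec must contain:", paste(need, collapse = ", ")))
  else if (nrow(fs)) {
    if (!all(fs$category %in% categoryLevels()))
      msgs <- c(msgs, "fpSpec category must be T, N or M")
    if (!all(fs$etiology_class %in% c("physiologic", "benign", "pathologic")))
      msgs <- c(msgs, "fpSpec etiology_class must be physiologic/benign/pathologic")
    if (!all(fs$count_dist %in% c("fixed", "poisson")))
      msgs <- c(msgs, "fpSpec count_dist must be 'fixed' or 'poisson'")
    if (any(fs$count_param < 0)) msgs <- c(msgs, "fp counts must be non-negative")
  }
  if (object@dilateVoxels < 0 || object@erodeVoxels < 0)
    msgs <- c(msgs, "dilate/erode voxels must be non-negative")
  if (object@hilarMergeRate < 0 || object@hilarMergeRate > 1)
    msgs <- c(msgs, "hilarMergeRate must be in [0,1]")
  if (object@volumeBias <= 0) msgs <- c(msgs, "volumeBias must be positive")
  if (length(msgs)) msgs else TRUE
})

#' @rdname ErrorInjectionConfig-class
#' @param fnRate,fpSpec,dilateVoxels,erodeVoxels,hilarMergeRate,volumeBias
#'   see slot documentation.
#' @return a validated `ErrorInjectionConfig`.
#' @export
ErrorInjectionConfig <- function(fnRate = c(T = 0, N = 0, M = 0),
                                 fpSpec = emptyFpSpec(),
                                 dilateVoxels = 0L, erodeVoxels = 0L,
                                 hilarMergeRate = 0, volumeBias = 1) {
  if (length(fnRate) == 1L && is.null(names(fnRate)))
    fnRate <- c(T = unname(fnRate), N = unname(fnRate), M = unname(fnRate))
  new("ErrorInjectionConfig", fnRate = fnRate,
      fpSpec = as.data.frame(fpSpec),
      dilateVoxels = as.integer(dilateVoxels),
      erodeVoxels = as.integer(erodeVoxels),
      hilarMergeRate = as.numeric(hilarMergeRate),
      volumeBias = as.numeric(volumeBias))
}

#' @rdname ErrorInjectionConfig-class
#' @export
emptyFpSpec <- function() {
  data.frame(category = character(), etiology_class = character(),
             etiology = character(), count_dist = character(),
             count_param = numeric(), stringsAsFactors = FALSE)
}

setMethod("show", "ErrorInjectionConfig", function(object) {
  cat(sprintf(paste0("ErrorInjectionConfig: fnRate T=%.3f N=%.3f M=%.3f, %d FP class(es), ",
                     "dilate=%d erode=%d, hilarMergeRate=%.3f, volumeBias=%.2f\n"),
              object@fnRate[["T"]], object@fnRate[["N"]], object@fnRate[["M"]],
              nrow(object@fpSpec), object@dilateVoxels, object@erodeVoxels,
              object@hilarMergeRate, object@volumeBias))
})

#' CaseBundle: one synthetic patient
#'
#' Holds the paired ground-truth instance mask, the (error-injected)
#' binary predicted mask, the compartment map, the per-lesion metadata
#' table (including aetiology tags for injected false positives) and the
#' complete injection log.
#'
#' @slot patientId character scalar.
#' @slot gt instance-labelled [LabelVolume-class].
#' @slot pred binary [LabelVolume-class].
#' @slot compartmentMap [LabelVolume-class] of compartment ids.
#' @slot lesionTable per-lesion metadata data.frame.
#' @slot injectionLog data.frame of every applied error operator.
#' @export
setClass("CaseBundle",
  representation(patientId = "character", gt = "LabelVolume",
                 pred = "LabelVolume", compartmentMap = "LabelVolume",
                 lesionTable = "data.frame", injectionLog = "data.frame"))

setValidity("CaseBundle", function(object) {
  msgs <- character()
  gtIds <- sort(setdiff(unique(as.vector(object@gt@voxels)), 0L))
  tabIds <- object@lesionTable$lesion_id[object@lesionTable$source == "ground_truth"]
  if (!setequal(as.character(gtIds), as.character(tabIds)) ||
      anyDuplicated(tabIds))
    msgs <- c(msgs, "every gt instance id must appear in lesionTable exactly once")
  lg <- object@injectionLog
  if (nrow(lg) || length(gtIds)) {
    nDel <- sum(lg$op %in% c("delete", "implicit_delete"))
    nSurv <- length(gtIds) - nDel
    if (nSurv < 0)
      msgs <- c(msgs, "logged deletions exceed ground-truth lesion count")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CaseBundle", function(object) {
  cat(sprintf("CaseBundle %s: %d gt lesion(s), %d log entries\n",
              object@patientId,
              length(setdiff(unique(as.vector(object@gt@voxels)), 0L)),
              nrow(object@injectionLog)))
})

# ---------------------------------------------------------------------------
# StageRules

#' StageRules: the encoded staging rule book
#'
#' All tables needed to derive T, N and M categories from a lesion set
#' and to map a TNM triple to a UICC stage group. Shipped as a versioned
#' JSON data file (builtin id `"ninth_edition"`); the file is the single
#' source of truth and is schema-validated on load: size thresholds must
#' be strictly increasing, the UICC lookup must be total over the
#' category cross-product, and the stage group must be non-decreasing
#' when exactly one of T/N/M increases.
#'
#' @slot tSizeThresholds data.frame `max_cm` (increasing; NA = no upper
#'   bound), `t` category for the largest lesion diameter.
#' @slot invasionMap named character: invasion flag -> minimum T category.
#' @slot nStationMap named character: nodal station label -> base N level
#'   ("N1", "N2", "N3"); N2 is subdivided into N2a (single station) and
#'   N2b (multiple stations) at derivation time.
#' @slot mSiteClass named character: metastatic site label ->
#'   "intrathoracic" (M1a) or "extrathoracic" (M1b/M1c by multiplicity).
#' @slot uiccLookup data.frame `t`, `n`, `m`, `stage` covering every
#'   combination of [tLevels()], [nLevels()], [mLevels()].
#' @slot edition character id, e.g. "ninth_edition".
#' @slot version character version string of the rules file.
#' @export
setClass("StageRules",
  representation(tSizeThresholds = "data.frame", invasionMap = "character",
                 nStationMap = "character", mSiteClass = "character",
                 uiccLookup = "data.frame", edition = "character",
                 version = "character"))

setValidity("StageRules", function(object) {
  msgs <- character()
  th <- object@tSizeThresholds
  if (!all(c("max_cm", "t") %in% names(th)))
    msgs <- c(msgs, "tSizeThresholds needs columns max_cm, t")
  else {
    fin <- th$max_cm[!is.na(th$max_cm)]
    if (is.unsorted(fin, strictly = TRUE))
      msgs <- c(msgs, "tSizeThresholds max_cm must be strictly increasing")
    if (!all(th$t %in% tLevels()))
      msgs <- c(msgs, "tSizeThresholds categories must be valid T levels")
  }
  if (!all(object@nStationMap %in% c("N1", "N2", "N3")))
    msgs <- c(msgs, "nStationMap values must be N1, N2 or N3")
  if (!all(object@mSiteClass %in% c("intrathoracic", "extrathoracic")))
    msgs <- c(msgs, "mSiteClass values must be intrathoracic or extrathoracic")
  lk <- object@uiccLookup
  if (!all(c("t", "n", "m", "stage") %in% names(lk))) {
    msgs <- c(msgs, "uiccLookup needs columns t, n, m, stage")
    return(msgs)
  }
  full <- expand.grid(t = tLevels(), n = nLevels(), m = mLevels(),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$t, d$n, d$m)
  missing <- setdiff(key(full), key(lk))
  if (length(missing))
    msgs <- c(msgs, sprintf("uiccLookup is not total; missing cell(s): %s",
                            paste(utils::head(missing, 3), collapse = "; ")))
  if (anyDuplicated(key(lk))) msgs <- c(msgs, "uiccLookup has duplicate cells")
  if (!all(lk$stage %in% uiccLevels()))
    msgs <- c(msgs, "uiccLookup stages must be valid UICC levels")
  if (!length(missing) && !anyDuplicated(key(lk))) {
    # monotonicity: stage non-decreasing when exactly one axis increases
    ord <- array(NA_integer_, dim = c(length(tLevels()), length(nLevels()),
                                      length(mLevels())))
    idx <- cbind(match(lk$t, tLevels()), match(lk$n, nLevels()),
                 match(lk$m, mLevels()))
    ord[idx] <- match(lk$stage, uiccLevels())
    mono <- all(apply(ord, c(2, 3), function(v) !is.unsorted(v))) &&
            all(apply(ord, c(1, 3), function(v) !is.unsorted(v))) &&
            all(apply(ord, c(1, 2), function(v) !is.unsorted(v)))
    if (!mono)
      msgs <- c(msgs, "uiccLookup violates monotonicity in T, N or M")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "StageRules", function(object) {
  cat(sprintf("StageRules '%s' (version %s): %d size thresholds, %d invasion flags, %d stations, %d metastatic sites, %d lookup cells\n",
              object@edition, object@version, nrow(object@tSizeThresholds),
              length(object@invasionMap), length(object@nStationMap),
              length(object@mSiteClass), nrow(object@uiccLookup)))
})
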