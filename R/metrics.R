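#' @include lesions.R
NULL

# Voxel-level and lesion-level figures of merit. Voxel metrics (Dice,
# FNV, FPV, TMTV) follow the component-based challenge definitions: FNV
# sums ground-truth lesions with zero overlapping prediction, FPV sums
# predicted components with zero ground-truth overlap. Lesion metrics
# (sensitivity, precision) count whole components.

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)` over binarized foreground. Two empty
#' masks give 1.0 by convention (with a warning): agreement on the
#' absence of disease is not penalized. Set `bothEmpty` to change this.
#'
#' @param gt,pred [LabelVolume-class]s (or 3D arrays) on the same grid.
#' @param bothEmpty value returned when both masks are empty.
#' @return Dice coefficient in \[0, 1\].
#' @examples
#' a <- array(0L, c(2, 2, 2)); b <- a
#' a[1:2, 1, 1] <- 1L; b[1:2, 1, 1] <- 1L
#' dice(LabelVolume(a), LabelVolume(b))
#' @export
dice <- function(gt, pred, bothEmpty = 1) {
  ga <- if (is(gt, "LabelVolume")) gt@voxels else gt
  pa <- if (is(pred, "LabelVolume")) pred@voxels else pred
  if (is(gt, "LabelVolume") && is(pred, "LabelVolume"))
    assertSameGrid(gt, pred)
  else if (!identical(dim(ga), dim(pa)))
    stop("grid mismatch: masks have different shapes")
  g <- ga > 0L; p <- pa > 0L
  sg <- sum(g); sp <- sum(p)
  if (sg + sp == 0) {
    warning("both masks empty; Dice defined as ", bothEmpty, " by convention")
    return(bothEmpty)
  }
  2 * sum(g & p) / (sg + sp)
}

#' False negative and false positive volume
#'
#' FNV: total volume (mL) of ground-truth lesions with no overlapping
#' predicted component. FPV: total volume of predicted components with
#' no ground-truth overlap. Both are component-based, driven by the
#' [MatchResult-class] partition.
#'
#' @param gtSet,predSet [LesionSet-class]s used in the match.
#' @param match a [MatchResult-class].
#' @return volume in mL.
#' @export
fnv <- function(gtSet, match) {
  tb <- gtSet@table
  sum(tb$volume_mL[tb$lesion_id %in% match@fnIds])
}

#' @rdname fnv
#' @export
fpv <- function(predSet, match) {
  tb <- predSet@table
  sum(tb$volume_mL[tb$lesion_id %in% match@fpIds])
}

#' Total metabolic tumour volume
#'
#' Sum of all segmented lesion volumes of one patient, in mL.
#'
#' @param lesionSet a [LesionSet-class] (or its table).
#' @return TMTV in mL (0 for an empty set).
#' @export
tmtv <- function(lesionSet) {
  tb <- if (is(lesionSet, "LesionSet")) lesionSet@table else lesionSet
  if (!nrow(tb)) return(0)
  sum(tb$volume_mL)
}

#' Per-case voxel metrics
#'
#' Convenience bundle of Dice, FNV, FPV and both TMTVs for one case.
#'
#' @param gt,pred [LabelVolume-class]s on the same grid.
#' @param gtSet,predSet,match optional precomputed decomposition/match
#'   (recomputed with defaults when missing).
#' @param connectivity passed to [extractComponents()] when recomputing.
#' @return one-row data.frame: `dsc`, `fnv_mL`, `fpv_mL`, `tmtv_gt_mL`,
#'   `tmtv_pred_mL`.
#' @export
voxelMetrics <- function(gt, pred, gtSet = NULL, predSet = NULL,
                         match = NULL, connectivity = 26L) {
  assertSameGrid(gt, pred)
  if (is.null(gtSet)) gtSet <- extractComponents(gt, connectivity, "ground_truth")
  if (is.null(predSet)) predSet <- extractComponents(pred, connectivity, "predicted")
  if (is.null(match)) match <- matchLesions(gtSet, predSet)
  d <- if (nLesions(gtSet) + nLesions(predSet) == 0)
    suppressWarnings(dice(gt, pred)) else dice(gt, pred)
  data.frame(dsc = d, fnv_mL = fnv(gtSet, match), fpv_mL = fpv(predSet, match),
             tmtv_gt_mL = tmtv(gtSet), tmtv_pred_mL = tmtv(predSet))
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean of (predicted - ground truth); limits of agreement
#' are bias +/- 1.96 sample (n-1) standard deviations of the
#' differences.
#'
#' @param gtValues,predValues paired numeric vectors (>= 2 pairs), e.g.
#'   per-patient TMTVs.
#' @return data.frame `bias_mL`, `loa_low_mL`, `loa_high_mL`, `n`.
#' @examples
#' blandAltman(c(10, 20), c(12, 18))  # differences +2, -2
#' @export
blandAltman <- function(gtValues, predValues) {
  if (length(gtValues) != length(predValues))
    stop("gtValues and predValues must be paired")
  if (length(gtValues) < 2)
    stop("Bland-Altman analysis requires at least 2 pairs")
  d <- predValues - gtValues
  bias <- mean(d)
  s <- stats::sd(d)
  data.frame(bias_mL = bias, loa_low_mL = bias - 1.96 * s,
             loa_high_mL = bias + 1.96 * s, n = length(d))
}

# ---------------------------------------------------------------------------
# Detection statistics

#' Lesion-level detection statistics
#'
#' Computes true positive / false negative / false positive counts and
#' the derived sensitivity (detected ground-truth lesions over all
#' ground-truth lesions) and precision (matched predicted components
#' over all predicted components) per T/N/M category and pooled. Pooled
#' values are micro-averages over summed counts; a per-patient
#' macro-averaged sensitivity is reported alongside. A category with no
#' ground-truth lesion has undefined sensitivity, reported as `NA`, not
#' 0. Percentages are rounded to one decimal, half away from zero.
#'
#' Merged predicted components detect every overlapped ground-truth
#' lesion (each counts toward `tp`) but appear once in the precision
#' denominator (`tp_pred`), so `tp` and `tp_pred` can differ when merge
#' events occur.
#'
#' @param records a detection-record data.frame, one row per lesion and
#'   side, with columns `patient_id`, `side` ("gt"/"pred"), `category`,
#'   `matched` (logical). Build from evaluated cases with
#'   [detectionRecords()] or from printed count tables with
#'   [countsToRecords()].
#' @return data.frame with one row per category plus a `"pooled"` row:
#'   `tp`, `fn`, `tp_pred`, `fp`, `sensitivity_pct`, `precision_pct`,
#'   and for the pooled row `macro_sensitivity_pct`.
#' @export
detectionStats <- function(records) {
  stopifnot(all(c("patient_id", "side", "category", "matched") %in% names(records)))
  cats <- categoryLevels()
  rows <- lapply(cats, function(cg) {
    g <- records[records$side == "gt" & records$category == cg, , drop = FALSE]
    p <- records[records$side == "pred" & records$category == cg, , drop = FALSE]
    data.frame(category = cg,
               tp = sum(g$matched), fn = sum(!g$matched),
               tp_pred = sum(p$matched), fp = sum(!p$matched),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pooled <- data.frame(category = "pooled", tp = sum(out$tp), fn = sum(out$fn),
                       tp_pred = sum(out$tp_pred), fp = sum(out$fp),
                       stringsAsFactors = FALSE)
  out <- rbind(out, pooled)
  out$sensitivity_pct <- asPct(out$tp, out$tp + out$fn)
  out$precision_pct <- asPct(out$tp_pred, out$tp_pred + out$fp)
  # per-patient macro-averaged sensitivity (pooled row only)
  g <- records[records$side == "gt", , drop = FALSE]
  out$macro_sensitivity_pct <- NA_real_
  if (nrow(g)) {
    per <- tapply(g$matched, g$patient_id, mean)
    out$macro_sensitivity_pct[out$category == "pooled"] <-
      pctRound(100 * mean(per))
  }
  out
}

#' Build detection records from evaluated cases
#'
#' @param gtSet,predSet annotated [LesionSet-class]s of one case.
#' @param match the case's [MatchResult-class].
#' @param patientId patient identifier.
#' @return detection-record data.frame (see [detectionStats()]).
#' @export
detectionRecords <- function(patientId, gtSet, predSet, match) {
  gtTb <- gtSet@table
  prTb <- predSet@table
  rbind(
    if (nrow(gtTb)) data.frame(patient_id = patientId, side = "gt",
                               lesion_id = gtTb$lesion_id,
                               category = gtTb$category,
                               matched = gtTb$lesion_id %in% match@tpPairs$gt_id,
                               etiology_class = gtTb$etiology_class,
                               etiology = gtTb$etiology,
                               annotated = TRUE,
                               stringsAsFactors = FALSE),
    if (nrow(prTb)) data.frame(patient_id = patientId, side = "pred",
                               lesion_id = prTb$lesion_id,
                               category = prTb$category,
                               matched = prTb$lesion_id %in% match@tpPairs$pred_id,
                               etiology_class = prTb$etiology_class,
                               etiology = prTb$etiology,
                               annotated = prTb$annotated,
                               stringsAsFactors = FALSE))
}

#' Expand a printed count table into detection records
#'
#' Turns a per-category count table (columns `category`, `tp`, `fn`,
#' `fp`) into an equivalent synthetic record set, so ratio statistics
#' can be recomputed from published counts through the same code path
#' as full evaluations.
#'
#' @param counts data.frame with columns `category`, `tp`, `fn`, `fp`.
#' @return detection-record data.frame.
#' @export
countsToRecords <- function(counts) {
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    cg <- counts$category[i]
    mk <- function(side, n, matched) if (n > 0)
      data.frame(patient_id = "cohort", side = side,
                 lesion_id = paste0(cg, side, seq_len(n), if (matched) "m" else "u"),
                 category = cg, matched = matched,
                 etiology_class = NA_character_, etiology = NA_character_,
                 annotated = NA, stringsAsFactors = FALSE)
    rows <- c(rows, list(mk("gt", counts$tp[i], TRUE), mk("gt", counts$fn[i], FALSE),
                         mk("pred", counts$tp[i], TRUE), mk("pred", counts$fp[i], FALSE)))
  }
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Aetiology taxonomy tally of false positives
#'
#' Counts false-positive lesions of one category by aetiology class
#' (physiologic / benign / pathologic) and label, with one-decimal
#' percentage shares of the total false-positive count. Rows missing an
#' aetiology are counted under `"unannotated"`, never dropped.
#'
#' @param fpTable data.frame of false-positive lesions with columns
#'   `etiology_class`, `etiology` and optionally `annotated`.
#' @return list with `total` FP count, `by_class` (count + share_pct)
#'   and `by_label` data.frames.
#' @export
taxonomyTally <- function(fpTable) {
  n <- nrow(fpTable)
  cls <- fpTable$etiology_class
  if ("annotated" %in% names(fpTable))
    cls[!is.na(fpTable$annotated) & !fpTable$annotated] <- NA_character_
  cls[is.na(cls) | cls == ""] <- "unannotated"
  lvl <- c("physiologic", "benign", "pathologic")
  if (any(cls == "unannotated")) lvl <- c(lvl, "unannotated")
  cnt <- table(factor(cls, levels = lvl))
  byClass <- data.frame(etiology_class = names(cnt), count = as.integer(cnt),
                        share_pct = asPct(as.integer(cnt), n),
                        stringsAsFactors = FALSE)
  lab <- fpTable$etiology
  lab[is.na(lab) | lab == ""] <- "unannotated"
  if (n > 0) {
    tl <- table(cls, lab)
    byLabel <- as.data.frame(tl, stringsAsFactors = FALSE)
    names(byLabel) <- c("etiology_class", "etiology", "count")
    byLabel <- byLabel[byLabel$count > 0, , drop = FALSE]
  } else {
    byLabel <- data.frame(etiology_class = character(), etiology = character(),
                          count = integer(), share_pct = numeric(),
                          stringsAsFactors = FALSE)
  }
  byLabel <- byLabel[order(byLabel$etiology_class, -byLabel$count), , drop = FALSE]
  rownames(byLabel) <- NULL
  if (nrow(byLabel)) byLabel$share_pct <- asPct(byLabel$count, n)
  list(total = n, by_class = byClass, by_label = byLabel)
}
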