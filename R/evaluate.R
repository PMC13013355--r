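#' @include phantom.R migration.R
NULL

#' Evaluate one case: masks in, metrics and stages out
#'
#' Runs the full per-patient pipeline: decompose both masks into
#' lesions, match predictions to ground truth by voxel overlap, assign
#' categories/stations/aetiologies to predicted components, measure
#' axial diameters, compute voxel metrics, stage the ground-truth and
#' the predicted lesion sets independently, and compare the resulting
#' UICC stages. Ground-truth lesion metadata comes from the sidecar
#' (falling back to compartment assignment when absent); predicted
#' staging uses only what a reader of the predicted masks could know:
#' inherited categories, measured diameters, metadata invasion flags.
#'
#' @param gt instance or binary ground-truth [LabelVolume-class].
#' @param pred predicted [LabelVolume-class] (binary or instance).
#' @param compartmentMap [LabelVolume-class] of compartment ids.
#' @param compartments data.frame `compartment_id`, `category`, `label`.
#' @param sidecar validated sidecar data.frame (see [readSidecar()]).
#' @param rules a [StageRules-class].
#' @param patientId id used in outputs.
#' @param connectivity component connectivity (default 26).
#' @param minOverlapVoxels match threshold (default 1).
#' @param boundaries decision boundaries for the migration record.
#' @return list with `patient_id`, `gtSet`, `predSet`, `match`,
#'   `voxel_metrics`, `records` (detection records), `stage_gt`,
#'   `stage_pred`, `migration`.
#' @export
evaluateCase <- function(gt, pred, compartmentMap, compartments, sidecar,
                         rules, patientId = "patient", connectivity = 26L,
                         minOverlapVoxels = 1L,
                         boundaries = defaultBoundaries()) {
  assertSameGrid(gt, pred, "gt/pred")
  assertSameGrid(gt, compartmentMap, "gt/compartment map")
  gtSet <- extractComponents(gt, connectivity, "ground_truth")
  predSet <- extractComponents(pred, connectivity, "predicted")

  # ground-truth metadata: sidecar rows first, compartment fallback
  tb <- gtSet@table
  if (nrow(tb)) {
    cmap <- compartmentMap@voxels
    for (i in seq_len(nrow(tb))) {
      row <- sidecar[sidecar$lesion_id == tb$lesion_id[i], , drop = FALSE]
      if (nrow(row)) {
        tb$category[i] <- row$category[1]
        tb$station_or_organ[i] <- row$station_or_organ[1]
        tb$invasion[i] <- row$invasion[1]
        if (!is.na(row$diameter_mm[1])) tb$diameter_mm[i] <- row$diameter_mm[1]
      } else {
        comp <- cmap[gtSet@voxelIndex[[tb$lesion_id[i]]]]
        comp <- comp[comp > 0L]
        if (length(comp)) {
          cid <- as.integer(names(which.max(table(comp))))
          cprow <- compartments[compartments$compartment_id == cid, ]
          tb$category[i] <- cprow$category[1]
          tb$station_or_organ[i] <- cprow$label[1]
        } else {
          tb$category[i] <- "M"
          tb$station_or_organ[i] <- "extrathoracic_unspecified"
        }
      }
      tb$etiology_class[i] <- "tumour"
      tb$annotated[i] <- TRUE
    }
    gtSet@table <- tb
  }

  match <- matchLesions(gtSet, predSet, minOverlapVoxels)
  predSet <- assignCategory(predSet, match, compartmentMap, compartments,
                            gtSet, sidecar)
  gtSet <- measureDiameter(gtSet)
  predSet <- measureDiameter(predSet)

  vm <- voxelMetrics(gt, pred, gtSet, predSet, match)
  vm <- cbind(data.frame(patient_id = patientId, stringsAsFactors = FALSE), vm)

  stageGt <- stagePatient(gtSet@table, rules, patientId)
  stagePred <- stagePatient(predSet@table, rules, patientId)
  mig <- migrationRecords(patientId, stageGt$uicc, stagePred$uicc, boundaries)

  list(patient_id = patientId, gtSet = gtSet, predSet = predSet,
       match = match, voxel_metrics = vm,
       records = detectionRecords(patientId, gtSet, predSet, match),
       stage_gt = stageGt, stage_pred = stagePred, migration = mig)
}

#' Evaluate a simulated cohort in memory
#'
#' Applies [evaluateCase()] to every [CaseBundle-class] and pools the
#' results: per-patient voxel metrics, cohort detection statistics,
#' false-positive taxonomy tallies per category, Bland-Altman agreement
#' of TMTV, stage assignments and the cohort migration summary.
#'
#' @param bundles list of [CaseBundle-class]s (from [simulateCohort()]).
#' @param rules a [StageRules-class]; default builtin ninth edition.
#' @param connectivity,minOverlapVoxels,boundaries see [evaluateCase()].
#' @param collapseN2 see [summarizeCohort()].
#' @return list with `patient_metrics`, `detection`, `records`,
#'   `taxonomy` (per category), `bland_altman`, `stage_assignments`,
#'   `migration_records`, `migration_summary`.
#' @export
evaluateCohort <- function(bundles, rules = loadStageRules("ninth_edition"),
                           connectivity = 26L, minOverlapVoxels = 1L,
                           boundaries = defaultBoundaries(),
                           collapseN2 = FALSE) {
  spec <- NULL
  results <- lapply(bundles, function(b) {
    comp <- compartmentsFromMap(b)
    evaluateCase(b@gt, b@pred, b@compartmentMap, comp, caseSidecar(b),
                 rules, b@patientId, connectivity, minOverlapVoxels,
                 boundaries)
  })
  poolEvaluations(results, boundaries = boundaries, collapseN2 = collapseN2)
}

# compartment metadata table of a bundle: recovered from its lesion
# table (category + label per compartment id)
#' @keywords internal
#' @noRd
compartmentsFromMap <- function(bundle) {
  tb <- bundle@lesionTable
  if (nrow(tb) && "compartment_id" %in% names(tb)) {
    u <- unique(tb[, c("compartment_id", "category", "station_or_organ")])
    names(u) <- c("compartment_id", "category", "label")
    u[!is.na(u$compartment_id), , drop = FALSE]
  } else {
    data.frame(compartment_id = integer(), category = character(),
               label = character(), stringsAsFactors = FALSE)
  }
}

#' Pool per-case evaluation results
#'
#' @param results list of [evaluateCase()] results.
#' @param boundaries decision boundaries used for the summary.
#' @param collapseN2 see [summarizeCohort()].
#' @return see [evaluateCohort()].
#' @export
poolEvaluations <- function(results, boundaries = defaultBoundaries(),
                            collapseN2 = FALSE) {
  pm <- do.call(rbind, lapply(results, `[[`, "voxel_metrics"))
  records <- do.call(rbind, lapply(results, `[[`, "records"))
  det <- detectionStats(records)
  tax <- lapply(stats::setNames(categoryLevels(), categoryLevels()),
                function(cg) {
    fp <- records[records$side == "pred" & !records$matched &
                  records$category == cg, , drop = FALSE]
    taxonomyTally(fp)
  })
  ba <- if (nrow(pm) >= 2) blandAltman(pm$tmtv_gt_mL, pm$tmtv_pred_mL) else NULL
  sa <- do.call(rbind, lapply(results, function(r) {
    data.frame(patient_id = r$patient_id,
               t_gt = r$stage_gt$t, n_gt = r$stage_gt$n, m_gt = r$stage_gt$m,
               uicc_gt = r$stage_gt$uicc,
               t_pred = r$stage_pred$t, n_pred = r$stage_pred$n,
               m_pred = r$stage_pred$m, uicc_pred = r$stage_pred$uicc,
               stringsAsFactors = FALSE)
  }))
  mig <- do.call(rbind, lapply(results, `[[`, "migration"))
  summ <- summarizeCohort(mig, sa, collapseN2 = collapseN2)
  list(patient_metrics = pm, detection = det, records = records,
       taxonomy = tax, bland_altman = ba, stage_assignments = sa,
       migration_records = mig, migration_summary = summ)
}
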