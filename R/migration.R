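#' @include staging.R
NULL

# Patient-level comparison of ground-truth and predicted UICC stages:
# direction of migration, number of treatment decision boundaries
# crossed, and the derived clinical impact level. The default decision
# boundaries sit between IB|IIA (adjuvant systemic therapy becomes
# routine) and IIIC|IVA (curative-intent multimodal treatment gives way
# to palliative systemic strategies).

#' Default treatment decision boundaries
#'
#' Boundaries are named by the stage pair they separate and ordered on
#' the UICC scale.
#'
#' @return character vector of boundary labels, e.g. `"IB|IIA"`.
#' @export
defaultBoundaries <- function() c("IB|IIA", "IIIC|IVA")

#' @keywords internal
#' @noRd
boundaryPositions <- function(boundaries) {
  lv <- uiccLevels()
  pos <- vapply(boundaries, function(b) {
    pair <- strsplit(b, "|", fixed = TRUE)[[1]]
    if (length(pair) != 2 || !all(pair %in% lv) ||
        match(pair[2], lv) != match(pair[1], lv) + 1)
      stop("invalid decision boundary (must separate adjacent UICC stages): ", b)
    match(pair[1], lv) + 0.5
  }, numeric(1))
  if (anyDuplicated(pos)) stop("decision boundaries must be distinct")
  sort(pos)
}

#' @keywords internal
#' @noRd
stageIndex <- function(stage) {
  idx <- match(stage, uiccLevels())
  if (anyNA(idx))
    stop("unknown UICC stage label(s): ",
         paste(unique(stage[is.na(idx)]), collapse = ", "))
  idx
}

#' Direction of stage migration
#'
#' A higher predicted than ground-truth UICC stage is upstaging, a
#' lower one downstaging, identical stages are concordant.
#'
#' @param gtStage,predStage UICC stage labels (see [uiccLevels()]).
#' @return `"concordant"`, `"upstaging"` or `"downstaging"` (vectorized).
#' @examples
#' classifyMigration("IIIA", "IVA")
#' @export
classifyMigration <- function(gtStage, predStage) {
  g <- stageIndex(gtStage); p <- stageIndex(predStage)
  ifelse(p > g, "upstaging", ifelse(p < g, "downstaging", "concordant"))
}

#' Number of decision boundaries crossed
#'
#' Counts the configured boundaries lying strictly between the two
#' stages on the ordinal UICC scale.
#'
#' @param gtStage,predStage UICC stage labels.
#' @param boundaries boundary labels (default [defaultBoundaries()]).
#' @return integer count (vectorized).
#' @examples
#' boundariesCrossed("IB", "IVA")   # both boundaries
#' boundariesCrossed("IIA", "IIIC") # same middle band
#' @export
boundariesCrossed <- function(gtStage, predStage,
                              boundaries = defaultBoundaries()) {
  pos <- boundaryPositions(boundaries)
  g <- stageIndex(gtStage); p <- stageIndex(predStage)
  lo <- pmin(g, p); hi <- pmax(g, p)
  vapply(seq_along(g), function(i) sum(pos > lo[i] & pos < hi[i]), integer(1))
}

#' Clinical impact level of a stage migration
#'
#' High = migration across both decision boundaries (change in
#' treatment intent), Moderate = across one boundary, Low = discordant
#' staging within the same boundary band, None = concordant staging.
#'
#' @inheritParams boundariesCrossed
#' @return factor with levels None, Low, Moderate, High (vectorized).
#' @export
impactLevel <- function(gtStage, predStage, boundaries = defaultBoundaries()) {
  bc <- boundariesCrossed(gtStage, predStage, boundaries)
  conc <- classifyMigration(gtStage, predStage) == "concordant"
  lv <- ifelse(conc, "None",
        ifelse(bc >= 2, "High", ifelse(bc == 1, "Moderate", "Low")))
  factor(lv, levels = c("None", "Low", "Moderate", "High"))
}

#' Build per-patient migration records
#'
#' @param patientId character vector of patient ids.
#' @inheritParams boundariesCrossed
#' @return data.frame `patient_id`, `gt_stage`, `pred_stage`,
#'   `direction`, `boundaries_crossed`, `impact`.
#' @export
migrationRecords <- function(patientId, gtStage, predStage,
                             boundaries = defaultBoundaries()) {
  data.frame(patient_id = patientId, gt_stage = gtStage,
             pred_stage = predStage,
             direction = classifyMigration(gtStage, predStage),
             boundaries_crossed = boundariesCrossed(gtStage, predStage, boundaries),
             impact = as.character(impactLevel(gtStage, predStage, boundaries)),
             stringsAsFactors = FALSE)
}

#' Summarize stage migration over a cohort
#'
#' Produces the impact-by-direction table (counts and one-decimal
#' percentages of cohort size), per-component T/N/M confusion matrices
#' (ground truth in rows, prediction in columns; Tx keeps its own
#' row/column), the UICC stage transition edge list for Sankey
#' rendering, overall concordance and the within-boundary agreement
#' (records that cross no decision boundary).
#'
#' @param records data.frame from [migrationRecords()] (one row per
#'   patient; duplicate ids are an error).
#' @param stageAssignments optional data.frame with per-patient
#'   `patient_id`, `t_gt`, `n_gt`, `m_gt`, `t_pred`, `n_pred`, `m_pred`
#'   used for the component confusion matrices.
#' @param collapseN2 collapse N2a/N2b into a single N2 row/column in
#'   the N confusion matrix.
#' @return list with `n`, `impact_table`, `direction_counts`,
#'   `concordance_pct`, `within_boundary_pct`, `confusion` (T/N/M
#'   matrices or NULL) and `sankey_edges`.
#' @export
summarizeCohort <- function(records, stageAssignments = NULL,
                            collapseN2 = FALSE) {
  if (anyDuplicated(records$patient_id))
    stop("duplicate patient ids in migration records")
  n <- nrow(records)
  impLv <- c("None", "Low", "Moderate", "High")
  dirLv <- c("concordant", "upstaging", "downstaging")
  tab <- table(factor(records$impact, levels = impLv),
               factor(records$direction, levels = dirLv))
  impactTable <- do.call(rbind, lapply(impLv, function(il) {
    data.frame(impact = il,
               upstaging = tab[il, "upstaging"],
               upstaging_pct = asPct(tab[il, "upstaging"], n),
               downstaging = tab[il, "downstaging"],
               downstaging_pct = asPct(tab[il, "downstaging"], n),
               concordant = tab[il, "concordant"],
               concordant_pct = asPct(tab[il, "concordant"], n),
               stringsAsFactors = FALSE)
  }))
  rownames(impactTable) <- NULL
  conc <- sum(records$direction == "concordant")
  within <- sum(records$boundaries_crossed == 0)
  dirCounts <- as.data.frame(table(factor(records$direction, levels = dirLv)),
                             stringsAsFactors = FALSE)
  names(dirCounts) <- c("direction", "count")
  dirCounts$pct <- asPct(dirCounts$count, n)
  confusion <- NULL
  if (!is.null(stageAssignments)) {
    confMat <- function(gt, pred, levels) {
      table(gt = factor(gt, levels = levels),
            pred = factor(pred, levels = levels))
    }
    nlv <- nLevels()
    nGt <- stageAssignments$n_gt; nPr <- stageAssignments$n_pred
    if (collapseN2) {
      nlv <- c("N0", "N1", "N2", "N3")
      nGt <- sub("^N2[ab]$", "N2", nGt)
      nPr <- sub("^N2[ab]$", "N2", nPr)
    }
    confusion <- list(
      T = confMat(stageAssignments$t_gt, stageAssignments$t_pred, tLevels()),
      N = confMat(nGt, nPr, nlv),
      M = confMat(stageAssignments$m_gt, stageAssignments$m_pred, mLevels()))
  }
  edges <- as.data.frame(table(source = factor(records$gt_stage,
                                               levels = uiccLevels()),
                               target = factor(records$pred_stage,
                                               levels = uiccLevels())),
                         stringsAsFactors = FALSE)
  names(edges) <- c("source", "target", "count")
  edges <- edges[edges$count > 0, , drop = FALSE]
  rownames(edges) <- NULL
  list(n = n, impact_table = impactTable, direction_counts = dirCounts,
       concordance_pct = asPct(conc, n),
       concordant = conc,
       within_boundary = within,
       within_boundary_pct = asPct(within, n),
       confusion = confusion, sankey_edges = edges)
}
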