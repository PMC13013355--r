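#' @include metrics.R
NULL

# Rule-based TNM derivation and UICC stage grouping. The tables (size
# thresholds, invasion map, nodal station map with the N2a/N2b split,
# metastatic site classes and the stage-group lookup) live in a
# versioned JSON data file; nothing is hard-coded here, so staging
# editions are swappable.

#' Load a staging rule book
#'
#' Reads and validates a [StageRules-class] JSON file. The builtin
#' `"ninth_edition"` rule book encodes the 9th-edition TNM size
#' thresholds, T-relevant invasion upgrades, nodal station levels
#' (with the single/multi-station N2a/N2b subdivision), metastatic site
#' classes and the TNM-to-UICC stage group lookup. Validation fails
#' loudly: a lookup that is not total over the category cross-product
#' names the missing cell, non-monotone size thresholds are rejected,
#' and the stage group must be non-decreasing when exactly one of T, N
#' or M increases.
#'
#' @param rules path to a rules JSON file, or a builtin id
#'   (`"ninth_edition"`).
#' @return a validated [StageRules-class].
#' @examples
#' rules <- loadStageRules("ninth_edition")
#' rules
#' @export
loadStageRules <- function(rules = "ninth_edition") {
  path <- if (file.exists(rules)) rules
  else system.file("extdata", paste0("stage_rules_", rules, ".json"),
                   package = "TNMseg")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown stage rules: ", rules)
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  need <- c("edition", "version", "t_size_thresholds", "invasion_map",
            "n_station_map", "m_site_class", "uicc_lookup")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("rules file schema error; missing field(s): ", paste(miss, collapse = ", "))
  th <- as.data.frame(x$t_size_thresholds)
  th$max_cm <- as.numeric(th$max_cm)
  new("StageRules",
      tSizeThresholds = th,
      invasionMap = unlist(x$invasion_map),
      nStationMap = unlist(x$n_station_map),
      mSiteClass = unlist(x$m_site_class),
      uiccLookup = as.data.frame(x$uicc_lookup),
      edition = x$edition, version = as.character(x$version))
}

#' Derive the T category from primary-tumour lesions
#'
#' The size component comes from the largest lesion's axial diameter
#' through the threshold table; any invasion flag upgrades the category
#' to at least the mapped minimum. No T lesions gives `"Tx"` (a primary
#' can be PET-occult). Invasion flags come only from metadata, never
#' from the masks.
#'
#' @param tLesions data.frame of category-T lesions with `diameter_mm`
#'   and optional ";"-separated `invasion` flags.
#' @param rules a [StageRules-class].
#' @return list `category`, `provenance` (driving lesion ids).
#' @export
deriveT <- function(tLesions, rules) {
  if (is.null(tLesions) || !nrow(tLesions))
    return(list(category = "Tx", provenance = character()))
  d <- tLesions$diameter_mm
  if (any(is.na(d))) stop("T lesions must carry diameter_mm")
  iMax <- which.max(d)
  dcm <- d[iMax] / 10
  th <- rules@tSizeThresholds
  ub <- ifelse(is.na(th$max_cm), Inf, th$max_cm)
  sizeT <- th$t[which(dcm <= ub)[1]]
  prov <- tLesions$lesion_id[iMax]
  cat <- sizeT
  inv <- as.character(tLesions$invasion)
  if (!is.null(inv)) {
    flags <- unlist(strsplit(inv[!is.na(inv) & inv != ""], ";"))
    flags <- trimws(flags[nzchar(flags)])
    if (length(flags)) {
      unknown <- setdiff(flags, names(rules@invasionMap))
      if (length(unknown))
        stop("unknown invasion flag(s): ", paste(unknown, collapse = ", "))
      minT <- rules@invasionMap[flags]
      best <- minT[which.max(match(minT, tLevels()))]
      if (match(best, tLevels()) > match(cat, tLevels())) {
        cat <- unname(best)
        hasInv <- vapply(inv, function(s)
          !is.na(s) && any(trimws(strsplit(s, ";")[[1]]) %in% flags), TRUE)
        prov <- unique(c(prov, tLesions$lesion_id[hasInv]))
      }
    }
  }
  list(category = cat, provenance = prov)
}

#' Derive the N category from nodal lesions
#'
#' Each nodal station label maps to a base level (N1/N2/N3); the patient
#' category is the maximum over involved stations, with N2 subdivided
#' into N2a (a single involved N2 station) and N2b (multiple N2
#' stations). No nodal lesions gives N0.
#'
#' @param nLesions data.frame of category-N lesions with
#'   `station_or_organ`.
#' @param rules a [StageRules-class].
#' @return list `category`, `provenance`.
#' @export
deriveN <- function(nLesions, rules) {
  if (is.null(nLesions) || !nrow(nLesions))
    return(list(category = "N0", provenance = character()))
  st <- nLesions$station_or_organ
  unknown <- setdiff(unique(st), names(rules@nStationMap))
  if (length(unknown))
    stop("unknown nodal station label(s): ", paste(unknown, collapse = ", "))
  lev <- rules@nStationMap[st]
  if (any(lev == "N3")) {
    cat <- "N3"
    prov <- nLesions$lesion_id[lev == "N3"]
  } else if (any(lev == "N2")) {
    nStations <- length(unique(st[lev == "N2"]))
    cat <- if (nStations >= 2) "N2b" else "N2a"
    prov <- nLesions$lesion_id[lev == "N2"]
  } else {
    cat <- "N1"
    prov <- nLesions$lesion_id
  }
  list(category = cat, provenance = unname(prov))
}

#' Derive the M category from metastatic lesions
#'
#' Intrathoracic spread (contralateral lung, pleural or pericardial
#' involvement) alone is M1a; a single extrathoracic lesion is M1b;
#' multiple extrathoracic lesions (or organs) are M1c. No metastatic
#' lesions gives M0.
#'
#' @param mLesions data.frame of category-M lesions with
#'   `station_or_organ` site labels.
#' @param rules a [StageRules-class].
#' @return list `category`, `provenance`.
#' @export
deriveM <- function(mLesions, rules) {
  if (is.null(mLesions) || !nrow(mLesions))
    return(list(category = "M0", provenance = character()))
  site <- mLesions$station_or_organ
  unknown <- setdiff(unique(site), names(rules@mSiteClass))
  if (length(unknown))
    stop("unknown metastatic site label(s): ", paste(unknown, collapse = ", "))
  cls <- rules@mSiteClass[site]
  extra <- which(cls == "extrathoracic")
  if (length(extra) == 0) {
    list(category = "M1a", provenance = mLesions$lesion_id)
  } else if (length(extra) == 1) {
    list(category = "M1b", provenance = mLesions$lesion_id[extra])
  } else {
    list(category = "M1c", provenance = mLesions$lesion_id[extra])
  }
}

#' Map a TNM triple to its UICC stage group
#'
#' @param t,n,m category labels.
#' @param rules a [StageRules-class].
#' @return UICC stage group label.
#' @export
uiccStage <- function(t, n, m, rules) {
  lk <- rules@uiccLookup
  hit <- lk$stage[lk$t == t & lk$n == n & lk$m == m]
  if (length(hit) != 1)
    stop(sprintf("uicc lookup cannot resolve cell (%s, %s, %s)", t, n, m))
  hit
}

#' Stage one patient from a categorized lesion set
#'
#' Composes [deriveT()], [deriveN()] and [deriveM()] on the patient's
#' lesions and maps the TNM triple to its UICC stage group. Run
#' independently on the ground-truth and on the predicted lesion set,
#' so segmentation errors are carried forward into staging exactly as a
#' reader using the predicted masks would inherit them.
#'
#' @param lesions data.frame with `lesion_id`, `category`,
#'   `station_or_organ`, `diameter_mm`, `invasion`.
#' @param rules a [StageRules-class].
#' @param patientId optional id for the result row.
#' @return one-row data.frame: `patient_id`, `t`, `n`, `m`, `uicc`,
#'   `provenance_t`, `provenance_n`, `provenance_m` (";"-joined ids).
#' @examples
#' rules <- loadStageRules("ninth_edition")
#' stagePatient(data.frame(lesion_id = "1", category = "T",
#'                         station_or_organ = "lung", diameter_mm = 25,
#'                         invasion = NA), rules)
#' @export
stagePatient <- function(lesions, rules, patientId = "patient") {
  if (is.null(lesions)) lesions <- emptyLesionTable()
  tt <- deriveT(lesions[lesions$category %in% "T", , drop = FALSE], rules)
  nn <- deriveN(lesions[lesions$category %in% "N", , drop = FALSE], rules)
  mm <- deriveM(lesions[lesions$category %in% "M", , drop = FALSE], rules)
  data.frame(patient_id = patientId, t = tt$category, n = nn$category,
             m = mm$category,
             uicc = uiccStage(tt$category, nn$category, mm$category, rules),
             provenance_t = paste(tt$provenance, collapse = ";"),
             provenance_n = paste(nn$provenance, collapse = ";"),
             provenance_m = paste(mm$provenance, collapse = ";"),
             stringsAsFactors = FALSE)
}
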