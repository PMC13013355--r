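rules <- loadStageRules("ninth_edition")

test_that("the builtin rule book loads and satisfies all invariants", {
  expect_s4_class(rules, "StageRules")
  expect_true(validObject(rules))
  expect_equal(rules@edition, "ninth_edition")
  # thresholds strictly increasing, lookup total (validity), spot checks
  expect_equal(nrow(rules@uiccLookup),
               length(tLevels()) * length(nLevels()) * length(mLevels()))
})

test_that("a lookup missing a cell fails validation naming the cell", {
  raw <- jsonlite::fromJSON(system.file("extdata",
    "stage_rules_ninth_edition.json", package = "TNMseg"),
    simplifyDataFrame = TRUE)
  raw$uicc_lookup <- raw$uicc_lookup[
    !(raw$uicc_lookup$t == "T2a" & raw$uicc_lookup$n == "N1" &
        raw$uicc_lookup$m == "M0"), ]
  p <- tempfile(fileext = ".json")
  jsonlite::write_json(raw, p, auto_unbox = TRUE, digits = NA, na = "null")
  expect_error(loadStageRules(p), "T2a N1 M0")
})

test_that("non-monotone size thresholds are rejected", {
  raw <- jsonlite::fromJSON(system.file("extdata",
    "stage_rules_ninth_edition.json", package = "TNMseg"),
    simplifyDataFrame = TRUE)
  raw$t_size_thresholds$max_cm <- c(1, 3, 2, 4, 5, 7, NA)
  p <- tempfile(fileext = ".json")
  jsonlite::write_json(raw, p, auto_unbox = TRUE, digits = NA, na = "null")
  expect_error(loadStageRules(p), "increasing")
})

test_that("UICC stage is monotone when exactly one category increases", {
  # exhaustive scan over the category grid
  for (m in mLevels()) for (n in nLevels()) {
    st <- vapply(tLevels(), function(t) uiccStage(t, n, m, rules), "")
    expect_false(is.unsorted(match(st, uiccLevels())),
                 info = paste("T scan at", n, m))
  }
  for (m in mLevels()) for (t in tLevels()) {
    st <- vapply(nLevels(), function(n) uiccStage(t, n, m, rules), "")
    expect_false(is.unsorted(match(st, uiccLevels())),
                 info = paste("N scan at", t, m))
  }
  for (t in tLevels()) for (n in nLevels()) {
    st <- vapply(mLevels(), function(m) uiccStage(t, n, m, rules), "")
    expect_false(is.unsorted(match(st, uiccLevels())),
                 info = paste("M scan at", t, n))
  }
})

test_that("T derivation combines size thresholds and invasion upgrades", {
  expect_equal(deriveT(NULL, rules)$category, "Tx")
  expect_equal(deriveT(lesionRow("1", "T", diameter = 25), rules)$category,
               "T1c")
  expect_equal(deriveT(lesionRow("1", "T", diameter = 8), rules)$category, "T1a")
  expect_equal(deriveT(lesionRow("1", "T", diameter = 45), rules)$category, "T2b")
  expect_equal(deriveT(lesionRow("1", "T", diameter = 80), rules)$category, "T4")
  # invasion dominates size
  expect_equal(deriveT(lesionRow("1", "T", diameter = 20,
                                 invasion = "mediastinum"), rules)$category,
               "T4")
  expect_equal(deriveT(lesionRow("1", "T", diameter = 20,
                                 invasion = "chest_wall"), rules)$category,
               "T3")
  # size dominates a weaker invasion minimum
  expect_equal(deriveT(lesionRow("1", "T", diameter = 60,
                                 invasion = "visceral_pleura"), rules)$category,
               "T3")
  # largest of several lesions drives the size component
  two <- rbind(lesionRow("1", "T", diameter = 12),
               lesionRow("2", "T", diameter = 33))
  d <- deriveT(two, rules)
  expect_equal(d$category, "T2a")
  expect_equal(d$provenance, "2")
  expect_error(deriveT(lesionRow("1", "T", diameter = 10,
                                 invasion = "martian"), rules), "invasion")
})

test_that("N derivation maps stations and subdivides N2 by station count", {
  expect_equal(deriveN(NULL, rules)$category, "N0")
  expect_equal(deriveN(lesionRow("1", "N", "ipsilateral_hilar"),
                       rules)$category, "N1")
  expect_equal(deriveN(lesionRow("1", "N", "ipsilateral_mediastinal"),
                       rules)$category, "N2a")
  two <- rbind(lesionRow("1", "N", "ipsilateral_mediastinal"),
               lesionRow("2", "N", "subcarinal"))
  expect_equal(deriveN(two, rules)$category, "N2b")
  # several lesions in one N2 station stay N2a
  same <- rbind(lesionRow("1", "N", "subcarinal"),
                lesionRow("2", "N", "subcarinal"))
  expect_equal(deriveN(same, rules)$category, "N2a")
  # contralateral disease dominates everything
  mix <- rbind(two, lesionRow("3", "N", "contralateral_mediastinal"))
  expect_equal(deriveN(mix, rules)$category, "N3")
  expect_error(deriveN(lesionRow("1", "N", "nowhere"), rules), "station")
})

test_that("M derivation distinguishes intrathoracic spread and multiplicity", {
  expect_equal(deriveM(NULL, rules)$category, "M0")
  expect_equal(deriveM(lesionRow("1", "M", "contralateral_lung"),
                       rules)$category, "M1a")
  expect_equal(deriveM(lesionRow("1", "M", "liver"), rules)$category, "M1b")
  two <- rbind(lesionRow("1", "M", "liver"), lesionRow("2", "M", "bone"))
  expect_equal(deriveM(two, rules)$category, "M1c")
  # two lesions in the same organ are still multiple extrathoracic lesions
  twoLiver <- rbind(lesionRow("1", "M", "liver"), lesionRow("2", "M", "liver"))
  expect_equal(deriveM(twoLiver, rules)$category, "M1c")
  # intrathoracic plus single extrathoracic -> M1b
  mix <- rbind(lesionRow("1", "M", "pleura"), lesionRow("2", "M", "brain"))
  expect_equal(deriveM(mix, rules)$category, "M1b")
  expect_error(deriveM(lesionRow("1", "M", "asteroid"), rules), "site")
})

test_that("patient staging composes the components and the lookup", {
  empty <- stagePatient(NULL, rules)
  expect_equal(c(empty$t, empty$n, empty$m), c("Tx", "N0", "M0"))

  p1 <- stagePatient(lesionRow("1", "T", "lung", diameter = 9), rules)
  expect_equal(p1$uicc, "IA1")

  # any M1c patient is stage IVB, whatever T and N
  for (t in c("Tx", "T1a", "T3")) for (n in c("N0", "N2b", "N3")) {
    expect_equal(uiccStage(t, n, "M1c", rules), "IVB")
  }

  les <- rbind(lesionRow("1", "T", "lung", diameter = 35),
               lesionRow("2", "N", "ipsilateral_hilar"),
               lesionRow("3", "M", "liver"))
  p2 <- stagePatient(les, rules)
  expect_equal(c(p2$t, p2$n, p2$m, p2$uicc), c("T2a", "N1", "M1b", "IVA"))
  expect_equal(p2$provenance_m, "3")
})

test_that("adding a distant-organ lesion never decreases the UICC stage", {
  sites <- c("liver", "bone", "brain", "adrenal_gland")
  set.seed(77)
  for (i in 1:25) {
    nT <- sample(0:2, 1); nN <- sample(0:3, 1); nM <- sample(0:2, 1)
    les <- list()
    if (nT) les <- c(les, list(data.frame(
      lesion_id = paste0("t", 1:nT), category = "T", station_or_organ = "lung",
      diameter_mm = runif(nT, 5, 80),
      invasion = sample(c(NA, "mediastinum"), nT, TRUE, prob = c(.8, .2)))))
    if (nN) les <- c(les, list(data.frame(
      lesion_id = paste0("n", 1:nN), category = "N",
      station_or_organ = sample(names(rules@nStationMap), nN, TRUE),
      diameter_mm = NA_real_, invasion = NA)))
    if (nM) les <- c(les, list(data.frame(
      lesion_id = paste0("m", 1:nM), category = "M",
      station_or_organ = sample(sites, nM, TRUE),
      diameter_mm = NA_real_, invasion = NA)))
    base <- if (length(les)) do.call(rbind, les) else NULL
    s0 <- stagePatient(base, rules)$uicc
    extra <- data.frame(lesion_id = "extra", category = "M",
                        station_or_organ = sample(sites, 1),
                        diameter_mm = NA_real_, invasion = NA)
    s1 <- stagePatient(rbind(base, extra), rules)$uicc
    expect_gte(match(s1, uiccLevels()), match(s0, uiccLevels()))
  }
})

test_that("deleting a solitary distant metastasis downstages the patient", {
  les <- rbind(lesionRow("1", "T", "lung", diameter = 18),
               lesionRow("2", "M", "brain"))
  full <- stagePatient(les, rules)
  expect_equal(full$m, "M1b")
  expect_equal(full$uicc, "IVA")
  # the false-negative pathway: lose the only metastasis
  reduced <- stagePatient(les[les$lesion_id != "2", ], rules)
  expect_equal(reduced$m, "M0")
  expect_equal(reduced$uicc, "IA2")
  expect_lt(match(reduced$uicc, uiccLevels()), match(full$uicc, uiccLevels()))
})
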