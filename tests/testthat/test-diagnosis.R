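# Sanz/PETHEMA-GIMEMA risk stratification and the advisory opinion.

test_that("the three case-report CBC panels map to low / intermediate / high", {
  expect_equal(stratifyRisk(cbcPanel(wbc = 2.1, platelets = 63)), "low")
  expect_equal(stratifyRisk(cbcPanel(wbc = 7.3, platelets = 27)),
               "intermediate")
  expect_equal(stratifyRisk(cbcPanel(wbc = 25.5, platelets = 16)), "high")
  # boundary values are inclusive as printed: WBC <= 10, platelets <= 40
  expect_equal(stratifyRisk(cbcPanel(wbc = 10, platelets = 40)),
               "intermediate")
  expect_equal(stratifyRisk(cbcPanel(wbc = 10, platelets = 40.5)), "low")
  expect_error(cbcPanel(wbc = -1, platelets = 10))
  expect_error(cbcPanel(wbc = Inf, platelets = 10))
})

test_that("risk regions partition the WBC x platelet quadrant", {
  grid <- expand.grid(wbc = seq(0, 30, by = 1.25),
                      platelets = seq(0, 120, by = 5))
  risks <- mapply(function(w, p) stratifyRisk(cbcPanel(w, p)),
                  grid$wbc, grid$platelets)
  expect_true(all(risks %in% c("low", "intermediate", "high")))
  expect_true(all(risks[grid$wbc > 10] == "high"))
  expect_true(all(risks[grid$wbc <= 10 & grid$platelets > 40] == "low"))
  expect_true(all(risks[grid$wbc <= 10 & grid$platelets <= 40] ==
                    "intermediate"))
})

test_that("opinions carry the printed treatment strings and disclaimer", {
  # patient 1: low risk, promyelocytes present
  s1 <- cellCountSummary(c(0, 0, 19, 4, 23, 103), nFields = 153)
  o1 <- renderOpinion(s1, "low")
  expect_true(suspectedApl(o1))
  expect_equal(potentialTreatment(o1), "ATRA + arsenic")

  s2 <- cellCountSummary(c(0, 0, 39, 2, 119, 35), nFields = 70)
  o2 <- renderOpinion(s2, "intermediate")
  expect_equal(potentialTreatment(o2), "ATRA + arsenic")

  # patient 3: high risk adds chemotherapy induction
  s3 <- cellCountSummary(c(0, 0, 5, 0, 90, 3), nFields = 15)
  o3 <- renderOpinion(s3, "high")
  expect_true(suspectedApl(o3))
  expect_equal(potentialTreatment(o3),
               "ATRA + arsenic + chemotherapy induction")
  expect_equal(o3@evidence$promyelocyteFraction, 90 / 98)
  expect_match(o3@note[1], "not.*clinical", ignore.case = TRUE)

  # no promyelocytes: not suspected, empty treatment (validity-enforced)
  s0 <- cellCountSummary(c(5, 2, 30, 4, 0, 60))
  o0 <- renderOpinion(s0, "high")
  expect_false(suspectedApl(o0))
  expect_equal(potentialTreatment(o0), "")

  # configurable positivity threshold
  oT <- renderOpinion(s1, "low", minPromyelocytes = 24L)
  expect_false(suspectedApl(oT))
})

test_that("count summaries handle the empty smear", {
  s <- cellCountSummary(rep(0, 6))
  expect_equal(s$total, 0L)
  expect_equal(s$promyelocyteFraction, 0)
})

test_that("opinions serialize to JSON", {
  tmp <- withr::local_tempfile(fileext = ".json")
  o <- renderOpinion(cellCountSummary(c(0, 0, 5, 0, 90, 3)), "high")
  writeOpinion(o, tmp)
  back <- jsonlite::read_json(tmp)
  expect_true(back$suspected_apl)
  expect_equal(back$risk, "high")
  expect_equal(back$potential_treatment,
               "ATRA + arsenic + chemotherapy induction")
  expect_equal(back$counts$promyelocyte, 90L)
})
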