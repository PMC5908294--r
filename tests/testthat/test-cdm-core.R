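tabs <- bundledTables()

test_that("the winning-score rule handles all three docking scenarios", {
  sy9 <- tabs$train[tabs$train$ligand_id == "SY9", ]
  w <- winningScore(sy9)
  expect_equal(w$score, -4.218)
  expect_equal(w$receptor_id, "2XYT")
  expect_equal(w$scenario, "both")

  tc9 <- tabs$train[tabs$train$ligand_id == "TC9", ]
  w2 <- winningScore(tc9)
  expect_equal(w2$score, -5.583)
  expect_equal(w2$receptor_id, "2XYT")
  expect_equal(w2$scenario, "single")

  none <- data.frame(ligand_id = "X", receptor_id = c("R1", "R2"),
                     status = "failed", score = NA_real_)
  w3 <- winningScore(none)
  expect_equal(w3$scenario, "none")
  expect_true(is.na(w3$score))

  dup <- data.frame(ligand_id = "X", receptor_id = c("R1", "R1"),
                    status = "docked", score = c(-1, -2))
  expect_error(winningScore(dup), "duplicate")

  # tie between conformations -> lexicographic receptor id
  tie <- data.frame(ligand_id = "X", receptor_id = c("R2", "R1"),
                    status = "docked", score = c(-3, -3))
  expect_equal(winningScore(tie)$receptor_id, "R1")
})

test_that("fitting on the training winning scores recovers the published constants", {
  w <- winningScores(tabs$train)
  expect_equal(nrow(w), 17L)
  model <- fitCDM(w)
  expect_equal(scoreLowest(model), -8.725)
  expect_equal(scoreHighest(model), -4.218)
  expect_equal(scoreRange(model), 4.507)

  expect_equal(scoreRange(fitCDM(c(-1, -3))), 2)
  expect_error(fitCDM(c(-5, -5)), "degenerate")
  expect_error(fitCDM(-5), "insufficient")
})

test_that("CDM predictions reproduce published single-compound values", {
  model <- fitCDM(winningScores(tabs$train))
  p <- predict(model, data.frame(ligand_id = "nicotine", score = -7.512,
                                 receptor_id = "3SQ6", scenario = "both"))
  expect_equal(p$cdm, 0.731)
  expect_equal(p$call, "binder")

  hex <- predict(model, data.frame(ligand_id = "hexamethonium",
                                   score = -2.786, receptor_id = "2XYT",
                                   scenario = "both"))
  expect_equal(hex$cdm, -0.318)
  expect_equal(hex$call, "non_binder")

  # boundary: the training minimum maps to exactly 1, still a binder
  top <- predict(model, data.frame(ligand_id = "best", score = -8.725,
                                   receptor_id = "3SQ6", scenario = "both"))
  expect_equal(top$cdm, 1)
  expect_equal(top$call, "binder")

  # scenario none: no value, non-binder
  nb <- predict(model, data.frame(ligand_id = "inert", score = NA_real_,
                                  receptor_id = NA_character_,
                                  scenario = "none"))
  expect_true(is.na(nb$cdm))
  expect_equal(nb$call, "non_binder")
})

test_that("predictTable reproduces the full test-set table", {
  model <- fitCDM(winningScores(tabs$train))
  res <- predictTable(model, tabs$test)
  expect_equal(res$n_binders, 11L)
  expect_equal(res$n_non_binders, 1L)
  mg <- res$predictions[res$predictions$ligand_id == "MG624", ]
  expect_equal(mg$winning_score, -4.954)
  expect_equal(mg$scenario, "single")
  expect_equal(mg$cdm, 0.163)
  expect_equal(mg$call, "binder")

  empty <- predictTable(model, tabs$test[0, ])
  expect_equal(nrow(empty$predictions), 0L)
  expect_equal(empty$n_binders + empty$n_non_binders, 0L)
})

test_that("the CDM value is strictly decreasing in the docking score", {
  model <- fitCDM(winningScores(tabs$train))
  scores <- seq(-12, 2, by = 0.25)
  vals <- predict(model, data.frame(ligand_id = paste0("L", seq_along(scores)),
                                    score = scores, receptor_id = "R",
                                    scenario = "both"))$cdm_exact
  expect_true(all(diff(vals) < 0))
})

test_that("training-set CDM values span [0, 1] with the extremes attained once", {
  w <- winningScores(tabs$train)
  model <- fitCDM(w)
  vals <- predict(model, w)$cdm_exact
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(sum(abs(vals - 1) < 1e-12), 1L)
  expect_equal(sum(abs(vals) < 1e-12), 1L)
})

test_that("fit and predictions are invariant under training-set permutation", {
  w <- winningScores(tabs$train)
  set.seed(99)
  perm <- w[sample(nrow(w)), ]
  m1 <- fitCDM(w); m2 <- fitCDM(perm)
  expect_equal(scoreLowest(m1), scoreLowest(m2))
  expect_equal(scoreHighest(m1), scoreHighest(m2))
  p1 <- predict(m1, w)
  p2 <- predict(m2, w)
  expect_equal(p2[match(p1$ligand_id, p2$ligand_id), "cdm_exact"],
               p1$cdm_exact)
})

test_that("score tables accept paper-style failure markers and reject malformed rows", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("ligand_id\treceptor_id\tscore",
               "A\tR1\t-5.0", "A\tR2\tND",
               "B\tR1\tfailed to dock", "B\tR2\t-3.2"), f)
  df <- readScoreTable(f)
  expect_equal(df$status, c("docked", "failed", "failed", "docked"))
  expect_equal(df$score[1], -5.0)
  expect_true(is.na(df$score[2]))

  f2 <- tempfile(fileext = ".csv")
  writeLines(c("ligand_id,receptor_id,status,score", "A,R1,docked,oops"), f2)
  expect_error(readScoreTable(f2), "unparseable")
})

test_that("a fitted model survives a JSON round-trip", {
  model <- fitCDM(winningScores(tabs$train))
  f <- tempfile(fileext = ".json")
  writeCDMModel(model, f)
  back <- readCDMModel(f)
  expect_equal(scoreLowest(back), scoreLowest(model))
  expect_equal(scoreHighest(back), scoreHighest(model))
  expect_setequal(receptorIds(back), c("2XYT", "3SQ6"))
  expect_equal(sort(trainingIds(back)), sort(trainingIds(model)))
})
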