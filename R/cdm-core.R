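.failedMarkers <- c("failed", "nd", "failed to dock", "na", "")

#' Read a docking score table
#'
#' Reads a TSV/CSV table of per-receptor docking attempts with columns
#' `ligand_id`, `receptor_id`, `status`, `score`. The `status` column may be
#' omitted, in which case rows whose score is blank or carries a failure
#' marker ("ND", "failed", "failed to dock") are treated as failed dockings.
#' Docking scores are in Glide XP GScore units: an opaque value where more
#' negative means more favorable.
#'
#' @param file path; comma separation is assumed for `.csv`, tabs otherwise.
#' @return data.frame with columns `ligand_id`, `receptor_id`, `status`
#'   ("docked"/"failed") and `score` (NA when failed).
#' @export
readScoreTable <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(file, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character",
                          strip.white = TRUE)
  need <- c("ligand_id", "receptor_id")
  if (!all(need %in% names(df)))
    stop("score table needs columns ligand_id and receptor_id (got: ",
         paste(names(df), collapse = ", "), ")")
  if (!"score" %in% names(df)) stop("score table needs a 'score' column")
  rawScore <- df$score
  score <- suppressWarnings(as.numeric(gsub("−", "-", rawScore)))
  failedScore <- tolower(trimws(rawScore)) %in% .failedMarkers
  if (any(is.na(score) & !failedScore))
    stop("unparseable score value(s): ",
         paste(unique(rawScore[is.na(score) & !failedScore]), collapse = ", "))
  status <- if ("status" %in% names(df)) tolower(trimws(df$status))
            else ifelse(failedScore, "failed", "docked")
  status[status %in% .failedMarkers] <- "failed"
  if (!all(status %in% c("docked", "failed")))
    stop("status values must be 'docked' or 'failed'")
  bad <- status == "docked" & is.na(score)
  if (any(bad))
    stop("docked record(s) without a score for ligand(s): ",
         paste(unique(df$ligand_id[bad]), collapse = ", "))
  data.frame(ligand_id = df$ligand_id, receptor_id = df$receptor_id,
             status = status,
             score = ifelse(status == "failed", NA_real_, score),
             stringsAsFactors = FALSE)
}

.checkRecords <- function(records) {
  need <- c("ligand_id", "receptor_id", "status", "score")
  if (!all(need %in% names(records)))
    stop("docking records need columns: ", paste(need, collapse = ", "))
  dup <- duplicated(records[, c("ligand_id", "receptor_id")])
  if (any(dup))
    stop("duplicate (ligand, receptor) record(s): ",
         paste(unique(paste(records$ligand_id[dup], records$receptor_id[dup],
                            sep = "/")), collapse = ", "))
  if (any(records$status == "docked" & !is.finite(records$score)))
    stop("docked records must carry a finite score")
  invisible(records)
}

#' Competitive winning score of one ligand
#'
#' Applies the competitive rule to one ligand's docking attempts across the
#' receptor-conformation ensemble. Three scenarios: the ligand docked to a
#' single conformation (that score wins), to several (the minimum, i.e. most
#' favorable, score wins), or to none (no score; the ligand is a predicted
#' non-binder). Ties between receptor conformations are broken by
#' lexicographic receptor id.
#'
#' @param records data.frame of docking records for one ligand (columns as
#'   in [readScoreTable()]).
#' @return one-row data.frame: `ligand_id`, `score` (NA for scenario
#'   "none"), `receptor_id` (NA for "none"), `scenario`
#'   ("single"/"both"/"none").
#' @export
winningScore <- function(records) {
  .checkRecords(records)
  if (length(unique(records$ligand_id)) != 1L)
    stop("winningScore expects records for exactly one ligand")
  docked <- records[records$status == "docked", , drop = FALSE]
  lig <- records$ligand_id[1]
  if (!nrow(docked))
    return(data.frame(ligand_id = lig, score = NA_real_,
                      receptor_id = NA_character_, scenario = "none",
                      stringsAsFactors = FALSE))
  docked <- docked[order(docked$score, docked$receptor_id), ]
  data.frame(ligand_id = lig, score = docked$score[1],
             receptor_id = docked$receptor_id[1],
             scenario = if (nrow(docked) == 1L) "single" else "both",
             stringsAsFactors = FALSE)
}

#' Winning scores for a whole score table
#'
#' @param records docking records for any number of ligands.
#' @return data.frame with one row per ligand (first-appearance order) and
#'   the columns of [winningScore()].
#' @export
winningScores <- function(records) {
  .checkRecords(records)
  out <- do.call(rbind, lapply(unique(records$ligand_id), function(l)
    winningScore(records[records$ligand_id == l, , drop = FALSE])))
  rownames(out) <- NULL
  out
}

#' Fit the competitive docking model
#'
#' Fits the min-max normalization of the CDM on a set of training winning
#' scores: the model stores the lowest and highest winning score; the CDM
#' value of a score \eqn{s} is then
#' \eqn{1 - (s - s_{lowest})/(s_{highest} - s_{lowest})}. Ligands whose
#' scenario is "none" carry no score and are excluded from the fit.
#'
#' @param winning data.frame from [winningScores()] (or any data.frame with
#'   `ligand_id`, `score`, optional `receptor_id`, `scenario`), or a bare
#'   numeric vector of winning scores.
#' @return a [CDMModel-class].
#' @examples
#' tabs <- bundledTables()
#' fitCDM(winningScores(tabs$train))   # score range [-8.725, -4.218]
#' @export
fitCDM <- function(winning) {
  if (is.numeric(winning))
    winning <- data.frame(ligand_id = paste0("L", seq_along(winning)),
                          score = winning, receptor_id = NA_character_,
                          scenario = "both", stringsAsFactors = FALSE)
  if ("scenario" %in% names(winning))
    winning <- winning[winning$scenario != "none", , drop = FALSE]
  scores <- winning$score
  if (length(scores) < 2L)
    stop("insufficient data: need at least 2 winning scores to fit the CDM")
  if (!all(is.finite(scores))) stop("winning scores must be finite")
  lo <- min(scores); hi <- max(scores)
  if (hi - lo <= 0)
    stop("degenerate score range: all winning scores are equal")
  rec <- if ("receptor_id" %in% names(winning))
    sort(unique(stats::na.omit(winning$receptor_id))) else character()
  new("CDMModel", scoreLowest = lo, scoreHighest = hi,
      trainingIds = as.character(winning$ligand_id), receptorIds = rec)
}

# round half away from zero, as printed tables do
.roundHalfUp <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Predict binding with a fitted CDM
#'
#' Evaluates the CDM equation at each ligand's winning score and classifies:
#' CDM value >= 0 predicts a binder, < 0 a non-binder; ligands that docked
#' to no conformation (scenario "none") are non-binders with no CDM value.
#' Values are not clipped, so test compounds scoring outside the training
#' range may exceed 1 or fall below 0. The classification threshold is
#' applied to the full-precision value; `cdm` additionally reports the
#' 3-decimal half-up rounding used in printed tables.
#'
#' @param object a fitted [CDMModel-class].
#' @param winning data.frame of winning scores from [winningScores()].
#' @param ... unused.
#' @return data.frame with columns `ligand_id`, `winning_score`,
#'   `winning_receptor`, `scenario`, `cdm` (rounded to 3 decimals),
#'   `cdm_exact` (full precision) and `call` ("binder"/"non_binder").
#' @aliases predict
#' @export
setMethod("predict", "CDMModel", function(object, winning, ...) {
  validObject(object)
  if (is.numeric(winning))
    winning <- data.frame(ligand_id = names(winning) %||%
                            paste0("L", seq_along(winning)),
                          score = as.numeric(winning),
                          receptor_id = NA_character_,
                          scenario = "both", stringsAsFactors = FALSE)
  if (!"scenario" %in% names(winning)) winning$scenario <- "both"
  rng <- scoreRange(object)
  cdmExact <- 1 - (winning$score - object@scoreLowest) / rng
  cdmExact[winning$scenario == "none"] <- NA_real_
  call <- ifelse(winning$scenario == "none", "non_binder",
                 ifelse(cdmExact >= 0, "binder", "non_binder"))
  data.frame(ligand_id = winning$ligand_id,
             winning_score = winning$score,
             winning_receptor = winning$receptor_id,
             scenario = winning$scenario,
             cdm = .roundHalfUp(cdmExact, 3L),
             cdm_exact = cdmExact,
             call = call,
             stringsAsFactors = FALSE)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict a full score table
#'
#' Convenience wrapper: derive winning scores per ligand from raw docking
#' records, evaluate the CDM and tally the calls.
#'
#' @param model a fitted [CDMModel-class].
#' @param records docking records (columns as in [readScoreTable()]).
#' @return list with `predictions` (the [predict,CDMModel-method] table) and
#'   counts `n_binders`, `n_non_binders`.
#' @examples
#' tabs <- bundledTables()
#' model <- fitCDM(winningScores(tabs$train))
#' predictTable(model, tabs$test)$n_binders   # 11
#' @export
predictTable <- function(model, records) {
  if (!nrow(records))
    return(list(predictions = predict(model,
                  data.frame(ligand_id = character(), score = numeric(),
                             receptor_id = character(), scenario = character(),
                             stringsAsFactors = FALSE)),
                n_binders = 0L, n_non_binders = 0L))
  win <- tryCatch(winningScores(records), error = function(e)
    stop("failed to derive winning scores: ", conditionMessage(e)))
  pred <- predict(model, win)
  list(predictions = pred,
       n_binders = sum(pred$call == "binder"),
       n_non_binders = sum(pred$call == "non_binder"))
}

#' Persist / restore a fitted CDM as JSON
#'
#' The stored file carries the normalization constants plus provenance
#' (training ligand ids and receptor-conformation ids), making the trained
#' model a storable, inspectable artifact.
#'
#' @param model a [CDMModel-class].
#' @param file JSON path.
#' @return `writeCDMModel`: `file` invisibly; `readCDMModel`: the model.
#' @export
writeCDMModel <- function(model, file) {
  stopifnot(is(model, "CDMModel"))
  jsonlite::write_json(
    list(score_lowest = model@scoreLowest,
         score_highest = model@scoreHighest,
         range = scoreRange(model),
         training_ids = model@trainingIds,
         receptor_ids = model@receptorIds),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeCDMModel
#' @export
readCDMModel <- function(file) {
  if (!file.exists(file)) stop("file not found: ", file)
  j <- jsonlite::fromJSON(file)
  new("CDMModel",
      scoreLowest = as.numeric(j$score_lowest),
      scoreHighest = as.numeric(j$score_highest),
      trainingIds = as.character(j$training_ids %||% character()),
      receptorIds = as.character(j$receptor_ids %||% character()))
}
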