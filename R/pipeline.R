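#' Configuration of the end-to-end analysis run
#'
#' Defaults replicate the study settings: signals for all eight ATC
#' classes over the full database; demographic rules (age band, number
#' of CNS-active drugs, number of calcium channel blockers) at minimum
#' support 1e-6, minimum confidence 0.001, maxlen 3; history-by-drug
#' rules on the age >= 60 subgroup at minimum confidence 0.01, maxlen 4.
#'
#' @param db_dir Directory holding the four canonical CSV tables (or
#'   pass a loaded `srs_db` to [run_full_analysis()] directly).
#' @param out_dir Output directory for the result CSVs and run log.
#' @param classes Drug classes for the signal stage.
#' @param event_def Fall-related event definition.
#' @param demographic,history Per-stage rule-mining settings: lists with
#'   `items`, `min_support`, `min_confidence`, `maxlen`, and for the
#'   subgroup stage `age_min_band` and `support_denominator`.
#' @param seed Seed applied before the run (the pipeline itself is
#'   deterministic; the seed covers any future resampling step).
#' @return A `run_config` list.
#' @export
run_config <- function(db_dir = NULL, out_dir = "results",
                       classes = drug_classes(),
                       event_def = fall_event_definition(),
                       demographic = list(
                         items = c("age", "n_cns", "n_ccb"),
                         min_support = 1e-6, min_confidence = 0.001,
                         maxlen = 3),
                       history = list(
                         items = c("class", "hist"),
                         min_support = 1e-6, min_confidence = 0.01,
                         maxlen = 4, age_min_band = "60-69",
                         support_denominator = "subset"),
                       seed = 1L) {
  if (length(classes) == 0)
    stop("class list is empty", call. = FALSE)
  unknown <- setdiff(classes, drug_classes())
  if (length(unknown) > 0)
    stop("unknown drug class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (blk in list(demographic, history)) {
    if (blk$min_support <= 0 || blk$min_support > 1)
      stop("min_support out of range", call. = FALSE)
    if (blk$min_confidence <= 0 || blk$min_confidence > 1)
      stop("min_confidence out of range", call. = FALSE)
    if (blk$maxlen < 1) stop("maxlen must be >= 1", call. = FALSE)
  }
  if (!history$age_min_band %in% age_bands())
    stop("age_min_band must be an age band label", call. = FALSE)
  structure(list(db_dir = db_dir, out_dir = out_dir, classes = classes,
                 event_def = event_def, demographic = demographic,
                 history = history, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis
#'
#' Signals plus both rule-mining stages; writes `signals.csv`,
#' `rules_demographic.csv`, `rules_history.csv` and `run_log.txt` to the
#' configured output directory with deterministic ordering. On any stage
#' failure the partial outputs of this run are removed.
#'
#' @param config A [run_config()].
#' @param db Optional pre-loaded `srs_db` (overrides `config$db_dir`).
#' @return Invisible list with the three result tibbles and the feature
#'   table.
#' @export
run_full_analysis <- function(config = run_config(), db = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(db)) {
    if (is.null(config$db_dir))
      stop("no database: set db_dir or pass db", call. = FALSE)
    db <- load_database(dir = config$db_dir)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- file.path(out_dir, c("signals.csv", "rules_demographic.csv",
                                  "rules_history.csv", "run_log.txt"))
  set.seed(config$seed)
  res <- tryCatch({
    features <- report_features(db, event_def = config$event_def)
    signals <- detect_signals(features, classes = config$classes)
    dem <- config$demographic
    rules_dem <- mine_rules(
      features, items = dem$items, min_support = dem$min_support,
      min_confidence = dem$min_confidence, maxlen = dem$maxlen)
    hi <- config$history
    bands <- age_bands()
    sub_bands <- bands[seq(match(hi$age_min_band, bands), length(bands))]
    sub <- features[features$age_band %in% sub_bands, ]
    rules_hist <- mine_rules(
      sub, items = hi$items, min_support = hi$min_support,
      min_confidence = hi$min_confidence, maxlen = hi$maxlen,
      support_denominator = hi$support_denominator,
      full_D = nrow(features))
    readr::write_csv(signals, outputs[1], progress = FALSE)
    readr::write_csv(rules_dem, outputs[2], progress = FALSE)
    readr::write_csv(rules_hist, outputs[3], progress = FALSE)
    n_excl <- sum(features$age_band == "EXCLUDED")
    writeLines(c(
      paste0("fallsignal version: ",
             as.character(utils::packageVersion("fallsignal"))),
      paste0("reports (D): ", nrow(features)),
      paste0("age-excluded reports: ", n_excl),
      paste0("fall-related reports: ", sum(features$fall_related)),
      paste0("subgroup (age >= ", hi$age_min_band, ") reports: ",
             nrow(sub)),
      paste0("demographic run: min_support=", dem$min_support,
             " min_confidence=", dem$min_confidence,
             " maxlen=", dem$maxlen),
      paste0("history run: min_support=", hi$min_support,
             " min_confidence=", hi$min_confidence,
             " maxlen=", hi$maxlen,
             " support_denominator=", hi$support_denominator),
      paste0("signals flagged: ",
             paste(signals$class_name[signals$is_signal],
                   collapse = ", "))),
      outputs[4])
    list(signals = signals, rules_demographic = rules_dem,
         rules_history = rules_hist, features = features)
  }, error = function(e) {
    unlink(outputs)
    stop("analysis failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
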