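#!/usr/bin/env Rscript
# Stage 1: simulate a JADER-like spontaneous-reporting database with
# known planted structure, and write it with its ground truth.
#
# The planted effects mirror the qualitative findings the downstream
# stages should recover: benzodiazepines, SSRIs and alpha-blockers raise
# the fall-related reporting probability, diuretics lower it, risk grows
# with the number of concomitant CNS-active drugs and with age, and a
# dementia comorbidity adds further risk.

suppressPackageStartupMessages(library(fallsignal))

out_db <- "results/synthetic_db"
n_reports <- 100000

cfg <- synthetic_config(
  n_reports = n_reports,
  seed = 20180417,
  risk_multipliers = c(
    "class:benzodiazepines" = 1.8,
    "class:ssri" = 2.9,
    "class:alpha_blockers" = 1.6,
    "class:nsmri" = 2.3,
    "class:diuretics" = 0.75,
    "n_cns:2" = 1.15, "n_cns:3" = 1.3, "n_cns:4" = 1.6, "n_cns:5" = 2.0,
    "age:80-89" = 1.5, "age:>=90" = 1.6,
    "hist:dementia" = 1.8, "hist:herpes zoster" = 1.5))

message("simulating ", n_reports, " reports ...")
db <- simulate_srs(cfg)
write_database(db, out_db)

gt <- list(seed = cfg$seed, n_reports = cfg$n_reports,
           baseline_fall_prob = cfg$baseline_fall_prob,
           class_prevalence = as.list(cfg$class_prevalence),
           risk_multipliers = as.list(cfg$risk_multipliers))
dir.create("results", showWarnings = FALSE)
if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(gt, "results/ground_truth.json",
                       auto_unbox = TRUE, digits = NA)
}

features <- report_features(db)
message("fall-related reports: ", sum(features$fall_related),
        " of ", nrow(features),
        " (", round(100 * mean(features$fall_related), 2), "%)")
message("age-excluded reports: ", sum(features$age_band == "EXCLUDED"))
message("database written to ", out_db)
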