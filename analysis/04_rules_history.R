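#!/usr/bin/env Rscript
# Stage 4: association rules over drug-class and comorbidity items in
# the age >= 60 subgroup, with the fall-related consequent. Thresholds:
# minimum support 1e-6, minimum confidence 0.01, maxlen 4.

suppressPackageStartupMessages(library(fallsignal))

db <- load_database(dir = "results/synthetic_db")
features <- report_features(db)

bands60 <- c("60-69", "70-79", "80-89", ">=90")
sub <- features[features$age_band %in% bands60, ]
message("subgroup (age >= 60): ", nrow(sub), " of ", nrow(features),
        " reports")

rules <- mine_rules(sub, items = c("class", "hist"),
                    min_support = 1e-6, min_confidence = 0.01,
                    maxlen = 4)
readr::write_csv(rules, "results/rules_history.csv", progress = FALSE)

message(nrow(rules), " history x drug rules extracted; top 10 by lift:")
top <- utils::head(rules, 10)
invisible(lapply(sprintf(
  "  {%s} => fall-related  n=%d  conf %.4f  lift %.2f  chi2 %.2f%s",
  top$lhs, top$case_n, top$confidence, top$lift, top$chi_squared,
  ifelse(top$significant, " *", "")), message))
message("written to results/rules_history.csv")
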