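#!/usr/bin/env Rscript
# Stage 3: association rules over demographic items -- age band, number
# of concomitant CNS-active drugs, number of calcium channel blockers --
# with the fall-related consequent. Thresholds: minimum support 1e-6,
# minimum confidence 0.001, maxlen 3; rules sorted by lift.

suppressPackageStartupMessages(library(fallsignal))

db <- load_database(dir = "results/synthetic_db")
features <- report_features(db)

rules <- mine_rules(features, items = c("age", "n_cns", "n_ccb"),
                    min_support = 1e-6, min_confidence = 0.001,
                    maxlen = 3)
readr::write_csv(rules, "results/rules_demographic.csv",
                 progress = FALSE)

message(nrow(rules), " demographic rules extracted; top 10 by lift:")
top <- utils::head(rules, 10)
invisible(lapply(sprintf(
  "  {%s} => fall-related  n=%d  conf %.4f  lift %.2f  chi2 %.2f%s",
  top$lhs, top$case_n, top$confidence, top$lift, top$chi_squared,
  ifelse(top$significant, " *", "")), message))

# does lift rise with the number of CNS-active drugs, as planted?
single <- rules[grepl("^n_cns:[0-9]+$", rules$lhs), ]
single <- single[order(single$lhs), ]
message("lift by CNS-active drug count: ",
        paste(sprintf("%s=%.2f", sub("n_cns:", "", single$lhs),
                      single$lift), collapse = ", "))
message("written to results/rules_demographic.csv")
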