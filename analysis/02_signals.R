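#!/usr/bin/env Rscript
# Stage 2: reporting-odds-ratio signal detection over the eight ATC drug
# classes of the simulated database.

suppressPackageStartupMessages(library(fallsignal))

db <- load_database(dir = "results/synthetic_db")
features <- report_features(db)

signals <- detect_signals(features)
dir.create("results", showWarnings = FALSE)
readr::write_csv(signals, "results/signals.csv", progress = FALSE)

fmt <- sprintf("%-60s %5d /%6d  ROR %5.2f (%.2f-%.2f)%s",
               signals$class_label, signals$case_count,
               signals$class_total, signals$ror, signals$ci_low,
               signals$ci_high, ifelse(signals$is_signal, "  *", ""))
message("signal table (", nrow(features), " reports, ",
        sum(features$fall_related), " fall-related); * = signal:")
invisible(lapply(fmt, message))
message("written to results/signals.csv")
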