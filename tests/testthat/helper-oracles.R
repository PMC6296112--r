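# Independent brute-force oracles used to cross-check the implementation.

# Exhaustive frequent-itemset enumeration: all subsets (size <= maxlen) of
# the observed items, counted by scanning every transaction.
enumerate_itemsets <- function(tx, min_support, maxlen,
                               D = length(tx)) {
  items <- sort(unique(unlist(tx)))
  count_min <- max(1L, ceiling(min_support * D - 1e-9))
  out <- list()
  for (k in seq_len(min(maxlen, length(items)))) {
    combos <- utils::combn(items, k, simplify = FALSE)
    for (s in combos) {
      cnt <- sum(vapply(tx, function(t) all(s %in% t), TRUE))
      if (cnt >= count_min)
        out[[length(out) + 1]] <- list(items = s, count = cnt)
    }
  }
  out
}

itemset_key <- function(sets) {
  vapply(sets, function(s) paste(sort(s), collapse = "|"), "")
}

# ROR computed directly from report-level odds, no 2x2 construction.
brute_force_ror <- function(features, class_name) {
  exposed <- features[[paste0("cls_", class_name)]]
  ev <- features$fall_related
  odds_exposed <- sum(ev & exposed) / sum(!ev & exposed)
  odds_other <- sum(ev & !exposed) / sum(!ev & !exposed)
  odds_exposed / odds_other
}

# Pearson chi-squared of the 2x2 table implied by rule counts.
pearson_chi2 <- function(n_xy, n_x, n_y, D) {
  o <- matrix(c(n_xy, n_x - n_xy, n_y - n_xy, D - n_x - n_y + n_xy),
              2, 2)
  e <- outer(rowSums(o), colSums(o)) / D
  sum((o - e)^2 / e)
}

# A tiny hand-built four-table database written as CSVs.
write_toy_db <- function(dir, orphan = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  demo <- data.frame(
    report_id = c("r1", "r2", "r3"),
    age_description = c("75", "elderly", "42"),
    sex = c("male", "female", "male"))
  drug <- data.frame(
    report_id = c("r1", "r1", "r2", "r3"),
    generic_name = c("zolpidem", "amlodipine", "acetaminophen",
                     "paroxetine"),
    role = c("suspected", "concomitant", "suspected", "suspected"))
  if (orphan)
    drug <- rbind(drug, data.frame(report_id = "r9",
                                   generic_name = "zolpidem",
                                   role = "suspected"))
  reac <- data.frame(
    report_id = c("r1", "r1", "r2", "r3"),
    pt_code = c("10016173", "10028813", "10028813", "10013573"),
    pt_name = c("fall", "nausea", "nausea", "dizziness"))
  hist <- data.frame(report_id = "r1", term = "hypertension")
  utils::write.csv(demo, file.path(dir, "demo.csv"), row.names = FALSE)
  utils::write.csv(drug, file.path(dir, "drug.csv"), row.names = FALSE)
  utils::write.csv(reac, file.path(dir, "reac.csv"), row.names = FALSE)
  utils::write.csv(hist, file.path(dir, "hist.csv"), row.names = FALSE)
  dir
}

# Random transaction databases for property tests.
random_transactions <- function(n_tx, n_items, lambda = 3) {
  pool <- sprintf("i%02d", seq_len(n_items))
  lapply(seq_len(n_tx), function(i) {
    k <- min(n_items, stats::rpois(1, lambda))
    if (k == 0) character(0) else sample(pool, k)
  })
}

# The study's printed signal table: class, cases, class total, ROR and
# 95% CI at two decimals; overall 3715 fall-related of 430587 reports.
printed_signal_table <- function() {
  data.frame(
    class_name = c("alpha_blockers", "diuretics",
                   "calcium_channel_blockers", "opioids",
                   "benzodiazepines", "hypnotics_sedatives",
                   "nsmri", "ssri"),
    case = c(64L, 162L, 542L, 189L, 561L, 38L, 68L, 212L),
    total = c(4600L, 25016L, 51482L, 23530L, 38300L, 2865L, 3479L,
              9058L),
    ror = c(1.63, 0.74, 1.26, 0.93, 1.83, 1.55, 2.31, 2.86),
    ci_low = c(1.27, 0.63, 1.15, 0.80, 1.68, 1.12, 1.82, 2.49),
    ci_high = c(2.09, 0.86, 1.38, 1.07, 2.01, 2.14, 2.95, 3.29),
    stringsAsFactors = FALSE)
}

printed_D <- function() 430587L
printed_fall_total <- function() 3715L
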