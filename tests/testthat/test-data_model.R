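test_that("age descriptions map onto the 10-year grid, others excluded", {
  cases <- list(
    list("75", "70-79"), list("19", "<=19"), list("0", "<=19"),
    list("20", "20-29"), list("89", "80-89"), list("90", ">=90"),
    list("104", ">=90"), list("70\u6b73\u4ee3", "70-79"),
    list("10\u6b73\u4ee3", "<=19"), list("90\u4ee3", ">=90"),
    list("45\u6b73", "40-49"),
    list("elderly", "EXCLUDED"), list("adults", "EXCLUDED"),
    list("young adults", "EXCLUDED"), list("first trimester", "EXCLUDED"),
    list("unknown", "EXCLUDED"), list("", "EXCLUDED"),
    list("  75 ", "70-79"))
  for (cs in cases)
    expect_identical(assign_age_band(cs[[1]]), cs[[2]], label = cs[[1]])
})

test_that("age banding partitions every report exactly once", {
  db <- simulate_srs(synthetic_config(n_reports = 3000, seed = 11))
  f <- report_features(db)
  smry <- age_band_summary(f)
  expect_identical(sum(smry$n), nrow(db$demo))
  expect_true(all(f$age_band %in% c(age_bands(), "EXCLUDED")))
})

test_that("packaged class map reproduces the 98-drug ATC table", {
  map <- drug_class_map()
  expect_identical(nrow(map), 98L)
  sizes <- table(map$class_name)
  expect_identical(as.integer(sizes[c(
    "alpha_blockers", "diuretics", "calcium_channel_blockers",
    "opioids", "benzodiazepines", "hypnotics_sedatives", "nsmri",
    "ssri")]), c(3L, 5L, 14L, 38L, 12L, 13L, 9L, 4L))
  expect_false(anyDuplicated(map$generic_name) > 0)
  expect_false(anyDuplicated(map$atc_code) > 0)
  # spot-check members and codes
  expect_identical(map$atc_code[map$generic_name == "zolpidem"],
                   "N05CF02")
  expect_identical(map$atc_code[map$generic_name == "amlodipine"],
                   "C08CA01")
  expect_identical(map$class_name[map$generic_name == "ramelteon"],
                   "hypnotics_sedatives")
  expect_identical(map$class_name[map$generic_name == "tapentadol"],
                   "opioids")
  # the eight classes are distinct by ATC prefix
  prefix <- substr(map$atc_code, 1, 5)
  expect_true(all(lengths(tapply(map$class_name, prefix, unique)) == 1))
})

test_that("drug classification is case-insensitive with composites", {
  expect_setequal(classify_drug("zolpidem")[[1]],
                  c("benzodiazepines", "cns_active"))
  expect_setequal(classify_drug(" Zolpidem ")[[1]],
                  c("benzodiazepines", "cns_active"))
  expect_identical(classify_drug("amlodipine")[[1]],
                   "calcium_channel_blockers")
  expect_identical(classify_drug("acetaminophen")[[1]], character(0))
  # standard-spelling aliases resolve to the packaged entries
  expect_setequal(classify_drug("triazolam")[[1]],
                  c("benzodiazepines", "cns_active"))
  expect_identical(classify_drug("furosemide")[[1]], "diuretics")
})

test_that("group drug counting is over distinct substances", {
  expect_identical(
    count_class_drugs(c("triazolam", "zolpidem", "paroxetine"),
                      "cns_active"), 3L)
  expect_identical(
    count_class_drugs(c("amlodipine", "amlodipine"),
                      "calcium_channel_blockers"), 1L)
  expect_identical(
    count_class_drugs(c("fentanyl", "ramelteon", "amitriptyline",
                        "sertraline", "nitrazepam"), "cns_active"), 5L)
  expect_identical(count_class_drugs(character(0), "cns_active"), 0L)
})

test_that("fall-related flag has any-match semantics and is monotone", {
  expect_true(flag_fall_related(pt_name = "dizziness"))
  expect_false(flag_fall_related(pt_name = "nausea"))
  expect_true(flag_fall_related(pt_name = c("fall", "nausea")))
  expect_true(flag_fall_related(pt_code = "10031127"))
  # monotone under event-set union: adding events never unsets the flag
  set.seed(4)
  pts <- c("10016173", "10028813", "10019211", "10013573", "10037844")
  for (i in 1:20) {
    base <- sample(pts, 2)
    more <- c(base, sample(pts, 2))
    expect_true(flag_fall_related(pt_code = base) <=
                  flag_fall_related(pt_code = more))
  }
})

test_that("four-table load attaches rows by report id", {
  dir <- write_toy_db(withr::local_tempdir())
  db <- load_database(dir = dir)
  f <- report_features(db)
  expect_identical(nrow(f), 3L)
  expect_identical(f$age_band, c("70-79", "EXCLUDED", "40-49"))
  expect_identical(f$fall_related, c(TRUE, FALSE, TRUE))
  expect_identical(f$n_cns, c(1L, 0L, 1L))
  expect_identical(f$n_ccb, c(1L, 0L, 0L))
  expect_identical(f$histories[[1]], "hypertension")
  expect_length(f$histories[[2]], 0)
})

test_that("orphan rows are reported, not silently dropped", {
  dir <- write_toy_db(withr::local_tempdir(), orphan = TRUE)
  expect_message(db <- load_database(dir = dir), "orphan")
  expect_identical(attr(db, "orphans")$drug, 1L)
  expect_identical(nrow(report_features(db)), 3L)
})

test_that("load validates files, roles and duplicate ids", {
  dir <- write_toy_db(withr::local_tempdir())
  expect_error(load_database(file.path(dir, "nope.csv"),
                             file.path(dir, "drug.csv"),
                             file.path(dir, "reac.csv"),
                             file.path(dir, "hist.csv")),
               "not found")
  demo <- utils::read.csv(file.path(dir, "demo.csv"))
  utils::write.csv(rbind(demo, demo[1, ]), file.path(dir, "demo.csv"),
                   row.names = FALSE)
  expect_error(load_database(dir = dir), "duplicate report_id")
  dir2 <- write_toy_db(withr::local_tempdir())
  drug <- utils::read.csv(file.path(dir2, "drug.csv"))
  drug$role[1] <- "bogus"
  utils::write.csv(drug, file.path(dir2, "drug.csv"), row.names = FALSE)
  expect_error(load_database(dir = dir2), "role")
  dir3 <- write_toy_db(withr::local_tempdir())
  writeLines(c("report_id,wrong", "r1,1"), file.path(dir3, "demo.csv"))
  expect_error(load_database(dir = dir3), "missing column")
})

test_that("a synthetic database round-trips write -> load exactly", {
  db <- simulate_srs(synthetic_config(n_reports = 10000, seed = 3))
  dir <- withr::local_tempdir()
  write_database(db, dir)
  db2 <- load_database(dir = dir)
  for (nm in c("demo", "drug", "reac", "hist"))
    expect_identical(as.data.frame(db2[[nm]]), as.data.frame(db[[nm]]),
                     label = nm)
})
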