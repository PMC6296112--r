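#' @importFrom rlang .data
NULL

#' Age bands of the analysis
#'
#' Reports are stratified on a 10-year grid. The open top band is labelled
#' `">=90"` internally; [age_band_display()] gives the decade-style alias
#' `"90-99"` used in printed rule tables.
#'
#' @return Character vector of the nine band labels, youngest first.
#' @export
age_bands <- function() {
  c("<=19", "20-29", "30-39", "40-49", "50-59",
    "60-69", "70-79", "80-89", ">=90")
}

#' @rdname age_bands
#' @param band Character vector of band labels.
#' @export
age_band_display <- function(band) {
  ifelse(band == ">=90", "90-99", ifelse(band == "<=19", "10-19", band))
}

#' Map a raw age description to an age band
#'
#' Accepts plain integer ages (`"75"`), integer ages with the Japanese
#' year suffix, and decade forms (the decade kanji suffix, e.g. the form
#' read "70s" meaning 70--79). Categorical descriptions that cannot be placed on the
#' 10-year grid -- "young adults", "adults", "elderly", pregnancy
#' trimesters, "unknown", empty strings -- map to `"EXCLUDED"`. Total
#' function: never errors.
#'
#' @param age_description Character vector of raw age descriptions.
#' @return Character vector of band labels or `"EXCLUDED"`.
#' @export
#' @examples
#' assign_age_band(c("75", "19", "elderly"))
assign_age_band <- function(age_description) {
  x <- trimws(as.character(age_description))
  out <- rep("EXCLUDED", length(x))
  dec <- grepl("^[0-9]+(\u6b73)?\u4ee3$", x)
  num <- !dec & grepl("^[0-9]+\u6b73?$", x)
  age <- rep(NA_real_, length(x))
  age[num] <- as.numeric(sub("\u6b73$", "", x[num]))
  # a decade form denotes the interval [d, d+9]; it lands in one band
  age[dec] <- as.numeric(sub("(\u6b73)?\u4ee3$", "", x[dec]))
  ok <- !is.na(age)
  bands <- age_bands()
  idx <- pmin(pmax(age[ok] %/% 10, 1), 9)
  out[ok] <- bands[idx]
  out
}

#' Fall-related adverse-event definition
#'
#' The default MedDRA Preferred Terms defining a fall-related event:
#' fall (10016173), dizziness (10013573), orthostatic hypotension
#' (10031127). Extensible by passing extra rows.
#'
#' @param extra Optional tibble/data.frame with columns `pt_code`,
#'   `pt_name` appended to the default set.
#' @return Tibble with columns `pt_code` (character), `pt_name`.
#' @export
fall_event_definition <- function(extra = NULL) {
  def <- tibble::tibble(
    pt_code = c("10016173", "10013573", "10031127"),
    pt_name = c("fall", "dizziness", "orthostatic hypotension"))
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)
    stopifnot(all(c("pt_code", "pt_name") %in% names(extra)))
    def <- dplyr::bind_rows(
      def, dplyr::mutate(extra, pt_code = as.character(.data$pt_code)))
  }
  def
}

#' Flag a report as fall-related
#'
#' `TRUE` iff any event matches the definition, by PT code or (fallback)
#' by PT name; monotone under adding events.
#'
#' @param pt_code,pt_name Character vectors of the report's event codes
#'   and names (either may be `NULL`).
#' @param event_def Event definition, see [fall_event_definition()].
#' @return Logical scalar.
#' @export
flag_fall_related <- function(pt_code = NULL, pt_name = NULL,
                              event_def = fall_event_definition()) {
  any(as.character(pt_code) %in% event_def$pt_code) ||
    any(tolower(as.character(pt_name)) %in% tolower(event_def$pt_name))
}

drug_roles <- function() c("suspected", "concomitant", "interacting")

new_srs_db <- function(demo, drug, reac, hist, orphans = NULL) {
  structure(list(demo = demo, drug = drug, reac = reac, hist = hist),
            orphans = orphans, class = "srs_db")
}

#' @export
print.srs_db <- function(x, ...) {
  cat("<srs_db> ", nrow(x$demo), " reports; ",
      nrow(x$drug), " drug rows, ", nrow(x$reac), " event rows, ",
      nrow(x$hist), " history rows\n", sep = "")
  orph <- attr(x, "orphans")
  if (!is.null(orph) && sum(unlist(orph)) > 0)
    cat("  orphan rows dropped from attachment:",
        paste(names(orph), unlist(orph), collapse = ", "), "\n")
  invisible(x)
}

db_schema <- function() {
  list(demo = c("report_id", "age_description", "sex"),
       drug = c("report_id", "generic_name", "role"),
       reac = c("report_id", "pt_code", "pt_name"),
       hist = c("report_id", "term"))
}

read_table_checked <- function(path, cols) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  probs <- readr::problems(tab)
  if (nrow(probs) > 0)
    stop("malformed row in ", basename(path), " at line ",
         probs$row[1] + 1L, ": ", probs$expected[1], call. = FALSE)
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0)
    stop("malformed file ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab[cols]
}

#' Load a four-table reporting database
#'
#' Reads the canonical CSV dialect (UTF-8, comma-separated, header row,
#' long format keyed by `report_id`): `demo.csv` (report_id,
#' age_description, sex), `drug.csv` (report_id, generic_name, role),
#' `reac.csv` (report_id, pt_code, pt_name), `hist.csv` (report_id,
#' term). Drug/event/history rows whose `report_id` does not occur in the
#' demographics table are counted and reported via a message and the
#' `"orphans"` attribute, never silently dropped.
#'
#' @param demo_path,drug_path,reac_path,hist_path Paths to the four CSV
#'   files; alternatively give `dir` containing them under the canonical
#'   file names.
#' @param dir Directory containing `demo.csv`, `drug.csv`, `reac.csv`,
#'   `hist.csv`.
#' @return An `srs_db` object (list of the four tibbles).
#' @export
load_database <- function(demo_path, drug_path, reac_path, hist_path,
                          dir = NULL) {
  if (!is.null(dir)) {
    demo_path <- file.path(dir, "demo.csv")
    drug_path <- file.path(dir, "drug.csv")
    reac_path <- file.path(dir, "reac.csv")
    hist_path <- file.path(dir, "hist.csv")
  }
  sch <- db_schema()
  demo <- read_table_checked(demo_path, sch$demo)
  drug <- read_table_checked(drug_path, sch$drug)
  reac <- read_table_checked(reac_path, sch$reac)
  hist <- read_table_checked(hist_path, sch$hist)
  if (anyDuplicated(demo$report_id))
    stop("duplicate report_id in demographics table: ",
         demo$report_id[duplicated(demo$report_id)][1], call. = FALSE)
  bad_role <- setdiff(unique(drug$role), drug_roles())
  if (length(bad_role) > 0)
    stop("invalid drug role code(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  ids <- demo$report_id
  orphans <- vapply(list(drug = drug, reac = reac, hist = hist),
                    function(t) sum(!t$report_id %in% ids), integer(1))
  if (sum(orphans) > 0)
    message("orphan rows referencing unknown report ids: ",
            paste(names(orphans), orphans, collapse = ", "))
  new_srs_db(demo, drug, reac, hist, orphans = as.list(orphans))
}

#' Write a database in the canonical CSV dialect
#'
#' @param db An `srs_db` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_database <- function(db, dir) {
  stopifnot(inherits(db, "srs_db"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("demo", "drug", "reac", "hist"))
    readr::write_csv(db[[nm]], file.path(dir, paste0(nm, ".csv")),
                     progress = FALSE)
  invisible(dir)
}

#' Report-level analysis features
#'
#' Joins the four tables into one row per report: age band, fall-related
#' flag, distinct-drug counts for the CNS-active and calcium-channel-
#' blocker groups, one exposure indicator per ATC class, and the list of
#' history terms. This is the substrate for both the disproportionality
#' and the rule-mining stages.
#'
#' @param db An `srs_db` object.
#' @param event_def Fall-related event definition.
#' @return Tibble with one row per demographics row, columns `report_id`,
#'   `age_band`, `fall_related`, `n_cns`, `n_ccb`, `cls_<class>` logical
#'   columns, and a `histories` list column.
#' @export
report_features <- function(db, event_def = fall_event_definition()) {
  stopifnot(inherits(db, "srs_db"))
  ids <- db$demo$report_id
  n <- length(ids)
  feat <- tibble::tibble(
    report_id = ids,
    age_band = assign_age_band(db$demo$age_description))

  # drug classification: one match pass over the long table
  map <- drug_class_map()
  dn <- canonical_drug_name(db$drug$generic_name)
  dcl <- map$class_name[match(dn, map$generic_name)]
  drid <- match(db$drug$report_id, ids)
  keep <- !is.na(drid) & !is.na(dcl)
  # distinct substances only: drop duplicated (report, canonical name)
  dup <- duplicated(paste(drid, dn, sep = "\r"))
  keep <- keep & !dup
  rid_k <- drid[keep]; cls_k <- dcl[keep]
  cns <- cns_active_classes()
  feat$n_cns <- tab_count(rid_k[cls_k %in% cns], n)
  feat$n_ccb <- tab_count(rid_k[cls_k == "calcium_channel_blockers"], n)
  for (cl in drug_classes())
    feat[[paste0("cls_", cl)]] <- tab_count(rid_k[cls_k == cl], n) > 0L

  # fall-related event flag
  erid <- match(db$reac$report_id, ids)
  is_fall <- db$reac$pt_code %in% event_def$pt_code |
    tolower(db$reac$pt_name) %in% tolower(event_def$pt_name)
  feat$fall_related <- tab_count(erid[!is.na(erid) & is_fall], n) > 0L

  # comorbidity terms
  hrid <- match(db$hist$report_id, ids)
  hk <- !is.na(hrid)
  feat$histories <- unname(split(
    db$hist$term[hk], factor(hrid[hk], levels = seq_len(n))))
  feat
}

# counts of occurrences of each report index 1..n
tab_count <- function(idx, n) {
  as.integer(tabulate(idx, nbins = n))
}

#' Retention summary after age stratification
#'
#' @param features Output of [report_features()].
#' @return Tibble with per-band report counts; `EXCLUDED` rows are the
#'   reports whose age description could not be banded.
#' @export
age_band_summary <- function(features) {
  lv <- c(age_bands(), "EXCLUDED")
  tibble::tibble(
    age_band = lv,
    n = as.integer(table(factor(features$age_band, levels = lv))))
}
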