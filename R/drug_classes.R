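#' ATC drug-class map for the fall-risk analysis
#'
#' The 98 compounds of the 2015 Beers Criteria fall-risk drug set, grouped
#' into eight ATC classes: alpha-adrenoreceptor antagonists (C02CA), loop
#' diuretics (C03CA/C03CC), calcium channel blockers (C08), opioids (N02A),
#' benzodiazepine derivatives and related drugs (N05CD/N05CF), other
#' hypnotics and sedatives (N05CA/N05CC/N05CH/N05CM), non-selective
#' monoamine reuptake inhibitors (N06AA) and SSRIs (N06AB).
#'
#' Two composite groups overlay the eight classes: `cns_active` (the union
#' of opioids, benzodiazepines, hypnotics/sedatives, non-selective
#' monoamine reuptake inhibitors and SSRIs) and `calcium_channel_blockers`
#' itself, both used for concomitant-drug counting.
#'
#' @return A tibble with columns `generic_name`, `atc_code`, `class_name`.
#' @export
drug_class_map <- function() {
  map <- rbind(
    cls("alpha_blockers",
        c("prazosin", "C02CA01", "doxazosin", "C02CA04",
          "urapidil", "C02CA06")),
    cls("diuretics",
        c("frosemide", "C03CA01", "bumetanide", "C03CA02",
          "piretanide", "C03CA03", "torasemide", "C03CA04",
          "ethacrynic acid", "C03CC01")),
    cls("calcium_channel_blockers",
        c("amlodipine", "C08CA01", "felodipine", "C08CA02",
          "nicardipine", "C08CA04", "nifedipine", "C08CA05",
          "nisoldipine", "C08CA07", "nitrendipine", "C08CA08",
          "nilvadipine", "C08CA10", "manidipine", "C08CA11",
          "barnidipine", "C08CA12", "cilnidipine", "C08CA14",
          "benidipine", "C08CA15", "verapamil", "C08DA01",
          "diltiazem", "C08DB01", "bepridil", "C08EA02")),
    cls("opioids",
        c("morphine", "N02AA01", "opium", "N02AA02",
          "oxycodone", "N02AA05", "dihydrocodeine", "N02AA08",
          "morphine, combinations", "N02AA51",
          "hydromorphone and naloxone", "N02AA53",
          "oxycodone and naloxone", "N02AA55",
          "oxycodone and naltrexone", "N02AA56",
          "dihydrocodeine, combinations", "N02AA58",
          "codeine, combinations excl. psycholeptics", "N02AA59",
          "codeine, combinations with psycholeptics", "N02AA79",
          "pethidine", "N02AB02", "fentanyl", "N02AB03",
          "pethidine, combinations excl. psycholeptics", "N02AB52",
          "pethidine, combinations with psycholeptics", "N02AB72",
          "methadone, combinations excl. psycholeptics", "N02AC52",
          "dextropropoxyphene, combinations excl. psycholeptics", "N02AC54",
          "dextropropoxyphene, combinations with psycholeptics", "N02AC74",
          "pentazocine", "N02AD01", "buprenorphine", "N02AE01",
          "butorphanol", "N02AF01",
          "morphine and antispasmodics", "N02AG01",
          "pethidine and antispasmodics", "N02AG03",
          "dihydrocodeine and paracetamol", "N02AJ01",
          "dihydrocodeine and acetylsalicylic acid", "N02AJ02",
          "dihydrocodeine and other non-opioid analgesics", "N02AJ03",
          "codeine and paracetamol", "N02AJ06",
          "codeine and acetylsalicylic acid", "N02AJ07",
          "codeine and ibuprofen", "N02AJ08",
          "codeine and other non-opioid analgesics", "N02AJ09",
          "tramadol and paracetamol", "N02AJ13",
          "tramadol and dexketoprofen", "N02AJ14",
          "tramadol and other non-opioid analgesics", "N02AJ15",
          "oxycodone and paracetamol", "N02AJ17",
          "oxycodone and acetylsalicylic acid", "N02AJ18",
          "oxycodone and ibuprofen", "N02AJ19",
          "tramadol", "N02AX02", "tapentadol", "N02AX06")),
    cls("benzodiazepines",
        c("flurazepam", "N05CD01", "nitrazepam", "N05CD02",
          "flunitrazepam", "N05CD03", "estazolam", "N05CD04",
          "triazoram", "N05CD05", "lormetazepam", "N05CD06",
          "midazolam", "N05CD08", "brotizolam", "N05CD09",
          "quazepam", "N05CD10", "zopiclone", "N05CF01",
          "zolpidem", "N05CF02", "eszopiclone", "N05CF04")),
    cls("hypnotics_sedatives",
        c("pentobarbital", "N05CA01", "amobarbital", "N05CA02",
          "barbital", "N05CA04", "secobarbital", "N05CA06",
          "thiopental", "N05CA19", "chloral hydrate", "N05CC01",
          "melatonin", "N05CH01", "ramelteon", "N05CH02",
          "bromisoval", "N05CM03", "scopolamine", "N05CM05",
          "triclofos", "N05CM07", "apronal", "N05CM12",
          "dexmedetomidine", "N05CM18")),
    cls("nsmri",
        c("desipramine", "N06AA01", "imipramine", "N06AA02",
          "clomipramine", "N06AA04", "trimipramine", "N06AA06",
          "lefepramine", "N06AA07", "amitriptyline", "N06AA09",
          "nortriptyline", "N06AA10", "dosulepin", "N06AA16",
          "amoxapine", "N06AA17")),
    cls("ssri",
        c("paroxetine", "N06AB05", "sertraline", "N06AB06",
          "fluvoxamine", "N06AB08", "escitalopram", "N06AB10"))
  )
  tibble::as_tibble(map)
}

cls <- function(class_name, pairs) {
  m <- matrix(pairs, ncol = 2, byrow = TRUE)
  data.frame(generic_name = m[, 1], atc_code = m[, 2],
             class_name = class_name, stringsAsFactors = FALSE)
}

# Common-spelling aliases for names the packaged table carries in a
# non-standard spelling; lookup-only, not part of the 98-row map.
drug_name_aliases <- function() {
  c(triazolam = "triazoram",
    furosemide = "frosemide",
    lofepramine = "lefepramine")
}

#' The eight drug classes of the analysis
#'
#' @param display if `TRUE`, return the long class labels used in the
#'   signal table instead of the internal identifiers.
#' @return Character vector of the eight class names.
#' @export
drug_classes <- function(display = FALSE) {
  ids <- c("alpha_blockers", "diuretics", "calcium_channel_blockers",
           "opioids", "benzodiazepines", "hypnotics_sedatives",
           "nsmri", "ssri")
  if (!display) return(ids)
  unname(class_display_names()[ids])
}

class_display_names <- function() {
  c(alpha_blockers = "Alpha-adrenoreceptor antagonists",
    diuretics = "Sulfonamides, plain/Aryloxyacetic acid derivatives",
    calcium_channel_blockers = "Calcium channel blockers",
    opioids = "Opioids",
    benzodiazepines =
      "Benzodiazepine derivatives/Benzodiazepine related drugs",
    hypnotics_sedatives = paste("Barbiturates, plain, Aldehydes, Melatonin",
                                "receptor agonists, and other hypnotics",
                                "and sedatives"),
    nsmri = "Non-selective monoamine reuptake inhibitors",
    ssri = "Selective serotonin reuptake inhibitors")
}

#' Classes forming the CNS-active composite group
#' @export
cns_active_classes <- function() {
  c("opioids", "benzodiazepines", "hypnotics_sedatives", "nsmri", "ssri")
}

# Canonicalise a generic name for lookup: trim, collapse whitespace,
# lower-case, resolve known aliases.
canonical_drug_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\s+", " ", x)
  al <- drug_name_aliases()
  hit <- match(x, names(al))
  x[!is.na(hit)] <- al[hit[!is.na(hit)]]
  x
}

#' Classify a drug by generic name
#'
#' Exact case-insensitive lookup against the packaged class map. A drug
#' belongs to at most one of the eight ATC classes; membership in the five
#' CNS classes additionally implies the `cns_active` composite group.
#'
#' @param generic_name Character vector of generic drug names.
#' @return A list (one element per input name) of character vectors of
#'   class names; empty for unmapped drugs.
#' @export
#' @examples
#' classify_drug("zolpidem")      # benzodiazepines + cns_active
#' classify_drug("acetaminophen") # unmapped: character(0)
classify_drug <- function(generic_name) {
  map <- drug_class_map()
  key <- canonical_drug_name(generic_name)
  idx <- match(key, map$generic_name)
  cns <- cns_active_classes()
  lapply(idx, function(i) {
    if (is.na(i)) return(character(0))
    cl <- map$class_name[i]
    if (cl %in% cns) c(cl, "cns_active") else cl
  })
}

# Generic names (canonical) belonging to a counting group.
group_members <- function(group) {
  map <- drug_class_map()
  if (group == "cns_active") {
    map$generic_name[map$class_name %in% cns_active_classes()]
  } else if (group %in% drug_classes()) {
    map$generic_name[map$class_name == group]
  } else {
    stop("unknown drug group: ", group, call. = FALSE)
  }
}

#' Count distinct drugs of a group within one report
#'
#' Counts distinct generic names (duplicated listings of one substance,
#' e.g. as both suspected and concomitant drug, count once). All role
#' codes are included.
#'
#' @param drug_names Character vector of the report's generic drug names.
#' @param group `"cns_active"`, `"calcium_channel_blockers"`, or any of
#'   the eight class names.
#' @return Integer count of distinct group members.
#' @export
count_class_drugs <- function(drug_names, group = "cns_active") {
  members <- group_members(group)
  length(unique(intersect(canonical_drug_name(drug_names), members)))
}
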