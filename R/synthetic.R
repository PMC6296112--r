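#' Configuration of the synthetic reporting-database simulator
#'
#' Defaults mirror the structure of a large spontaneous-reporting
#' database of ~430k reports: per-class exposure prevalences equal to the
#' class report shares of the study database, a baseline fall-related
#' reporting probability of 3715/430587, and an age distribution with
#' about 57% of reports at age 60 or older. All exposures are independent
#' Bernoulli draws by default; the fall-related event probability of a
#' report is `clip(baseline * prod(multipliers of its items))` --
#' multiplicative risk, so at these rare event rates the planted
#' multiplier, the reporting odds ratio and the rule lift all coincide to
#' first order.
#'
#' @param n_reports Number of reports.
#' @param age_probs Probability vector over the nine age bands (must sum
#'   to 1).
#' @param excluded_age_prob Probability that a report carries a
#'   non-numeric age description (banded `EXCLUDED`).
#' @param class_prevalence Named probability of exposure per ATC class.
#' @param cns_count_dist Distribution of the number of distinct drugs
#'   (1..6) drawn from an exposed CNS class.
#' @param ccb_count_dist Same for calcium channel blockers (1..3).
#' @param comorbidity_prevalence Named probability per history term.
#' @param baseline_fall_prob Baseline fall-related probability in (0,1).
#' @param risk_multipliers Named multiplicative effects keyed by
#'   transaction items (e.g. `"class:benzodiazepines"`, `"age:80-89"`,
#'   `"n_cns:3"`, `"hist:dementia"`). Unlisted items have effect 1.
#' @param seed Integer seed; the same config is byte-identical across
#'   runs.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_reports = 10000,
    age_probs = c(0.05, 0.05, 0.07, 0.11, 0.15, 0.18, 0.20, 0.14, 0.05),
    excluded_age_prob = 0.02,
    class_prevalence = c(
      alpha_blockers = 4600 / 430587,
      diuretics = 25016 / 430587,
      calcium_channel_blockers = 51482 / 430587,
      opioids = 23530 / 430587,
      benzodiazepines = 38300 / 430587,
      hypnotics_sedatives = 2865 / 430587,
      nsmri = 3479 / 430587,
      ssri = 9058 / 430587),
    cns_count_dist = c(`1` = 0.70, `2` = 0.20, `3` = 0.07, `4` = 0.02,
                       `5` = 0.008, `6` = 0.002),
    ccb_count_dist = c(`1` = 0.85, `2` = 0.13, `3` = 0.02),
    comorbidity_prevalence = c(
      hypertension = 0.08, `type 2 diabetes mellitus` = 0.05,
      depression = 0.03, insomnia = 0.02, dementia = 0.012,
      schizophrenia = 0.012, osteoporosis = 0.01,
      `herpes zoster` = 0.005, `back pain` = 0.008,
      `rheumatoid arthritis` = 0.01),
    baseline_fall_prob = 3715 / 430587,
    risk_multipliers = numeric(0),
    seed = 1L) {
  cfg <- list(n_reports = n_reports, age_probs = age_probs,
              excluded_age_prob = excluded_age_prob,
              class_prevalence = class_prevalence,
              cns_count_dist = cns_count_dist,
              ccb_count_dist = ccb_count_dist,
              comorbidity_prevalence = comorbidity_prevalence,
              baseline_fall_prob = baseline_fall_prob,
              risk_multipliers = risk_multipliers, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_config <- function(cfg) {
  if (cfg$n_reports < 0 || cfg$n_reports != round(cfg$n_reports))
    stop("n_reports must be a nonnegative integer", call. = FALSE)
  for (nm in c("age_probs", "cns_count_dist", "ccb_count_dist")) {
    p <- cfg[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop(nm, " must be a probability vector summing to 1",
           call. = FALSE)
  }
  if (length(cfg$age_probs) != 9)
    stop("age_probs must have 9 entries (one per band)", call. = FALSE)
  probs <- c(cfg$excluded_age_prob, cfg$class_prevalence,
             cfg$comorbidity_prevalence)
  if (any(probs < 0 | probs > 1))
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  if (cfg$baseline_fall_prob <= 0 || cfg$baseline_fall_prob >= 1)
    stop("baseline_fall_prob must lie in (0, 1)", call. = FALSE)
  if (!setequal(names(cfg$class_prevalence), drug_classes()))
    stop("class_prevalence must name all eight drug classes",
         call. = FALSE)
  if (any(cfg$risk_multipliers < 0))
    stop("risk multipliers must be nonnegative", call. = FALSE)
  invisible(cfg)
}

# inert drugs and events used as filler so that every report has at
# least one drug row and one event row
filler_drugs <- function() {
  c("acetaminophen", "metformin", "atorvastatin", "omeprazole",
    "levothyroxine", "albuterol", "lisinopril", "losartan",
    "rosuvastatin", "pantoprazole", "montelukast", "cetirizine",
    "allopurinol", "clopidogrel", "warfarin", "insulin glargine")
}

filler_events <- function() {
  tibble::tibble(
    pt_code = c("10028813", "10019211", "10037844", "10047700",
                "10012735", "10028395"),
    pt_name = c("nausea", "hepatic function abnormal", "rash",
                "vomiting", "diarrhoea", "nasopharyngitis"))
}

#' Simulate a four-table reporting database
#'
#' Draws `n_reports` independent reports under a
#' [synthetic_config()]: age band (or an excluded categorical
#' description), independent per-class drug exposures with
#' per-class distinct-drug counts, comorbidity terms, and a fall-related
#' event with probability `clip(baseline * prod(multipliers))` over the
#' report's items. Exposed classes contribute drug names drawn from the
#' packaged ATC class lists; every report additionally carries at least
#' one inert filler drug, and reports without a fall-related event get a
#' filler event, so every report has a non-empty event set.
#'
#' @param config A `synthetic_config`.
#' @return An `srs_db`; the config is attached as attribute `"config"`
#'   and the per-report planted probability as attribute `"p_fall"`.
#' @export
simulate_srs <- function(config = synthetic_config()) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_reports
  bands <- age_bands()
  if (n == 0) {
    db <- new_srs_db(
      demo = tibble::tibble(report_id = character(),
                            age_description = character(),
                            sex = character()),
      drug = tibble::tibble(report_id = character(),
                            generic_name = character(),
                            role = character()),
      reac = tibble::tibble(report_id = character(),
                            pt_code = character(),
                            pt_name = character()),
      hist = tibble::tibble(report_id = character(), term = character()))
    attr(db, "config") <- config
    return(db)
  }
  ids <- sprintf("R%07d", seq_len(n))

  ## demographics
  band <- sample(bands, n, replace = TRUE, prob = config$age_probs)
  excluded <- stats::runif(n) < config$excluded_age_prob
  lo <- c(0, 2:9 * 10)[match(band, bands)]
  age_num <- lo + sample.int(10, n, replace = TRUE) - 1L
  age_num[band == "<=19"] <- sample.int(20, sum(band == "<=19"),
                                        replace = TRUE) - 1L
  age_desc <- as.character(age_num)
  age_desc[excluded] <- sample(c("elderly", "adults", "unknown"),
                               sum(excluded), replace = TRUE)
  band[excluded] <- "EXCLUDED"
  demo <- tibble::tibble(report_id = ids, age_description = age_desc,
                         sex = sample(c("male", "female"), n,
                                      replace = TRUE))

  ## per-class exposures and drug draws
  classes <- drug_classes()
  cns <- cns_active_classes()
  expo <- matrix(FALSE, n, length(classes),
                 dimnames = list(NULL, classes))
  drug_rows <- list()
  for (cl in classes) {
    e <- stats::runif(n) < config$class_prevalence[[cl]]
    expo[, cl] <- e
    idx <- which(e)
    if (length(idx) == 0) next
    members <- group_members(cl)
    dist <- if (cl %in% cns) config$cns_count_dist
            else if (cl == "calcium_channel_blockers")
              config$ccb_count_dist
            else c(`1` = 1)
    k <- as.integer(sample(names(dist), length(idx), replace = TRUE,
                           prob = dist))
    k <- pmin(k, length(members))
    rid <- rep.int(idx, k)
    nm <- unlist(lapply(k, function(ki)
      sample(members, ki, replace = FALSE)), use.names = FALSE)
    drug_rows[[cl]] <- data.frame(idx = rid, generic_name = nm,
                                  stringsAsFactors = FALSE)
  }
  # filler drugs: 1 + Poisson(0.5) per report
  n_fill <- 1L + stats::rpois(n, 0.5)
  drug_rows$filler <- data.frame(
    idx = rep.int(seq_len(n), n_fill),
    generic_name = sample(filler_drugs(), sum(n_fill), replace = TRUE),
    stringsAsFactors = FALSE)
  dr <- do.call(rbind, drug_rows)
  dr <- dr[order(dr$idx), , drop = FALSE]
  role <- sample(drug_roles(), nrow(dr), replace = TRUE,
                 prob = c(0.5, 0.45, 0.05))
  role[!duplicated(dr$idx)] <- "suspected"
  drug <- tibble::tibble(report_id = ids[dr$idx],
                         generic_name = dr$generic_name, role = role)

  ## comorbidities
  terms <- names(config$comorbidity_prevalence)
  hist_rows <- lapply(terms, function(tm) {
    idx <- which(stats::runif(n) < config$comorbidity_prevalence[[tm]])
    data.frame(idx = idx, term = rep(tm, length(idx)),
               stringsAsFactors = FALSE)
  })
  hr <- do.call(rbind, hist_rows)
  hr <- hr[order(hr$idx), , drop = FALSE]
  hist <- tibble::tibble(report_id = ids[hr$idx], term = hr$term)
  has_hist <- matrix(FALSE, n, length(terms),
                     dimnames = list(NULL, terms))
  has_hist[cbind(hr$idx, match(hr$term, terms))] <- TRUE

  ## planted fall-related probability: multiplicative on items
  mult <- config$risk_multipliers
  log_p <- rep(log(config$baseline_fall_prob), n)
  item_effect <- function(item, present) {
    if (item %in% names(mult)) log(mult[[item]]) * present else 0
  }
  for (cl in classes)
    log_p <- log_p + item_effect(paste0("class:", cl), expo[, cl])
  for (tm in terms)
    log_p <- log_p + item_effect(paste0("hist:", tm), has_hist[, tm])
  age_item <- paste0("age:", band)
  hit <- match(age_item, names(mult))
  log_p <- log_p + ifelse(is.na(hit), 0, log(mult[hit]))
  # distinct CNS / CCB drug counts as realised from the draws
  # drawn names are already canonical (they come from the packaged lists)
  cnt_of <- function(group) {
    rows <- dr[dr$generic_name %in% group_members(group), , drop = FALSE]
    rows <- rows[!duplicated(paste(rows$idx, rows$generic_name)), ,
                 drop = FALSE]
    tab_count(rows$idx, n)
  }
  n_cns <- cnt_of("cns_active")
  n_ccb <- cnt_of("calcium_channel_blockers")
  for (v in list(c("n_cns"), c("n_ccb"))) {
    counts <- if (v == "n_cns") n_cns else n_ccb
    items <- paste0(v, ":", counts)
    hit <- match(items, names(mult))
    log_p <- log_p + ifelse(is.na(hit) | counts == 0, 0, log(mult[hit]))
  }
  p_fall <- pmin(pmax(exp(log_p), 1e-9), 1 - 1e-9)
  fall <- stats::runif(n) < p_fall

  ## events: one fall PT for fall reports, else one filler PT
  fdef <- fall_event_definition()
  fidx <- which(fall)
  fpick <- sample.int(nrow(fdef), length(fidx), replace = TRUE)
  oidx <- which(!fall)
  fe <- filler_events()
  opick <- sample.int(nrow(fe), length(oidx), replace = TRUE)
  reac <- tibble::tibble(
    report_id = c(ids[fidx], ids[oidx]),
    pt_code = c(fdef$pt_code[fpick], fe$pt_code[opick]),
    pt_name = c(fdef$pt_name[fpick], fe$pt_name[opick]))
  reac <- reac[order(match(reac$report_id, ids)), ]

  db <- new_srs_db(demo, drug, reac, hist)
  attr(db, "config") <- config
  attr(db, "p_fall") <- p_fall
  db
}

#' Build a database realising an exact 2x2 contingency table
#'
#' Constructs `a + b + c + d` minimal reports such that
#' [build_contingency()] for (`drug_class`, fall-related) returns exactly
#' `(a, b, c, d)`: `a` reports with one drug of the class and a fall
#' event, `b` with the class drug and a filler event, `c` with a filler
#' drug and a fall event, `d` with filler drug and filler event.
#'
#' @param a,b,c,d Nonnegative integer cell counts (not all zero).
#' @param drug_class One of [drug_classes()].
#' @return An `srs_db`.
#' @export
fixture_from_counts <- function(a, b, c, d,
                                drug_class = "benzodiazepines") {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  if (sum(cells) == 0)
    stop("all four cells are zero: empty table", call. = FALSE)
  if (!drug_class %in% drug_classes())
    stop("unknown drug class: ", drug_class, call. = FALSE)
  n <- sum(cells)
  ids <- sprintf("R%07d", seq_len(n))
  exposed <- rep(c(TRUE, TRUE, FALSE, FALSE), cells)
  event <- rep(c(TRUE, FALSE, TRUE, FALSE), cells)
  class_drug <- group_members(drug_class)[1]
  fdef <- fall_event_definition()
  demo <- tibble::tibble(report_id = ids, age_description = "60",
                         sex = "female")
  drug <- tibble::tibble(
    report_id = ids,
    generic_name = ifelse(exposed, class_drug, filler_drugs()[1]),
    role = "suspected")
  reac <- tibble::tibble(
    report_id = ids,
    pt_code = ifelse(event, fdef$pt_code[1], filler_events()$pt_code[1]),
    pt_name = ifelse(event, fdef$pt_name[1], filler_events()$pt_name[1]))
  hist <- tibble::tibble(report_id = character(), term = character())
  new_srs_db(demo, drug, reac, hist)
}
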