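#' Two-by-two contingency table for a drug class
#'
#' Counts reports once each into the standard disproportionality layout:
#' `a` = target event and index class, `b` = other events and index
#' class, `c` = target event and other drugs, `d` = other events and
#' other drugs. Class membership means any drug of the report maps to the
#' class. The full database (age-excluded reports included) is used.
#'
#' @param features Report features, see [report_features()].
#' @param class_name One of [drug_classes()].
#' @param event_col Name of the logical event column (default
#'   `"fall_related"`).
#' @return A `contingency_2x2` object (named integer vector a, b, c, d).
#' @export
build_contingency <- function(features, class_name,
                              event_col = "fall_related") {
  if (nrow(features) == 0)
    stop("empty report set", call. = FALSE)
  col <- paste0("cls_", class_name)
  if (!col %in% names(features))
    stop("unknown drug class: ", class_name, call. = FALSE)
  exposed <- features[[col]]
  event <- features[[event_col]]
  contingency_table(
    a = sum(exposed & event), b = sum(exposed & !event),
    c = sum(!exposed & event), d = sum(!exposed & !event),
    class_name = class_name)
}

#' @rdname build_contingency
#' @param a,b,c,d Nonnegative cell counts.
#' @export
contingency_table <- function(a, b, c, d, class_name = NA_character_) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  structure(as.integer(cells), names = names(cells),
            class_name = class_name, class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(unclass(x), 2, 2, byrow = TRUE,
              dimnames = list(c("index class", "other drugs"),
                              c("target event", "other events")))
  cat("<contingency_2x2>", attr(x, "class_name"), "\n")
  print(m)
  invisible(x)
}

#' Crude reporting odds ratio with Woolf 95% confidence interval
#'
#' ROR = (a/c)/(b/d); the CI is the log-normal (Woolf) interval
#' `exp(log(ROR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is
#' zero the Haldane-Anscombe correction (+0.5 to every cell) is applied
#' and the result is flagged `corrected`. A class is a signal when the CI
#' lower bound exceeds 1 and there are at least 2 cases.
#'
#' @param table A `contingency_2x2` object.
#' @param conf_z Normal quantile for the interval (1.96 for 95%).
#' @return One-row tibble: `class_name`, `case_count` (= a),
#'   `class_total` (= a+b), `reporting_ratio` (percent), `ror`, `ci_low`,
#'   `ci_high`, `is_signal`, `corrected`.
#' @export
ror <- function(table, conf_z = 1.96) {
  stopifnot(inherits(table, "contingency_2x2"))
  cells <- as.numeric(table)
  names(cells) <- names(table)
  corrected <- any(cells == 0)
  x <- if (corrected) cells + 0.5 else cells
  est <- (x["a"] / x["c"]) / (x["b"] / x["d"])
  se <- sqrt(sum(1 / x))
  ci <- exp(log(est) + c(-1, 1) * conf_z * se)
  tibble::tibble(
    class_name = attr(table, "class_name"),
    case_count = as.integer(cells["a"]),
    class_total = as.integer(cells["a"] + cells["b"]),
    reporting_ratio = unname(100 * cells["a"] / (cells["a"] + cells["b"])),
    ror = unname(est),
    ci_low = ci[1], ci_high = ci[2],
    is_signal = ci[1] > 1 && cells["a"] >= 2,
    corrected = corrected)
}

#' Signal detection across drug classes
#'
#' One ROR row per class, in the given class order.
#'
#' @param features Report features.
#' @param classes Character vector of class names (default: all eight).
#' @param event_col Logical event column name.
#' @return Tibble of [ror()] rows plus a `class_label` display column.
#' @export
detect_signals <- function(features, classes = drug_classes(),
                           event_col = "fall_related") {
  if (length(classes) == 0)
    stop("class list is empty", call. = FALSE)
  unknown <- setdiff(classes, drug_classes())
  if (length(unknown) > 0)
    stop("unknown drug class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- dplyr::bind_rows(lapply(
    classes, function(cl) ror(build_contingency(features, cl, event_col))))
  out$class_label <- unname(class_display_names()[out$class_name])
  out
}
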