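ITEM_NAMESPACES <- c("age", "n_cns", "n_ccb", "class", "hist", "ev")

#' Encode reports as transactions
#'
#' Each report becomes an itemset of namespaced strings: `age:<band>`
#' (only for banded reports), `n_cns:<k>` / `n_ccb:<k>` (only when k >=
#' 1), `class:<name>` for each exposed ATC class, `hist:<term>` for each
#' comorbidity term, and `ev:fall_related` when the report is
#' fall-related. Reports with no mapped items are retained as empty
#' transactions and still contribute to the transaction total D.
#'
#' @param features Report features, see [report_features()].
#' @param items Namespaces to emit in addition to the consequent, a
#'   subset of `c("age", "n_cns", "n_ccb", "class", "hist")`.
#' @return A `transactions` object: list with `items` (list of character
#'   vectors), `report_id`, and `D` (number of transactions).
#' @export
encode_transactions <- function(features,
                                items = c("age", "n_cns", "n_ccb")) {
  unknown <- setdiff(items, setdiff(ITEM_NAMESPACES, "ev"))
  if (length(unknown) > 0)
    stop("unknown item namespace(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n <- nrow(features)
  parts <- vector("list", 0)
  if ("age" %in% items)
    parts$age <- ifelse(features$age_band == "EXCLUDED", NA_character_,
                        paste0("age:", features$age_band))
  if ("n_cns" %in% items)
    parts$n_cns <- ifelse(features$n_cns >= 1,
                          paste0("n_cns:", features$n_cns), NA_character_)
  if ("n_ccb" %in% items)
    parts$n_ccb <- ifelse(features$n_ccb >= 1,
                          paste0("n_ccb:", features$n_ccb), NA_character_)
  scalar <- c(parts, list(
    ev = ifelse(features$fall_related, "ev:fall_related", NA_character_)))
  mat <- do.call(cbind, scalar)
  tx <- apply(mat, 1, function(r) unname(r[!is.na(r)]), simplify = FALSE)
  if ("class" %in% items) {
    cols <- paste0("cls_", drug_classes())
    expo <- as.matrix(features[cols])
    cl_items <- paste0("class:", drug_classes())
    tx <- lapply(seq_len(n), function(i)
      c(tx[[i]], cl_items[expo[i, ]]))
  }
  if ("hist" %in% items) {
    tx <- lapply(seq_len(n), function(i) {
      h <- unique(features$histories[[i]])
      if (length(h) > 0) c(tx[[i]], paste0("hist:", h)) else tx[[i]]
    })
  }
  structure(list(items = tx, report_id = features$report_id, D = n),
            class = "transactions")
}

#' @export
print.transactions <- function(x, ...) {
  cat("<transactions> D =", x$D, "transactions,",
      length(unique(unlist(x$items))), "distinct items\n")
  invisible(x)
}

#' Level-wise apriori frequent-itemset mining
#'
#' Classic apriori: level k candidates are generated by joining frequent
#' (k-1)-itemsets sharing a (k-2)-prefix, pruned by the anti-monotonicity
#' of support (every subset of a frequent itemset must be frequent), and
#' counted by intersecting sorted transaction-id lists. An itemset is
#' frequent when `support >= min_support`, i.e. count >=
#' `ceiling(min_support * D)` (at least 1).
#'
#' @param transactions A `transactions` object (or bare list of character
#'   vectors).
#' @param min_support Minimum support in (0, 1].
#' @param maxlen Maximum itemset size (counting all items jointly; a rule
#'   mined from these itemsets has at most `maxlen - 1` antecedent items
#'   plus the consequent).
#' @param D Transaction count used as the support denominator; defaults
#'   to the number of transactions. Overriding it rescales support (used
#'   by subgroup analyses that keep the full-database denominator) while
#'   counts remain subgroup counts.
#' @return Tibble: `items` (list of sorted character vectors), `size`,
#'   `count`, `support`.
#' @export
apriori <- function(transactions, min_support = 1e-6, maxlen = 3,
                    D = NULL) {
  tx <- if (inherits(transactions, "transactions")) transactions$items
        else transactions
  if (length(tx) == 0)
    stop("empty transaction list", call. = FALSE)
  stopifnot(min_support > 0, min_support <= 1, maxlen >= 1)
  if (is.null(D)) D <- length(tx)
  count_min <- max(1L, as.integer(ceiling(min_support * D - 1e-9)))

  # inverted index: item -> sorted vector of transaction ids
  lens <- lengths(tx)
  flat <- unlist(tx, use.names = FALSE)
  tids_all <- split(rep.int(seq_along(tx), lens), flat)
  tids_all <- lapply(tids_all, function(v) sort.int(unique.default(v)))
  freq1 <- tids_all[vapply(tids_all, length, 1L) >= count_min]
  freq1 <- freq1[order(names(freq1), method = "radix")]

  sets <- list()   # per level: list(keys = list of char vecs, tids = list)
  if (length(freq1) > 0)
    sets[[1]] <- list(keys = lapply(names(freq1), identity),
                      tids = unname(freq1))
  k <- 1
  while (k < maxlen && length(sets) == k && length(sets[[k]]$keys) >= 2) {
    prev <- sets[[k]]
    keys <- prev$keys
    keystr <- vapply(keys, paste, "", collapse = "\x1f")
    prefix <- vapply(keys, function(s) paste(s[-length(s)],
                                             collapse = "\x1f"), "")
    last <- vapply(keys, function(s) s[length(s)], "")
    cand_keys <- list(); cand_tids <- list()
    for (grp in split(seq_along(keys), prefix)) {
      if (length(grp) < 2) next
      grp <- grp[order(last[grp], method = "radix")]
      for (i in seq_len(length(grp) - 1)) {
        for (j in seq(i + 1, length(grp))) {
          cand <- c(keys[[grp[i]]], last[grp[j]])
          # subset pruning: all k-subsets of the candidate frequent
          if (k >= 2) {
            ok <- all(vapply(seq_len(length(cand)), function(drop)
              paste(cand[-drop], collapse = "\x1f") %in% keystr, TRUE))
            if (!ok) next
          }
          tid <- intersect_sorted(prev$tids[[grp[i]]],
                                  prev$tids[[grp[j]]])
          if (length(tid) >= count_min) {
            cand_keys[[length(cand_keys) + 1]] <- cand
            cand_tids[[length(cand_tids) + 1]] <- tid
          }
        }
      }
    }
    if (length(cand_keys) == 0) break
    ord <- order(vapply(cand_keys, paste, "", collapse = "\x1f"),
                 method = "radix")
    sets[[k + 1]] <- list(keys = cand_keys[ord], tids = cand_tids[ord])
    k <- k + 1
  }

  if (length(sets) == 0)
    return(tibble::tibble(items = list(), size = integer(),
                          count = integer(), support = numeric()))
  all_keys <- do.call(c, lapply(sets, `[[`, "keys"))
  all_counts <- unlist(lapply(sets, function(s)
    vapply(s$tids, length, 1L)))
  tibble::tibble(items = all_keys,
                 size = lengths(all_keys),
                 count = as.integer(all_counts),
                 support = all_counts / D)
}

intersect_sorted <- function(x, y) x[match(x, y, 0L) > 0L]

#' Interest measures of a single association rule
#'
#' For a rule X => Y with `n_xy` joint cases, `n_x` antecedent cases,
#' `n_y` consequent cases out of `D` transactions:
#' support = n_xy / D, confidence = n_xy / n_x,
#' lift = confidence / (n_y / D), and the lift-based chi-squared
#' statistic
#' `D * (lift - 1)^2 * support * confidence /
#'  ((confidence - support) * (lift - confidence))`,
#' which equals the Pearson chi-squared of the underlying 2x2 table.
#' At exact independence (lift = 1) chi-squared is 0 by definition.
#' Degenerate denominators (n_x = D, n_y = D, or n_xy = 0) leave
#' chi-squared undefined: `NA` with the reason in `chi_flag`.
#'
#' @param n_xy,n_x,n_y,D Counts (vectorised); `n_xy <= min(n_x, n_y)`,
#'   `n_x, n_y > 0`, `D > 0`.
#' @return Tibble: `support`, `confidence`, `lift`, `chi_squared`,
#'   `chi_flag` (NA when defined).
#' @export
score_rule <- function(n_xy, n_x, n_y, D) {
  stopifnot(all(D > 0), all(n_x > 0), all(n_y > 0),
            all(n_xy <= pmin(n_x, n_y)))
  support <- n_xy / D
  confidence <- n_xy / n_x
  lift <- confidence / (n_y / D)
  chi <- D * (lift - 1)^2 * support * confidence /
    ((confidence - support) * (lift - confidence))
  flag <- rep(NA_character_, length(chi))
  indep <- abs(lift - 1) < 1e-12
  chi[indep] <- 0
  bad <- n_x == D | n_y == D | n_xy == 0
  chi[bad & !indep] <- NA_real_
  flag[bad & !indep] <- dplyr::case_when(
    n_x[bad & !indep] == D ~ "antecedent covers all transactions",
    n_y[bad & !indep] == D ~ "consequent covers all transactions",
    TRUE ~ "no joint cases")
  tibble::tibble(support = support, confidence = confidence,
                 lift = lift, chi_squared = chi, chi_flag = flag)
}

#' Generate association rules with a fixed consequent
#'
#' For every frequent itemset containing the consequent item, emits the
#' rule (itemset minus consequent) => consequent when its confidence
#' reaches `min_confidence`; the consequent restriction is a post-filter
#' over the frequent itemsets. Rules are scored with [score_rule()]
#' (support denominator `D`) and sorted by lift descending, then support
#' descending, then lexicographic antecedent. `significant` flags
#' chi-squared >= 4.
#'
#' @param itemsets Output of [apriori()].
#' @param rhs_item Consequent item (default `"ev:fall_related"`).
#' @param min_confidence Minimum confidence in (0, 1].
#' @param D Support denominator (defaults to the one implied by the
#'   itemsets' counts/support; pass explicitly when overriding).
#' @return Tibble: `lhs` (comma-joined antecedent), `rhs`, `case_n`,
#'   `support`, `confidence`, `lift`, `chi_squared`, `chi_flag`,
#'   `significant`.
#' @export
generate_rules <- function(itemsets, rhs_item = "ev:fall_related",
                           min_confidence = 0.001, D = NULL) {
  stopifnot(min_confidence > 0, min_confidence <= 1)
  empty <- tibble::tibble(
    lhs = character(), rhs = character(), case_n = integer(),
    support = numeric(), confidence = numeric(), lift = numeric(),
    chi_squared = numeric(), chi_flag = character(),
    significant = logical())
  if (nrow(itemsets) == 0) return(empty)
  if (is.null(D)) D <- round(itemsets$count[1] / itemsets$support[1])
  keystr <- vapply(itemsets$items, paste, "", collapse = "\x1f")
  counts <- stats::setNames(itemsets$count, keystr)
  if (!rhs_item %in% keystr) {
    warning("consequent item '", rhs_item,
            "' is not frequent; no rules generated")
    return(empty)
  }
  n_y <- counts[[rhs_item]]
  has_rhs <- which(itemsets$size >= 2 &
                     vapply(itemsets$items, function(s)
                       rhs_item %in% s, TRUE))
  if (length(has_rhs) == 0) return(empty)
  rows <- lapply(has_rhs, function(i) {
    set <- itemsets$items[[i]]
    lhs <- setdiff(set, rhs_item)
    key <- paste(lhs, collapse = "\x1f")
    n_x <- counts[[key]]   # frequent by anti-monotonicity
    list(lhs = lhs, n_xy = itemsets$count[i], n_x = n_x)
  })
  n_xy <- vapply(rows, `[[`, 1L, "n_xy")
  n_x <- vapply(rows, `[[`, 1L, "n_x")
  sc <- score_rule(n_xy, n_x, rep(n_y, length(n_x)), D)
  out <- tibble::tibble(
    lhs = vapply(rows, function(r) paste(r$lhs, collapse = ","), ""),
    rhs = rhs_item, case_n = n_xy,
    support = sc$support, confidence = sc$confidence, lift = sc$lift,
    chi_squared = sc$chi_squared, chi_flag = sc$chi_flag,
    significant = !is.na(sc$chi_squared) & sc$chi_squared >= 4)
  out <- out[out$confidence >= min_confidence - 1e-12, ]
  out[order(-out$lift, -out$support, out$lhs, method = "radix"), ]
}

#' Mine fall-related association rules from report features
#'
#' Convenience wrapper: encode, mine frequent itemsets, generate rules.
#'
#' @inheritParams encode_transactions
#' @inheritParams apriori
#' @inheritParams generate_rules
#' @param support_denominator `"subset"` (default) uses the analysed
#'   transaction count as D; `"full"` uses `full_D`, for subgroup runs
#'   that keep the full-database denominator.
#' @param full_D Full-database transaction count (required with
#'   `support_denominator = "full"`).
#' @return Rule tibble, see [generate_rules()].
#' @export
mine_rules <- function(features, items = c("age", "n_cns", "n_ccb"),
                       min_support = 1e-6, min_confidence = 0.001,
                       maxlen = 3, rhs_item = "ev:fall_related",
                       support_denominator = c("subset", "full"),
                       full_D = NULL) {
  support_denominator <- match.arg(support_denominator)
  tx <- encode_transactions(features, items)
  D <- if (support_denominator == "full") {
    if (is.null(full_D))
      stop("full_D required with support_denominator = 'full'",
           call. = FALSE)
    full_D
  } else tx$D
  sets <- apriori(tx, min_support = min_support, maxlen = maxlen, D = D)
  generate_rules(sets, rhs_item = rhs_item,
                 min_confidence = min_confidence, D = D)
}
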