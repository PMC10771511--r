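#' Extract serious adverse-event records from a trial
#'
#' Keeps reported events with severity `serious` and at least one affected
#' subject, and drops the per-arm aggregation rows titled
#' "Total, serious adverse events" so totals are never double counted.
#' Records violating `affected <= at_risk` are quarantined (returned in the
#' `quarantined` attribute with a diagnostic), never silently kept.
#'
#' @param trial A `trial_record`.
#' @return Tibble of unmatched safety records: `nct_id`, `arm_title`,
#'   `event_title`, `category`, `severity`, `affected`, `at_risk`; attribute
#'   `quarantined` holds any count-inconsistent rows.
#' @export
extract_safety <- function(trial) {
  stopifnot(inherits(trial, "trial_record"))
  ev <- trial$events
  empty <- tibble::tibble(
    nct_id = character(0), arm_title = character(0), event_title = character(0),
    category = character(0), severity = character(0),
    affected = integer(0), at_risk = integer(0)
  )
  if (nrow(ev) == 0) {
    return(structure(empty, quarantined = empty))
  }
  ev <- tibble::tibble(nct_id = trial$nct_id, ev)
  keep <- ev$severity == "serious" &
    !is.na(ev$affected) & ev$affected >= 1L &
    normalize_title(ev$event_title) != "total, serious adverse events"
  ev <- ev[keep, ]
  bad <- !is.na(ev$at_risk) & ev$affected > ev$at_risk
  if (any(bad)) {
    rlang::warn(paste0(
      "Quarantined ", sum(bad), " event record(s) in ", trial$nct_id,
      " with affected > at_risk."
    ))
  }
  structure(ev[!bad, ], quarantined = ev[bad, ])
}

#' Match an adverse-event arm title to the efficacy arm groups
#'
#' Arm titles in the reported-events section are not always written
#' exactly as in the efficacy analyses (e.g. "Laquinimod 0.6 mg" vs
#' "Laquinimod"). An exact match — case-insensitive, whitespace-normalized —
#' wins with method `"string"`; otherwise the candidate with the highest
#' embedding cosine similarity is returned with method `"embedding"`.
#'
#' @param arm_title Event-section arm title.
#' @param efficacy_group_titles Non-empty character vector of candidate
#'   efficacy arm titles.
#' @param backend Embedding backend (default [ngram_backend()]).
#' @return List with `matched_group` and `match_method`.
#' @export
match_ae_group <- function(arm_title, efficacy_group_titles, backend = ngram_backend()) {
  if (length(efficacy_group_titles) == 0) {
    rlang::abort("match_ae_group: empty candidate list.")
  }
  hit <- match(normalize_title(arm_title), normalize_title(efficacy_group_titles))
  if (!is.na(hit)) {
    return(list(matched_group = efficacy_group_titles[hit], match_method = "string"))
  }
  emb <- backend$embed(c(arm_title, efficacy_group_titles))
  sims <- vapply(
    seq_along(efficacy_group_titles),
    function(i) cosine_similarity(emb[1, ], emb[1 + i, ]),
    numeric(1)
  )
  best <- which(sims >= max(sims) - 1e-12)[1]
  list(matched_group = efficacy_group_titles[best], match_method = "embedding")
}

#' Match every safety record of a corpus to its trial's efficacy arms
#'
#' @param records Safety records (from [extract_safety()], possibly bound
#'   over many trials).
#' @param efficacy Resolved efficacy rows (see [resolve_arms_rows()]); the
#'   candidate arm titles per trial are the union of its
#'   `intervention_group` and `comparator_group` values.
#' @param backend Embedding backend.
#' @return `records` with `matched_group` and `match_method` columns;
#'   records from trials with no resolved efficacy arms keep `NA`.
#' @export
match_safety_records <- function(records, efficacy, backend = ngram_backend()) {
  n <- nrow(records)
  records$matched_group <- rep(NA_character_, n)
  records$match_method <- rep(NA_character_, n)
  if (n == 0) {
    return(records)
  }
  cand_map <- split(
    c(efficacy$intervention_group, efficacy$comparator_group),
    c(efficacy$nct_id, efficacy$nct_id)
  )
  cand_map <- lapply(cand_map, function(x) unique(x[!is.na(x)]))
  # memoize per (trial, arm_title): event tables repeat arm titles heavily
  for (nct in unique(records$nct_id)) {
    cands <- cand_map[[nct]]
    if (is.null(cands) || length(cands) == 0) next
    idx <- which(records$nct_id == nct & !is.na(records$arm_title))
    arms <- unique(records$arm_title[idx])
    if (length(arms) == 0) next
    matches <- lapply(arms, match_ae_group, efficacy_group_titles = cands, backend = backend)
    names(matches) <- arms
    records$matched_group[idx] <- vapply(records$arm_title[idx], function(a) matches[[a]]$matched_group, character(1))
    records$match_method[idx] <- vapply(records$arm_title[idx], function(a) matches[[a]]$match_method, character(1))
  }
  records
}

#' Restrict safety records to trials with valid efficacy results
#'
#' The linked representation only covers studies where both facets exist:
#' a safety record is retained iff its trial has at least one classified
#' (non-indeterminate, non-excluded) efficacy row. The retained/total
#' fraction is attached as attribute `retained_fraction`.
#'
#' @param safety Safety records.
#' @param efficacy Classified efficacy rows (see [classify_rows()]).
#' @return The retained subset, with attribute `retained_fraction`.
#' @export
filter_to_efficacy_trials <- function(safety, efficacy) {
  valid <- !is.na(efficacy$significance) & efficacy$significance != "indeterminate" &
    !(efficacy$excluded %in% TRUE)
  valid_ncts <- unique(efficacy$nct_id[valid])
  keep <- safety$nct_id %in% valid_ncts
  structure(
    safety[keep, ],
    retained_fraction = if (nrow(safety) == 0) NA_real_ else mean(keep)
  )
}

#' Ratio-weighted co-occurrence of SAE categories
#'
#' Two adverse-event body-system categories co-occur when both report
#' affected participants in the same trial. Each co-occurrence contributes
#' the product of the categories' per-trial affected/at-risk ratios, so
#' the weight of a pair (a, b) is
#' \deqn{w(a,b) = \sum_t c_t(a,b)\, r_t(a)\, r_t(b)}
#' where \eqn{c_t(a,b)} indicates that both categories report affected
#' subjects in trial \eqn{t} and \eqn{r_t(x)} is category \eqn{x}'s pooled
#' ratio \eqn{\sum \mathrm{affected} / \sum \mathrm{at\_risk}} over its
#' records in \eqn{t}. Records with missing `at_risk` are skipped (and
#' tallied in attribute `skipped_no_at_risk`).
#'
#' @param records Matched safety records with `nct_id`, `category`,
#'   `affected`, `at_risk`.
#' @return A `cooccurrence_matrix`: list with `categories` (sorted) and
#'   `weights` (symmetric non-negative matrix, zero diagonal).
#' @export
compute_cooccurrence <- function(records) {
  usable <- !is.na(records$at_risk) & records$at_risk >= 1
  skipped <- sum(!usable)
  records <- records[usable, ]
  categories <- sort(unique(records$category))
  k <- length(categories)
  weights <- matrix(0, k, k, dimnames = list(categories, categories))
  if (k > 0 && nrow(records) > 0) {
    per_trial <- dplyr::summarise(
      dplyr::group_by(records, .data$nct_id, .data$category),
      ratio = sum(.data$affected) / sum(.data$at_risk),
      .groups = "drop"
    )
    for (trial in split(per_trial, per_trial$nct_id)) {
      if (nrow(trial) < 2) next
      idx <- match(trial$category, categories)
      for (i in seq_len(nrow(trial) - 1)) {
        for (j in (i + 1):nrow(trial)) {
          w <- trial$ratio[i] * trial$ratio[j]
          weights[idx[i], idx[j]] <- weights[idx[i], idx[j]] + w
          weights[idx[j], idx[i]] <- weights[idx[j], idx[i]] + w
        }
      }
    }
  }
  structure(
    list(categories = categories, weights = weights),
    skipped_no_at_risk = skipped,
    class = "cooccurrence_matrix"
  )
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat(sprintf(
    "<cooccurrence_matrix: %d categories, total weight %.4f>\n",
    length(x$categories), sum(x$weights) / 2
  ))
  invisible(x)
}

#' Edge-list view of a co-occurrence matrix
#'
#' @param cooc A `cooccurrence_matrix`.
#' @param drop_zero Drop never-co-reported pairs (default TRUE).
#' @return Tibble `category_a`, `category_b`, `weight` (each unordered pair
#'   once, a < b lexicographically), sorted by decreasing weight.
#' @export
cooccurrence_edges <- function(cooc, drop_zero = TRUE) {
  k <- length(cooc$categories)
  if (k < 2) {
    return(tibble::tibble(category_a = character(0), category_b = character(0), weight = numeric(0)))
  }
  pairs <- which(upper.tri(cooc$weights), arr.ind = TRUE)
  out <- tibble::tibble(
    category_a = cooc$categories[pairs[, "row"]],
    category_b = cooc$categories[pairs[, "col"]],
    weight = cooc$weights[pairs]
  )
  if (drop_zero) out <- out[out$weight > 0, ]
  out[order(-out$weight, out$category_a, out$category_b), ]
}

#' Affected-subject totals by intervention type or event category
#'
#' Sums affected subjects over safety records, keyed either by the SAE
#' body-system category or by the trial's intervention type. For the
#' intervention-type table, records from trials with zero or multiple
#' intervention types are excluded, so every count is attributable to
#' exactly one type.
#'
#' @param records Safety records.
#' @param key `"category"` or `"intervention_type"`.
#' @param trial_types For `key = "intervention_type"`: a tibble mapping
#'   `nct_id` to `intervention_types` (list-column), e.g. distilled from
#'   trial records.
#' @return Tibble `key`, `affected`, sorted descending.
#' @export
aggregate_affected <- function(records, key = c("category", "intervention_type"), trial_types = NULL) {
  key <- match.arg(key)
  if (key == "intervention_type") {
    if (is.null(trial_types)) {
      rlang::abort("aggregate_affected: trial_types required for key = 'intervention_type'.")
    }
    n_types <- vapply(trial_types$intervention_types, length, integer(1))
    single <- trial_types[n_types == 1L, ]
    single$key <- vapply(single$intervention_types, `[[`, character(1), 1)
    records <- dplyr::inner_join(records, single[, c("nct_id", "key")], by = "nct_id")
  } else {
    records$key <- records$category
  }
  out <- dplyr::summarise(
    dplyr::group_by(records, .data$key),
    affected = sum(.data$affected),
    .groups = "drop"
  )
  names(out)[1] <- key
  out[order(-out$affected, out[[key]]), ]
}
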