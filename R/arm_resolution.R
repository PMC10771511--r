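#' Deterministic character n-gram embedding backend
#'
#' The default similarity backend for arm-title matching: titles are
#' lowercased and whitespace-normalized, decomposed into overlapping
#' character n-grams (with a leading/trailing space as a word boundary
#' marker), and each n-gram's term frequency is accumulated into a
#' fixed-length vector via a deterministic polynomial hash. Cosine
#' similarity on these vectors behaves like a fuzzy string match: identical
#' normalized titles score exactly 1, and dose suffixes or small edits
#' lower the score gracefully. No model download is needed and results are
#' identical across platforms and runs.
#'
#' A transformer-based biomedical sentence encoder can be plugged in as an
#' alternative backend: any list with fields `name`, `version`, and
#' `embed(texts) -> matrix` satisfies the contract.
#'
#' @param n n-gram size (default 3).
#' @param dim Length of the hashed vector (default 4096).
#' @return An embedding backend: list with `name`, `version`, and `embed`.
#' @export
ngram_backend <- function(n = 3L, dim = 4096L) {
  force(n)
  force(dim)
  list(
    name = sprintf("ngram%d", n),
    version = "1.0",
    embed = function(texts) {
      mat <- matrix(0, nrow = length(texts), ncol = dim)
      for (i in seq_along(texts)) {
        s <- paste0(" ", normalize_title(texts[i]), " ")
        codes <- utf8ToInt(s)
        len <- length(codes)
        if (len < n) {
          idx <- (poly_hash(codes) %% dim) + 1L
          mat[i, idx] <- mat[i, idx] + 1
        } else {
          for (start in seq_len(len - n + 1L)) {
            idx <- (poly_hash(codes[start:(start + n - 1L)]) %% dim) + 1L
            mat[i, idx] <- mat[i, idx] + 1
          }
        }
      }
      mat
    }
  )
}

# Deterministic polynomial hash of an integer code sequence (base 131,
# modulo a prime below 2^31); avoids platform-dependent hashing.
poly_hash <- function(codes) {
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 2147483629
  h
}

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal length with non-zero norm.
#' @return The cosine of the angle between `u` and `v`, in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    rlang::abort("cosine_similarity: vectors must have equal length.")
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    rlang::abort("cosine_similarity: zero-norm vector.")
  }
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Resolve two analysis-section group titles into intervention vs comparator
#'
#' The statistical-analysis section of a registry record names its two
#' compared groups but does not say which is the intervention; the study
#' design section labels its arms "Experimental" and "Comparator" but the
#' titles are not always consistent between the two sections. This function
#' assigns roles by similarity: (a) an exact case-insensitive title match
#' against a design arm short-circuits and fixes that group's role; (b)
#' otherwise each group inherits the role of its most similar design arm
#' under the backend's embedding cosine; (c) if both groups would inherit
#' the same role, the bijective (group, role) pairing with the larger total
#' similarity wins. Similarity ties are broken by earlier design-arm
#' document order.
#'
#' Rows from studies without at least one experimental and one comparator
#' design arm cannot be resolved and are excluded (`NULL` is returned, with
#' the reason attached).
#'
#' @param group_titles Exactly two analysis-section group titles.
#' @param design_arms Tibble of design arms with columns `title` and `role`
#'   (see [read_trial_xml()]).
#' @param backend Embedding backend (default [ngram_backend()]).
#' @param min_score Optional minimum similarity; assignments whose weaker
#'   score falls below it are excluded. Default `NULL` (bare argmax, no
#'   threshold).
#' @return A one-row tibble with `intervention_group`, `comparator_group`,
#'   `score_intervention`, `score_comparator`, and `method` (`"exact"` when
#'   both groups matched design titles verbatim, else `"embedding"`), or an
#'   `arm_exclusion` object (with `$reason`) when the row is excluded.
#' @export
resolve_arms <- function(group_titles, design_arms, backend = ngram_backend(), min_score = NULL) {
  if (length(group_titles) != 2) {
    rlang::abort("resolve_arms: exactly two group titles are required.")
  }
  exp_idx <- which(design_arms$role == "experimental")
  comp_idx <- which(design_arms$role == "comparator")
  if (length(exp_idx) == 0 || length(comp_idx) == 0) {
    return(arm_exclusion("no_experimental_comparator_design_arms"))
  }

  g_norm <- normalize_title(group_titles)
  d_norm <- normalize_title(design_arms$title)
  emb <- backend$embed(c(group_titles, design_arms$title))
  sims <- matrix(0, nrow = 2, ncol = nrow(design_arms))
  for (g in 1:2) {
    for (a in seq_len(nrow(design_arms))) {
      sims[g, a] <- cosine_similarity(emb[g, ], emb[2 + a, ])
    }
  }

  # per-group best arm within a role set; earlier document order wins ties
  best_in <- function(g, idx) {
    s <- sims[g, idx]
    k <- which(s >= max(s) - 1e-12)[1]
    list(arm = idx[k], score = s[k])
  }

  info <- lapply(1:2, function(g) {
    exact <- match(g_norm[g], d_norm)
    bE <- best_in(g, exp_idx)
    bC <- best_in(g, comp_idx)
    if (!is.na(exact)) {
      role <- design_arms$role[exact]
      list(
        exact = TRUE, role = role, score = 1.0,
        simE = if (role == "experimental") 1.0 else bE$score,
        simC = if (role == "comparator") 1.0 else bC$score
      )
    } else {
      # inherit role of the single best-matching design arm (any role)
      ball <- best_in(g, seq_len(nrow(design_arms)))
      role <- design_arms$role[ball$arm]
      list(exact = FALSE, role = role, score = ball$score, simE = bE$score, simC = bC$score)
    }
  })

  roles <- vapply(info, `[[`, character(1), "role")
  g1_is_intervention <- if (setequal(roles, c("experimental", "comparator"))) {
    roles[1] == "experimental"
  } else if (info[[1]]$exact && !info[[2]]$exact) {
    info[[1]]$role == "experimental"
  } else if (info[[2]]$exact && !info[[1]]$exact) {
    info[[2]]$role != "experimental"
  } else {
    # both groups lean the same way: take the pairing with larger total
    # similarity (evaluated by brute force over the two possibilities)
    (info[[1]]$simE + info[[2]]$simC) >= (info[[2]]$simE + info[[1]]$simC)
  }

  iv <- if (g1_is_intervention) 1L else 2L
  cp <- 3L - iv
  score_iv <- if (info[[iv]]$exact) 1.0 else info[[iv]]$simE
  score_cp <- if (info[[cp]]$exact) 1.0 else info[[cp]]$simC
  if (!is.null(min_score) && min(score_iv, score_cp) < min_score) {
    return(arm_exclusion("below_min_score"))
  }
  tibble::tibble(
    intervention_group = group_titles[iv],
    comparator_group = group_titles[cp],
    score_intervention = score_iv,
    score_comparator = score_cp,
    method = if (info[[1]]$exact && info[[2]]$exact) "exact" else "embedding"
  )
}

#' Resolve arms for every classified efficacy row of a corpus
#'
#' Applies [resolve_arms()] across a classified efficacy table, looking up
#' each trial's design arms. Rows that are excluded (not exactly two
#' groups, missing design roles, or below `min_score`) carry `NA`
#' assignments and a populated `exclusion_reason`.
#'
#' @param rows Efficacy rows (classified or raw) with `nct_id` and
#'   `group_titles`.
#' @param trials List of `trial_record`s, or a named list/tibble mapping
#'   nct_id to design-arm tibbles.
#' @inheritParams resolve_arms
#' @return `rows` with columns `intervention_group`, `comparator_group`,
#'   `score_intervention`, `score_comparator`, `match_method`,
#'   `exclusion_reason` appended.
#' @export
resolve_arms_rows <- function(rows, trials, backend = ngram_backend(), min_score = NULL) {
  arm_map <- design_arm_map(trials)
  n <- nrow(rows)
  out <- rows
  out$intervention_group <- rep(NA_character_, n)
  out$comparator_group <- rep(NA_character_, n)
  out$score_intervention <- rep(NA_real_, n)
  out$score_comparator <- rep(NA_real_, n)
  out$match_method <- rep(NA_character_, n)
  out$exclusion_reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (isTRUE(rows$excluded[i])) {
      out$exclusion_reason[i] <- "not_two_groups"
      next
    }
    arms <- arm_map[[rows$nct_id[i]]]
    if (is.null(arms)) {
      out$exclusion_reason[i] <- "unknown_trial"
      next
    }
    asg <- resolve_arms(rows$group_titles[[i]], arms, backend, min_score)
    if (inherits(asg, "arm_exclusion")) {
      out$exclusion_reason[i] <- asg$reason
      next
    }
    out$intervention_group[i] <- asg$intervention_group
    out$comparator_group[i] <- asg$comparator_group
    out$score_intervention[i] <- asg$score_intervention
    out$score_comparator[i] <- asg$score_comparator
    out$match_method[i] <- asg$method
  }
  out
}

arm_exclusion <- function(reason) {
  structure(list(reason = reason), class = "arm_exclusion")
}

design_arm_map <- function(trials) {
  if (inherits(trials, "trial_record")) trials <- list(trials)
  if (is.list(trials) && length(trials) > 0 && inherits(trials[[1]], "trial_record")) {
    return(setNames(
      lapply(trials, `[[`, "design_arms"),
      vapply(trials, `[[`, character(1), "nct_id")
    ))
  }
  trials
}

#' Score arm assignments against a gold standard
#'
#' Given predicted assignments and manually labelled ground truth, reports
#' the fraction of exact title matches for the intervention role and for
#' the comparator role separately.
#'
#' @param assignments Tibble with `nct_id`, `intervention_group`,
#'   `comparator_group` (and optionally `row_id`).
#' @param gold Tibble with the same keys plus `intervention_truth` and
#'   `comparator_truth`.
#' @return Named numeric vector `c(intervention = ..., comparator = ...)`.
#' @export
evaluate_assignments <- function(assignments, gold) {
  keys <- intersect(c("nct_id", "row_id"), intersect(names(assignments), names(gold)))
  if (length(keys) == 0) {
    rlang::abort("evaluate_assignments: no common key columns (nct_id/row_id).")
  }
  joined <- dplyr::inner_join(
    assignments[, c(keys, "intervention_group", "comparator_group")],
    gold[, c(keys, "intervention_truth", "comparator_truth")],
    by = keys
  )
  if (nrow(joined) != nrow(gold)) {
    missing <- dplyr::anti_join(gold, assignments, by = keys)
    rlang::abort(paste0(
      "evaluate_assignments: ", nrow(missing), " gold row(s) have no aligned prediction: ",
      paste(utils::head(missing$nct_id, 5), collapse = ", ")
    ))
  }
  c(
    intervention = mean(joined$intervention_group == joined$intervention_truth),
    comparator = mean(joined$comparator_group == joined$comparator_truth)
  )
}
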