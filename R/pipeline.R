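EFFICACY_LIST_COLS <- c("conditions", "intervention_types", "group_titles", "labels", "mesh_trees", "mesh_names")

bind_or <- function(rows, empty) {
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0 && ncol(out) == 0) empty else out
}

#' Run the full arm-level results pipeline in memory
#'
#' Composes the stages end to end on a list of parsed trial records:
#' flatten analyses to efficacy rows, classify significance, resolve
#' intervention vs comparator arms, type outcomes, extract and match
#' serious adverse events, restrict safety to trials with valid efficacy,
#' compute the SAE category co-occurrence, and assemble the knowledge
#' graph.
#'
#' @param records List of `trial_record`s (e.g. from [scan_corpus()]).
#' @param backend Embedding backend for arm matching.
#' @param extractor MeSH extractor for outcome typing.
#' @param min_score Optional minimum similarity for arm resolution.
#' @return List with `efficacy` (classified + resolved rows),
#'   `outcome_labels`, `safety_all` (all matched SAE records), `safety`
#'   (restricted to trials with valid efficacy), `cooccurrence`, `graph`,
#'   and `funnel` (classification branch counts).
#' @export
process_corpus <- function(records, backend = ngram_backend(),
                           extractor = dictionary_extractor(), min_score = NULL) {
  empty_trial <- structure(
    list(
      nct_id = "NCT00000000", conditions = character(0), intervention_types = character(0),
      design_arms = tibble::tibble(title = character(0), role = character(0)),
      outcomes = tibble::tibble(title = character(0), rank = character(0), analyses = list()),
      events = tibble::tibble(
        arm_title = character(0), event_title = character(0), category = character(0),
        severity = character(0), affected = integer(0), at_risk = integer(0)
      )
    ),
    class = "trial_record"
  )
  raw <- bind_or(lapply(records, to_efficacy_rows), to_efficacy_rows(empty_trial))
  classified <- classify_rows(raw)
  resolved <- resolve_arms_rows(classified, records, backend, min_score)
  labels <- classify_outcomes(resolved$outcome_title, extractor)
  safety_raw <- bind_or(lapply(records, extract_safety), extract_safety(empty_trial))
  matched <- match_safety_records(safety_raw, resolved, backend)
  safety <- filter_to_efficacy_trials(matched[!is.na(matched$matched_group), ], resolved)
  cooc <- compute_cooccurrence(safety)
  list(
    efficacy = resolved,
    outcome_labels = labels,
    safety_all = matched,
    safety = safety,
    cooccurrence = cooc,
    graph = build_graph(resolved, safety, labels),
    funnel = significance_funnel(classified)
  )
}

#' File-based pipeline commands
#'
#' The command-line surface of the package: each command reads and writes
#' documented CSV/JSONL/graph artifacts under `out`, so stages communicate
#' via files, partial corpora can be inspected, and any stage can be
#' re-run independently. `run_pipeline("all", ...)` composes parse,
#' classify, resolve-arms, type-outcomes, link-safety and build-kg in
#' workflow order.
#'
#' @param command One of `"simulate"`, `"parse"`, `"classify"`,
#'   `"resolve-arms"`, `"type-outcomes"`, `"link-safety"`, `"build-kg"`,
#'   `"report"`, `"evaluate"`, `"all"`.
#' @param input Input path (corpus directory/zip for parse/simulate-based
#'   commands; the artifact directory for later stages).
#' @param out Output directory.
#' @param backend Backend name (`"ngram"`) or an embedding backend object.
#' @param extractor Extractor name (`"dictionary"`) or an extractor object.
#' @param min_score Optional minimum arm-resolution similarity.
#' @param seed Seed for `simulate`.
#' @param n Number of trials for `simulate`.
#' @param format Graph export format for `build-kg`.
#' @return Invisibly, a named list of written artifact paths (plus
#'   computed metrics for `evaluate`).
#' @export
run_pipeline <- function(command, input = NULL, out = NULL,
                         backend = "ngram", extractor = "dictionary",
                         min_score = NULL, seed = 1L, n = 50L,
                         format = "neo4j_csv") {
  command <- match.arg(command, c(
    "simulate", "parse", "classify", "resolve-arms", "type-outcomes",
    "link-safety", "build-kg", "report", "evaluate", "all"
  ))
  backend <- resolve_backend(backend)
  extractor <- resolve_extractor(extractor)
  if (is.null(out)) rlang::abort("run_pipeline: 'out' directory is required.")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  art <- function(name) file.path(out, name)

  read_eff <- function(name) {
    read_records(art(name), "csv", list_cols = EFFICACY_LIST_COLS)
  }

  result <- switch(command,
    simulate = {
      cfg <- generator_config(n_trials = n, seed = seed)
      gen <- generate_corpus(cfg, out)
      inform(sprintf("simulate: wrote %d trial(s) to %s", length(gen$files), out))
      list(corpus = out, manifest = file.path(out, "manifest.jsonl"))
    },
    parse = {
      records <- scan_corpus(input)
      raw <- bind_or(lapply(records, to_efficacy_rows), NULL)
      if (is.null(raw)) raw <- to_efficacy_rows_empty()
      safety <- dplyr::bind_rows(lapply(records, extract_safety))
      arms <- dplyr::bind_rows(lapply(records, function(r) {
        tibble::tibble(nct_id = r$nct_id, r$design_arms[, c("title", "role")])
      }))
      info <- dplyr::bind_rows(lapply(records, function(r) {
        tibble::tibble(
          nct_id = r$nct_id,
          conditions = list(r$conditions),
          intervention_types = list(r$intervention_types)
        )
      }))
      write_records(raw, art("efficacy_raw.csv"), "csv")
      write_records(safety, art("safety_raw.csv"), "csv")
      write_records(arms, art("design_arms.csv"), "csv")
      write_records(info, art("trial_info.csv"), "csv")
      inform(sprintf(
        "parse: %d trial(s), %d efficacy row(s), %d serious event record(s), %d skipped file(s)",
        length(records), nrow(raw), nrow(safety), attr(records, "skipped") %||% 0L
      ))
      list(
        efficacy_raw = art("efficacy_raw.csv"), safety_raw = art("safety_raw.csv"),
        design_arms = art("design_arms.csv"), trial_info = art("trial_info.csv")
      )
    },
    classify = {
      raw <- read_eff("efficacy_raw.csv")
      classified <- classify_rows(raw)
      write_records(classified, art("efficacy_classified.csv"), "csv")
      funnel <- significance_funnel(classified)
      inform(paste0(
        "classify funnel: ",
        paste(names(funnel), funnel, sep = "=", collapse = ", ")
      ))
      list(efficacy_classified = art("efficacy_classified.csv"), funnel = funnel)
    },
    `resolve-arms` = {
      classified <- read_eff("efficacy_classified.csv")
      arms <- read_records(art("design_arms.csv"), "csv")
      arm_map <- lapply(split(arms, arms$nct_id), function(x) x[, c("title", "role")])
      resolved <- resolve_arms_rows(classified, arm_map, backend, min_score)
      write_records(resolved, art("efficacy_resolved.csv"), "csv")
      inform(sprintf(
        "resolve-arms: %d of %d row(s) assigned",
        sum(!is.na(resolved$intervention_group)), nrow(resolved)
      ))
      list(efficacy_resolved = art("efficacy_resolved.csv"))
    },
    `type-outcomes` = {
      resolved <- read_eff("efficacy_resolved.csv")
      labels <- classify_outcomes(resolved$outcome_title, extractor)
      write_records(labels, art("outcome_labels.csv"), "csv")
      inform(sprintf(
        "type-outcomes: %d unique outcome(s), %.1f%% labelled",
        nrow(labels), 100 * (labelled_fraction(labels) %||% 0)
      ))
      list(outcome_labels = art("outcome_labels.csv"))
    },
    `link-safety` = {
      resolved <- read_eff("efficacy_resolved.csv")
      safety_raw <- read_records(art("safety_raw.csv"), "csv")
      matched <- match_safety_records(safety_raw, resolved, backend)
      safety <- filter_to_efficacy_trials(matched[!is.na(matched$matched_group), ], resolved)
      write_records(safety, art("safety_matched.csv"), "csv")
      cooc <- compute_cooccurrence(safety)
      write_records(cooccurrence_edges(cooc), art("cooccurrence_edges.csv"), "csv")
      write_records(aggregate_affected(safety, "category"), art("affected_by_category.csv"), "csv")
      info <- read_records(art("trial_info.csv"), "csv", list_cols = EFFICACY_LIST_COLS)
      write_records(
        aggregate_affected(safety, "intervention_type", trial_types = info),
        art("affected_by_intervention_type.csv"), "csv"
      )
      inform(sprintf(
        "link-safety: %d record(s) retained (fraction %.2f)",
        nrow(safety), attr(safety, "retained_fraction") %||% NA_real_
      ))
      list(
        safety_matched = art("safety_matched.csv"),
        cooccurrence_edges = art("cooccurrence_edges.csv")
      )
    },
    `build-kg` = {
      resolved <- read_eff("efficacy_resolved.csv")
      labels <- read_eff("outcome_labels.csv")
      safety <- read_records(art("safety_matched.csv"), "csv")
      graph <- build_graph(resolved, safety, labels)
      paths <- export_graph(graph, art("kg"), format)
      inform(sprintf("build-kg: %d node(s), %d edge(s)", nrow(graph$nodes), nrow(graph$edges)))
      list(kg = paths)
    },
    report = {
      resolved <- read_eff("efficacy_resolved.csv")
      labels <- read_eff("outcome_labels.csv")
      safety <- read_records(art("safety_matched.csv"), "csv")
      tables <- summarize_results(resolved, safety, labels, extractor)
      written <- character(0)
      for (nm in names(tables)) {
        if (is.null(tables[[nm]])) next
        p <- art(paste0("summary_", nm, ".csv"))
        write_records(tables[[nm]], p, "csv")
        written <- c(written, p)
      }
      list(summaries = written)
    },
    evaluate = {
      manifest <- read_manifest(file.path(input, "manifest.jsonl"))
      truth <- manifest_tables(manifest)
      resolved <- read_eff("efficacy_resolved.csv")
      metrics <- evaluate_against_manifest(resolved, truth)
      writeLines(jsonlite::toJSON(metrics, auto_unbox = TRUE, digits = NA), art("evaluation.json"))
      inform(paste0(
        "evaluate: ",
        paste(names(metrics), sprintf("%.4f", unlist(metrics)), sep = "=", collapse = ", ")
      ))
      list(evaluation = art("evaluation.json"), metrics = metrics)
    },
    all = {
      run_pipeline("parse", input = input, out = out, backend = backend, extractor = extractor)
      run_pipeline("classify", out = out)
      run_pipeline("resolve-arms", out = out, backend = backend, min_score = min_score)
      run_pipeline("type-outcomes", out = out, extractor = extractor)
      run_pipeline("link-safety", out = out, backend = backend)
      run_pipeline("build-kg", out = out, format = format)
      run_pipeline("report", out = out, extractor = extractor)
      list(out = out)
    }
  )
  invisible(result)
}

to_efficacy_rows_empty <- function() {
  tibble::tibble(
    nct_id = character(0), conditions = list(), intervention_types = list(),
    outcome_title = character(0), outcome_rank = character(0),
    group_titles = list(), n_groups = integer(0), excluded = logical(0),
    p_value_raw = character(0), method = character(0), param_name_raw = character(0),
    param_value = numeric(0), ci_percent = numeric(0),
    ci_lower_raw = character(0), ci_upper_raw = character(0), non_inferiority = character(0)
  )
}

resolve_backend <- function(backend) {
  if (is.list(backend)) {
    return(backend)
  }
  switch(backend,
    ngram = ngram_backend(),
    rlang::abort(paste0(
      "Unknown backend '", backend, "'. Available backends: ngram."
    ))
  )
}

resolve_extractor <- function(extractor) {
  if (is.list(extractor)) {
    return(extractor)
  }
  switch(extractor,
    dictionary = dictionary_extractor(),
    rlang::abort(paste0(
      "Unknown extractor '", extractor, "'. Available extractors: dictionary."
    ))
  )
}

#' Score a processed corpus against its generator manifest
#'
#' Compares the pipeline's significance labels and arm assignments with
#' the ground truth planted by [generate_corpus()].
#'
#' @param resolved Classified, arm-resolved efficacy rows.
#' @param truth Manifest truth tables ([manifest_tables()]).
#' @return List with `label_agreement` (fraction of non-excluded rows
#'   whose label matches the planted label), `intervention_accuracy` and
#'   `comparator_accuracy` (over rows with an assignment and a
#'   design-valid trial), and `n_rows`.
#' @export
evaluate_against_manifest <- function(resolved, truth) {
  # key rows by trial, outcome, group set and occurrence order, so repeated
  # analyses of the same outcome align one-to-one with the manifest
  key <- function(tab) {
    base <- paste(
      tab$nct_id, tab$outcome_title,
      vapply(tab$group_titles, paste, character(1), collapse = "\r"),
      sep = "\n"
    )
    seq_in_group <- stats::ave(seq_along(base), base, FUN = seq_along)
    paste(base, seq_in_group)
  }
  res <- resolved
  tru <- truth$rows
  res$k <- key(res)
  tru$k <- key(tru)
  joined <- dplyr::inner_join(
    res[, c("k", "significance", "intervention_group", "comparator_group", "excluded")],
    tru[, c("k", "label", "intervention_group_truth", "comparator_group_truth", "design_valid")],
    by = "k"
  )
  if (nrow(joined) != nrow(tru)) {
    rlang::warn(sprintf(
      "evaluate_against_manifest: %d of %d manifest row(s) aligned.",
      nrow(joined), nrow(tru)
    ))
  }
  kept <- joined[!joined$excluded %in% TRUE, ]
  assigned <- kept[!is.na(kept$intervention_group) & kept$design_valid, ]
  list(
    label_agreement = mean(kept$significance == kept$label),
    intervention_accuracy = mean(assigned$intervention_group == assigned$intervention_group_truth),
    comparator_accuracy = mean(assigned$comparator_group == assigned$comparator_group_truth),
    n_rows = nrow(kept)
  )
}
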