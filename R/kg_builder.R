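node_id <- function(node_type, title) {
  paste0(node_type, ":", normalize_title(title))
}

#' Assemble the arm-level results knowledge graph
#'
#' Builds the typed graph linking efficacy and safety at the arm level:
#' \itemize{
#'   \item one `positive` or `negative` edge (intervention_arm -> outcome)
#'     per classified, arm-resolved efficacy row, carrying the comparator
#'     arm, the verbatim p-value and parameter fields, the NCT id and the
#'     trial's condition list;
#'   \item one `has_ae` edge (intervention_arm -> adverse_event) per
#'     matched serious adverse-event record, carrying the
#'     affected/at-risk ratio, NCT id and severity;
#'   \item `is_a` edges from outcomes to their outcome-type nodes
#'     (biomarker / PRO / clinical_endpoint), from adverse events to their
#'     body-system category nodes, and from arms to MeSH concept nodes.
#' }
#' Node identity is (node type, whitespace- and case-normalized title), so
#' the same arm or outcome title reported by many trials becomes a single
#' node and per-trial provenance lives on the edges. Indeterminate and
#' excluded efficacy rows never reach the graph. Statistics are carried
#' verbatim; the graph never recomputes them.
#'
#' @param efficacy Classified, arm-resolved efficacy rows (output of
#'   [classify_rows()] then [resolve_arms_rows()]).
#' @param safety Matched safety records (output of
#'   [match_safety_records()]), or `NULL`.
#' @param outcome_labels Outcome label table ([classify_outcomes()]), or
#'   `NULL`.
#' @param concepts Optional tibble `title`, `concept` mapping arm titles to
#'   MeSH concept names; titles must reference arms present in the graph.
#' @return A `kg` object: list of `nodes` (tibble `id`, `node_type`,
#'   `title`) and `edges` (tibble `src`, `dst`, `edge_type` plus attribute
#'   columns), both deterministically ordered.
#' @export
build_graph <- function(efficacy, safety = NULL, outcome_labels = NULL, concepts = NULL) {
  eff <- efficacy[
    !is.na(efficacy$significance) &
      efficacy$significance %in% c("positive", "negative") &
      !is.na(efficacy$intervention_group),
  ]
  saf <- if (is.null(safety) || nrow(safety) == 0) {
    NULL
  } else {
    safety[!is.na(safety$matched_group), ]
  }

  nodes <- list()
  add_nodes <- function(node_type, titles) {
    titles <- unique(titles[!is.na(titles) & nzchar(titles)])
    # first-seen casing wins for the display title
    titles <- titles[!duplicated(normalize_title(titles))]
    if (length(titles) == 0) {
      return(invisible(NULL))
    }
    nodes[[length(nodes) + 1]] <<- tibble::tibble(
      id = node_id(node_type, titles), node_type = node_type, title = titles
    )
    invisible(NULL)
  }

  add_nodes("intervention_arm", c(eff$intervention_group, if (!is.null(saf)) saf$matched_group))
  add_nodes("outcome", eff$outcome_title)
  if (!is.null(saf)) {
    add_nodes("adverse_event", saf$event_title)
    add_nodes("adverse_event_category", saf$category)
  }

  edges <- list()
  if (nrow(eff) > 0) {
    edges[[length(edges) + 1]] <- tibble::tibble(
      src = node_id("intervention_arm", eff$intervention_group),
      dst = node_id("outcome", eff$outcome_title),
      edge_type = eff$significance,
      nct_id = eff$nct_id,
      comparator = eff$comparator_group,
      p_value = as.character(eff$p_value_raw),
      param_name = as.character(eff$param_name_raw),
      param_value = as.numeric(eff$param_value),
      ci_lower = as.character(eff$ci_lower_raw),
      ci_upper = as.character(eff$ci_upper_raw),
      basis = eff$basis,
      condition = vapply(eff$conditions, paste, character(1), collapse = "|"),
      ratio = NA_real_,
      severity = NA_character_
    )
  }
  if (!is.null(saf) && nrow(saf) > 0) {
    edges[[length(edges) + 1]] <- tibble::tibble(
      src = node_id("intervention_arm", saf$matched_group),
      dst = node_id("adverse_event", saf$event_title),
      edge_type = "has_ae",
      nct_id = saf$nct_id,
      comparator = NA_character_, p_value = NA_character_,
      param_name = NA_character_, param_value = NA_real_,
      ci_lower = NA_character_, ci_upper = NA_character_, basis = NA_character_,
      condition = NA_character_,
      ratio = ifelse(is.na(saf$at_risk), NA_real_, saf$affected / saf$at_risk),
      severity = saf$severity
    )
    ae_cat <- dplyr::distinct(tibble::tibble(
      src = node_id("adverse_event", saf$event_title),
      dst = node_id("adverse_event_category", saf$category)
    ))
    edges[[length(edges) + 1]] <- is_a_edges(ae_cat)
  }
  if (!is.null(outcome_labels) && nrow(outcome_labels) > 0 && nrow(eff) > 0) {
    lab <- outcome_labels[normalize_title(outcome_labels$outcome_title) %in%
      normalize_title(eff$outcome_title), ]
    lab_long <- tidyr::unnest(lab[, c("outcome_title", "labels")], "labels")
    if (nrow(lab_long) > 0) {
      add_nodes("outcome_type", unique(lab_long$labels))
      edges[[length(edges) + 1]] <- is_a_edges(dplyr::distinct(tibble::tibble(
        src = node_id("outcome", lab_long$outcome_title),
        dst = node_id("outcome_type", lab_long$labels)
      )))
    }
  }
  nodes_tab <- dplyr::bind_rows(nodes)
  if (nrow(nodes_tab) == 0) {
    nodes_tab <- tibble::tibble(id = character(0), node_type = character(0), title = character(0))
  }
  if (!is.null(concepts) && nrow(concepts) > 0) {
    arm_ids <- node_id("intervention_arm", concepts$title)
    dangling <- setdiff(arm_ids, nodes_tab$id[nodes_tab$node_type == "intervention_arm"])
    if (length(dangling) > 0) {
      rlang::abort(paste0(
        "build_graph: concept map references arms absent from the graph: ",
        paste(utils::head(dangling, 5), collapse = ", ")
      ))
    }
    concept_nodes <- tibble::tibble(
      id = node_id("concept", unique(concepts$concept)),
      node_type = "concept", title = unique(concepts$concept)
    )
    nodes_tab <- dplyr::bind_rows(nodes_tab, concept_nodes)
    edges[[length(edges) + 1]] <- is_a_edges(dplyr::distinct(tibble::tibble(
      src = arm_ids, dst = node_id("concept", concepts$concept)
    )))
  }

  edges_tab <- dplyr::bind_rows(edges)
  if (nrow(edges_tab) > 0) {
    dangling <- setdiff(c(edges_tab$src, edges_tab$dst), nodes_tab$id)
    if (length(dangling) > 0) {
      rlang::abort(paste0(
        "build_graph: dangling edge endpoint(s): ",
        paste(utils::head(dangling, 5), collapse = ", ")
      ))
    }
  } else {
    edges_tab <- is_a_edges(tibble::tibble(src = character(0), dst = character(0)))[0, ]
  }
  nodes_tab <- nodes_tab[order(nodes_tab$node_type, nodes_tab$id), ]
  edges_tab <- edges_tab[order(edges_tab$edge_type, edges_tab$src, edges_tab$dst, edges_tab$nct_id, method = "radix"), ]
  structure(list(nodes = nodes_tab, edges = edges_tab), class = "kg")
}

is_a_edges <- function(pairs) {
  tibble::tibble(
    src = pairs$src, dst = pairs$dst, edge_type = "is_a",
    nct_id = NA_character_, comparator = NA_character_, p_value = NA_character_,
    param_name = NA_character_, param_value = NA_real_,
    ci_lower = NA_character_, ci_upper = NA_character_, basis = NA_character_,
    condition = NA_character_, ratio = NA_real_, severity = NA_character_
  )
}

#' @export
print.kg <- function(x, ...) {
  cat(sprintf("<kg: %d nodes, %d edges>\n", nrow(x$nodes), nrow(x$edges)))
  print(table(x$nodes$node_type))
  print(table(x$edges$edge_type))
  invisible(x)
}

#' Export a knowledge graph
#'
#' Writes the graph in one of four interchange formats:
#' \describe{
#'   \item{neo4j_csv}{`nodes.csv` / `edges.csv` in the Neo4j bulk-import
#'     header dialect (`:ID`, `:LABEL`, `:START_ID`, `:END_ID`, `:TYPE`).}
#'   \item{graphml}{a single `graph.graphml` readable by igraph/Gephi.}
#'   \item{cypher}{`graph.cypher`, a replayable script using `MERGE` on
#'     (type, title) so repeated replays are idempotent.}
#'   \item{jsonl}{`nodes.jsonl` / `edges.jsonl`, one object per line.}
#' }
#'
#' @param graph A `kg`.
#' @param dir Output directory (created if missing).
#' @param format One of `"neo4j_csv"`, `"graphml"`, `"cypher"`, `"jsonl"`.
#' @return Character vector of written file paths, invisibly.
#' @export
export_graph <- function(graph, dir, format = c("neo4j_csv", "graphml", "cypher", "jsonl")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- switch(format,
    neo4j_csv = {
      nodes <- graph$nodes
      names(nodes) <- c(":ID", ":LABEL", "title")
      edges <- graph$edges
      names(edges)[1:3] <- c(":START_ID", ":END_ID", ":TYPE")
      np <- file.path(dir, "nodes.csv")
      ep <- file.path(dir, "edges.csv")
      readr::write_csv(nodes, np, na = "", progress = FALSE)
      readr::write_csv(edges, ep, na = "", progress = FALSE)
      c(np, ep)
    },
    graphml = {
      p <- file.path(dir, "graph.graphml")
      igraph::write_graph(as_igraph(graph), p, format = "graphml")
      p
    },
    cypher = {
      p <- file.path(dir, "graph.cypher")
      writeLines(cypher_statements(graph), p)
      p
    },
    jsonl = {
      np <- file.path(dir, "nodes.jsonl")
      ep <- file.path(dir, "edges.jsonl")
      write_records(graph$nodes, np, "jsonl")
      write_records(graph$edges, ep, "jsonl")
      c(np, ep)
    }
  )
  invisible(paths)
}

#' Convert a knowledge graph to an igraph object
#'
#' @param graph A `kg`.
#' @return An `igraph` directed graph with node/edge attributes.
#' @export
as_igraph <- function(graph) {
  vertices <- as.data.frame(graph$nodes)
  names(vertices)[1] <- "name"
  edges <- as.data.frame(graph$edges)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

cypher_escape <- function(x) gsub("'", "\\\\'", x)

cypher_statements <- function(graph) {
  node_stmts <- sprintf(
    "MERGE (:%s {title: '%s'});",
    graph$nodes$node_type, cypher_escape(graph$nodes$title)
  )
  edge_stmts <- vapply(seq_len(nrow(graph$edges)), function(i) {
    e <- graph$edges[i, ]
    src <- graph$nodes[match(e$src, graph$nodes$id), ]
    dst <- graph$nodes[match(e$dst, graph$nodes$id), ]
    attrs <- c(
      if (!is.na(e$nct_id)) sprintf("nct_id: '%s'", cypher_escape(e$nct_id)),
      if (!is.na(e$comparator)) sprintf("comparator: '%s'", cypher_escape(e$comparator)),
      if (!is.na(e$p_value)) sprintf("p_value: '%s'", cypher_escape(e$p_value)),
      if (!is.na(e$ratio)) sprintf("ratio: %.12g", e$ratio),
      if (!is.na(e$severity)) sprintf("severity: '%s'", cypher_escape(e$severity))
    )
    sprintf(
      "MATCH (a:%s {title: '%s'}), (b:%s {title: '%s'}) MERGE (a)-[:%s%s]->(b);",
      src$node_type, cypher_escape(src$title),
      dst$node_type, cypher_escape(dst$title),
      e$edge_type,
      if (length(attrs)) paste0(" {", paste(attrs, collapse = ", "), "}") else ""
    )
  }, character(1))
  c(node_stmts, edge_stmts)
}

#' Import a graph exported as neo4j_csv or graphml
#'
#' Inverse of [export_graph()] for the formats that round-trip: reading a
#' `neo4j_csv` export back and re-exporting it is byte-stable.
#'
#' @param dir Directory holding a `neo4j_csv` export (or a `.graphml`
#'   path for `format = "graphml"`).
#' @param format `"neo4j_csv"` or `"graphml"`.
#' @return A `kg`.
#' @export
import_graph <- function(dir, format = c("neo4j_csv", "graphml")) {
  format <- match.arg(format)
  if (format == "neo4j_csv") {
    nodes <- readr::read_csv(file.path(dir, "nodes.csv"), show_col_types = FALSE, progress = FALSE, na = "")
    names(nodes) <- c("id", "node_type", "title")
    edges <- readr::read_csv(
      file.path(dir, "edges.csv"),
      show_col_types = FALSE, progress = FALSE, na = "",
      col_types = readr::cols(
        param_value = readr::col_double(), ratio = readr::col_double(),
        .default = readr::col_character()
      )
    )
    names(edges)[1:3] <- c("src", "dst", "edge_type")
    structure(list(nodes = tibble::as_tibble(nodes), edges = tibble::as_tibble(edges)), class = "kg")
  } else {
    g <- igraph::read_graph(dir, format = "graphml")
    nodes <- tibble::tibble(
      id = igraph::V(g)$name,
      node_type = igraph::V(g)$node_type,
      title = igraph::V(g)$title
    )
    el <- igraph::as_data_frame(g, what = "edges")
    names(el)[1:3] <- c("src", "dst", "edge_type")
    structure(list(nodes = nodes, edges = tibble::as_tibble(el)), class = "kg")
  }
}

#' Descriptive summary tables for a processed corpus
#'
#' Produces the corpus-level descriptive tables: node and edge counts by
#' type; the positive/negative split of efficacy results by outcome type,
#' by intervention type (single-type trials only), and by health-problem
#' category; outcome-typing coverage by outcome rank; and the ranked
#' biomarker outcomes per health problem with their positive and negative
#' counts.
#'
#' @param efficacy Classified, arm-resolved efficacy rows.
#' @param safety Matched safety records (or `NULL`).
#' @param outcome_labels Outcome label table (or `NULL`).
#' @param extractor MeSH extractor used to map trial conditions to disease
#'   categories.
#' @return A named list of tibbles: `nodes_edges`, `by_outcome_type`,
#'   `by_intervention_type`, `by_health_problem`, `coverage_by_rank`,
#'   `biomarker_outcomes`.
#' @export
summarize_results <- function(efficacy, safety = NULL, outcome_labels = NULL,
                              extractor = dictionary_extractor()) {
  graph <- build_graph(efficacy, safety, outcome_labels)
  nodes_edges <- dplyr::bind_rows(
    dplyr::count(graph$nodes, .data$node_type, name = "count"),
    dplyr::count(graph$edges, .data$edge_type, name = "count") |>
      dplyr::rename(node_type = "edge_type")
  )

  eff <- efficacy[
    !is.na(efficacy$significance) & efficacy$significance %in% c("positive", "negative") &
      !is.na(efficacy$intervention_group),
  ]
  split_table <- function(tab, key) {
    out <- dplyr::summarise(
      dplyr::group_by(tab, .data[[key]]),
      positive = sum(.data$significance == "positive"),
      negative = sum(.data$significance == "negative"),
      .groups = "drop"
    )
    out$positive_pct <- 100 * out$positive / pmax(1, out$positive + out$negative)
    out[order(-(out$positive + out$negative)), ]
  }

  by_outcome_type <- NULL
  biomarker_outcomes <- NULL
  if (!is.null(outcome_labels) && nrow(eff) > 0) {
    joined <- dplyr::left_join(
      eff, outcome_labels[, c("outcome_title", "labels", "biomarker")],
      by = "outcome_title"
    )
    long <- tidyr::unnest(joined[, c("significance", "labels", "nct_id")], "labels")
    if (nrow(long) > 0) by_outcome_type <- split_table(long, "labels")
  }

  by_intervention_type <- NULL
  if (nrow(eff) > 0) {
    n_types <- vapply(eff$intervention_types, length, integer(1))
    single <- eff[n_types == 1L, ]
    if (nrow(single) > 0) {
      single$intervention_type <- vapply(single$intervention_types, `[[`, character(1), 1)
      by_intervention_type <- split_table(single, "intervention_type")
    }
  }

  by_health_problem <- NULL
  if (nrow(eff) > 0) {
    conds <- unique(unlist(eff$conditions))
    cond_cat <- setNames(lapply(conds, map_condition_category, extractor = extractor), conds)
    rows <- lapply(seq_len(nrow(eff)), function(i) {
      cats <- unique(unlist(cond_cat[eff$conditions[[i]]]))
      if (length(cats) == 0) {
        return(NULL)
      }
      tibble::tibble(health_problem = cats, significance = eff$significance[i], outcome_title = eff$outcome_title[i])
    })
    long <- dplyr::bind_rows(rows)
    if (nrow(long) > 0) {
      by_health_problem <- split_table(long, "health_problem")
      if (!is.null(outcome_labels)) {
        bio <- dplyr::left_join(long, outcome_labels[, c("outcome_title", "biomarker")], by = "outcome_title")
        bio <- bio[bio$biomarker %in% TRUE, ]
        if (nrow(bio) > 0) {
          biomarker_outcomes <- dplyr::summarise(
            dplyr::group_by(bio, .data$health_problem, .data$outcome_title),
            positive = sum(.data$significance == "positive"),
            negative = sum(.data$significance == "negative"),
            .groups = "drop"
          )
          biomarker_outcomes <- biomarker_outcomes[
            order(
              biomarker_outcomes$health_problem,
              -(biomarker_outcomes$positive + biomarker_outcomes$negative)
            ),
          ]
        }
      }
    }
  }

  coverage_by_rank <- NULL
  if (!is.null(outcome_labels) && nrow(eff) > 0 && "outcome_rank" %in% names(eff)) {
    joined <- dplyr::left_join(eff, outcome_labels[, c("outcome_title", "labels")], by = "outcome_title")
    joined$labelled <- vapply(joined$labels, function(l) length(l) > 0, logical(1))
    coverage_by_rank <- dplyr::summarise(
      dplyr::group_by(joined, .data$outcome_rank),
      results = dplyr::n(),
      coverage = mean(.data$labelled),
      labelled = sum(.data$labelled),
      .groups = "drop"
    )
  }

  list(
    nodes_edges = nodes_edges,
    by_outcome_type = by_outcome_type,
    by_intervention_type = by_intervention_type,
    by_health_problem = by_health_problem,
    coverage_by_rank = coverage_by_rank,
    biomarker_outcomes = biomarker_outcomes
  )
}

#' Retrieve the subgraph around matching arms and events
#'
#' Selects intervention-arm nodes whose title — or whose linked MeSH
#' concept — matches `arm_pattern` (case-insensitive substring), together
#' with their efficacy edges, and their `has_ae` edges whose adverse-event
#' title or body-system category matches `event_pattern`. Passing `NULL`
#' for `event_pattern` keeps all adverse-event edges of the matched arms.
#'
#' @param graph A `kg`.
#' @param arm_pattern Case-insensitive substring for arm titles/concepts.
#' @param event_pattern Case-insensitive substring for event titles or
#'   categories, or `NULL`.
#' @return A `kg` restricted to the matching nodes and their edges.
#' @export
query_subgraph <- function(graph, arm_pattern, event_pattern = NULL) {
  nodes <- graph$nodes
  edges <- graph$edges
  arm_nodes <- nodes[nodes$node_type == "intervention_arm", ]
  title_hit <- grepl(arm_pattern, arm_nodes$title, ignore.case = TRUE, fixed = FALSE)
  concept_ids <- nodes$id[nodes$node_type == "concept" &
    grepl(arm_pattern, nodes$title, ignore.case = TRUE)]
  via_concept <- edges$src[edges$edge_type == "is_a" & edges$dst %in% concept_ids]
  arm_ids <- union(arm_nodes$id[title_hit], intersect(via_concept, arm_nodes$id))

  eff_edges <- edges[edges$edge_type %in% c("positive", "negative") & edges$src %in% arm_ids, ]
  ae_edges <- edges[edges$edge_type == "has_ae" & edges$src %in% arm_ids, ]
  if (!is.null(event_pattern) && nrow(ae_edges) > 0) {
    ev_nodes <- nodes[nodes$node_type == "adverse_event", ]
    ev_title_hit <- ev_nodes$id[grepl(event_pattern, ev_nodes$title, ignore.case = TRUE)]
    cat_ids <- nodes$id[nodes$node_type == "adverse_event_category" &
      grepl(event_pattern, nodes$title, ignore.case = TRUE)]
    ev_via_cat <- edges$src[edges$edge_type == "is_a" & edges$dst %in% cat_ids]
    keep_events <- union(ev_title_hit, ev_via_cat)
    ae_edges <- ae_edges[ae_edges$dst %in% keep_events, ]
  }
  sub_edges <- dplyr::bind_rows(eff_edges, ae_edges)
  keep_ids <- union(arm_ids, c(sub_edges$src, sub_edges$dst))
  taxo <- edges[edges$edge_type == "is_a" & edges$src %in% keep_ids, ]
  sub_edges <- dplyr::bind_rows(sub_edges, taxo)
  keep_ids <- union(keep_ids, c(taxo$dst))
  structure(
    list(nodes = nodes[nodes$id %in% keep_ids, ], edges = sub_edges),
    class = "kg"
  )
}
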