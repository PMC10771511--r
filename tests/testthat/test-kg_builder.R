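toy_graph <- function() {
  eff <- efficacy_row("NCT00000001", "Drug X", "Placebo", "Outcome 1", "positive",
    conditions = "rheumatoid arthritis"
  )
  safety <- tibble::tibble(
    nct_id = "NCT00000001", arm_title = "Drug X", event_title = "Sepsis",
    category = "Infections and infestations", severity = "serious",
    affected = 2L, at_risk = 100L, matched_group = "Drug X", match_method = "string"
  )
  labels <- classify_outcomes("Outcome 1")
  build_graph(eff, safety, labels)
}

test_that("one efficacy row and one safety record give the minimal linked graph", {
  g <- toy_graph()
  main <- g$nodes[g$nodes$node_type %in% c("intervention_arm", "outcome", "adverse_event"), ]
  expect_equal(nrow(main), 3)
  expect_equal(sum(g$edges$edge_type == "positive"), 1)
  expect_equal(sum(g$edges$edge_type == "has_ae"), 1)
  pos <- g$edges[g$edges$edge_type == "positive", ]
  expect_equal(pos$comparator, "Placebo")
  expect_equal(pos$nct_id, "NCT00000001")
  expect_equal(pos$condition, "rheumatoid arthritis")
  ae <- g$edges[g$edges$edge_type == "has_ae", ]
  expect_equal(ae$ratio, 0.02)
  expect_equal(ae$severity, "serious")
})

test_that("empty inputs build an empty graph", {
  g <- build_graph(efficacy_row("NCT00000001", "A", "B", "O")[0, ])
  expect_equal(nrow(g$nodes), 0)
  expect_equal(nrow(g$edges), 0)
})

test_that("indeterminate and unresolved rows never reach the graph", {
  eff <- dplyr::bind_rows(
    efficacy_row("NCT00000001", "Drug X", "Placebo", "O1", "positive"),
    efficacy_row("NCT00000002", "Drug Y", "Placebo", "O2", "indeterminate")
  )
  unresolved <- efficacy_row("NCT00000003", "Drug Z", "Placebo", "O3", "negative")
  unresolved$intervention_group <- NA_character_
  eff <- dplyr::bind_rows(eff, unresolved)
  g <- build_graph(eff)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$edge_type, "positive")
})

test_that("node identity dedups titles across trials; ids are deterministic", {
  eff <- dplyr::bind_rows(
    efficacy_row("NCT00000001", "Drug X", "Placebo", "Shared Outcome", "positive"),
    efficacy_row("NCT00000002", "drug x", "Placebo", "Shared Outcome", "negative")
  )
  g1 <- build_graph(eff)
  g2 <- build_graph(eff)
  expect_identical(g1, g2)
  expect_equal(sum(g1$nodes$node_type == "intervention_arm"), 1)
  expect_equal(sum(g1$nodes$node_type == "outcome"), 1)
  expect_equal(nrow(g1$edges), 2) # provenance stays on the edges
})

test_that("dangling concept references abort the build with offenders listed", {
  eff <- efficacy_row("NCT00000001", "Drug X", "Placebo", "O1", "positive")
  expect_error(
    build_graph(eff, concepts = tibble::tibble(title = "Nonexistent Arm", concept = "Imipenem")),
    "dangling|absent"
  )
})

test_that("exports round-trip: graphml via igraph, neo4j_csv byte-stable, cypher replayable", {
  g <- toy_graph()
  dir <- withr::local_tempdir()

  gml <- export_graph(g, dir, "graphml")
  back <- import_graph(file.path(dir, "graph.graphml"), "graphml")
  expect_equal(nrow(back$nodes), nrow(g$nodes))
  expect_equal(nrow(back$edges), nrow(g$edges))
  expect_setequal(back$nodes$title, g$nodes$title)

  d1 <- file.path(dir, "csv1")
  d2 <- file.path(dir, "csv2")
  export_graph(g, d1, "neo4j_csv")
  header <- readLines(file.path(d1, "nodes.csv"), n = 1)
  expect_match(header, ":ID")
  expect_match(readLines(file.path(d1, "edges.csv"), n = 1), ":START_ID")
  reimported <- import_graph(d1, "neo4j_csv")
  export_graph(reimported, d2, "neo4j_csv")
  expect_identical(
    readLines(file.path(d1, "edges.csv")),
    readLines(file.path(d2, "edges.csv"))
  )
  expect_identical(
    readLines(file.path(d1, "nodes.csv")),
    readLines(file.path(d2, "nodes.csv"))
  )

  cy <- export_graph(g, dir, "cypher")
  lines <- readLines(file.path(dir, "graph.cypher"))
  expect_true(all(grepl("^(MERGE|MATCH)", lines)))
  expect_equal(sum(grepl("^MERGE \\(:", lines)), nrow(g$nodes))
  expect_equal(sum(grepl("MERGE \\(a\\)", lines)), nrow(g$edges))

  jl <- export_graph(g, dir, "jsonl")
  expect_length(readLines(file.path(dir, "nodes.jsonl")), nrow(g$nodes))

  expect_error(export_graph(g, dir, "dot"), "arg")

  # empty graph: header-only files
  empty_dir <- file.path(dir, "empty")
  export_graph(build_graph(efficacy_row("NCT00000001", "A", "B", "O")[0, ]), empty_dir, "neo4j_csv")
  expect_length(readLines(file.path(empty_dir, "nodes.csv")), 1)
})

test_that("conservation: graph edge counts equal classified rows and matched records", {
  cfg <- generator_config(n_trials = 25, seed = 77)
  dir <- withr::local_tempdir()
  generate_corpus(cfg, dir)
  res <- suppressWarnings(process_corpus(scan_corpus(dir)))
  eff <- res$efficacy
  classified_resolved <- sum(
    eff$significance %in% c("positive", "negative") & !is.na(eff$intervention_group)
  )
  et <- table(res$graph$edges$edge_type)
  expect_equal(
    sum(et[c("positive", "negative")], na.rm = TRUE),
    classified_resolved
  )
  expect_equal(unname(et["has_ae"]), sum(!is.na(res$safety$matched_group)))
  # every main node is reachable by at least one edge
  main <- res$graph$nodes[res$graph$nodes$node_type %in% c("intervention_arm", "outcome", "adverse_event"), ]
  touched <- unique(c(res$graph$edges$src, res$graph$edges$dst))
  expect_true(all(main$id %in% touched))
})

test_that("summary tables reproduce a planted positive/negative split", {
  eff <- dplyr::bind_rows(lapply(1:10, function(i) {
    efficacy_row(
      sprintf("NCT%08d", i), paste("Drug", i), "Placebo",
      sprintf("Change From Baseline in LDL-C at Week %d", i),
      ifelse(i <= 4, "positive", "negative"),
      conditions = "hypercholesterolemia"
    )
  }))
  labels <- classify_outcomes(unique(eff$outcome_title))
  tables <- summarize_results(eff, outcome_labels = labels)
  bio <- tables$by_outcome_type[tables$by_outcome_type$labels == "biomarker", ]
  expect_equal(bio$positive, 4)
  expect_equal(bio$negative, 6)
  expect_equal(bio$positive_pct, 40)
  hp <- tables$by_health_problem
  expect_equal(hp$health_problem, "Nutritional and Metabolic Diseases")
  expect_equal(hp$positive, 4)
  cov <- tables$coverage_by_rank
  expect_equal(cov$coverage[cov$outcome_rank == "primary"], 1)
  expect_equal(nrow(tables$biomarker_outcomes), 10)
})

test_that("subgraph queries match arms by title or concept and filter events", {
  eff <- efficacy_row("NCT00000001", "Imipenem/Cilastatin IV", "Placebo", "Clinical Cure", "positive")
  safety <- tibble::tibble(
    nct_id = "NCT00000001", arm_title = "Imipenem/Cilastatin IV",
    event_title = c("Urinary tract infection", "Sepsis", "Nausea"),
    category = c("Infections and infestations", "Infections and infestations", "Gastrointestinal disorders"),
    severity = "serious", affected = 1L, at_risk = 50L,
    matched_group = "Imipenem/Cilastatin IV", match_method = "string"
  )
  g <- build_graph(eff, safety, concepts = tibble::tibble(title = "Imipenem/Cilastatin IV", concept = "Imipenem"))

  sub <- query_subgraph(g, "imipenem", "infection")
  expect_equal(sum(sub$edges$edge_type == "has_ae"), 2)
  expect_equal(sum(sub$edges$edge_type == "positive"), 1)

  # matched via the concept node even when the arm title differs
  g2 <- build_graph(eff, safety, concepts = tibble::tibble(title = "Imipenem/Cilastatin IV", concept = "Tienam"))
  sub2 <- query_subgraph(g2, "tienam", NULL)
  expect_equal(sum(sub2$edges$edge_type == "has_ae"), 3)

  none <- query_subgraph(g, "nonexistent drug", NULL)
  expect_equal(nrow(none$edges), 0)
})
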