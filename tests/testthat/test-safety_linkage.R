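test_that("serious events with affected subjects are kept; totals and decoys drop", {
  ev <- dplyr::bind_rows(
    event_row("Oral Paricalcitol in the Oral Stratum", "Abdominal pain", "Gastrointestinal disorders", affected = 1, at_risk = 72),
    event_row("Arm A", "Total, serious adverse events", "Total", affected = 9, at_risk = 72),
    event_row("Arm A", "Syncope", "Cardiac disorders", affected = 0, at_risk = 72),
    event_row("Arm A", "Headache", "Nervous system disorders", severity = "other", affected = 3, at_risk = 72)
  )
  rec <- make_record("NCT00977080", events = ev)
  out <- extract_safety(rec)
  expect_equal(nrow(out), 1)
  expect_equal(out$event_title, "Abdominal pain")
  expect_equal(out$category, "Gastrointestinal disorders")
  expect_equal(out$affected, 1L)
  expect_equal(out$at_risk, 72L)
})

test_that("count-inconsistent records are quarantined, not silently kept", {
  ev <- dplyr::bind_rows(
    event_row("Arm A", "Sepsis", "Infections and infestations", affected = 80, at_risk = 72),
    event_row("Arm A", "Nausea", "Gastrointestinal disorders", affected = 2, at_risk = 72)
  )
  rec <- make_record("NCT00000001", events = ev)
  expect_warning(out <- extract_safety(rec), "Quarantined")
  expect_equal(nrow(out), 1)
  expect_equal(nrow(attr(out, "quarantined")), 1)
  expect_equal(attr(out, "quarantined")$event_title, "Sepsis")
})

test_that("arm matching tries exact strings first, then embedding argmax", {
  m <- match_ae_group("Tocilizumab + Placebo", c("Tocilizumab + Placebo", "Placebo"))
  expect_equal(m$matched_group, "Tocilizumab + Placebo")
  expect_equal(m$match_method, "string")

  # string matching is invariant to case and surrounding whitespace
  m2 <- match_ae_group("  tocilizumab +  placebo ", c("Tocilizumab + Placebo", "Placebo"))
  expect_equal(m2$matched_group, "Tocilizumab + Placebo")
  expect_equal(m2$match_method, "string")

  m3 <- match_ae_group("Laquinimod 0.6 mg", c("Laquinimod", "Placebo"))
  expect_equal(m3$matched_group, "Laquinimod")
  expect_equal(m3$match_method, "embedding")

  m4 <- match_ae_group("Anything", "Only Candidate")
  expect_equal(m4$matched_group, "Only Candidate")

  expect_error(match_ae_group("x", character(0)), "empty candidate")
})

test_that("safety is restricted to trials with valid efficacy results", {
  safety <- dplyr::bind_rows(
    tibble::tibble(nct_id = "NCT00000001", category = "A", affected = 1L, at_risk = 10L),
    tibble::tibble(nct_id = "NCT00000002", category = "B", affected = 2L, at_risk = 10L),
    tibble::tibble(nct_id = "NCT00000003", category = "C", affected = 3L, at_risk = 10L)
  )
  efficacy <- tibble::tibble(
    nct_id = c("NCT00000001", "NCT00000002", "NCT00000003"),
    significance = c("positive", "indeterminate", "negative"),
    excluded = FALSE
  )
  out <- filter_to_efficacy_trials(safety, efficacy)
  expect_setequal(out$nct_id, c("NCT00000001", "NCT00000003"))
  expect_equal(attr(out, "retained_fraction"), 2 / 3)

  disjoint <- filter_to_efficacy_trials(
    safety,
    tibble::tibble(nct_id = "NCT09999999", significance = "positive", excluded = FALSE)
  )
  expect_equal(nrow(disjoint), 0)
})

test_that("co-occurrence weight is the product of per-trial category ratios", {
  records <- dplyr::bind_rows(
    tibble::tibble(nct_id = "NCT00000001", category = "A", affected = 5L, at_risk = 10L),
    tibble::tibble(nct_id = "NCT00000001", category = "B", affected = 2L, at_risk = 10L)
  )
  cooc <- compute_cooccurrence(records)
  expect_equal(cooc$weights["A", "B"], 0.5 * 0.2)
  expect_equal(cooc$weights["B", "A"], 0.10)
  expect_equal(diag(cooc$weights), c(A = 0, B = 0))

  # per-trial contributions add across trials
  two <- dplyr::bind_rows(
    records,
    tibble::tibble(nct_id = "NCT00000002", category = c("A", "B"), affected = c(1L, 1L), at_risk = c(4L, 2L))
  )
  cooc2 <- compute_cooccurrence(two)
  expect_equal(cooc2$weights["A", "B"], 0.10 + 0.25 * 0.5)

  # same-category events pool by summed counts before the ratio
  pooled <- dplyr::bind_rows(
    tibble::tibble(nct_id = "NCT00000003", category = "A", affected = c(1L, 2L), at_risk = c(10L, 20L)),
    tibble::tibble(nct_id = "NCT00000003", category = "B", affected = 3L, at_risk = 30L)
  )
  cooc3 <- compute_cooccurrence(pooled)
  expect_equal(cooc3$weights["A", "B"], (3 / 30) * (3 / 30))

  # categories never co-reported in a trial have zero weight
  apart <- tibble::tibble(
    nct_id = c("NCT00000004", "NCT00000005"), category = c("A", "B"),
    affected = 1L, at_risk = 10L
  )
  expect_equal(sum(compute_cooccurrence(apart)$weights), 0)
})

test_that("co-occurrence equals brute-force enumeration on random corpora", {
  for (seed in 1:10) {
    records <- random_safety_records(n_trials = sample(3:20, 1), seed = 2000 + seed)
    if (nrow(records) == 0) next
    got <- compute_cooccurrence(records)
    want <- brute_force_cooccurrence(records)
    expect_equal(max(abs(got$weights - want[got$categories, got$categories])), 0, tolerance = 1e-12)
    # invariants: symmetry, zero diagonal, bounded by the trial count
    expect_identical(got$weights, t(got$weights))
    expect_true(all(diag(got$weights) == 0))
    expect_true(all(got$weights >= 0 & got$weights <= length(unique(records$nct_id))))
  }
})

test_that("cooccurrence_edges lists each pair once, sorted by weight", {
  records <- dplyr::bind_rows(
    tibble::tibble(nct_id = "NCT00000001", category = c("A", "B", "C"), affected = c(9L, 5L, 1L), at_risk = 10L)
  )
  edges <- cooccurrence_edges(compute_cooccurrence(records))
  expect_equal(nrow(edges), 3)
  expect_equal(edges$weight, sort(edges$weight, decreasing = TRUE))
  expect_equal(edges$category_a[1], "A")
  expect_equal(edges$category_b[1], "B")
})

test_that("affected totals aggregate by category and by single intervention type", {
  records <- dplyr::bind_rows(
    tibble::tibble(nct_id = "NCT00000001", category = "Cardiac disorders", affected = c(1L, 2L, 3L), at_risk = 10L),
    tibble::tibble(nct_id = "NCT00000002", category = "Infections and infestations", affected = 10L, at_risk = 10L)
  )
  by_cat <- aggregate_affected(records, "category")
  expect_equal(by_cat$affected[by_cat$category == "Cardiac disorders"], 6L)

  trial_types <- tibble::tibble(
    nct_id = c("NCT00000001", "NCT00000002"),
    intervention_types = list("Drug", c("Drug", "Device"))
  )
  by_type <- aggregate_affected(records, "intervention_type", trial_types = trial_types)
  # the two-type trial is excluded entirely
  expect_equal(by_type$intervention_type, "Drug")
  expect_equal(by_type$affected, 6L)
  expect_error(aggregate_affected(records, "intervention_type"), "trial_types")
})

test_that("corpus-level safety matching recovers the generator's intended arms", {
  cfg <- generator_config(n_trials = 30, seed = 321)
  dir <- withr::local_tempdir()
  gen <- generate_corpus(cfg, dir)
  truth <- manifest_tables(gen$manifest)
  recs <- scan_corpus(dir)
  res <- suppressWarnings(process_corpus(recs))
  j <- dplyr::inner_join(
    res$safety_all, truth$events,
    by = c("nct_id", "arm_title", "event_title", "category", "affected", "at_risk"),
    relationship = "many-to-many"
  )
  matched <- j[!is.na(j$matched_group), ]
  expect_gt(nrow(matched), 20)
  expect_equal(matched$matched_group, matched$expected_matched_group)
  expect_equal(matched$match_method, matched$expected_match_method)
  # retained fraction agrees with the manifest's trial-level truth
  valid_ncts <- unique(res$efficacy$nct_id[
    res$efficacy$significance %in% c("positive", "negative") & !res$efficacy$excluded
  ])
  expect_true(all(res$safety$nct_id %in% valid_ncts))
})
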