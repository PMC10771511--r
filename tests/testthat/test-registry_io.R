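test_that("a results XML document parses into arms, outcomes, analyses and events", {
  events <- '<reported_events>
    <group_list>
      <group group_id="E1"><title>Abatacept</title></group>
      <group group_id="E2"><title>Placebo</title></group>
    </group_list>
    <serious_events><category_list><category>
      <title>Cardiac disorders</title>
      <event_list>
        <event><sub_title>Syncope</sub_title>
          <counts group_id="E1" subjects_affected="1" subjects_at_risk="147"/>
        </event>
        <event><sub_title>Atrial fibrillation</sub_title>
          <counts><group_id>E2</group_id><subjects_affected>2</subjects_affected><subjects_at_risk>150</subjects_at_risk></counts>
        </event>
      </event_list>
    </category></category_list></serious_events>
  </reported_events>'
  rec <- read_trial_xml(fixture_xml(events_block = events))

  expect_s3_class(rec, "trial_record")
  expect_equal(rec$nct_id, "NCT01050998")
  expect_equal(rec$design_arms$role, c("experimental", "comparator"))
  expect_equal(nrow(rec$outcomes), 1)
  expect_match(rec$outcomes$title, "Disease Activity Score of 28 Joints")
  expect_equal(nrow(rec$outcomes$analyses[[1]]), 1)
  expect_equal(rec$outcomes$analyses[[1]]$group_titles[[1]], c("Abatacept", "Placebo"))
  expect_equal(rec$outcomes$analyses[[1]]$p_value_raw, "0.0757")

  # both counts dialects (attribute and child-element) parse identically
  expect_equal(nrow(rec$events), 2)
  expect_equal(rec$events$arm_title, c("Abatacept", "Placebo"))
  expect_equal(rec$events$affected, c(1L, 2L))
  expect_equal(rec$events$at_risk, c(147L, 150L))
  expect_equal(rec$events$severity, c("serious", "serious"))
})

test_that("design-only registrations yield empty result tables, not errors", {
  rec <- read_trial_xml(design_only_xml())
  expect_equal(nrow(rec$outcomes), 0)
  expect_equal(nrow(rec$events), 0)
  expect_equal(nrow(to_efficacy_rows(rec)), 0)
})

test_that("arm roles derive only from the design arm-type string", {
  xml <- fixture_xml(arms = list(
    list(title = "A", type = "Experimental"),
    list(title = "B", type = "Active Comparator"),
    list(title = "C", type = "placebo comparator"),
    list(title = "D", type = "Other"),
    list(title = "E", type = "No Intervention")
  ))
  rec <- read_trial_xml(xml)
  expect_equal(
    rec$design_arms$role,
    c("experimental", "comparator", "comparator", "other", "other")
  )
})

test_that("malformed XML and missing nct_id are rejected with diagnostics", {
  bad <- tempfile(fileext = ".xml")
  writeLines("<clinical_study><unclosed>", bad)
  expect_error(read_trial_xml(bad), class = "ctarmkg_parse_error")
  expect_error(
    read_trial_xml("<clinical_study><id_info/></clinical_study>"),
    class = "ctarmkg_missing_id"
  )
  expect_error(
    read_trial_xml("<clinical_study><id_info><nct_id>XYZ123</nct_id></id_info></clinical_study>"),
    class = "ctarmkg_missing_id"
  )
})

test_that("scan_corpus yields records in lexicographic order with a skip count", {
  dir <- withr::local_tempdir()
  ids <- sprintf("NCT0000000%d", 5:1) # written in reverse order on purpose
  for (id in ids) writeLines(design_only_xml(id), file.path(dir, paste0(id, ".xml")))
  writeLines("<clinical_study><truncat", file.path(dir, "NCT00000099.xml"))

  recs <- suppressWarnings(scan_corpus(dir))
  expect_length(recs, 5)
  expect_equal(attr(recs, "skipped"), 1L)
  expect_equal(
    vapply(recs, `[[`, character(1), "nct_id"),
    sort(ids)
  )
})

test_that("scanning an empty corpus warns and returns an empty stream", {
  dir <- withr::local_tempdir()
  expect_warning(recs <- scan_corpus(dir), "empty")
  expect_length(recs, 0)
  expect_error(scan_corpus(file.path(dir, "nope")), "does not exist")
})

test_that("to_efficacy_rows emits one row per analysis and flags non-two-group analyses", {
  two_analyses <- '<analysis>
      <group_id_list><group_id>O1</group_id><group_id>O2</group_id></group_id_list>
      <p_value>0.01</p_value>
    </analysis>
    <analysis>
      <group_id_list><group_id>O1</group_id><group_id>O2</group_id></group_id_list>
      <p_value>0.50</p_value>
    </analysis>'
  rec <- read_trial_xml(fixture_xml(analysis = two_analyses))
  rows <- to_efficacy_rows(rec)
  expect_equal(nrow(rows), 2)
  expect_false(any(rows$excluded))

  three_groups <- '<analysis>
      <group_id_list><group_id>O1</group_id><group_id>O2</group_id><group_id>O1</group_id></group_id_list>
      <p_value>0.01</p_value>
    </analysis>'
  rec3 <- read_trial_xml(fixture_xml(analysis = three_groups))
  rows3 <- to_efficacy_rows(rec3)
  expect_true(rows3$excluded)
  expect_equal(rows3$n_groups, 3L)
})

test_that("a transformed efficacy row carries the registry fields verbatim", {
  xml <- fixture_xml(
    nct_id = "NCT03400800",
    arms = list(
      list(title = "Inclisiran", type = "Experimental"),
      list(title = "Placebo", type = "Placebo Comparator")
    ),
    outcome_title = "Percentage Change in LDL-C From Baseline to Day 510",
    analysis = '<analysis>
      <group_id_list><group_id>O1</group_id><group_id>O2</group_id></group_id_list>
      <p_value>&lt;0.0001</p_value>
    </analysis>'
  )
  rows <- to_efficacy_rows(read_trial_xml(xml))
  expect_equal(rows$nct_id, "NCT03400800")
  expect_equal(rows$group_titles[[1]], c("Inclisiran", "Placebo"))
  expect_equal(rows$outcome_title, "Percentage Change in LDL-C From Baseline to Day 510")
  expect_equal(rows$p_value_raw, "<0.0001")
})

test_that("parsing the generator's XML reproduces the ground-truth manifest counts", {
  for (seed in c(11, 12)) {
    cfg <- generator_config(n_trials = 8, seed = seed)
    dir <- withr::local_tempdir()
    gen <- generate_corpus(cfg, dir)
    truth <- manifest_tables(gen$manifest)
    recs <- scan_corpus(dir)
    expect_length(recs, 8)
    for (i in seq_along(recs)) {
      rec <- recs[[i]]
      tr <- truth$trials[truth$trials$nct_id == rec$nct_id, ]
      expect_equal(nrow(rec$design_arms), tr$n_arms)
      expect_equal(nrow(rec$outcomes), tr$n_outcomes)
      expect_equal(sum(vapply(rec$outcomes$analyses, nrow, integer(1))), tr$n_analyses)
      expect_equal(nrow(rec$events), tr$n_event_elements)
    }
  }
})

test_that("write_records round-trips CSV and JSONL, and rewriting is byte-stable", {
  rows <- efficacy_row("NCT00000001", "Drug X", "Placebo", "Outcome 1")
  rows <- dplyr::bind_rows(rows, efficacy_row("NCT00000002", "Drug Y", "Placebo", "Outcome 2", "negative"))

  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_records(rows, p1, "csv")
  back <- read_records(p1, "csv", list_cols = c("conditions", "intervention_types", "group_titles"))
  expect_equal(nrow(back), 2)
  expect_equal(back$group_titles[[1]], c("Drug X", "Placebo"))
  expect_equal(back$significance, rows$significance)
  write_records(back, p2, "csv")
  expect_identical(readLines(p1), readLines(p2))

  pj <- withr::local_tempfile(fileext = ".jsonl")
  write_records(rows, pj, "jsonl")
  backj <- read_records(pj, "jsonl")
  expect_equal(nrow(backj), 2)
  expect_equal(backj$intervention_group, rows$intervention_group)

  # zero rows: header-only CSV
  p0 <- withr::local_tempfile(fileext = ".csv")
  write_records(rows[0, ], p0, "csv")
  expect_length(readLines(p0), 1)
})
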