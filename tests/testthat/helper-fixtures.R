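# Hand-written XML fixtures and record builders, independent of the
# package's own generator, so parser tests have a second route.

fixture_xml <- function(nct_id = "NCT01050998",
                        conditions = "Rheumatoid Arthritis",
                        intervention_types = "Drug",
                        arms = list(
                          list(title = "Abatacept", type = "Experimental"),
                          list(title = "Placebo", type = "Placebo Comparator")
                        ),
                        outcome_title = "Percentage of Participants Who Achieved Disease Activity Score of 28 Joints Using C-Reactive Protein (DAS28 [CRP]) Response at Day 85 by Region",
                        analysis = '<analysis>
        <group_id_list><group_id>O1</group_id><group_id>O2</group_id></group_id_list>
        <p_value>0.0757</p_value>
        <method>ANCOVA</method>
        <param_type>Mean Difference (Final Values)</param_type>
      </analysis>',
                        events_block = "") {
  arm_xml <- paste(vapply(arms, function(a) {
    sprintf(
      "<arm_group><arm_group_label>%s</arm_group_label><arm_group_type>%s</arm_group_type></arm_group>",
      a$title, a$type
    )
  }, character(1)), collapse = "\n")
  group_xml <- paste(vapply(seq_along(arms), function(i) {
    sprintf('<group group_id="O%d"><title>%s</title></group>', i, arms[[i]]$title)
  }, character(1)), collapse = "")
  sprintf(
    '<clinical_study>
  <id_info><nct_id>%s</nct_id></id_info>
  %s
  %s
  %s
  <clinical_results>
    <outcome_list>
      <outcome>
        <type>Primary</type>
        <title>%s</title>
        <group_list>%s</group_list>
        <analysis_list>%s</analysis_list>
      </outcome>
    </outcome_list>
    %s
  </clinical_results>
</clinical_study>',
    nct_id,
    paste(sprintf("<condition>%s</condition>", conditions), collapse = "\n"),
    paste(sprintf(
      "<intervention><intervention_type>%s</intervention_type></intervention>",
      intervention_types
    ), collapse = "\n"),
    arm_xml, outcome_title, group_xml, analysis, events_block
  )
}

design_only_xml <- function(nct_id = "NCT00000001") {
  sprintf(
    "<clinical_study><id_info><nct_id>%s</nct_id></id_info>
     <arm_group><arm_group_label>A</arm_group_label><arm_group_type>Experimental</arm_group_type></arm_group>
    </clinical_study>", nct_id
  )
}

# Build a trial_record directly (no XML), for safety/graph unit tests.
make_record <- function(nct_id, events = NULL, arms = NULL, conditions = character(0),
                        intervention_types = "Drug") {
  empty_events <- tibble::tibble(
    arm_title = character(0), event_title = character(0), category = character(0),
    severity = character(0), affected = integer(0), at_risk = integer(0)
  )
  structure(
    list(
      nct_id = nct_id,
      conditions = conditions,
      intervention_types = intervention_types,
      design_arms = arms %||% tibble::tibble(
        title = c("Drug X", "Placebo"), role = c("experimental", "comparator")
      ),
      outcomes = tibble::tibble(title = character(0), rank = character(0), analyses = list()),
      events = events %||% empty_events
    ),
    class = "trial_record"
  )
}

event_row <- function(arm_title, event_title, category, severity = "serious",
                      affected = 1L, at_risk = 100L) {
  tibble::tibble(
    arm_title = arm_title, event_title = event_title, category = category,
    severity = severity, affected = as.integer(affected), at_risk = as.integer(at_risk)
  )
}

# Minimal resolved-efficacy row for graph tests.
efficacy_row <- function(nct_id, intervention, comparator, outcome,
                         significance = "positive", rank = "primary",
                         conditions = character(0), types = "Drug") {
  tibble::tibble(
    nct_id = nct_id,
    conditions = list(conditions),
    intervention_types = list(types),
    outcome_title = outcome,
    outcome_rank = rank,
    group_titles = list(c(intervention, comparator)),
    n_groups = 2L,
    excluded = FALSE,
    p_value_raw = "0.01",
    method = NA_character_,
    param_name_raw = NA_character_,
    param_value = NA_real_,
    ci_percent = NA_real_,
    ci_lower_raw = NA_character_,
    ci_upper_raw = NA_character_,
    non_inferiority = NA_character_,
    p_op = "eq", p_value = 0.01, param_kind = "unknown",
    ci_lower = NA_real_, ci_upper = NA_real_,
    significance = significance,
    basis = if (significance == "indeterminate") "none" else "p_value",
    intervention_group = intervention,
    comparator_group = comparator,
    score_intervention = 1, score_comparator = 1,
    match_method = "exact", exclusion_reason = NA_character_
  )
}

# Independent brute-force oracle for the co-occurrence statistic:
# plain loops over (trial, category pair), nothing shared with the
# implementation.
brute_force_cooccurrence <- function(records) {
  records <- records[!is.na(records$at_risk) & records$at_risk >= 1, ]
  cats <- sort(unique(records$category))
  w <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  for (nct in unique(records$nct_id)) {
    tr <- records[records$nct_id == nct, ]
    present <- unique(tr$category)
    if (length(present) < 2) next
    ratio <- function(cat) {
      sub <- tr[tr$category == cat, ]
      sum(sub$affected) / sum(sub$at_risk)
    }
    for (a in present) {
      for (b in present) {
        if (a < b) {
          w[a, b] <- w[a, b] + ratio(a) * ratio(b)
          w[b, a] <- w[a, b]
        }
      }
    }
  }
  w
}

# Random safety-record tables for co-occurrence property tests.
random_safety_records <- function(n_trials, seed) {
  withr::with_seed(seed, {
    rows <- list()
    cats <- paste("Category", LETTERS[1:6])
    for (t in seq_len(n_trials)) {
      n <- sample(0:8, 1)
      if (n == 0) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        nct_id = sprintf("NCT%08d", t),
        arm_title = "arm",
        event_title = paste("event", seq_len(n)),
        category = sample(cats, n, replace = TRUE),
        severity = "serious",
        affected = sample(1:20, n, replace = TRUE),
        at_risk = sample(30:200, n, replace = TRUE)
      )
    }
    dplyr::bind_rows(rows)
  })
}
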