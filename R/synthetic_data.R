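GEN_DRUGS <- c(
  "Inclisiran", "Caplacizumab", "Canagliflozin", "Baloxavir", "Laquinimod",
  "Tocilizumab", "Sunitinib", "Paricalcitol", "Dupilumab", "Semaglutide",
  "Rivaroxaban", "Ustekinumab", "Pembrolizumab", "Aripiprazole", "Evolocumab",
  "Sacubitril"
)
GEN_COMPARATORS <- c("Placebo", "Matching Placebo", "Standard of Care", "Sham Procedure")
GEN_CONDITIONS <- c(
  "Rheumatoid Arthritis", "Type 2 Diabetes", "Asthma", "Hypertension",
  "Major Depressive Disorder", "Influenza", "Psoriasis", "Heart Failure",
  "Multiple Sclerosis", "Osteoporosis", "Chronic Kidney Disease",
  "Atopic Dermatitis", "Hypercholesterolemia", "Schizophrenia", "Obesity",
  "Migraine"
)
GEN_BIOMARKERS <- c(
  "LDL-C", "Hemoglobin A1c", "C-Reactive Protein", "FEV1",
  "Bone Mineral Density", "Systolic Blood Pressure", "Triglycerides",
  "Blood Glucose", "Interleukin-6", "Viral Load"
)
GEN_CLINICAL_EVENTS <- c(
  "Myocardial Infarction", "Stroke", "Pneumonia", "Sepsis", "Migraine",
  "Depression", "Urinary Tract Infection", "Heart Failure"
)
GEN_PRO_TITLES <- c(
  "Overall Well-Being Score", "Global Impression Scale Rating",
  "Daily Functioning Score at Week 12", "Patient Reported Symptom Diary Total"
)
GEN_QUESTIONNAIRE_TITLES <- c(
  "Treatment Satisfaction Questionnaire Total",
  "Health Survey Summary Measure"
)
GEN_PLAIN_TITLES <- c(
  "Overall Treatment Success", "Time to First Response",
  "Number of Participants With Improvement", "Duration of Hospital Stay"
)
GEN_AE_CATEGORIES <- c(
  "Cardiac disorders", "Gastrointestinal disorders",
  "Infections and infestations", "Nervous system disorders",
  "Respiratory, thoracic and mediastinal disorders", "Vascular disorders",
  "Hepatobiliary disorders", "Renal and urinary disorders",
  "Blood and lymphatic system disorders", "Psychiatric disorders"
)
GEN_AE_TITLES <- list(
  "Cardiac disorders" = c("Atrial fibrillation", "Cardiac failure", "Syncope"),
  "Gastrointestinal disorders" = c("Abdominal pain", "Nausea", "Pancreatitis"),
  "Infections and infestations" = c("Pneumonia", "Urinary tract infection", "Sepsis"),
  "Nervous system disorders" = c("Headache", "Seizure", "Dizziness"),
  "Respiratory, thoracic and mediastinal disorders" = c("Dyspnoea", "Pulmonary embolism", "Cough"),
  "Vascular disorders" = c("Hypertension", "Deep vein thrombosis", "Hypotension"),
  "Hepatobiliary disorders" = c("Hepatocellular injury", "Cholecystitis", "Jaundice"),
  "Renal and urinary disorders" = c("Acute kidney injury", "Renal failure", "Haematuria"),
  "Blood and lymphatic system disorders" = c("Anaemia", "Thrombocytopenia", "Neutropenia"),
  "Psychiatric disorders" = c("Anxiety", "Insomnia", "Confusional state")
)

#' Configuration for the synthetic registry-corpus generator
#'
#' Bundles the knobs of the ground-truthed corpus generator. The defaults
#' describe a corpus exercising every rule of the downstream pipeline: a
#' mix of p-value dialects (plain decimals, `<`/`<=` bounds, scientific
#' notation, unparseable strings), a share of confidence-interval-only
#' analyses split between ratio- and difference-type parameters, a planted
#' positive share of 0.4361 among decidable results (the share the
#' corpus-wide classification reports), and moderate title drift between
#' the design and analysis sections.
#'
#' @param n_trials Number of trials to generate.
#' @param p_value_dialect_mix Named probabilities over
#'   `c("plain", "lt", "le", "scientific", "unparseable")`.
#' @param ci_only_fraction Fraction of analyses reporting a confidence
#'   interval and no p-value.
#' @param ratio_kind_fraction Among CI-only analyses with a known
#'   parameter kind, the fraction with a ratio-type parameter.
#' @param unknown_kind_fraction Among CI-only analyses, the fraction whose
#'   parameter name matches neither keyword list (these are planted
#'   indeterminate).
#' @param target_positive_fraction Probability that a decidable analysis
#'   is planted positive.
#' @param title_noise Title drift level in \[0, 1\] applied to
#'   analysis-section group titles (see [perturb_title()]).
#' @param ae_categories Body-system categories to draw events from.
#' @param seed Corpus seed; identical config and seed give a byte-identical
#'   corpus.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_trials = 100L,
                             p_value_dialect_mix = c(
                               plain = 0.45, lt = 0.20, le = 0.05,
                               scientific = 0.10, unparseable = 0.20
                             ),
                             ci_only_fraction = 0.25,
                             ratio_kind_fraction = 0.5,
                             unknown_kind_fraction = 0.1,
                             target_positive_fraction = 0.4361,
                             title_noise = 0.2,
                             ae_categories = GEN_AE_CATEGORIES,
                             seed = 1L) {
  stopifnot(
    n_trials >= 0,
    abs(sum(p_value_dialect_mix) - 1) < 1e-8,
    ci_only_fraction >= 0, ci_only_fraction <= 1,
    ratio_kind_fraction >= 0, ratio_kind_fraction <= 1,
    target_positive_fraction >= 0, target_positive_fraction <= 1,
    title_noise >= 0, title_noise <= 1
  )
  structure(
    list(
      n_trials = as.integer(n_trials),
      p_value_dialect_mix = p_value_dialect_mix,
      ci_only_fraction = ci_only_fraction,
      ratio_kind_fraction = ratio_kind_fraction,
      unknown_kind_fraction = unknown_kind_fraction,
      target_positive_fraction = target_positive_fraction,
      title_noise = title_noise,
      ae_categories = ae_categories,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

#' Apply seeded drift to an arm title
#'
#' Emulates the inconsistencies between design-section and
#' analysis-section arm titles seen in registry data: dose suffixes,
#' casing changes, small typos, and word truncation. Each edit is applied
#' with a probability scaling with `noise`; `noise = 0` is the identity.
#'
#' @param title The title to perturb.
#' @param noise Drift level in \[0, 1\].
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return The perturbed title.
#' @export
perturb_title <- function(title, noise, seed = NULL) {
  stopifnot(noise >= 0, noise <= 1)
  if (noise == 0) {
    return(title)
  }
  run <- function() {
    out <- title
    if (stats::runif(1) < noise) { # dose suffix
      out <- paste0(out, " ", sample(c(5, 10, 25, 50, 100, 250), 1), " mg")
    }
    if (stats::runif(1) < noise * 0.5) { # casing
      out <- if (stats::runif(1) < 0.5) toupper(out) else tolower(out)
    }
    if (stats::runif(1) < noise * 0.25) { # typo: drop one interior character
      n <- nchar(out)
      if (n > 4) {
        i <- sample(2:(n - 1), 1)
        out <- paste0(substr(out, 1, i - 1), substr(out, i + 1, n))
      }
    }
    if (stats::runif(1) < noise * 0.15) { # truncate to the first word
      out <- strsplit(out, " ", fixed = TRUE)[[1]][1]
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

plant_p_value <- function(dialect, label) {
  switch(dialect,
    plain = if (label == "positive") {
      sprintf("%.4f", stats::runif(1, 0.0005, 0.0499))
    } else {
      sprintf("%.4f", stats::runif(1, 0.0501, 0.95))
    },
    lt = if (label == "positive") {
      sample(c("<0.0001", "<0.001", "<0.01", "<0.05"), 1)
    } else {
      sample(c(">0.05", ">0.1", ">0.5"), 1)
    },
    le = if (label == "positive") {
      sample(c("<=0.05", "≤0.05", "<=0.01"), 1)
    } else {
      sample(c(">=0.05", "≥0.1"), 1)
    },
    scientific = if (label == "positive") {
      sprintf("%.1e", stats::runif(1, 1e-6, 0.04))
    } else {
      sprintf("%.1e", stats::runif(1, 0.06, 0.9))
    },
    unparseable = sample(c("NA", "N/A", "p<.05*", "not reported"), 1)
  )
}

plant_ci <- function(kind, label) {
  null_value <- if (kind == "ratio") 1 else 0
  if (label == "negative") {
    lower <- null_value - stats::runif(1, 0.05, if (kind == "ratio") 0.4 else 1)
    upper <- null_value + stats::runif(1, 0.05, if (kind == "ratio") 0.6 else 1)
  } else if (stats::runif(1) < 0.5) { # entirely above the null
    lower <- null_value + stats::runif(1, 0.05, 0.5)
    upper <- lower + stats::runif(1, 0.2, 1.5)
  } else { # entirely below
    upper <- null_value - stats::runif(1, 0.05, if (kind == "ratio") 0.3 else 0.5)
    lower <- upper - stats::runif(1, 0.2, if (kind == "ratio") 0.4 else 1.5)
  }
  c(sprintf("%.2f", lower), sprintf("%.2f", upper))
}

plant_outcome <- function() {
  template <- sample(6, 1, prob = c(0.22, 0.13, 0.15, 0.10, 0.22, 0.18))
  switch(template,
    { # biomarker
      term <- sample(GEN_BIOMARKERS, 1)
      list(
        title = sprintf("Change From Baseline in %s at Week %d", term, sample(c(4, 12, 24, 52), 1)),
        labels = "biomarker"
      )
    },
    { # biomarker measured on a reported scale
      term <- sample(GEN_BIOMARKERS, 1)
      list(
        title = sprintf("%s Score at Day %d", term, sample(c(28, 85, 180), 1)),
        labels = c("biomarker", "PRO")
      )
    },
    list(title = sample(GEN_PRO_TITLES, 1), labels = "PRO"),
    { # questionnaire instrument: PRO via the E05.318.308.980 branch only
      list(title = sample(GEN_QUESTIONNAIRE_TITLES, 1), labels = "PRO")
    },
    { # clinical endpoint
      ev <- sample(GEN_CLINICAL_EVENTS, 1)
      list(
        title = sprintf("Incidence of %s Through Week %d", ev, sample(c(12, 26, 52), 1)),
        labels = "clinical_endpoint"
      )
    },
    list(title = sample(GEN_PLAIN_TITLES, 1), labels = character(0))
  )
}

#' Generate one synthetic registry XML trial with ground truth
#'
#' Emits one legacy-dialect XML document plus a machine-readable manifest
#' fragment recording every planted truth: design-arm roles, the intended
#' significance label and basis of every analysis, the intended
#' intervention/comparator assignment of the (possibly drifted) group
#' titles, outcome label sets, and the serious adverse-event records the
#' safety stage should retain, with their expected matched arm. The same
#' `(config, seed, index)` always produces identical bytes.
#'
#' @param config A [generator_config()].
#' @param seed Corpus seed (defaults to `config$seed`).
#' @param index 1-based trial index; also determines the NCT id.
#' @return List with `xml` (a string) and `manifest` (a list).
#' @export
generate_trial <- function(config, seed = config$seed, index = 1L) {
  trial_seed <- (as.numeric(seed) + index * 7919) %% 2147483647
  withr::with_seed(trial_seed, generate_trial_impl(config, index))
}

generate_trial_impl <- function(config, index) {
  nct_id <- sprintf("NCT%08d", 10000000 + index)
  drug <- sample(GEN_DRUGS, 1)
  dose <- if (stats::runif(1) < 0.5) paste0(" ", sample(c(5, 10, 25, 50, 100), 1), " mg") else ""
  exp_title <- paste0(drug, dose)
  comp_title <- sample(GEN_COMPARATORS, 1)
  design_valid <- stats::runif(1) > 0.05
  arm_types <- if (design_valid) {
    c("Experimental", sample(c("Placebo Comparator", "Active Comparator"), 1))
  } else {
    c("Other", "Other")
  }
  conditions <- sample(GEN_CONDITIONS, sample(1:2, 1, prob = c(0.85, 0.15)))
  intervention_types <- if (stats::runif(1) < 0.85) {
    sample(c("Drug", "Biological", "Device", "Behavioral"), 1, prob = c(0.7, 0.15, 0.1, 0.05))
  } else {
    sample(c("Drug", "Biological", "Device", "Behavioral"), 2)
  }

  # one drifted variant per trial, reused across its analyses
  g_exp <- perturb_title(exp_title, config$title_noise)
  g_comp <- perturb_title(comp_title, config$title_noise)

  n_outcomes <- sample(1:3, 1)
  outcomes <- list()
  rows <- list()
  for (oi in seq_len(n_outcomes)) {
    oc <- plant_outcome()
    rank <- if (oi == 1) "Primary" else "Secondary"
    n_analyses <- if (stats::runif(1) < 0.8) 1L else 2L
    analyses <- list()
    for (ai in seq_len(n_analyses)) {
      an <- plant_analysis(config, g_exp, g_comp)
      analyses[[ai]] <- an$analysis
      rows[[length(rows) + 1]] <- c(
        list(
          nct_id = nct_id, outcome_title = oc$title, outcome_rank = tolower(rank),
          intervention_group_truth = if (an$excluded) NA else g_exp,
          comparator_group_truth = if (an$excluded) NA else g_comp,
          design_valid = design_valid
        ),
        an$truth
      )
    }
    outcomes[[oi]] <- list(title = oc$title, rank = rank, labels = oc$labels, analyses = analyses)
  }

  canonical_groups <- c(g_exp, g_comp)
  n_events <- sample(0:5, 1)
  events <- list()
  if (n_events > 0) {
    for (ei in seq_len(n_events)) {
      category <- sample(config$ae_categories, 1)
      title <- sample(GEN_AE_TITLES[[category]] %||% c("Adverse event"), 1)
      exact <- stats::runif(1) < 0.6
      is_exp_arm <- stats::runif(1) < 0.5
      arm_title <- if (exact) {
        if (is_exp_arm) g_exp else g_comp
      } else {
        paste(if (is_exp_arm) exp_title else comp_title, sample(c("Arm", "Group"), 1))
      }
      at_risk <- sample(20:500, 1)
      affected <- sample(1:10, 1)
      events[[ei]] <- list(
        arm_title = arm_title, event_title = title, category = category,
        severity = "serious", affected = affected, at_risk = at_risk,
        expected_matched_group = if (is_exp_arm) g_exp else g_comp,
        expected_match_method = if (exact) "string" else "embedding"
      )
    }
  }
  # decoy records the safety stage must drop
  decoys <- list()
  if (n_events > 0 && stats::runif(1) < 0.5) {
    decoys[[length(decoys) + 1]] <- list(
      arm_title = g_exp, event_title = "Total, serious adverse events",
      category = "Total", severity = "serious",
      affected = sum(vapply(events, `[[`, numeric(1), "affected")), at_risk = 500L
    )
  }
  if (stats::runif(1) < 0.3) {
    decoys[[length(decoys) + 1]] <- list(
      arm_title = g_comp, event_title = "Syncope", category = "Cardiac disorders",
      severity = "serious", affected = 0L, at_risk = 100L
    )
  }
  if (stats::runif(1) < 0.5) {
    decoys[[length(decoys) + 1]] <- list(
      arm_title = g_exp, event_title = "Headache", category = "Nervous system disorders",
      severity = "other", affected = sample(1:20, 1), at_risk = 200L
    )
  }

  xml <- build_trial_xml(
    nct_id, conditions, intervention_types,
    arms = list(
      list(title = exp_title, type = arm_types[1]),
      list(title = comp_title, type = arm_types[2])
    ),
    outcomes = outcomes, events = events, decoys = decoys
  )

  any_classified <- any(vapply(
    rows,
    function(r) !isTRUE(r$excluded) && r$label %in% c("positive", "negative"),
    logical(1)
  ))
  manifest <- list(
    nct_id = nct_id,
    design_valid = design_valid,
    arms = list(
      list(title = exp_title, role = if (design_valid) "experimental" else "other"),
      list(title = comp_title, role = if (design_valid) "comparator" else "other")
    ),
    conditions = as.list(conditions),
    intervention_types = as.list(intervention_types),
    rows = rows,
    outcomes = lapply(outcomes, function(o) {
      list(title = o$title, rank = tolower(o$rank), labels = as.list(o$labels))
    }),
    events = lapply(events, function(e) {
      c(e, list(
        kept = TRUE,
        counted_in_kg = design_valid && any_classified
      ))
    }),
    counts = list(
      n_arms = 2L,
      n_outcomes = n_outcomes,
      n_analyses = length(rows),
      n_event_elements = length(events) + length(decoys)
    )
  )
  list(xml = xml, manifest = manifest)
}

plant_analysis <- function(config, g_exp, g_comp) {
  three_groups <- stats::runif(1) < 0.05
  swap <- stats::runif(1) < 0.5
  groups <- if (swap) c(g_comp, g_exp) else c(g_exp, g_comp)
  if (three_groups) groups <- c(groups, "All Participants")

  p_raw <- NA_character_
  param_name <- NA_character_
  ci <- NULL
  ci_percent <- NA_real_
  basis <- "none"
  label <- "indeterminate"
  if (stats::runif(1) >= config$ci_only_fraction) {
    dialect <- sample(names(config$p_value_dialect_mix), 1, prob = config$p_value_dialect_mix)
    if (dialect == "unparseable") {
      p_raw <- plant_p_value(dialect, "indeterminate")
    } else {
      label <- if (stats::runif(1) < config$target_positive_fraction) "positive" else "negative"
      basis <- "p_value"
      p_raw <- plant_p_value(dialect, label)
      if (stats::runif(1) < 0.3) {
        # an interval alongside the p-value: must never influence the label
        kind <- sample(c("ratio", "difference"), 1)
        param_name <- if (kind == "ratio") "Hazard Ratio" else "Mean Difference"
        ci <- plant_ci(kind, sample(c("positive", "negative"), 1))
        ci_percent <- 95
      }
    }
  } else {
    if (stats::runif(1) < config$unknown_kind_fraction) {
      param_name <- "Cohen's d"
      ci <- c("0.20", "0.90")
      ci_percent <- 95
    } else {
      label <- if (stats::runif(1) < config$target_positive_fraction) "positive" else "negative"
      kind <- if (stats::runif(1) < config$ratio_kind_fraction) "ratio" else "difference"
      basis <- if (kind == "ratio") "ci_ratio" else "ci_difference"
      param_name <- if (kind == "ratio") {
        sample(c("Odds Ratio", "Hazard Ratio", "Risk Ratio (RR)"), 1)
      } else {
        sample(c("Mean Difference (Final Values)", "Risk Difference", "Slope"), 1)
      }
      ci <- plant_ci(kind, label)
      ci_percent <- sample(c(95, 90), 1, prob = c(0.85, 0.15))
    }
  }
  list(
    analysis = list(
      groups = groups,
      p_value = p_raw,
      method = sample(c("ANCOVA", "Cochran-Mantel-Haenszel", "t-test, 2 sided", "Regression, Cox"), 1),
      param_name = param_name,
      param_value = if (!is.null(ci)) sprintf("%.2f", mean(as.numeric(ci))) else NA_character_,
      ci_percent = ci_percent,
      ci_lower = if (!is.null(ci)) ci[1] else NA_character_,
      ci_upper = if (!is.null(ci)) ci[2] else NA_character_
    ),
    excluded = three_groups,
    truth = list(
      group_titles = as.list(groups),
      excluded = three_groups,
      label = if (three_groups) NA_character_ else label,
      basis = if (three_groups) NA_character_ else basis
    )
  )
}

xml_add_text_child <- function(parent, name, value) {
  if (is.null(value) || length(value) == 0 || is.na(value)) {
    return(invisible(NULL))
  }
  xml2::xml_add_child(parent, name, as.character(value))
  invisible(NULL)
}

build_trial_xml <- function(nct_id, conditions, intervention_types, arms, outcomes, events, decoys) {
  doc <- xml2::xml_new_root("clinical_study")
  id_info <- xml2::xml_add_child(doc, "id_info")
  xml_add_text_child(id_info, "nct_id", nct_id)
  for (cond in conditions) xml_add_text_child(doc, "condition", cond)
  for (ty in intervention_types) {
    iv <- xml2::xml_add_child(doc, "intervention")
    xml_add_text_child(iv, "intervention_type", ty)
    xml_add_text_child(iv, "intervention_name", "synthetic")
  }
  for (arm in arms) {
    ag <- xml2::xml_add_child(doc, "arm_group")
    xml_add_text_child(ag, "arm_group_label", arm$title)
    xml_add_text_child(ag, "arm_group_type", arm$type)
  }
  results <- xml2::xml_add_child(doc, "clinical_results")
  if (length(outcomes) > 0) {
    olist <- xml2::xml_add_child(results, "outcome_list")
    for (oc in outcomes) {
      node <- xml2::xml_add_child(olist, "outcome")
      xml_add_text_child(node, "type", oc$rank)
      xml_add_text_child(node, "title", oc$title)
      all_groups <- unique(unlist(lapply(oc$analyses, `[[`, "groups")))
      glist <- xml2::xml_add_child(node, "group_list")
      for (gi in seq_along(all_groups)) {
        g <- xml2::xml_add_child(glist, "group", group_id = paste0("O", gi))
        xml_add_text_child(g, "title", all_groups[gi])
      }
      alist <- xml2::xml_add_child(node, "analysis_list")
      for (an in oc$analyses) {
        anode <- xml2::xml_add_child(alist, "analysis")
        gidlist <- xml2::xml_add_child(anode, "group_id_list")
        for (g in an$groups) {
          xml_add_text_child(gidlist, "group_id", paste0("O", match(g, all_groups)))
        }
        xml_add_text_child(anode, "non_inferiority_type", "Superiority")
        xml_add_text_child(anode, "p_value", an$p_value)
        xml_add_text_child(anode, "method", an$method)
        xml_add_text_child(anode, "param_type", an$param_name)
        xml_add_text_child(anode, "param_value", an$param_value)
        xml_add_text_child(anode, "ci_percent", an$ci_percent)
        xml_add_text_child(anode, "ci_lower_limit", an$ci_lower)
        xml_add_text_child(anode, "ci_upper_limit", an$ci_upper)
      }
    }
  }
  all_events <- c(events, decoys)
  if (length(all_events) > 0) {
    re <- xml2::xml_add_child(results, "reported_events")
    arm_titles <- unique(vapply(all_events, `[[`, character(1), "arm_title"))
    glist <- xml2::xml_add_child(re, "group_list")
    for (gi in seq_along(arm_titles)) {
      g <- xml2::xml_add_child(glist, "group", group_id = paste0("E", gi))
      xml_add_text_child(g, "title", arm_titles[gi])
    }
    add_block <- function(tag, evs) {
      if (length(evs) == 0) {
        return(invisible(NULL))
      }
      block <- xml2::xml_add_child(re, tag)
      clist <- xml2::xml_add_child(block, "category_list")
      for (cat in unique(vapply(evs, `[[`, character(1), "category"))) {
        cnode <- xml2::xml_add_child(clist, "category")
        xml_add_text_child(cnode, "title", cat)
        elist <- xml2::xml_add_child(cnode, "event_list")
        for (ev in evs[vapply(evs, function(e) e$category == cat, logical(1))]) {
          enode <- xml2::xml_add_child(elist, "event")
          xml_add_text_child(enode, "sub_title", ev$event_title)
          gid <- paste0("E", match(ev$arm_title, arm_titles))
          # counts written as attributes or as child elements, alternating
          # on the affected parity, to cover both registry dialects
          if (ev$affected %% 2 == 0) {
            xml2::xml_add_child(enode, "counts",
              group_id = gid,
              subjects_affected = as.character(ev$affected),
              subjects_at_risk = as.character(ev$at_risk)
            )
          } else {
            ct <- xml2::xml_add_child(enode, "counts")
            xml_add_text_child(ct, "group_id", gid)
            xml_add_text_child(ct, "subjects_affected", ev$affected)
            xml_add_text_child(ct, "subjects_at_risk", ev$at_risk)
          }
        }
      }
      invisible(NULL)
    }
    serious <- all_events[vapply(all_events, function(e) e$severity == "serious", logical(1))]
    other <- all_events[vapply(all_events, function(e) e$severity == "other", logical(1))]
    add_block("serious_events", serious)
    add_block("other_events", other)
  }
  as.character(doc)
}

#' Generate a seeded corpus of synthetic registry XML trials
#'
#' Writes `n_trials` XML files (named by NCT id) plus a `manifest.jsonl`
#' ground-truth file to `out_dir`. The corpus is a pure function of
#' `(config, config$seed)`; trial `i` depends only on the seed and its
#' index, so corpora are extensible without reshuffling earlier trials.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created; must not already contain a
#'   conflicting corpus).
#' @return Invisibly, a list with `dir`, `files`, and `manifest` (the list
#'   of per-trial fragments; see [manifest_tables()]).
#' @export
generate_corpus <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- vector("list", config$n_trials)
  files <- character(config$n_trials)
  manifest_path <- file.path(out_dir, "manifest.jsonl")
  con <- file(manifest_path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(config$n_trials)) {
    tr <- generate_trial(config, config$seed, i)
    files[i] <- file.path(out_dir, paste0(tr$manifest$nct_id, ".xml"))
    writeLines(tr$xml, files[i], useBytes = TRUE)
    manifest[[i]] <- tr$manifest
    writeLines(jsonlite::toJSON(tr$manifest, auto_unbox = TRUE, digits = NA, null = "null"), con)
  }
  invisible(list(dir = out_dir, files = files, manifest = manifest))
}

#' Read a corpus ground-truth manifest back from disk
#'
#' @param path Path to a `manifest.jsonl` written by [generate_corpus()].
#' @return List of per-trial manifest fragments.
#' @export
read_manifest <- function(path) {
  lapply(readLines(path, encoding = "UTF-8"), function(l) {
    jsonlite::fromJSON(l, simplifyVector = FALSE)
  })
}

#' Flatten a corpus manifest into analysis-ready truth tables
#'
#' @param manifest List of per-trial fragments (from [generate_corpus()]
#'   or [read_manifest()]).
#' @return List of tibbles: `trials` (nct_id, design_valid, counts),
#'   `rows` (per-analysis intended labels and arm assignments),
#'   `outcomes` (intended label sets) and `events` (planted safety
#'   records with expected matches).
#' @export
manifest_tables <- function(manifest) {
  trials <- dplyr::bind_rows(lapply(manifest, function(m) {
    tibble::tibble(
      nct_id = m$nct_id,
      design_valid = isTRUE(m$design_valid),
      intervention_types = list(unlist(m$intervention_types)),
      conditions = list(unlist(m$conditions)),
      n_arms = m$counts$n_arms,
      n_outcomes = m$counts$n_outcomes,
      n_analyses = m$counts$n_analyses,
      n_event_elements = m$counts$n_event_elements
    )
  }))
  rows <- dplyr::bind_rows(lapply(manifest, function(m) {
    dplyr::bind_rows(lapply(m$rows, function(r) {
      tibble::tibble(
        nct_id = r$nct_id,
        outcome_title = r$outcome_title,
        outcome_rank = r$outcome_rank,
        group_titles = list(unlist(r$group_titles)),
        excluded = isTRUE(r$excluded),
        label = r$label %||% NA_character_,
        basis = r$basis %||% NA_character_,
        intervention_group_truth = r$intervention_group_truth %||% NA_character_,
        comparator_group_truth = r$comparator_group_truth %||% NA_character_,
        design_valid = isTRUE(r$design_valid)
      )
    }))
  }))
  outcomes <- dplyr::bind_rows(lapply(manifest, function(m) {
    dplyr::bind_rows(lapply(m$outcomes, function(o) {
      tibble::tibble(
        nct_id = m$nct_id, outcome_title = o$title, outcome_rank = o$rank,
        labels = list(as.character(unlist(o$labels)))
      )
    }))
  }))
  events <- dplyr::bind_rows(lapply(manifest, function(m) {
    dplyr::bind_rows(lapply(m$events, function(e) {
      tibble::tibble(
        nct_id = m$nct_id, arm_title = e$arm_title, event_title = e$event_title,
        category = e$category, severity = e$severity,
        affected = e$affected, at_risk = e$at_risk,
        expected_matched_group = e$expected_matched_group,
        expected_match_method = e$expected_match_method,
        counted_in_kg = isTRUE(e$counted_in_kg)
      )
    }))
  }))
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(
      nct_id = character(0), outcome_title = character(0), outcome_rank = character(0),
      group_titles = list(), excluded = logical(0), label = character(0),
      basis = character(0), intervention_group_truth = character(0),
      comparator_group_truth = character(0), design_valid = logical(0)
    )
  }
  list(trials = trials, rows = rows, outcomes = outcomes, events = events)
}
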