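#' Read one legacy registry XML document into a trial record
#'
#' Parses the classic ClinicalTrials.gov per-study XML dialect (the
#' "AllPublicXML" layout, one file per NCT identifier) into a normalized
#' trial record: design arms with experimental/comparator roles, outcome
#' measures with their statistical-analysis blocks, and reported
#' (adverse-event) records. Sections absent from the document yield empty
#' tables, never an error, so design-only registrations parse cleanly.
#'
#' Arm roles are derived only from the design-section arm-type string:
#' "Experimental" (case-insensitive) maps to \code{experimental}, any type
#' containing "comparator" (covers "Placebo Comparator", "Active Comparator")
#' maps to \code{comparator}, anything else to \code{other}. All titles are
#' whitespace-normalized at parse time; the verbatim strings are retained in
#' \code{*_raw} columns for provenance.
#'
#' @param source Path to an XML file, an XML string, or an `xml_document`.
#' @return A `trial_record`: a list with elements `nct_id`, `conditions`,
#'   `intervention_types`, `design_arms` (tibble: title, role, description,
#'   title_raw), `outcomes` (tibble: title, rank, analyses list-column of
#'   per-analysis tibbles) and `events` (tibble: arm_title, event_title,
#'   category, severity, affected, at_risk).
#' @export
read_trial_xml <- function(source) {
  doc <- tryCatch(
    {
      if (inherits(source, "xml_document")) source else xml2::read_xml(source, encoding = "UTF-8")
    },
    error = function(e) {
      rlang::abort(
        paste0("Malformed XML", if (is.character(source) && file.exists(source)) paste0(" in '", source, "'"), ": ", conditionMessage(e)),
        class = "ctarmkg_parse_error"
      )
    }
  )
  root <- xml2::xml_root(doc)

  nct_id <- xml_text1(root, ".//id_info/nct_id")
  if (is.na(nct_id) || !grepl("^NCT\\d{8}$", normalize_ws(nct_id))) {
    rlang::abort("Record rejected: missing or invalid <nct_id> element.",
      class = "ctarmkg_missing_id"
    )
  }
  nct_id <- normalize_ws(nct_id)

  conditions <- normalize_ws(xml2::xml_text(xml2::xml_find_all(root, "./condition")))
  conditions <- conditions[nzchar(conditions)]

  intervention_types <- normalize_ws(
    xml2::xml_text(xml2::xml_find_all(root, "./intervention/intervention_type"))
  )
  intervention_types <- unique(intervention_types[nzchar(intervention_types)])

  arms <- xml2::xml_find_all(root, "./arm_group")
  design_arms <- tibble::tibble(
    title_raw = vapply(arms, function(a) xml_text1(a, "./arm_group_label"), character(1)),
    title = normalize_ws(title_raw),
    role = arm_role(vapply(arms, function(a) xml_text1(a, "./arm_group_type"), character(1))),
    description = normalize_ws(vapply(arms, function(a) xml_text1(a, "./description"), character(1)))
  )[, c("title", "role", "description", "title_raw")]
  design_arms <- design_arms[!is.na(design_arms$title) & nzchar(design_arms$title), ]

  outcomes <- parse_outcomes(root)
  events <- parse_reported_events(root)

  structure(
    list(
      nct_id = nct_id,
      conditions = conditions,
      intervention_types = intervention_types,
      design_arms = design_arms,
      outcomes = outcomes,
      events = events
    ),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  n_analyses <- sum(vapply(x$outcomes$analyses, nrow, integer(1)))
  cat(
    sprintf(
      "<trial_record %s: %d arm(s), %d outcome(s), %d analysis block(s), %d event(s)>\n",
      x$nct_id, nrow(x$design_arms), nrow(x$outcomes), n_analyses, nrow(x$events)
    )
  )
  invisible(x)
}

xml_text1 <- function(node, xpath) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) NA_character_ else xml2::xml_text(hit)
}

arm_role <- function(type_string) {
  type <- normalize_title(type_string)
  dplyr::case_when(
    is.na(type) | !nzchar(type) ~ "other",
    type == "experimental" ~ "experimental",
    grepl("comparator", type, fixed = TRUE) ~ "comparator",
    TRUE ~ "other"
  )
}

empty_analyses <- function() {
  tibble::tibble(
    group_titles = list(),
    p_value_raw = character(0),
    method = character(0),
    param_name_raw = character(0),
    param_value = numeric(0),
    ci_percent = numeric(0),
    ci_lower_raw = character(0),
    ci_upper_raw = character(0),
    non_inferiority = character(0)
  )
}

parse_outcomes <- function(root) {
  nodes <- xml2::xml_find_all(root, ".//clinical_results/outcome_list/outcome")
  if (length(nodes) == 0) {
    return(tibble::tibble(title = character(0), rank = character(0), analyses = list()))
  }
  rows <- lapply(nodes, function(oc) {
    rank <- normalize_title(xml_text1(oc, "./type"))
    rank <- if (isTRUE(rank %in% c("primary", "secondary"))) rank else "other"
    groups <- xml2::xml_find_all(oc, "./group_list/group")
    group_map <- setNames(
      normalize_ws(vapply(groups, function(g) xml_text1(g, "./title"), character(1))),
      vapply(groups, function(g) xml2::xml_attr(g, "group_id") %||% NA_character_, character(1))
    )
    analyses <- xml2::xml_find_all(oc, "./analysis_list/analysis")
    atab <- if (length(analyses) == 0) {
      empty_analyses()
    } else {
      tibble::tibble(
        group_titles = lapply(analyses, function(an) {
          ids <- normalize_ws(xml2::xml_text(xml2::xml_find_all(an, "./group_id_list/group_id")))
          titles <- unname(group_map[ids])
          # unmapped ids fall back to the literal reference string
          ifelse(is.na(titles), ids, titles)
        }),
        p_value_raw = vapply(analyses, function(an) xml_text1(an, "./p_value"), character(1)),
        method = normalize_ws(vapply(analyses, function(an) xml_text1(an, "./method"), character(1))),
        param_name_raw = vapply(analyses, function(an) xml_text1(an, "./param_type"), character(1)),
        param_value = coerce_number(vapply(analyses, function(an) xml_text1(an, "./param_value"), character(1))),
        ci_percent = coerce_number(vapply(analyses, function(an) xml_text1(an, "./ci_percent"), character(1))),
        ci_lower_raw = vapply(analyses, function(an) xml_text1(an, "./ci_lower_limit"), character(1)),
        ci_upper_raw = vapply(analyses, function(an) xml_text1(an, "./ci_upper_limit"), character(1)),
        non_inferiority = normalize_ws(vapply(analyses, function(an) xml_text1(an, "./non_inferiority_type"), character(1)))
      )
    }
    tibble::tibble(title = normalize_ws(xml_text1(oc, "./title")), rank = rank, analyses = list(atab))
  })
  dplyr::bind_rows(rows)
}

parse_reported_events <- function(root) {
  re <- xml2::xml_find_first(root, ".//clinical_results/reported_events")
  empty <- tibble::tibble(
    arm_title = character(0), event_title = character(0), category = character(0),
    severity = character(0), affected = integer(0), at_risk = integer(0)
  )
  if (inherits(re, "xml_missing")) {
    return(empty)
  }
  groups <- xml2::xml_find_all(re, "./group_list/group")
  group_map <- setNames(
    normalize_ws(vapply(groups, function(g) xml_text1(g, "./title"), character(1))),
    vapply(groups, function(g) xml2::xml_attr(g, "group_id") %||% NA_character_, character(1))
  )
  parse_block <- function(block_xpath, severity) {
    cats <- xml2::xml_find_all(re, paste0("./", block_xpath, "/category_list/category"))
    rows <- lapply(cats, function(cat) {
      cat_title <- normalize_ws(xml_text1(cat, "./title"))
      events <- xml2::xml_find_all(cat, "./event_list/event")
      out <- lapply(events, function(ev) {
        counts <- xml2::xml_find_all(ev, "./counts")
        sub_title <- normalize_ws(xml_text1(ev, "./sub_title"))
        if (length(counts) == 0) {
          return(NULL)
        }
        tibble::tibble(
          arm_title = vapply(counts, function(ct) {
            gid <- xml2::xml_attr(ct, "group_id")
            if (is.na(gid)) gid <- xml_text1(ct, "./group_id")
            if (is.na(gid)) NA_character_ else unname(group_map[normalize_ws(gid)])
          }, character(1)),
          event_title = sub_title,
          category = cat_title,
          severity = severity,
          affected = count_field(counts, "subjects_affected"),
          at_risk = count_field(counts, "subjects_at_risk")
        )
      })
      dplyr::bind_rows(out)
    })
    dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(
    parse_block("serious_events", "serious"),
    parse_block("other_events", "other")
  )
  if (nrow(out) == 0) empty else out
}

# Count elements appear either as attributes or as child elements across
# registry versions; accept both.
count_field <- function(count_nodes, field) {
  vapply(count_nodes, function(ct) {
    val <- xml2::xml_attr(ct, field)
    if (is.na(val)) val <- xml_text1(ct, paste0("./", field))
    n <- coerce_number(val)
    if (is.na(n)) NA_integer_ else as.integer(n)
  }, integer(1))
}

#' Scan a corpus directory or zip archive of registry XML files
#'
#' Reads every \code{*.xml} member under \code{root} (a directory or a zip
#' archive) in deterministic lexicographic member-name order, independent of
#' filesystem enumeration order. Unreadable or rejected members are skipped
#' with a warning; the skip count is attached as an attribute.
#'
#' @param root Directory or `.zip` archive containing per-trial XML files.
#' @return A list of `trial_record` objects (sorted by member name) with
#'   attribute `skipped` giving the number of unreadable members.
#' @export
scan_corpus <- function(root) {
  if (!file.exists(root)) {
    rlang::abort(paste0("Corpus root '", root, "' does not exist."))
  }
  cleanup <- NULL
  if (!dir.exists(root) && grepl("\\.zip$", root, ignore.case = TRUE)) {
    exdir <- tempfile("ctarmkg_corpus_")
    utils::unzip(root, exdir = exdir)
    root <- exdir
    cleanup <- function() unlink(exdir, recursive = TRUE)
  }
  on.exit(if (!is.null(cleanup)) cleanup(), add = TRUE)
  files <- list.files(root, pattern = "\\.xml$", recursive = TRUE, full.names = TRUE)
  files <- files[order(basename(files), method = "radix")]
  if (length(files) == 0) {
    rlang::warn("Corpus is empty: no *.xml members found.")
  }
  skipped <- 0L
  records <- list()
  for (f in files) {
    rec <- tryCatch(read_trial_xml(f), error = function(e) {
      rlang::warn(paste0("Skipping unreadable member '", basename(f), "': ", conditionMessage(e)))
      NULL
    })
    if (is.null(rec)) {
      skipped <- skipped + 1L
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  attr(records, "skipped") <- skipped
  records
}

#' Flatten a trial record into raw efficacy rows
#'
#' Emits one row per statistical-analysis block, carrying the trial
#' identifier, the compared group titles, the outcome title and rank, and all
#' raw statistics fields. Analyses comparing anything other than exactly two
#' groups are kept but flagged \code{excluded = TRUE}; downstream
#' classification and graph construction drop them, since only one-to-one
#' intervention-versus-comparator comparisons are representable.
#'
#' @param trial A `trial_record`.
#' @return A tibble of raw efficacy rows (possibly zero rows) with columns
#'   `nct_id`, `conditions` (list), `intervention_types` (list),
#'   `outcome_title`, `outcome_rank`, `group_titles` (list), `n_groups`,
#'   `excluded`, and the raw statistics fields of each analysis block.
#' @export
to_efficacy_rows <- function(trial) {
  stopifnot(inherits(trial, "trial_record"))
  empty <- tibble::tibble(
    nct_id = character(0), conditions = list(), intervention_types = list(),
    outcome_title = character(0), outcome_rank = character(0),
    group_titles = list(), n_groups = integer(0), excluded = logical(0),
    p_value_raw = character(0), method = character(0), param_name_raw = character(0),
    param_value = numeric(0), ci_percent = numeric(0),
    ci_lower_raw = character(0), ci_upper_raw = character(0), non_inferiority = character(0)
  )
  if (nrow(trial$outcomes) == 0) {
    return(empty)
  }
  per_outcome <- lapply(seq_len(nrow(trial$outcomes)), function(i) {
    atab <- trial$outcomes$analyses[[i]]
    if (nrow(atab) == 0) {
      return(NULL)
    }
    tibble::tibble(
      nct_id = trial$nct_id,
      conditions = rep(list(trial$conditions), nrow(atab)),
      intervention_types = rep(list(trial$intervention_types), nrow(atab)),
      outcome_title = trial$outcomes$title[i],
      outcome_rank = trial$outcomes$rank[i],
      group_titles = atab$group_titles,
      n_groups = vapply(atab$group_titles, length, integer(1)),
      excluded = vapply(atab$group_titles, length, integer(1)) != 2L,
      p_value_raw = atab$p_value_raw,
      method = atab$method,
      param_name_raw = atab$param_name_raw,
      param_value = atab$param_value,
      ci_percent = atab$ci_percent,
      ci_lower_raw = atab$ci_lower_raw,
      ci_upper_raw = atab$ci_upper_raw,
      non_inferiority = atab$non_inferiority
    )
  })
  out <- dplyr::bind_rows(per_outcome)
  if (nrow(out) == 0) empty else out
}

#' Write (and read back) flat record tables
#'
#' Writes any record tibble to disk as CSV or JSONL with a fixed column
#' order (the order of the input tibble). List-columns are serialized as
#' compact JSON arrays so that `read_records()` reproduces the table
#' field-for-field; a write-read-write cycle is byte-stable.
#'
#' @param rows A tibble whose rows share a schema.
#' @param path Output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_records <- function(rows, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  if (format == "csv") {
    flat <- rows
    for (col in names(flat)) {
      if (is.list(flat[[col]])) flat[[col]] <- pack_list_col(flat[[col]])
    }
    readr::write_csv(flat, path, na = "", progress = FALSE)
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    if (nrow(rows) > 0) {
      for (i in seq_len(nrow(rows))) {
        writeLines(jsonlite::toJSON(as.list(rows[i, ]), auto_unbox = TRUE, na = "null", digits = NA), con)
      }
    }
  }
  invisible(path)
}

#' @rdname write_records
#' @param list_cols For CSV input, names of columns to restore as
#'   list-columns (those packed as JSON arrays on write).
#' @export
read_records <- function(path, format = c("csv", "jsonl"), list_cols = character(0)) {
  format <- match.arg(format)
  if (format == "csv") {
    out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE, na = "")
    for (col in intersect(list_cols, names(out))) {
      out[[col]] <- unpack_list_col(out[[col]])
    }
    out
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    rows <- lapply(lines, function(l) {
      x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
      x <- lapply(x, function(v) if (length(v) != 1 || is.list(v)) list(unlist(v)) else v)
      tibble::as_tibble(x)
    })
    dplyr::bind_rows(rows)
  }
}
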