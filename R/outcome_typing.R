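PRO_KEYWORDS <- c(
  "survey", "questionnaire", "patient reported", "patient-reported",
  "scale", "score"
)

the_cache <- new.env(parent = emptyenv())

#' Toy MeSH dictionary shipped with the package
#'
#' A small plain-text subset of the Medical Subject Headings vocabulary
#' (term, tree number, preferred name) covering the branches the outcome
#' and condition rules key on: D (Chemicals and Drugs) and E (Analytical,
#' Diagnostic and Therapeutic Techniques) for biomarkers, C (Diseases) and
#' F03 (Mental Disorders) for clinical endpoints, including the
#' E05.318.308.980 "Surveys and Questionnaires" branch that the biomarker
#' rule must exclude. It backs the default offline extractor; it is not a
#' licensed full MeSH distribution.
#'
#' @return Tibble with columns `term` (lowercased match string),
#'   `tree_number`, `name`.
#' @export
mesh_toy_dictionary <- function() {
  if (is.null(the_cache$dict)) {
    path <- system.file("extdata", "mesh_toy_dictionary.tsv", package = "ctarmkg")
    the_cache$dict <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  the_cache$dict
}

mesh_disease_categories <- function() {
  if (is.null(the_cache$categories)) {
    path <- system.file("extdata", "mesh_disease_categories.tsv", package = "ctarmkg")
    the_cache$categories <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  the_cache$categories
}

#' Offline dictionary-based MeSH extractor
#'
#' The extractor contract maps free text to a list of MeSH terms (tree
#' number + name), deterministically for a fixed extractor version. This
#' default implementation matches dictionary terms as case-insensitive,
#' word-bounded substrings of the input, so corpus runs need no network. A
#' client for a full-text indexing service (such as NLM's Medical Text
#' Indexer) can be supplied anywhere an extractor is accepted: any list
#' with `name`, `version`, and `extract(text) -> tibble(tree_number, name)`
#' satisfies the contract.
#'
#' @param dictionary A dictionary tibble (default [mesh_toy_dictionary()]).
#' @return An extractor: list with `name`, `version`, `extract`.
#' @export
dictionary_extractor <- function(dictionary = mesh_toy_dictionary()) {
  # longest terms first so multi-word entries are found before their parts
  dict <- dictionary[order(-nchar(dictionary$term)), ]
  patterns <- paste0("(?<![a-z0-9])", stringr::str_escape(dict$term), "(?![a-z0-9])")
  list(
    name = "dictionary",
    version = "1.0",
    extract = function(text) {
      empty <- tibble::tibble(tree_number = character(0), name = character(0))
      if (length(text) != 1 || is.na(text) || !nzchar(normalize_ws(text))) {
        return(empty)
      }
      s <- normalize_title(text)
      hit <- vapply(patterns, function(p) grepl(p, s, perl = TRUE), logical(1))
      if (!any(hit)) {
        return(empty)
      }
      dplyr::distinct(tibble::tibble(
        tree_number = dict$tree_number[hit],
        name = dict$name[hit]
      ))
    }
  )
}

# Dotted-component prefix test: "F03" matches "F03.600" but never "F030";
# a bare root letter ("C", "D", "E") matches any tree in that branch.
tree_has_prefix <- function(tree_numbers, prefix) {
  if (length(tree_numbers) == 0) {
    return(logical(0))
  }
  if (grepl("^[A-Z]$", prefix)) {
    return(grepl(paste0("^", prefix, "[0-9]"), tree_numbers))
  }
  pre_parts <- strsplit(prefix, ".", fixed = TRUE)[[1]]
  vapply(strsplit(tree_numbers, ".", fixed = TRUE), function(parts) {
    length(parts) >= length(pre_parts) && all(parts[seq_along(pre_parts)] == pre_parts)
  }, logical(1))
}

as_tree_numbers <- function(terms) {
  if (is.data.frame(terms)) terms$tree_number else as.character(terms)
}

#' Outcome typing rules: biomarker, patient-reported, clinical endpoint
#'
#' Three independent predicates classify an outcome from its extracted
#' MeSH terms and its title:
#' \describe{
#'   \item{biomarker}{any MeSH tree number in root D (Chemicals and Drugs)
#'     or E (Analytical, Diagnostic and Therapeutic Techniques), excluding
#'     terms under E05.318.308.980 (Surveys and Questionnaires), which is
#'     patient-reported territory.}
#'   \item{PRO}{any of the keywords "Survey", "Questionnaire",
#'     "Patient Reported", "Patient-Reported", "Scale", "Score" matched
#'     case-insensitively in the outcome title or in any extracted MeSH
#'     name.}
#'   \item{clinical endpoint}{any MeSH tree number in root C (Diseases) or
#'     under F03 (Mental Disorders).}
#' }
#'
#' @param terms MeSH terms: a tibble with `tree_number` (and `name`), or a
#'   character vector of tree numbers.
#' @param outcome_title Outcome title text.
#' @param mesh_names Character vector of extracted MeSH preferred names.
#' @return A logical flag.
#' @name outcome_rules
NULL

#' @rdname outcome_rules
#' @export
label_biomarker <- function(terms) {
  trees <- as_tree_numbers(terms)
  eligible <- (tree_has_prefix(trees, "D") | tree_has_prefix(trees, "E")) &
    !tree_has_prefix(trees, "E05.318.308.980")
  any(eligible)
}

#' @rdname outcome_rules
#' @export
label_pro <- function(outcome_title, mesh_names = character(0)) {
  haystack <- stringr::str_to_lower(c(outcome_title, mesh_names))
  haystack <- haystack[!is.na(haystack)]
  any(vapply(
    PRO_KEYWORDS,
    function(k) any(grepl(k, haystack, fixed = TRUE)),
    logical(1)
  ))
}

#' @rdname outcome_rules
#' @export
label_clinical <- function(terms) {
  trees <- as_tree_numbers(terms)
  any(tree_has_prefix(trees, "C") | tree_has_prefix(trees, "F03"))
}

#' Classify one outcome title
#'
#' Runs the extractor on the title and applies the three typing rules (see
#' [label_biomarker()]). Labels are a set: an outcome may be both a
#' biomarker and patient-reported, or carry no label at all. If the
#' extractor fails, the PRO keyword rule is still applied to the bare
#' title and the failure is logged as a warning.
#'
#' @param title Outcome title.
#' @param extractor A MeSH extractor (default [dictionary_extractor()]).
#' @return A list with `outcome_title`, `mesh_terms` (tibble), `labels`
#'   (character subset of `c("biomarker", "PRO", "clinical_endpoint")`),
#'   `pro_source` (`"title"`, `"mesh"`, `"both"` or `NA`), and
#'   `extractor_version`.
#' @export
classify_outcome <- function(title, extractor = dictionary_extractor()) {
  terms <- tryCatch(extractor$extract(title), error = function(e) {
    rlang::warn(paste0("MeSH extractor failed on '", title, "': ", conditionMessage(e)))
    tibble::tibble(tree_number = character(0), name = character(0))
  })
  pro_title <- label_pro(title, character(0))
  pro_mesh <- length(terms$name) > 0 && label_pro(NA_character_, terms$name)
  labels <- c(
    if (label_biomarker(terms)) "biomarker",
    if (pro_title || pro_mesh) "PRO",
    if (label_clinical(terms)) "clinical_endpoint"
  )
  list(
    outcome_title = title,
    mesh_terms = terms,
    labels = labels %||% character(0),
    pro_source = if (pro_title && pro_mesh) "both" else if (pro_title) "title" else if (pro_mesh) "mesh" else NA_character_,
    extractor_version = paste0(extractor$name, "/", extractor$version)
  )
}

#' Classify many outcome titles into a flat label table
#'
#' @param titles Character vector of outcome titles (deduplicated
#'   internally; the returned table has one row per unique title).
#' @inheritParams classify_outcome
#' @return Tibble with `outcome_title`, `mesh_trees` and `mesh_names`
#'   (list-columns), logical flags `biomarker`, `pro`, `clinical_endpoint`,
#'   `labels` (list-column), and `pro_source`.
#' @export
classify_outcomes <- function(titles, extractor = dictionary_extractor()) {
  titles <- unique(titles[!is.na(titles)])
  rows <- lapply(titles, function(t) {
    res <- classify_outcome(t, extractor)
    tibble::tibble(
      outcome_title = t,
      mesh_trees = list(res$mesh_terms$tree_number),
      mesh_names = list(res$mesh_terms$name),
      biomarker = "biomarker" %in% res$labels,
      pro = "PRO" %in% res$labels,
      clinical_endpoint = "clinical_endpoint" %in% res$labels,
      labels = list(res$labels),
      pro_source = res$pro_source
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      outcome_title = character(0), mesh_trees = list(), mesh_names = list(),
      biomarker = logical(0), pro = logical(0), clinical_endpoint = logical(0),
      labels = list(), pro_source = character(0)
    )
  }
  out
}

#' Map a condition string to top-level MeSH disease categories
#'
#' Extracts disease terms (root C, or F03 for mental disorders) from the
#' condition text and returns the distinct first-level branch names, in
#' the order encountered (e.g. "rheumatoid arthritis" sits under
#' Musculoskeletal Diseases via C05).
#'
#' @param condition Condition free text.
#' @inheritParams classify_outcome
#' @return Character vector of category names (possibly empty).
#' @export
map_condition_category <- function(condition, extractor = dictionary_extractor()) {
  terms <- extractor$extract(condition)
  trees <- terms$tree_number
  disease <- trees[tree_has_prefix(trees, "C") | tree_has_prefix(trees, "F03")]
  if (length(disease) == 0) {
    return(character(0))
  }
  prefixes <- unique(vapply(
    strsplit(disease, ".", fixed = TRUE),
    function(p) if (p[1] == "F03" || grepl("^F03", p[1])) "F03" else p[1],
    character(1)
  ))
  cats <- mesh_disease_categories()
  names_out <- cats$name[match(prefixes, cats$prefix)]
  names_out[!is.na(names_out)]
}

#' Coverage of outcome typing over a label table
#'
#' Fraction of outcomes that received at least one label, overall and per
#' outcome rank when a rank column is supplied.
#'
#' @param label_table Output of [classify_outcomes()].
#' @return Fraction in \[0, 1\].
#' @export
labelled_fraction <- function(label_table) {
  if (nrow(label_table) == 0) {
    return(NA_real_)
  }
  mean(vapply(label_table$labels, length, integer(1)) > 0)
}
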