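#' Parse a reported p-value string
#'
#' Registry p-value fields are free text: blanks, an optional leading
#' relational operator (`<`, `<=`, the Unicode less-than-or-equal sign, `=`,
#' `>`, `>=`, the Unicode greater-than-or-equal sign), plain decimals, and
#' scientific notation all occur. Blanks are removed, the operator is
#' normalized (defaulting to equality when absent), and the remainder is
#' coerced to a number. Failure is a value (`NULL`), not an exception, so
#' the significance cascade can fall through to the confidence-interval
#' branch.
#'
#' @param raw A single p-value string (or `NA`).
#' @return A list with elements `op` (one of `"lt"`, `"le"`, `"eq"`, `"ge"`,
#'   `"gt"`) and `value` (a number in \[0, 1\]), or `NULL` if the string does
#'   not parse.
#' @examples
#' parse_p_value("<0.0001") # op "lt", value 1e-04
#' parse_p_value("0.0757") # op "eq"
#' parse_p_value("NA") # NULL
#' @export
parse_p_value <- function(raw) {
  if (length(raw) != 1 || is.na(raw)) {
    return(NULL)
  }
  s <- gsub("[[:space:]]", "", raw)
  if (!nzchar(s)) {
    return(NULL)
  }
  op <- "eq"
  if (startsWith(s, "<=") || startsWith(s, "≤")) {
    op <- "le"
    s <- sub("^(<=|≤)", "", s)
  } else if (startsWith(s, ">=") || startsWith(s, "≥")) {
    op <- "ge"
    s <- sub("^(>=|≥)", "", s)
  } else if (startsWith(s, "<")) {
    op <- "lt"
    s <- substring(s, 2)
  } else if (startsWith(s, ">")) {
    op <- "gt"
    s <- substring(s, 2)
  } else if (startsWith(s, "=")) {
    op <- "eq"
    s <- substring(s, 2)
  }
  value <- suppressWarnings(as.numeric(s))
  if (is.na(value) || value < 0 || value > 1) {
    return(NULL)
  }
  list(op = op, value = value)
}

RATIO_KEYWORDS <- c(
  "odds ratio", "hazard ratio", "risk ratio", "relative risk", "rate ratio",
  "ratio"
)
DIFFERENCE_KEYWORDS <- c(
  "mean difference", "risk difference", "difference", "slope", "change"
)

#' Classify a statistical-parameter name as ratio- or difference-type
#'
#' Effect measures split by their null value: ratio-type parameters (odds
#' ratio, hazard ratio, risk ratio, relative risk, rate ratio) have null 1;
#' difference-type parameters (mean difference, risk difference, slope,
#' change) have null 0. The classification is a case-insensitive keyword
#' match on the parameter-name string; anything else is `"unknown"` and the
#' confidence-interval rule cannot be applied to it.
#'
#' @param param_name Free-text parameter name (or `NA`).
#' @return `"ratio"`, `"difference"`, or `"unknown"`.
#' @export
classify_param_kind <- function(param_name) {
  if (length(param_name) != 1 || is.na(param_name) || !nzchar(normalize_ws(param_name))) {
    return("unknown")
  }
  name <- normalize_title(param_name)
  if (any(vapply(RATIO_KEYWORDS, grepl, logical(1), x = name, fixed = TRUE))) {
    return("ratio")
  }
  if (any(vapply(DIFFERENCE_KEYWORDS, grepl, logical(1), x = name, fixed = TRUE))) {
    return("difference")
  }
  "unknown"
}

#' Classify one efficacy result as statistically positive or negative
#'
#' Implements the fixed rule cascade used throughout the pipeline:
#' \enumerate{
#'   \item If the p-value parses, the result is \emph{positive} when the
#'     stated relation guarantees p is at most 0.05 (`eq`/`le`/`lt` with
#'     value at most 0.05) and \emph{negative} when it guarantees p exceeds
#'     0.05 (`eq` with value above 0.05, or `ge`/`gt` with value at least
#'     0.05). Bounds that decide neither way (e.g. "<0.1") are
#'     \emph{indeterminate} rather than guessed.
#'   \item Otherwise, with a confidence interval and a ratio-type parameter:
#'     \emph{negative} iff 1 lies in the closed interval
#'     \[lower, upper\], else \emph{positive}.
#'   \item Otherwise, with a confidence interval and a difference-type
#'     parameter: \emph{negative} iff 0 lies in the closed interval, else
#'     \emph{positive}.
#'   \item Otherwise \emph{indeterminate}.
#' }
#' When the p-value decides, the interval never influences the label.
#'
#' @param p Parsed p-value (list from [parse_p_value()]) or `NULL`.
#' @param ci Confidence interval: list/vector with `lower` and `upper`
#'   (finite, lower <= upper), or `NULL`.
#' @param kind Parameter kind from [classify_param_kind()].
#' @return A list with `label` (`"positive"`, `"negative"`,
#'   `"indeterminate"`) and `basis` (`"p_value"`, `"ci_ratio"`,
#'   `"ci_difference"`, `"none"`). `label` is indeterminate iff `basis` is
#'   `"none"`.
#' @export
classify_significance <- function(p = NULL, ci = NULL, kind = "unknown") {
  if (!is.null(p)) {
    if (p$op %in% c("eq", "le", "lt") && p$value <= 0.05) {
      return(list(label = "positive", basis = "p_value"))
    }
    if ((p$op == "eq" && p$value > 0.05) || (p$op %in% c("ge", "gt") && p$value >= 0.05)) {
      return(list(label = "negative", basis = "p_value"))
    }
    return(list(label = "indeterminate", basis = "none"))
  }
  if (!is.null(ci)) {
    ci <- as.list(ci)
    lower <- ci$lower
    upper <- ci$upper
    ok <- is.finite(lower) && is.finite(upper) && lower <= upper
    if (ok && kind == "ratio") {
      contained <- lower <= 1 && 1 <= upper
      return(list(label = if (contained) "negative" else "positive", basis = "ci_ratio"))
    }
    if (ok && kind == "difference") {
      contained <- lower <= 0 && 0 <= upper
      return(list(label = if (contained) "negative" else "positive", basis = "ci_difference"))
    }
  }
  list(label = "indeterminate", basis = "none")
}

#' Classify a table of raw efficacy rows
#'
#' Applies [parse_p_value()], [classify_param_kind()] and
#' [classify_significance()] to every non-excluded row of a raw efficacy
#' table (see [to_efficacy_rows()]), attaching the parsed fields, the
#' significance label and the basis on which it was decided. Rows flagged
#' `excluded` (group count not equal to two) receive `NA` labels.
#'
#' @param rows Raw efficacy rows.
#' @return The input tibble with columns `p_op`, `p_value`, `param_kind`,
#'   `ci_lower`, `ci_upper`, `significance`, `basis` added. The branch
#'   counts of the classification funnel are available via
#'   [significance_funnel()].
#' @export
classify_rows <- function(rows) {
  stopifnot(is.data.frame(rows))
  n <- nrow(rows)
  out <- rows
  out$p_op <- rep(NA_character_, n)
  out$p_value <- rep(NA_real_, n)
  out$param_kind <- rep(NA_character_, n)
  out$ci_lower <- rep(NA_real_, n)
  out$ci_upper <- rep(NA_real_, n)
  out$significance <- rep(NA_character_, n)
  out$basis <- rep(NA_character_, n)
  if (n == 0) {
    return(out)
  }
  excluded <- if ("excluded" %in% names(rows)) rows$excluded else rep(FALSE, n)
  for (i in seq_len(n)) {
    if (isTRUE(excluded[i])) next
    p <- parse_p_value(rows$p_value_raw[i])
    kind <- classify_param_kind(rows$param_name_raw[i])
    lower <- coerce_number(rows$ci_lower_raw[i])
    upper <- coerce_number(rows$ci_upper_raw[i])
    ci <- if (is.finite(lower) && is.finite(upper) && lower <= upper) {
      list(lower = lower, upper = upper)
    } else {
      NULL
    }
    res <- classify_significance(p, ci, kind)
    if (!is.null(p)) {
      out$p_op[i] <- p$op
      out$p_value[i] <- p$value
    }
    out$param_kind[i] <- kind
    if (!is.null(ci)) {
      out$ci_lower[i] <- lower
      out$ci_upper[i] <- upper
    }
    out$significance[i] <- res$label
    out$basis[i] <- res$basis
  }
  out
}

#' Branch counts of the classification funnel
#'
#' Tallies how many classified rows were decided on each basis (p-value,
#' ratio-type interval, difference-type interval), how many remained
#' indeterminate, and how many analyses were excluded for not comparing
#' exactly two groups.
#'
#' @param classified Output of [classify_rows()].
#' @return A named integer vector with components `p_value`, `ci_ratio`,
#'   `ci_difference`, `indeterminate`, `excluded`, `positive`, `negative`.
#' @export
significance_funnel <- function(classified) {
  excluded <- if ("excluded" %in% names(classified)) classified$excluded else rep(FALSE, nrow(classified))
  kept <- classified[!excluded %in% TRUE, , drop = FALSE]
  c(
    p_value = sum(kept$basis == "p_value", na.rm = TRUE),
    ci_ratio = sum(kept$basis == "ci_ratio", na.rm = TRUE),
    ci_difference = sum(kept$basis == "ci_difference", na.rm = TRUE),
    indeterminate = sum(kept$basis == "none", na.rm = TRUE),
    excluded = sum(excluded %in% TRUE),
    positive = sum(kept$significance == "positive", na.rm = TRUE),
    negative = sum(kept$significance == "negative", na.rm = TRUE)
  )
}
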