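# The literal placeholder token used in template assets.
REPORT_PLACEHOLDER <- "<REPORT TEXT HERE>"

STRATEGY_KEYS <- c("standard-json", "cot-json", "standard", "cot")
STRATEGY_LABELS <- c(
  "standard-json" = "Standard—JSON",
  "cot-json" = "CoT—JSON",
  "standard" = "Standard",
  "cot" = "CoT"
)

#' Prompt strategy
#'
#' One of the four prompting strategies: reasoning style crossed with
#' output format.  Chain-of-thought (CoT) strategies frame the task as
#' document classification with sentence extraction as the intermediate
#' step; standard strategies request the AIF sentences only, with the
#' document label derived from whether any are returned.
#'
#' @param key one of `"standard-json"`, `"cot-json"`, `"standard"`,
#'   `"cot"`.
#' @return object of class `aif_strategy` with fields `key`, `label`,
#'   `reasoning` (`"standard"`/`"cot"`), `output_format`
#'   (`"json"`/`"free_text"`).
#' @export
prompt_strategy <- function(key = STRATEGY_KEYS) {
  key <- match.arg(key)
  structure(
    list(key = key,
         label = unname(STRATEGY_LABELS[key]),
         reasoning = if (grepl("^cot", key)) "cot" else "standard",
         output_format = if (grepl("json$", key)) "json" else "free_text"),
    class = "aif_strategy"
  )
}

as_strategy <- function(x) {
  if (inherits(x, "aif_strategy")) return(x)
  prompt_strategy(x)
}

#' Load a prompt template
#'
#' Template texts ship as editable assets under
#' `system.file("templates", package = "aifpipe")`, one file per strategy,
#' each containing the report placeholder `<REPORT TEXT HERE>` exactly
#' once.
#'
#' @param strategy an `aif_strategy` or strategy key.
#' @param path optional path to a custom template file (same placeholder
#'   contract).
#' @return object of class `aif_template` with fields `strategy`,
#'   `instruction_text`.
#' @export
prompt_template <- function(strategy, path = NULL) {
  strategy <- as_strategy(strategy)
  if (is.null(path)) {
    path <- system.file("templates", paste0(strategy$key, ".txt"),
                        package = "aifpipe", mustWork = TRUE)
  }
  instruction_text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                            collapse = "\n")
  new_prompt_template(strategy, instruction_text)
}

new_prompt_template <- function(strategy, instruction_text) {
  strategy <- as_strategy(strategy)
  hits <- gregexpr(REPORT_PLACEHOLDER, instruction_text, fixed = TRUE)[[1]]
  n_hits <- if (hits[1] == -1L) 0L else length(hits)
  if (n_hits != 1L) {
    stop("template must contain the placeholder '", REPORT_PLACEHOLDER,
         "' exactly once (found ", n_hits, ")", call. = FALSE)
  }
  structure(list(strategy = strategy, instruction_text = instruction_text),
            class = "aif_template")
}

#' Build the prompt for one report
#'
#' Replaces the placeholder with the report text verbatim -- no escaping
#' or other mutation, so the report text is always byte-contained in the
#' prompt.  Application of model-specific chat/instruction templates
#' (system/user roles, special tokens) is the generation backend's
#' responsibility.
#'
#' @param report an [aif_report()].
#' @param template an `aif_template`.
#' @return prompt string.
#' @export
build_prompt <- function(report, template) {
  parts <- strsplit(template$instruction_text, REPORT_PLACEHOLDER,
                    fixed = TRUE)[[1]]
  paste0(parts[1], report$text, if (length(parts) > 1L) parts[2] else "")
}

# Canonical answer rendering: deterministic JSON (fixed key order, no
# whitespace) or free text with a configurable negative marker.
render_answer <- function(strategy, positive, sentences,
                          negative_marker = "NONE") {
  strategy <- as_strategy(strategy)
  sentences <- as.character(sentences)
  if (strategy$output_format == "json") {
    arr <- as.character(jsonlite::toJSON(sentences))
    if (strategy$reasoning == "cot") {
      sprintf('{"actionable_findings_present":%s,"aif_sentences":%s}',
              if (positive) "true" else "false", arr)
    } else {
      sprintf('{"aif_sentences":%s}', arr)
    }
  } else {
    body <- if (length(sentences)) paste(sentences, collapse = "\n") else
      negative_marker
    if (strategy$reasoning == "cot") {
      paste0("Actionable findings present: ",
             if (positive) "yes" else "no", "\n", body)
    } else {
      body
    }
  }
}

#' Build one fine-tuning example
#'
#' The input is the prompt for the report; the target is the gold answer
#' rendered in the template's output format.  JSON targets use the
#' canonical serialisation (fixed key order and separators) so that
#' `render(parse(target))` is the identity.  Free-text targets newline-join
#' the gold sentences, with a configurable negative marker for AIF-free
#' reports; CoT free-text targets carry the document label on the first
#' line.
#'
#' @param report an [aif_report()].
#' @param gold the report's [aif_annotation()].
#' @param template an `aif_template`.
#' @param negative_marker marker emitted for negative free-text targets.
#' @return list with elements `input` and `target`.
#' @export
build_training_example <- function(report, gold, template,
                                   negative_marker = "NONE") {
  if (!identical(report$report_id, gold$report_id)) {
    stop("gold annotation does not belong to report ", report$report_id,
         call. = FALSE)
  }
  list(
    input = build_prompt(report, template),
    target = render_answer(template$strategy,
                           gold$doc_label == "positive",
                           gold$aif_sentences, negative_marker)
  )
}
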