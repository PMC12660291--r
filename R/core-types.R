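#' Construct a radiology report object
#'
#' A report carries its raw text, the deterministic sentence segmentation of
#' that text, and an optional map from section names to sentence index
#' ranges.  Sentence identity throughout the pipeline is by verbatim string;
#' character offsets are not tracked.
#'
#' @param report_id opaque identifier string.
#' @param text full report text.
#' @param sections optional named list of integer `c(start, end)` sentence
#'   index ranges (1-based, inclusive); ranges must be in-range, ordered and
#'   disjoint.
#' @return object of class `aif_report` with fields `report_id`, `text`,
#'   `sentences`, `sections`.
#' @export
#' @examples
#' r <- aif_report("r1", "Mild emphysema. Severe emphysema in both lungs.")
#' r$sentences
aif_report <- function(report_id, text, sections = NULL) {
  assert_string(report_id, "report_id")
  assert_string(text, "text")
  sentences <- segment_sentences(text)
  if (!is.null(sections)) {
    if (!is.list(sections) || is.null(names(sections)) ||
        any(!nzchar(names(sections)))) {
      stop("sections must be a named list of index ranges", call. = FALSE)
    }
    last_end <- 0L
    for (nm in names(sections)) {
      rg <- sections[[nm]]
      if (!is.numeric(rg) || length(rg) != 2L || any(is.na(rg)) ||
          rg[1] > rg[2] || rg[1] < 1 || rg[2] > length(sentences)) {
        stop("section '", nm, "' has an invalid sentence range",
             call. = FALSE)
      }
      if (rg[1] <= last_end) {
        stop("section ranges must be ordered and disjoint", call. = FALSE)
      }
      last_end <- rg[2]
      sections[[nm]] <- as.integer(rg)
    }
  }
  structure(
    list(report_id = report_id, text = text, sentences = sentences,
         sections = sections),
    class = "aif_report"
  )
}

#' @export
print.aif_report <- function(x, ...) {
  cat(sprintf("<aif_report %s: %d sentences, %d tokens>\n",
              x$report_id, length(x$sentences), count_tokens_ws(x$text)))
  invisible(x)
}

#' Construct a gold annotation
#'
#' Records the verbatim AIF sentences of a report.  The document label is
#' derived, never stored: positive if and only if at least one AIF sentence
#' is present.  When the report is supplied, every annotated sentence is
#' checked to occur verbatim in the report text.
#'
#' @param report_id identifier matching the annotated report.
#' @param aif_sentences character vector of verbatim AIF sentences.
#' @param report optional `aif_report` to validate grounding against.
#' @return object of class `aif_annotation` with fields `report_id`,
#'   `aif_sentences`, `doc_label` (`"positive"`/`"negative"`).
#' @export
aif_annotation <- function(report_id, aif_sentences = character(0),
                           report = NULL) {
  assert_string(report_id, "report_id")
  if (length(aif_sentences) && !is.character(aif_sentences)) {
    stop("aif_sentences must be a character vector", call. = FALSE)
  }
  aif_sentences <- unique(as.character(aif_sentences))
  if (!is.null(report)) {
    if (!identical(report$report_id, report_id)) {
      stop("annotation report_id does not match report", call. = FALSE)
    }
    missing <- aif_sentences[!vapply(aif_sentences, grepl, logical(1),
                                     x = report$text, fixed = TRUE)]
    if (length(missing)) {
      stop("annotated sentence not found verbatim in report ", report_id,
           ": ", missing[1], call. = FALSE)
    }
  }
  structure(
    list(report_id = report_id, aif_sentences = aif_sentences,
         doc_label = if (length(aif_sentences)) "positive" else "negative"),
    class = "aif_annotation"
  )
}

#' Construct a dataset of reports with gold annotations
#'
#' @param name dataset name.
#' @param reports list of [aif_report()] objects with unique ids.
#' @param annotations list of [aif_annotation()] objects; their ids must be
#'   a subset of the report ids, at most one per report.
#' @return object of class `aif_dataset` with fields `name`, `reports`
#'   (named by id), `annotations` (named by id).
#' @export
aif_dataset <- function(name, reports, annotations = list()) {
  assert_string(name, "name")
  ids <- vapply(reports, function(r) r$report_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate report_id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  names(reports) <- ids
  ann_ids <- vapply(annotations, function(a) a$report_id, character(1))
  if (anyDuplicated(ann_ids)) {
    stop("duplicate annotation for report_id: ",
         ann_ids[duplicated(ann_ids)][1], call. = FALSE)
  }
  if (length(ann_ids) && !all(ann_ids %in% ids)) {
    stop("annotation for unknown report_id: ",
         setdiff(ann_ids, ids)[1], call. = FALSE)
  }
  names(annotations) <- ann_ids
  structure(
    list(name = name, reports = reports, annotations = annotations),
    class = "aif_dataset"
  )
}

#' @export
print.aif_dataset <- function(x, ...) {
  n_pos <- sum(vapply(x$annotations,
                      function(a) a$doc_label == "positive", logical(1)))
  cat(sprintf("<aif_dataset '%s': %d reports, %d annotated (%d positive)>\n",
              x$name, length(x$reports), length(x$annotations), n_pos))
  invisible(x)
}

# Internal constructor for extraction results (generation module output).
new_extraction_result <- function(report_id, predicted_label,
                                  predicted_sentences, attempts,
                                  parse_status, raw_generations) {
  stopifnot(parse_status %in% c("ok", "recovered", "fatal_null"))
  if (parse_status == "fatal_null") {
    stopifnot(is.na(predicted_label), length(predicted_sentences) == 0L)
  }
  structure(
    list(report_id = report_id,
         predicted_label = predicted_label,
         predicted_sentences = as.character(predicted_sentences),
         attempts = as.integer(attempts),
         parse_status = parse_status,
         raw_generations = as.character(raw_generations)),
    class = "aif_extraction"
  )
}
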