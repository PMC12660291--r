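#' Read a dataset from a JSONL file
#'
#' One JSON object per line: `{"report_id": str, "text": str,
#' "aif_sentences": [str, ...]?, "sections": {name: [start, end]}?}`.
#' A line with an `aif_sentences` field (possibly empty) is treated as
#' annotated; the document label is derived from the sentence list, never
#' stored.
#'
#' @param path JSONL file path.
#' @param name dataset name (defaults to the file stem).
#' @return an [aif_dataset()].
#' @export
read_dataset <- function(path, name = NULL) {
  name <- name %||% tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  reports <- list()
  annotations <- list()
  seen <- character(0)
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) {
        stop(sprintf("malformed JSON on line %d of %s: %s", i, path,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    id <- chr_from_json(rec$report_id, "report_id", i)
    if (id %in% seen) {
      stop(sprintf("duplicate report_id '%s' on line %d of %s",
                   id, i, path), call. = FALSE)
    }
    seen <- c(seen, id)
    text <- chr_from_json(rec$text, "text", i)
    sections <- NULL
    if (!is.null(rec$sections)) {
      sections <- lapply(rec$sections, function(rg) {
        as.integer(unlist(rg, use.names = FALSE))
      })
    }
    rep <- aif_report(id, text, sections = sections)
    reports[[length(reports) + 1L]] <- rep
    if (!is.null(rec$aif_sentences)) {
      sents <- chr_from_json(rec$aif_sentences, "aif_sentences", i)
      annotations[[length(annotations) + 1L]] <-
        aif_annotation(id, sents, report = rep)
    }
  }
  aif_dataset(name, reports, annotations)
}

#' Write a dataset to a JSONL file
#'
#' Inverse of [read_dataset()]: annotated reports carry their
#' `aif_sentences` array inline (empty array for annotated negatives);
#' unannotated reports omit the field.  `write_dataset(read_dataset(f), f2)`
#' reproduces `f` byte-for-byte when `f` was written by this function.
#'
#' @param dataset an [aif_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  records <- lapply(dataset$reports, function(r) {
    rec <- list(report_id = r$report_id, text = r$text)
    ann <- dataset$annotations[[r$report_id]]
    if (!is.null(ann)) rec$aif_sentences <- I(ann$aif_sentences)
    if (!is.null(r$sections)) {
      rec$sections <- lapply(r$sections, I)
    }
    rec
  })
  write_jsonl(unname(records), path)
}

#' Write gold annotations to a JSONL file
#'
#' `{"report_id": str, "aif_sentences": [str, ...]}` per annotated report.
#'
#' @param dataset an [aif_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(dataset, path) {
  records <- lapply(unname(dataset$annotations), function(a) {
    list(report_id = a$report_id, aif_sentences = I(a$aif_sentences))
  })
  write_jsonl(records, path)
}

#' Attach annotations from a JSONL file to a dataset
#'
#' @param dataset an [aif_dataset()] (existing annotations are replaced).
#' @param path annotations JSONL path.
#' @return the annotated [aif_dataset()].
#' @export
read_annotations <- function(dataset, path) {
  recs <- read_jsonl(path)
  annotations <- lapply(recs, function(rec) {
    id <- chr_from_json(rec$report_id, "report_id")
    sents <- chr_from_json(rec$aif_sentences %||% list(), "aif_sentences")
    aif_annotation(id, sents, report = dataset$reports[[id]])
  })
  aif_dataset(dataset$name, unname(dataset$reports), annotations)
}

#' Write extraction results to a predictions JSONL file
#'
#' @param results list of extraction results from [run_extraction()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(results, path) {
  records <- lapply(results, function(r) {
    list(report_id = r$report_id,
         predicted_label = if (is.na(r$predicted_label)) NULL else
           r$predicted_label,
         predicted_sentences = I(r$predicted_sentences),
         attempts = r$attempts,
         parse_status = r$parse_status)
  })
  write_jsonl(records, path)
}

#' Read extraction results from a predictions JSONL file
#'
#' @param path predictions JSONL path.
#' @return list of extraction result objects.
#' @export
read_predictions <- function(path) {
  lapply(read_jsonl(path), function(rec) {
    label <- rec$predicted_label
    new_extraction_result(
      report_id = chr_from_json(rec$report_id, "report_id"),
      predicted_label = if (is.null(label)) NA else isTRUE(label),
      predicted_sentences = chr_from_json(rec$predicted_sentences %||% list(),
                                          "predicted_sentences"),
      attempts = rec$attempts %||% 1L,
      parse_status = rec$parse_status %||% "ok",
      raw_generations = character(0)
    )
  })
}
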