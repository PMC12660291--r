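#' Decoding configuration
#'
#' The four decoding strategies: greedy (deterministic argmax), nucleus
#' (top-p sampling softened by temperature), beam search, and the hybrid
#' controller.  Hybrid decoding runs greedy first and, on structured-output
#' parse failure, retries with nucleus sampling at
#' (`fallback_temperature`, `fallback_top_p`) until an attempt parses or
#' the attempt cap is reached, after which a parsable null answer is
#' returned.  The default cap of 6 reads the five-attempt fallback limit
#' as five nucleus retries after the failed greedy attempt; set
#' `max_attempts = 5` to count the greedy attempt against the limit
#' instead.
#'
#' @param method `"greedy"`, `"nucleus"`, `"beam"`, or `"hybrid"`.
#' @param temperature nucleus temperature (> 0).
#' @param top_p nucleus probability mass threshold in (0, 1].
#' @param num_beams beam count (>= 2, beam only).
#' @param max_attempts hybrid attempt cap including the greedy attempt.
#' @param fallback_temperature,fallback_top_p nucleus parameters for hybrid
#'   fallback attempts (default 0.5 each).
#' @return object of class `aif_decoding`.
#' @export
decoding_config <- function(method = c("hybrid", "greedy", "nucleus",
                                       "beam"),
                            temperature = 0.5, top_p = 0.5, num_beams = 4L,
                            max_attempts = 6L, fallback_temperature = 0.5,
                            fallback_top_p = 0.5) {
  method <- match.arg(method)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (top_p <= 0 || top_p > 1) stop("top_p must be in (0, 1]",
                                    call. = FALSE)
  assert_count(num_beams, "num_beams", min = 2L)
  assert_count(max_attempts, "max_attempts", min = 1L)
  structure(
    list(method = method, temperature = temperature, top_p = top_p,
         num_beams = as.integer(num_beams),
         max_attempts = as.integer(max_attempts),
         fallback_temperature = fallback_temperature,
         fallback_top_p = fallback_top_p),
    class = "aif_decoding"
  )
}

#' Strip generation artefacts around a JSON payload
#'
#' Rule-based cleanup applied before JSON validation: removes code-fence
#' markers, then returns the first brace-balanced object span (string
#' contents and escapes are respected, so braces inside JSON strings do
#' not confuse the scanner).  Leading and trailing prose, and any trailing
#' repetition after the first complete object, are discarded.  Idempotent.
#' When no balanced span exists the input is returned unchanged with
#' attribute `payload_found = FALSE`.
#'
#' @param raw raw generation string.
#' @return candidate payload string with attribute `payload_found`.
#' @export
#' @examples
#' strip_artefacts("```json\n{\"a\":1}\n```")
strip_artefacts <- function(raw) {
  assert_string(raw, "raw")
  txt <- gsub("```[A-Za-z]*", "", raw)
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  depth <- 0L
  start <- NA_integer_
  in_string <- FALSE
  escaped <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_string) {
      if (escaped) {
        escaped <- FALSE
      } else if (ch == "\\") {
        escaped <- TRUE
      } else if (ch == "\"") {
        in_string <- FALSE
      }
      next
    }
    if (ch == "\"" && depth > 0L) {
      in_string <- TRUE
    } else if (ch == "{") {
      if (depth == 0L) start <- i
      depth <- depth + 1L
    } else if (ch == "}") {
      if (depth > 0L) {
        depth <- depth - 1L
        if (depth == 0L) {
          out <- substr(txt, start, i)
          attr(out, "payload_found") <- TRUE
          return(out)
        }
      }
    }
  }
  out <- raw
  attr(out, "payload_found") <- FALSE
  out
}

#' Parse and validate a raw generation
#'
#' JSON strategies: [strip_artefacts()], strict JSON parse, then schema
#' validation against the canonical answer shape --
#' `{"actionable_findings_present": bool, "aif_sentences": [str, ...]}`
#' for CoT strategies, `{"aif_sentences": [str, ...]}` for standard
#' strategies.  Free-text strategies: non-empty lines are sentences, with
#' a configurable negative marker mapping to the empty list; CoT free-text
#' outputs may carry an "Actionable findings present: yes/no" label line.
#' For standard strategies the document label is derived: positive if and
#' only if any sentences are returned.  Failures never raise; they are
#' signalled with `valid = FALSE` (the retry controller owns recovery).
#'
#' @param raw raw generation string.
#' @param strategy an `aif_strategy` or strategy key.
#' @param negative_marker free-text marker meaning "no findings".
#' @return list with fields `valid`, `label` (logical or NA), `sentences`.
#' @export
parse_answer <- function(raw, strategy, negative_marker = "NONE") {
  strategy <- as_strategy(strategy)
  invalid <- list(valid = FALSE, label = NA, sentences = character(0))
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) return(invalid)

  if (strategy$output_format == "json") {
    cand <- strip_artefacts(raw)
    if (!isTRUE(attr(cand, "payload_found"))) return(invalid)
    parsed <- tryCatch(
      jsonlite::fromJSON(as.character(cand), simplifyVector = FALSE),
      error = function(e) NULL
    )
    if (!is.list(parsed)) return(invalid)
    sents <- parsed$aif_sentences
    if (is.null(sents) || !is.list(sents) ||
        !all(vapply(sents, function(s) is.character(s) && length(s) == 1L,
                    logical(1)))) {
      return(invalid)
    }
    sentences <- unlist(sents, use.names = FALSE) %||% character(0)
    if (strategy$reasoning == "cot") {
      lab <- parsed$actionable_findings_present
      if (!is.logical(lab) || length(lab) != 1L || is.na(lab)) {
        return(invalid)
      }
      label <- lab
    } else {
      label <- length(sentences) > 0L
    }
    return(list(valid = TRUE, label = label, sentences = sentences))
  }

  # free-text formats
  lines <- trimws(strsplit(raw, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(invalid)
  label <- NA
  if (strategy$reasoning == "cot") {
    m <- regmatches(lines[1],
                    regexec("^actionable findings present:\\s*(yes|no)\\s*$",
                            tolower(lines[1])))[[1]]
    if (length(m)) {
      label <- m[2] == "yes"
      lines <- lines[-1]
    }
  }
  lines <- lines[tolower(lines) != tolower(negative_marker)]
  if (is.na(label)) label <- length(lines) > 0L
  list(valid = TRUE, label = label, sentences = lines)
}

#' Extract AIFs from one report through a generation backend
#'
#' With hybrid decoding, attempt 1 is greedy; attempts 2..`max_attempts`
#' are nucleus fallbacks at the configured fallback temperature/top-p with
#' per-attempt derived seeds (`seed + attempt - 1`), stopping at the first
#' attempt whose output parses and validates.  Parse status is `"ok"` when
#' attempt 1 succeeds, `"recovered"` when a fallback attempt succeeds, and
#' `"fatal_null"` when all attempts are exhausted, in which case the
#' predicted label is null (NA) and the sentence list empty -- the
#' pipeline's JSON-parsable null answer, scored as incorrect downstream.
#' Non-hybrid methods make a single attempt.
#'
#' @param report an [aif_report()].
#' @param template an `aif_template`.
#' @param backend a generation backend ([scripted_backend()],
#'   [oracle_backend()], or any object with a
#'   `generate(prompt, config, seed)` function).
#' @param config an [decoding_config()].
#' @param seed integer base seed.
#' @return an extraction result (class `aif_extraction`) with fields
#'   `report_id`, `predicted_label`, `predicted_sentences`, `attempts`,
#'   `parse_status`, `raw_generations`.
#' @export
extract_findings <- function(report, template, backend,
                             config = decoding_config(), seed = 1L) {
  n_attempts <- if (config$method == "hybrid") config$max_attempts else 1L
  raws <- character(0)
  for (attempt in seq_len(n_attempts)) {
    attempt_cfg <- if (config$method != "hybrid") {
      config
    } else if (attempt == 1L) {
      decoding_config("greedy")
    } else {
      decoding_config("nucleus",
                      temperature = config$fallback_temperature,
                      top_p = config$fallback_top_p)
    }
    raw <- tryCatch(
      backend$generate(build_prompt(report, template), attempt_cfg,
                       seed + attempt - 1L),
      error = function(e) {
        stop("backend failure on report ", report$report_id, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
    raws <- c(raws, raw)
    ans <- parse_answer(raw, template$strategy)
    if (ans$valid) {
      return(new_extraction_result(
        report$report_id, ans$label, ans$sentences, attempt,
        if (attempt == 1L) "ok" else "recovered", raws
      ))
    }
  }
  new_extraction_result(report$report_id, NA, character(0), n_attempts,
                        "fatal_null", raws)
}

#' Run extraction over a dataset
#'
#' Order-preserving loop over the dataset's reports with per-report base
#' seeds derived from `seed`, plus a parsing-error tally:
#' `reports_retried` counts reports needing more than one attempt
#' (recovered or fatal) and `fatal_nulls` counts exhausted reports.
#'
#' @param dataset an [aif_dataset()].
#' @param template an `aif_template`.
#' @param backend a generation backend.
#' @param config an [decoding_config()].
#' @param seed integer base seed.
#' @return list with `results` (list of extraction results) and `tally`
#'   (list with `reports_retried`, `fatal_nulls`).
#' @export
run_extraction <- function(dataset, template, backend,
                           config = decoding_config(), seed = 1L) {
  results <- vector("list", length(dataset$reports))
  for (i in seq_along(dataset$reports)) {
    results[[i]] <- extract_findings(dataset$reports[[i]], template,
                                     backend, config,
                                     seed = seed + 1000L * (i - 1L))
  }
  list(results = results, tally = tally_parsing_errors(results))
}

#' Tally parsing errors from extraction results
#'
#' @param results list of extraction results.
#' @return list with `reports_retried` (attempts > 1) and `fatal_nulls`.
#' @export
tally_parsing_errors <- function(results) {
  statuses <- vapply(results, function(r) r$parse_status, character(1))
  list(
    reports_retried = sum(statuses %in% c("recovered", "fatal_null")),
    fatal_nulls = sum(statuses == "fatal_null")
  )
}

#' Audit predicted sentences for grounding in the source report
#'
#' Flags every predicted sentence whose normalized, whitespace-collapsed
#' form is not a substring of the similarly collapsed report text -- the
#' literal-level hallucination check.  A sound extraction pipeline, and
#' the gold-oracle backend by construction, yields zero flags.
#'
#' @param results list of extraction results.
#' @param dataset the [aif_dataset()] the results came from.
#' @return data.frame with columns `report_id`, `sentence`, one row per
#'   ungrounded prediction (zero rows when everything is grounded).
#' @export
audit_grounding <- function(results, dataset) {
  rows <- list()
  for (r in results) {
    report <- dataset$reports[[r$report_id]]
    if (is.null(report)) stop("unknown report_id: ", r$report_id,
                              call. = FALSE)
    hay <- collapse_ws(report$text)
    for (s in r$predicted_sentences) {
      needle <- collapse_ws(normalize_sentence(s))
      if (nzchar(needle) && !grepl(needle, hay, fixed = TRUE)) {
        rows[[length(rows) + 1L]] <- data.frame(
          report_id = r$report_id, sentence = s, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(report_id = character(0), sentence = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
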