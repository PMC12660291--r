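ERROR_KINDS <- c("boundary_soft", "multiple_reference_soft",
                 "text_artefact_soft", "hard_false_positive",
                 "missed_aif_hard", "ungrounded")
SOFT_KINDS <- c("boundary_soft", "multiple_reference_soft",
                "text_artefact_soft")

# Extended normalization for text-artefact comparison: edge strip,
# lowercase, collapse interior whitespace.
extended_normalize <- function(x) {
  tolower(collapse_ws(normalize_sentence(x)))
}

jaccard_tokens <- function(a, b) {
  tok <- function(s) {
    t <- unlist(strsplit(tolower(s), "[^a-z]+"), use.names = FALSE)
    unique(t[nzchar(t)])
  }
  ta <- tok(a)
  tb <- tok(b)
  if (!length(ta) && !length(tb)) return(1)
  length(intersect(ta, tb)) / length(union(ta, tb))
}

new_error_record <- function(report_id, kind, gold_sentence = NA_character_,
                             pred_sentence = NA_character_) {
  data.frame(report_id = report_id, kind = kind,
             gold_sentence = gold_sentence, pred_sentence = pred_sentence,
             stringsAsFactors = FALSE)
}

empty_error_records <- function() {
  data.frame(report_id = character(0), kind = character(0),
             gold_sentence = character(0), pred_sentence = character(0),
             stringsAsFactors = FALSE)
}

#' Classify sentence-level mismatches into soft and hard error types
#'
#' Deterministic rule cascade over the false-positive and false-negative
#' sets from [match_sentences()], mirroring qualitative error analysis of
#' extraction mistakes.  Soft kinds would not affect clinical practice;
#' hard kinds would.
#'
#' 1. `boundary_soft`: an FP/FN pair where one normalized string is a
#'    substring of the other (a sentence boundary disagreement beyond the
#'    edge normalization); pairs are consumed greedily by longest overlap,
#'    ties broken by report order.
#' 2. `text_artefact_soft`: an FP equal to a remaining FN under extended
#'    normalization (lowercasing and interior whitespace collapsing).
#' 3. `multiple_reference_soft`: a remaining FN whose token-set Jaccard
#'    overlap with any matched (true-positive) gold sentence of the same
#'    report reaches `jaccard_threshold` -- one missed reference to an
#'    AIF the prediction did capture elsewhere.
#' 4. `ungrounded`: a remaining FP not present in the report text after
#'    normalization (a hallucination).
#' 5. Remaining FPs are `hard_false_positive` (extraction of a
#'    non-actionable or misjudged finding); remaining FNs are
#'    `missed_aif_hard`.
#'
#' @param gold the report's [aif_annotation()].
#' @param pred the report's extraction result.
#' @param report the [aif_report()] itself.
#' @param jaccard_threshold multiple-reference overlap threshold
#'   (default 0.6).
#' @return data.frame of error records (`report_id`, `kind`,
#'   `gold_sentence`, `pred_sentence`); zero rows when prediction and
#'   gold agree.
#' @export
classify_errors <- function(gold, pred, report, jaccard_threshold = 0.6) {
  if (!identical(gold$report_id, pred$report_id) ||
      !identical(gold$report_id, report$report_id)) {
    stop("gold, prediction and report must share a report_id",
         call. = FALSE)
  }
  m <- match_sentences(gold, pred)
  fp <- m$fp
  fn <- m$fn
  records <- empty_error_records()

  # (1) boundary pairs, greedy by longest normalized overlap
  if (length(fp) && length(fn)) {
    repeat {
      best <- NULL
      for (i in seq_along(fp)) {
        for (j in seq_along(fn)) {
          a <- normalize_sentence(fp[i])
          b <- normalize_sentence(fn[j])
          if (!nzchar(a) || !nzchar(b)) next
          if (grepl(a, b, fixed = TRUE) || grepl(b, a, fixed = TRUE)) {
            overlap <- min(nchar(a), nchar(b))
            if (is.null(best) || overlap > best$overlap) {
              best <- list(i = i, j = j, overlap = overlap)
            }
          }
        }
      }
      if (is.null(best)) break
      records <- rbind(records,
                       new_error_record(gold$report_id, "boundary_soft",
                                        gold_sentence = fn[best$j],
                                        pred_sentence = fp[best$i]))
      fp <- fp[-best$i]
      fn <- fn[-best$j]
      if (!length(fp) || !length(fn)) break
    }
  }

  # (2) text artefact pairs under extended normalization
  if (length(fp) && length(fn)) {
    i <- 1L
    while (i <= length(fp)) {
      hit <- which(extended_normalize(fn) == extended_normalize(fp[i]))
      if (length(hit)) {
        records <- rbind(records,
                         new_error_record(gold$report_id,
                                          "text_artefact_soft",
                                          gold_sentence = fn[hit[1]],
                                          pred_sentence = fp[i]))
        fn <- fn[-hit[1]]
        fp <- fp[-i]
      } else {
        i <- i + 1L
      }
    }
  }

  # (3) multiple-reference misses against matched gold sentences
  if (length(fn) && length(m$tp_gold)) {
    keep <- logical(length(fn))
    for (j in seq_along(fn)) {
      overlaps <- vapply(m$tp_gold, jaccard_tokens, numeric(1), a = fn[j])
      if (max(overlaps) >= jaccard_threshold) {
        records <- rbind(records,
                         new_error_record(gold$report_id,
                                          "multiple_reference_soft",
                                          gold_sentence = fn[j]))
      } else {
        keep[j] <- TRUE
      }
    }
    fn <- fn[keep]
  }

  # (4) ungrounded predictions, (5) remaining hard errors
  if (length(fp)) {
    hay <- collapse_ws(report$text)
    for (s in fp) {
      needle <- collapse_ws(normalize_sentence(s))
      kind <- if (nzchar(needle) && grepl(needle, hay, fixed = TRUE)) {
        "hard_false_positive"
      } else {
        "ungrounded"
      }
      records <- rbind(records,
                       new_error_record(gold$report_id, kind,
                                        pred_sentence = s))
    }
  }
  for (s in fn) {
    records <- rbind(records,
                     new_error_record(gold$report_id, "missed_aif_hard",
                                      gold_sentence = s))
  }
  records
}

#' Classify errors across a whole run
#'
#' @param dataset an [aif_dataset()].
#' @param results list of extraction results.
#' @param jaccard_threshold see [classify_errors()].
#' @return row-bound error records for the corpus.
#' @export
classify_errors_run <- function(dataset, results, jaccard_threshold = 0.6) {
  recs <- lapply(results, function(res) {
    classify_errors(dataset$annotations[[res$report_id]], res,
                    dataset$reports[[res$report_id]],
                    jaccard_threshold = jaccard_threshold)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) empty_error_records() else out
}

#' Summarise error records and recompute soft-forgiven metrics
#'
#' Counts records per kind and per soft/hard split, and recomputes the
#' sentence-level metrics treating soft errors as correct: each
#' boundary/artefact pair moves one FP and one FN into TP, and each
#' forgiven multiple-reference miss removes one FN.  The adjusted
#' precision/recall/F1 therefore can never fall below the unadjusted
#' values; the gap estimates how much exact-match scoring understates
#' practical performance.
#'
#' @param records error records from [classify_errors_run()].
#' @param dataset an [aif_dataset()].
#' @param results the extraction results the records came from.
#' @return list with `counts` (named integer vector over all kinds),
#'   `soft`, `hard`, `unadjusted` and `adjusted` sentence metrics
#'   (precision, recall, f1).
#' @export
summarize_errors <- function(records, dataset, results) {
  counts <- table(factor(records$kind, levels = ERROR_KINDS))
  counts <- stats::setNames(as.integer(counts), ERROR_KINDS)

  tp <- fp <- fn <- 0L
  for (res in results) {
    m <- match_sentences(dataset$annotations[[res$report_id]], res)
    tp <- tp + m$n_tp
    fp <- fp + m$n_fp
    fn <- fn + m$n_fn
  }
  n_pair <- counts["boundary_soft"] + counts["text_artefact_soft"]
  n_multi <- counts["multiple_reference_soft"]
  adj_tp <- tp + n_pair + n_multi
  adj_fp <- fp - n_pair
  adj_fn <- fn - n_pair - n_multi
  list(
    counts = counts,
    soft = unname(sum(counts[SOFT_KINDS])),
    hard = unname(sum(counts[setdiff(ERROR_KINDS, SOFT_KINDS)])),
    unadjusted = as.list(prf(tp, fp, fn)),
    adjusted = as.list(prf(adj_tp, adj_fp, adj_fn))
  )
}

#' Write error records and summary to disk
#'
#' @param records error records.
#' @param summary output of [summarize_errors()].
#' @param records_path JSONL path for per-record review output.
#' @param summary_path JSON path for the per-kind counts and adjusted
#'   metrics.
#' @return `summary_path`, invisibly.
#' @export
write_error_report <- function(records, summary, records_path,
                               summary_path) {
  recs <- lapply(seq_len(nrow(records)), function(i) {
    r <- as.list(records[i, ])
    r[!is.na(r)]
  })
  write_jsonl(recs, records_path)
  jsonlite::write_json(
    list(counts = as.list(summary$counts), soft = summary$soft,
         hard = summary$hard, unadjusted = summary$unadjusted,
         adjusted = summary$adjusted),
    summary_path, auto_unbox = TRUE, digits = NA
  )
  invisible(summary_path)
}
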