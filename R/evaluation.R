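# Characters stripped from sentence edges during normalization: ASCII
# punctuation, unicode dashes and curly quotes, digits, and whitespace.
# Frozen here; interior characters are never touched.
EDGE_CHAR_CLASS <- paste0(
  "[\\s0-9",
  "!\"#$%&'()*+,./:;<=>?@\\[\\]\\\\^_`{|}~\\-",
  "\u2010\u2011\u2012\u2013\u2014\u2018\u2019\u201c\u201d",
  "]"
)

#' Normalize a sentence for matching
#'
#' Strips any leading or trailing run of whitespace, punctuation, and
#' digits (ASCII punctuation plus unicode dashes/quotes), leaving interior
#' content untouched and case preserved.  This compensates for sentence
#' boundary disagreements such as an omitted numeral at the start of a
#' numbered list entry, without jeopardising sentence meaning.
#' Idempotent; vectorised.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_sentence("1. Incidental 2.1 cm left adrenal nodule.")
normalize_sentence <- function(x) {
  gsub(paste0("^(?:", EDGE_CHAR_CLASS, ")+|(?:", EDGE_CHAR_CLASS, ")+$"),
       "", x, perl = TRUE)
}

#' Derive a document label from a sentence list
#'
#' Positive if and only if one or more AIF sentences are present.
#'
#' @param sentences character vector of AIF sentences.
#' @return `"positive"` or `"negative"`.
#' @export
derive_doc_label <- function(sentences) {
  if (length(sentences)) "positive" else "negative"
}

# Deduplicate by normalized form, keeping the first original string of
# each form and dropping strings that normalize to empty.
norm_dedup <- function(x) {
  norm <- normalize_sentence(x)
  keep <- nzchar(norm) & !duplicated(norm)
  list(norm = norm[keep], orig = x[keep])
}

#' Match predicted against gold sentences for one report
#'
#' Both sides are normalized ([normalize_sentence()]) then deduplicated
#' per report (set semantics, so duplicate references to one finding are
#' never double-credited); exact string equality on normalized forms
#' defines a true positive.  Unmatched predictions are false positives,
#' unmatched gold sentences false negatives.  A fatal-null prediction
#' contributes no TP/FP and all gold sentences as FN.
#'
#' @param gold an [aif_annotation()].
#' @param pred the report's extraction result.
#' @return list with `tp`, `fp`, `fn` (original sentence strings) and
#'   integer counts `n_tp`, `n_fp`, `n_fn`.
#' @export
match_sentences <- function(gold, pred) {
  if (!identical(gold$report_id, pred$report_id)) {
    stop("report_id mismatch: gold ", gold$report_id, " vs prediction ",
         pred$report_id, call. = FALSE)
  }
  g <- norm_dedup(gold$aif_sentences)
  p <- norm_dedup(pred$predicted_sentences)
  tp_idx <- p$norm %in% g$norm
  fn_idx <- !(g$norm %in% p$norm)
  list(
    tp = p$orig[tp_idx],
    tp_gold = g$orig[g$norm %in% p$norm],
    fp = p$orig[!tp_idx],
    fn = g$orig[fn_idx],
    n_tp = sum(tp_idx),
    n_fp = sum(!tp_idx),
    n_fn = sum(fn_idx)
  )
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

#' Compute the two-tier metrics report
#'
#' Document level: accuracy, the 2x2 confusion matrix, and macro-averaged
#' precision/recall/F1 (unweighted mean over the positive and negative
#' classes).  A fatal-null prediction is scored as the incorrect label
#' against its gold label.  Sentence level: micro (corpus-pooled)
#' precision/recall/F1 from summed per-report TP/FP/FN after
#' normalization and per-report deduplication.  Zero-denominator metrics
#' are defined as 0 so empty-prediction runs remain scoreable.
#'
#' @param dataset an [aif_dataset()]; every evaluated report must be
#'   annotated.
#' @param results list of extraction results (e.g.
#'   `run_extraction(...)$results`).
#' @return object of class `aif_metrics`: fields `doc` (precision,
#'   recall, f1 -- macro; accuracy; confusion = c(tp, fp, tn, fn)),
#'   `sent` (precision, recall, f1, tp, fp, fn), `parsing_errors`.
#' @export
compute_metrics <- function(dataset, results) {
  doc_tp <- doc_fp <- doc_tn <- doc_fn <- 0L
  s_tp <- s_fp <- s_fn <- 0L
  for (res in results) {
    ann <- dataset$annotations[[res$report_id]]
    if (is.null(ann)) {
      stop("no gold annotation for report ", res$report_id, call. = FALSE)
    }
    gold_pos <- ann$doc_label == "positive"
    pred_pos <- if (is.na(res$predicted_label)) !gold_pos else
      isTRUE(res$predicted_label)
    if (gold_pos && pred_pos) doc_tp <- doc_tp + 1L
    if (gold_pos && !pred_pos) doc_fn <- doc_fn + 1L
    if (!gold_pos && pred_pos) doc_fp <- doc_fp + 1L
    if (!gold_pos && !pred_pos) doc_tn <- doc_tn + 1L
    m <- match_sentences(ann, res)
    s_tp <- s_tp + m$n_tp
    s_fp <- s_fp + m$n_fp
    s_fn <- s_fn + m$n_fn
  }
  pos <- prf(doc_tp, doc_fp, doc_fn)
  neg <- prf(doc_tn, doc_fn, doc_fp)  # negative class: TN are its hits
  sent <- prf(s_tp, s_fp, s_fn)
  n <- doc_tp + doc_fp + doc_tn + doc_fn
  structure(
    list(
      doc = list(
        precision = unname((pos["precision"] + neg["precision"]) / 2),
        recall = unname((pos["recall"] + neg["recall"]) / 2),
        f1 = unname((pos["f1"] + neg["f1"]) / 2),
        accuracy = if (n > 0) (doc_tp + doc_tn) / n else 0,
        confusion = c(tp = doc_tp, fp = doc_fp, tn = doc_tn, fn = doc_fn)
      ),
      sent = list(
        precision = unname(sent["precision"]),
        recall = unname(sent["recall"]),
        f1 = unname(sent["f1"]),
        tp = s_tp, fp = s_fp, fn = s_fn
      ),
      parsing_errors = tally_parsing_errors(results)
    ),
    class = "aif_metrics"
  )
}

#' @export
print.aif_metrics <- function(x, ...) {
  cat("Document level (macro):\n")
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f  accuracy %.3f\n",
              x$doc$precision, x$doc$recall, x$doc$f1, x$doc$accuracy))
  cm <- x$doc$confusion
  cat("  confusion:          predicted +   predicted -\n")
  cat(sprintf("    gold positive   %9d   %11d\n", cm["tp"], cm["fn"]))
  cat(sprintf("    gold negative   %9d   %11d\n", cm["fp"], cm["tn"]))
  cat("Sentence level (micro):\n")
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f  (TP %d, FP %d, FN %d)\n",
              x$sent$precision, x$sent$recall, x$sent$f1,
              x$sent$tp, x$sent$fp, x$sent$fn))
  cat(sprintf("Parsing errors: %d retried, %d fatal null\n",
              x$parsing_errors$reports_retried,
              x$parsing_errors$fatal_nulls))
  invisible(x)
}

#' Write a metrics report to JSON
#'
#' @param metrics an `aif_metrics` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  out <- list(
    doc = list(precision = metrics$doc$precision,
               recall = metrics$doc$recall, f1 = metrics$doc$f1,
               accuracy = metrics$doc$accuracy,
               confusion = as.list(metrics$doc$confusion)),
    sent = metrics$sent,
    parsing_errors = metrics$parsing_errors
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a metrics report from JSON
#'
#' @param path JSON file written by [write_metrics()].
#' @return an `aif_metrics` object.
#' @export
read_metrics <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(
    list(
      doc = list(precision = x$doc$precision, recall = x$doc$recall,
                 f1 = x$doc$f1, accuracy = x$doc$accuracy,
                 confusion = unlist(x$doc$confusion)),
      sent = as.list(x$sent),
      parsing_errors = as.list(x$parsing_errors)
    ),
    class = "aif_metrics"
  )
}

#' Aggregate metrics over repeated runs
#'
#' Mean and 95% confidence-interval half-width over k runs (k >= 2), with
#' the half-width computed as `t(0.975, k - 1) * sd / sqrt(k)` using the
#' sample standard deviation -- appropriate for the small run counts
#' (typically three seeds) used for stochastic training.
#'
#' @param runs either a numeric vector of one metric over runs, or a list
#'   of `aif_metrics` objects (aggregated per scalar metric).
#' @return for numeric input, a list with `mean`, `ci_half_width`, `k`;
#'   for metrics input, a data.frame with one row per metric.
#' @export
aggregate_runs <- function(runs) {
  if (is.numeric(runs)) {
    k <- length(runs)
    if (k < 2L) stop("need at least 2 runs to aggregate", call. = FALSE)
    hw <- stats::qt(0.975, df = k - 1) * stats::sd(runs) / sqrt(k)
    return(list(mean = mean(runs), ci_half_width = hw, k = k))
  }
  if (!is.list(runs) || !all(vapply(runs, inherits, logical(1),
                                    "aif_metrics"))) {
    stop("runs must be a numeric vector or a list of aif_metrics",
         call. = FALSE)
  }
  fields <- list(
    doc_precision = function(m) m$doc$precision,
    doc_recall = function(m) m$doc$recall,
    doc_f1 = function(m) m$doc$f1,
    doc_accuracy = function(m) m$doc$accuracy,
    sent_precision = function(m) m$sent$precision,
    sent_recall = function(m) m$sent$recall,
    sent_f1 = function(m) m$sent$f1
  )
  rows <- lapply(names(fields), function(nm) {
    vals <- vapply(runs, fields[[nm]], numeric(1))
    agg <- aggregate_runs(vals)
    data.frame(metric = nm, mean = agg$mean,
               ci_half_width = agg$ci_half_width, k = agg$k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohen's kappa for two binary annotators
#'
#' Standard two-rater chance-corrected agreement on the 2x2 table:
#' `kappa = (p_o - p_e) / (1 - p_e)`, with observed agreement `p_o` and
#' marginal-product expected agreement `p_e`.  Returns 1 when both
#' agreement terms are 1 (degenerate single-category case).
#'
#' @param labels_a,labels_b equal-length vectors of binary labels (any
#'   two-valued type).
#' @return list with `kappa`, `observed_agreement`, `expected_agreement`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || !length(labels_a)) {
    stop("labels_a and labels_b must be equal non-zero length",
         call. = FALSE)
  }
  lev <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = lev)
  b <- factor(as.character(labels_b), levels = lev)
  n <- length(a)
  tab <- table(a, b)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 1
  list(kappa = kappa, observed_agreement = p_o, expected_agreement = p_e)
}
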