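# Independent brute-force oracles the implementation is checked against.

# Character-level splitter: break after terminal punctuation followed by
# whitespace and a capital letter.  No abbreviation or numeral logic --
# only valid as an oracle on fixtures free of those constructs.
brute_split <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(0)
  start <- 1L
  i <- 1L
  while (i < n) {
    if (chars[i] %in% c(".", "!", "?") && grepl("\\s", chars[i + 1L])) {
      j <- i + 1L
      while (j <= n && grepl("\\s", chars[j])) j <- j + 1L
      if (j <= n && grepl("[A-Z]", chars[j])) {
        out <- c(out, trimws(substr(text, start, i)))
        start <- j
        i <- j
        next
      }
    }
    i <- i + 1L
  }
  c(out, trimws(substr(text, start, n)))
}

# Quadratic all-pairs matcher over normalized, deduplicated sentence sets.
brute_match <- function(gold_sents, pred_sents) {
  dedup <- function(x) {
    norm <- normalize_sentence(x)
    unique(norm[nzchar(norm)])
  }
  g <- dedup(gold_sents)
  p <- dedup(pred_sents)
  tp <- 0L
  for (a in p) {
    for (b in g) if (identical(a, b)) tp <- tp + 1L
  }
  list(tp = tp, fp = length(p) - tp, fn = length(g) - tp)
}

# Direct-formula metric recount from labels and per-report sentence sets.
brute_metrics <- function(gold_labels, pred_labels, gold_sets, pred_sets) {
  stopifnot(length(gold_labels) == length(pred_labels))
  eff <- ifelse(is.na(pred_labels), !gold_labels, pred_labels)
  tp <- sum(gold_labels & eff)
  fn <- sum(gold_labels & !eff)
  fp <- sum(!gold_labels & eff)
  tn <- sum(!gold_labels & !eff)
  prf1 <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }
  pos <- prf1(tp, fp, fn)
  neg <- prf1(tn, fn, fp)
  s_tp <- s_fp <- s_fn <- 0L
  for (i in seq_along(gold_sets)) {
    m <- brute_match(gold_sets[[i]], pred_sets[[i]])
    s_tp <- s_tp + m$tp
    s_fp <- s_fp + m$fp
    s_fn <- s_fn + m$fn
  }
  sent <- prf1(s_tp, s_fp, s_fn)
  list(doc_precision = (pos[1] + neg[1]) / 2,
       doc_recall = (pos[2] + neg[2]) / 2,
       doc_f1 = (pos[3] + neg[3]) / 2,
       doc_accuracy = (tp + tn) / length(gold_labels),
       confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
       sent_precision = sent[1], sent_recall = sent[2], sent_f1 = sent[3])
}

# Hand-built two-report fixture used across IO and evaluation tests.
tiny_dataset <- function() {
  r1 <- aif_report(
    "r1",
    paste("Clinical details: Known lung cancer. Findings: The known right",
          "upper lobe primary is avid. Severe emphysema is seen in both",
          "lungs. Interpretation: Appearances are stable.")
  )
  r2 <- aif_report(
    "r2",
    paste("Clinical details: Staging scan. Findings: Mild emphysema is",
          "noted. No other abnormality. Interpretation: No actionable",
          "finding.")
  )
  aif_dataset(
    "tiny", list(r1, r2),
    list(aif_annotation("r1", "Severe emphysema is seen in both lungs.",
                        report = r1),
         aif_annotation("r2", character(0), report = r2))
  )
}

# Bare extraction-result builder for evaluation tests.
fake_result <- function(report_id, sentences, label = NULL,
                        status = "ok", attempts = 1L) {
  if (identical(status, "fatal_null")) {
    return(aifpipe:::new_extraction_result(report_id, NA, character(0),
                                           attempts, status, character(0)))
  }
  label <- if (is.null(label)) length(sentences) > 0L else label
  aifpipe:::new_extraction_result(report_id, label, sentences, attempts,
                                  status, character(0))
}
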