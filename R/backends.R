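#' Scripted generation backend
#'
#' A fixture backend for controller tests: returns pre-scripted outputs in
#' sequence, per prompt.  `outputs` is either a character vector (the same
#' output sequence is replayed for every prompt) or a named list keyed by
#' exact prompt string.  Once a sequence is exhausted its last element is
#' repeated.  Calls are recorded (prompt, decoding method, seed) for
#' assertions about the controller's decoding schedule.
#'
#' @param outputs character vector or named list of character vectors.
#' @return backend object (class `aif_backend`) with a
#'   `generate(prompt, config, seed)` function and a `calls()` accessor.
#' @export
scripted_backend <- function(outputs) {
  state <- new.env(parent = emptyenv())
  state$counts <- list()
  state$calls <- list()
  generate <- function(prompt, config, seed) {
    k <- (state$counts[[prompt]] %||% 0L) + 1L
    state$counts[[prompt]] <- k
    state$calls[[length(state$calls) + 1L]] <-
      list(prompt = prompt, method = config$method, seed = seed)
    seqn <- if (is.list(outputs)) {
      if (is.null(outputs[[prompt]])) {
        stop("no scripted outputs for prompt", call. = FALSE)
      }
      outputs[[prompt]]
    } else {
      outputs
    }
    seqn[[min(k, length(seqn))]]
  }
  structure(list(kind = "scripted", generate = generate,
                 calls = function() state$calls),
            class = "aif_backend")
}

#' Perturbation settings for the gold-oracle backend
#'
#' Each entry is the per-report (or per-sentence, where noted) probability
#' of applying the perturbation.  With all rates at zero the oracle
#' returns the gold answer exactly.
#'
#' @param boundary_trim per-sentence: prepend a list numeral and strip the
#'   terminal period -- edge noise the evaluation normalization absorbs.
#' @param boundary_word_drop per-sentence: drop the leading word -- a
#'   boundary disagreement *beyond* the normalization's reach.
#' @param artefact_wrap per-report: wrap the payload in code fences and
#'   surrounding prose (exercises [strip_artefacts()]).
#' @param duplicate_drop per-report: drop the last gold sentence when the
#'   report has two or more (emulates missing one reference of a
#'   multi-reference AIF).
#' @param distractor_insert per-report: add a report sentence that is not
#'   in the gold annotation (a grounded false positive).
#' @param label_flip per-report: answer with the wrong document label
#'   (positives return no sentences; negatives return a grounded
#'   distractor).
#' @param ungrounded_insert per-report: add a fabricated sentence absent
#'   from the report (a hallucination, for grounding-audit fixtures).
#' @return named list of rates.
#' @export
oracle_perturbations <- function(boundary_trim = 0, boundary_word_drop = 0,
                                 artefact_wrap = 0, duplicate_drop = 0,
                                 distractor_insert = 0, label_flip = 0,
                                 ungrounded_insert = 0) {
  rates <- list(boundary_trim = boundary_trim,
                boundary_word_drop = boundary_word_drop,
                artefact_wrap = artefact_wrap,
                duplicate_drop = duplicate_drop,
                distractor_insert = distractor_insert,
                label_flip = label_flip,
                ungrounded_insert = ungrounded_insert)
  stopifnot(all(vapply(rates, function(p) is.numeric(p) && p >= 0 &&
                         p <= 1, logical(1))))
  rates
}

UNGROUNDED_SENTENCE <-
  "Fabricated finding not present in the source report."

#' Gold-oracle generation backend
#'
#' Answers each prompt from the gold annotation of the report whose text
#' the prompt contains, rendered in the given strategy's output format.
#' Configurable perturbations inject known error classes so end-to-end
#' metric and taxonomy tests have exact expected scores.  Perturbation
#' draws are seeded per report (from the passed seed and the report's
#' index), so runs are deterministic.
#'
#' @param dataset an [aif_dataset()]; unannotated reports answer negative.
#' @param strategy an `aif_strategy` or key; must match the template used
#'   for extraction.
#' @param perturb an [oracle_perturbations()] list.
#' @param negative_marker free-text negative marker.
#' @return backend object (class `aif_backend`).
#' @export
oracle_backend <- function(dataset, strategy = "cot-json",
                           perturb = oracle_perturbations(),
                           negative_marker = "NONE") {
  strategy <- as_strategy(strategy)
  perturb <- do.call(oracle_perturbations, perturb)
  texts <- vapply(dataset$reports, function(r) r$text, character(1))
  ids <- names(dataset$reports)

  generate <- function(prompt, config, seed) {
    hit <- which(vapply(texts, grepl, logical(1), x = prompt,
                        fixed = TRUE))
    if (length(hit) != 1L) {
      stop("oracle backend could not identify the report in the prompt",
           call. = FALSE)
    }
    report <- dataset$reports[[hit]]
    ann <- dataset$annotations[[ids[hit]]]
    gold <- if (is.null(ann)) character(0) else ann$aif_sentences

    with_seed(seed + 97L * hit, {
      sentences <- gold
      positive <- length(sentences) > 0L

      if (stats::runif(1) < perturb$label_flip) {
        if (positive) {
          sentences <- character(0)
          positive <- FALSE
        } else {
          pool <- setdiff(report$sentences, gold)
          if (length(pool)) {
            sentences <- pool[sample.int(length(pool), 1)]
            positive <- TRUE
          }
        }
      }
      if (length(sentences) >= 2L &&
          stats::runif(1) < perturb$duplicate_drop) {
        # drop the sentence most redundant with another reference, so the
        # perturbation emulates missing one mention of a multi-reference AIF
        overlap <- vapply(seq_along(sentences), function(i) {
          max(vapply(sentences[-i], jaccard_tokens, numeric(1),
                     a = sentences[i]))
        }, numeric(1))
        sentences <- sentences[-which.max(overlap)]
      }
      if (length(sentences)) {
        drop <- stats::runif(length(sentences)) < perturb$boundary_word_drop
        sentences[drop] <- sub("^\\S+\\s+", "", sentences[drop])
        trim <- stats::runif(length(sentences)) < perturb$boundary_trim
        sentences[trim] <- paste0("1. ", sub("\\.\\s*$", "",
                                             sentences[trim]))
      }
      if (stats::runif(1) < perturb$distractor_insert) {
        pool <- setdiff(report$sentences, c(gold, sentences))
        if (length(pool)) {
          sentences <- c(sentences, pool[sample.int(length(pool), 1)])
          positive <- TRUE
        }
      }
      if (stats::runif(1) < perturb$ungrounded_insert) {
        sentences <- c(sentences, UNGROUNDED_SENTENCE)
        positive <- TRUE
      }

      out <- render_answer(strategy, positive, sentences, negative_marker)
      if (stats::runif(1) < perturb$artefact_wrap) {
        out <- paste0("Here is the answer:\n```json\n", out,
                      "\n```\nI hope this helps.")
      }
      out
    })
  }
  structure(list(kind = "oracle", generate = generate,
                 strategy = strategy, perturb = perturb),
            class = "aif_backend")
}
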