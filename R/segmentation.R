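# Abbreviations after which a terminal period never ends a sentence.
# Lowercased; multi-part abbreviations ("e.g") are matched on the token
# preceding the final period with interior periods retained.
SENTENCE_ABBREVIATIONS <- c(
  "cm", "mm", "dr", "mr", "mrs", "prof", "e.g", "i.e", "vs", "approx", "etc"
)

#' Deterministic rule-based sentence segmentation
#'
#' Splits report text on terminal punctuation (`.`, `!`, `?`) followed by
#' whitespace and an upper-case letter, digit, or opening quote/bracket.
#' Two guard rules keep clinically common patterns intact:
#'
#' * a period preceded by a purely numeric token is treated as a numbered
#'   list marker ("1. Incidental renal nodule."), so list entries remain
#'   single sentences including their numeral;
#' * a period preceded by a stop-listed abbreviation (`cm`, `Dr`, `e.g.`,
#'   `vs`, ...) never splits.
#'
#' Segmentation is idempotent: re-segmenting any returned sentence yields
#' that sentence alone.  Sentences are verbatim (trimmed) substrings of the
#' input in original order, and concatenating them with single spaces
#' reproduces the input up to whitespace collapsing.
#'
#' @param text single string; whitespace-only input yields `character(0)`.
#' @return character vector of sentences.
#' @export
#' @examples
#' segment_sentences("No abnormality. 1. Incidental renal nodule.")
segment_sentences <- function(text) {
  assert_string(text, "text")
  if (!nzchar(trimws(text))) return(character(0))

  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_space <- grepl("^\\s$", chars, perl = TRUE)
  is_terminal <- chars %in% c(".", "!", "?")

  bounds <- integer(0)
  for (i in which(is_terminal)) {
    if (i == n || !is_space[i + 1L]) next

    # step back over any closing punctuation run to the preceding token
    j <- i - 1L
    while (j >= 1L && chars[j] %in% c(".", "!", "?", ")", "]", "\"", "'")) {
      j <- j - 1L
    }
    k <- j
    while (k >= 1L && grepl("^[A-Za-z0-9.]$", chars[k], perl = TRUE)) {
      k <- k - 1L
    }
    tok <- if (j > k) tolower(paste(chars[(k + 1L):j], collapse = "")) else ""
    tok <- sub("\\.+$", "", tok)
    if (grepl("^[0-9]+$", tok)) next            # numbered-list marker
    if (tok %in% SENTENCE_ABBREVIATIONS) next

    # next non-space character must plausibly open a sentence
    m <- i + 1L
    while (m <= n && is_space[m]) m <- m + 1L
    if (m > n) next
    if (!grepl("^[A-Z0-9\"'(\\[]$", chars[m], perl = TRUE)) next

    bounds <- c(bounds, i)
  }

  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  sentences <- trimws(substring(text, starts, ends))
  sentences[nzchar(sentences)]
}
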