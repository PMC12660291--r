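`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

collapse_ws <- function(x) {
  trimws(gsub("\\s+", " ", x, perl = TRUE))
}

#' Count whitespace-delimited tokens
#'
#' The default tokenizer hook used when profiling datasets against length
#' targets.  Counts maximal runs of non-whitespace characters.
#'
#' @param x character vector of texts.
#' @return integer vector of token counts (0 for empty/whitespace-only).
#' @export
#' @examples
#' count_tokens_ws("Mild emphysema is noted.")
count_tokens_ws <- function(x) {
  x <- trimws(x)
  n <- lengths(strsplit(x, "\\s+", perl = TRUE))
  n[!nzchar(x)] <- 0L
  as.integer(n)
}

assert_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single non-NA string", call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(what, " must be a single integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(x))
}

# Read a JSONL file into a list of records; errors carry the line number.
read_jsonl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    j <- j + 1L
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) {
        stop(sprintf("malformed JSON on line %d of %s: %s",
                     i, path, conditionMessage(e)), call. = FALSE)
      }
    )
    if (!is.list(rec)) {
      stop(sprintf("line %d of %s is not a JSON object", i, path),
           call. = FALSE)
    }
    out[[j]] <- rec
  }
  out
}

# Write a list of records as one JSON object per line.  Fields that must
# serialise as arrays even when length <= 1 should be wrapped in I().
write_jsonl <- function(records, path) {
  lines <- vapply(records, function(rec) {
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

chr_from_json <- function(x, what, line = NULL) {
  where <- if (is.null(line)) "" else sprintf(" (line %d)", line)
  if (is.null(x)) stop("missing field ", what, where, call. = FALSE)
  if (is.list(x)) {
    if (!all(vapply(x, function(s) is.character(s) && length(s) == 1L,
                    logical(1)))) {
      stop("field ", what, where, " must be an array of strings",
           call. = FALSE)
    }
    return(unlist(x, use.names = FALSE) %||% character(0))
  }
  if (!is.character(x)) stop("field ", what, where, " must be a string",
                             call. = FALSE)
  x
}
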