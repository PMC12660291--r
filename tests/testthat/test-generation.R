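test_that("artefact stripping removes fences, prose and repetition", {
  expect_identical(as.character(strip_artefacts("```json\n{\"a\":1}\n```")),
                   '{"a":1}')
  expect_identical(
    as.character(strip_artefacts(
      'Here is the answer: {"a":1} Hope this helps')),
    '{"a":1}'
  )
  expect_identical(
    as.character(strip_artefacts('{"a":1} {"b":2}')), '{"a":1}'
  )
  # braces inside JSON strings do not end the span
  expect_identical(
    as.character(strip_artefacts('x {"a":"close} brace"} y')),
    '{"a":"close} brace"}'
  )
  no_payload <- strip_artefacts("no json here")
  expect_false(attr(no_payload, "payload_found"))
  expect_identical(as.character(no_payload), "no json here")
})

test_that("artefact stripping is idempotent over decorated payloads", {
  payloads <- c('{"aif_sentences":[]}',
                '{"actionable_findings_present":true,"aif_sentences":["A."]}',
                '{"a":{"nested":1}}')
  wraps <- list(
    function(x) x,
    function(x) paste0("```json\n", x, "\n```"),
    function(x) paste0("Sure! ", x, " Let me know."),
    function(x) paste0(x, " ", x),
    function(x) paste0("prefix {unbalanced ", x)
  )
  for (p in payloads) {
    for (w in wraps) {
      once <- strip_artefacts(w(p))
      twice <- strip_artefacts(as.character(once))
      expect_identical(as.character(twice), as.character(once))
    }
  }
})

test_that("the answer parser enforces the canonical schemas", {
  ok <- parse_answer(
    '{"actionable_findings_present": true, "aif_sentences": ["Severe emphysema."]}',
    "cot-json")
  expect_true(ok$valid)
  expect_true(ok$label)
  expect_length(ok$sentences, 1L)

  neg <- parse_answer('{"aif_sentences": []}', "standard-json")
  expect_true(neg$valid)
  expect_false(neg$label)

  bad_type <- parse_answer('{"actionable_findings_present": "yes"}',
                           "cot-json")
  expect_false(bad_type$valid)
  expect_false(parse_answer('{"aif_sentences": "not a list"}',
                            "standard-json")$valid)
  expect_false(parse_answer("not json at all", "cot-json")$valid)
})

test_that("free-text parsing maps the negative marker to no findings", {
  res <- parse_answer("Actionable findings present: no\nNONE", "cot")
  expect_true(res$valid)
  expect_false(res$label)
  expect_length(res$sentences, 0L)
  res <- parse_answer("First finding.\nSecond finding.", "standard")
  expect_true(res$label)
  expect_identical(res$sentences, c("First finding.", "Second finding."))
  expect_false(parse_answer("   \n ", "standard")$valid)
})

test_that("the hybrid controller retries with nucleus and stops on success", {
  ds <- tiny_dataset()
  r <- ds$reports[[1]]
  tpl <- prompt_template("cot-json")
  good <- '{"actionable_findings_present": false, "aif_sentences": []}'

  be <- scripted_backend(good)
  res <- extract_findings(r, tpl, be, decoding_config("hybrid"), seed = 1L)
  expect_identical(res$attempts, 1L)
  expect_identical(res$parse_status, "ok")

  for (k in 1:3) {
    be <- scripted_backend(c(rep("garbage", k), good))
    res <- extract_findings(r, tpl, be, decoding_config("hybrid"),
                            seed = 1L)
    expect_identical(res$attempts, k + 1L)
    expect_identical(res$parse_status, "recovered")
    methods <- vapply(be$calls(), function(c) c$method, character(1))
    expect_identical(methods[1], "greedy")
    expect_identical(unique(methods[-1]), "nucleus")
    expect_identical(sum(methods == "greedy"), 1L)
  }
})

test_that("exhausting the attempt cap returns the parsable null answer", {
  ds <- tiny_dataset()
  tpl <- prompt_template("cot-json")
  be <- scripted_backend("never valid")
  cfg <- decoding_config("hybrid", max_attempts = 6L)
  res <- extract_findings(ds$reports[[1]], tpl, be, cfg, seed = 1L)
  expect_identical(res$attempts, 6L)
  expect_identical(res$parse_status, "fatal_null")
  expect_true(is.na(res$predicted_label))
  expect_identical(res$predicted_sentences, character(0))
  expect_length(res$raw_generations, 6L)
  # configurable cap is honoured
  res5 <- extract_findings(ds$reports[[1]], tpl, be,
                           decoding_config("hybrid", max_attempts = 5L),
                           seed = 1L)
  expect_identical(res5$attempts, 5L)
})

test_that("per-attempt seeds derive from the base seed", {
  ds <- tiny_dataset()
  tpl <- prompt_template("cot-json")
  be <- scripted_backend(c("bad", "bad", "bad"))
  extract_findings(ds$reports[[1]], tpl, be,
                   decoding_config("hybrid", max_attempts = 3L),
                   seed = 10L)
  seeds <- vapply(be$calls(), function(c) c$seed, numeric(1))
  expect_identical(seeds, c(10, 11, 12))
})

test_that("the run tally equals a recount over result statuses", {
  ds <- generate_dataset(internal_profile(10L, seed = 19L))
  tpl <- prompt_template("cot-json")
  run <- run_extraction(ds, tpl, oracle_backend(ds, "cot-json"),
                        seed = 2L)
  expect_identical(run$tally$reports_retried, 0L)
  expect_identical(run$tally$fatal_nulls, 0L)

  statuses <- c("ok", "recovered", "recovered", "fatal_null", "ok")
  results <- lapply(seq_along(statuses), function(i) {
    fake_result(paste0("r", i), character(0), status = statuses[i],
                attempts = if (statuses[i] == "ok") 1L else 4L)
  })
  tally <- tally_parsing_errors(results)
  expect_identical(tally$reports_retried,
                   sum(statuses %in% c("recovered", "fatal_null")))
  expect_identical(tally$fatal_nulls, sum(statuses == "fatal_null"))
})

test_that("scripted runs are byte-for-byte deterministic", {
  ds <- generate_dataset(internal_profile(6L, seed = 23L))
  tpl <- prompt_template("cot-json")
  mk <- function() oracle_backend(ds, "cot-json",
                                  perturb = list(boundary_trim = 0.5,
                                                 label_flip = 0.3))
  run1 <- run_extraction(ds, tpl, mk(), seed = 5L)
  run2 <- run_extraction(ds, tpl, mk(), seed = 5L)
  expect_identical(
    lapply(run1$results, function(r) r[c("predicted_label",
                                         "predicted_sentences")]),
    lapply(run2$results, function(r) r[c("predicted_label",
                                         "predicted_sentences")])
  )
})

test_that("grounding audit passes oracle runs and catches planted strings", {
  ds <- generate_dataset(internal_profile(25L, seed = 29L))
  tpl <- prompt_template("cot-json")
  run <- run_extraction(ds, tpl, oracle_backend(ds, "cot-json"), seed = 4L)
  expect_identical(nrow(audit_grounding(run$results, ds)), 0L)

  planted <- run$results
  planted[[1]] <- fake_result(planted[[1]]$report_id,
                              c(planted[[1]]$predicted_sentences,
                                "This sentence was never in the report."))
  flags <- audit_grounding(planted, ds)
  expect_identical(nrow(flags), 1L)
  expect_identical(flags$sentence,
                   "This sentence was never in the report.")
})
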