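test_that("normalization strips edges, keeps interiors, and is idempotent", {
  expect_identical(
    normalize_sentence("1. Incidental 2.1 cm left adrenal nodule."),
    "Incidental 2.1 cm left adrenal nodule"
  )
  expect_identical(normalize_sentence("   ...123  "), "")
  expect_identical(normalize_sentence("“Quoted finding” – 3"),
                   "Quoted finding")

  set.seed(42)
  edges <- c(" ", ".", ",", "1", "23", "-", "—", "(", ")", "\"", "")
  cores <- c("Severe emphysema", "a 2.1 cm nodule", "No AIF",
             "mid 3. interior", "")
  for (i in 1:200) {
    s <- paste0(paste(sample(edges, 3, TRUE), collapse = ""),
                sample(cores, 1),
                paste(sample(edges, 3, TRUE), collapse = ""))
    once <- normalize_sentence(s)
    expect_identical(normalize_sentence(once), once)
  }
})

test_that("sentence matching uses normalized set semantics", {
  gold <- aif_annotation("r", c("A first finding sentence.",
                                "B second finding sentence."))
  pred <- fake_result("r", "1. A first finding sentence.")
  m <- match_sentences(gold, pred)
  expect_identical(c(m$n_tp, m$n_fp, m$n_fn), c(1L, 0L, 1L))

  m2 <- match_sentences(aif_annotation("r", character(0)),
                        fake_result("r", "X unexpected"))
  expect_identical(c(m2$n_tp, m2$n_fp, m2$n_fn), c(0L, 1L, 0L))

  # duplicates collapse before counting
  m3 <- match_sentences(
    aif_annotation("r", "Only one gold."),
    fake_result("r", c("Only one gold.", "1. Only one gold."))
  )
  expect_identical(c(m3$n_tp, m3$n_fp, m3$n_fn), c(1L, 0L, 0L))

  expect_error(match_sentences(aif_annotation("a", character(0)),
                               fake_result("b", character(0))),
               "report_id mismatch")
})

test_that("random sentence sets match the brute-force quadratic oracle", {
  set.seed(7)
  vocab <- sprintf("Finding %s is described here.", letters[1:8])
  for (i in 1:50) {
    gold_s <- sample(vocab, sample(0:4, 1))
    pred_s <- sample(c(vocab, paste0("1. ", vocab)), sample(0:4, 1))
    m <- match_sentences(aif_annotation("r", gold_s),
                         fake_result("r", pred_s))
    b <- brute_match(gold_s, pred_s)
    expect_identical(c(m$n_tp, m$n_fp, m$n_fn),
                     as.integer(c(b$tp, b$fp, b$fn)))
  }
})

test_that("document and sentence metrics follow the stated formulas", {
  ds <- tiny_dataset()
  # symmetric confusion: one TP, one FP over an expanded 4-report set
  r3 <- aif_report("r3", "Findings: Nothing. Interpretation: Clear.")
  r4 <- aif_report("r4",
                   "Findings: Severe emphysema both lungs. Interpretation: Noted.")
  ds4 <- aif_dataset("t4",
    c(unname(ds$reports), list(r3, r4)),
    c(unname(ds$annotations),
      list(aif_annotation("r3", character(0), report = r3),
           aif_annotation("r4", "Findings: Severe emphysema both lungs.",
                          report = r4))))
  results <- list(
    fake_result("r1", "Severe emphysema is seen in both lungs."),  # doc TP
    fake_result("r2", "Findings: Mild emphysema is noted."),       # doc FP
    fake_result("r3", character(0)),                               # doc TN
    fake_result("r4", character(0))                                # doc FN
  )
  m <- compute_metrics(ds4, results)
  expect_equal(m$doc$accuracy, 0.5)
  expect_equal(m$doc$precision, 0.5)
  expect_equal(m$doc$recall, 0.5)
  expect_equal(m$doc$f1, 0.5)
  expect_identical(unname(m$doc$confusion), c(1L, 1L, 1L, 1L))

  # forced sentence arithmetic: TP=3, FP=1, FN=2
  g <- aif_annotation("s", sprintf("Gold sentence %d here.", 1:5))
  p <- fake_result("s", c(sprintf("Gold sentence %d here.", 1:3),
                          "A spurious sentence."))
  ds1 <- local({
    txt <- paste(c(sprintf("Gold sentence %d here.", 1:5),
                   "A spurious sentence."), collapse = " ")
    r <- aif_report("s", txt)
    aif_dataset("one", list(r),
                list(aif_annotation("s", g$aif_sentences, report = r)))
  })
  m2 <- compute_metrics(ds1, list(p))
  expect_equal(m2$sent$precision, 0.75)
  expect_equal(m2$sent$recall, 0.6)
  expect_equal(m2$sent$f1, 2 * 0.75 * 0.6 / (0.75 + 0.6))
})

test_that("a fatal null is scored incorrect against either gold label", {
  ds <- tiny_dataset()
  res <- list(fake_result("r1", character(0), status = "fatal_null"),
              fake_result("r2", character(0), status = "fatal_null"))
  m <- compute_metrics(ds, res)
  expect_identical(unname(m$doc$confusion["fn"]), 1L)  # gold positive
  expect_identical(unname(m$doc$confusion["fp"]), 1L)  # gold negative
  expect_equal(m$doc$accuracy, 0)
  expect_identical(m$sent$fn, 1L)
  expect_identical(m$parsing_errors$fatal_nulls, 2L)
})

test_that("metrics equal brute-force recounts on random small fixtures", {
  set.seed(11)
  for (trial in 1:25) {
    n <- sample(2:10, 1)
    vocab <- sprintf("Candidate sentence %s in report.", letters[1:6])
    gold_sets <- list()
    pred_sets <- list()
    reports <- list()
    annotations <- list()
    results <- list()
    gold_lab <- logical(n)
    pred_lab <- logical(n)
    for (i in seq_len(n)) {
      id <- sprintf("r%d", i)
      gold_s <- sample(vocab, sample(0:3, 1))
      pred_s <- sample(vocab, sample(0:3, 1))
      fatal <- stats::runif(1) < 0.15
      text <- paste(c(vocab, "Header text."), collapse = " ")
      reports[[i]] <- aif_report(id, text)
      annotations[[i]] <- aif_annotation(id, gold_s, report = reports[[i]])
      results[[i]] <- if (fatal) {
        fake_result(id, character(0), status = "fatal_null")
      } else {
        fake_result(id, pred_s)
      }
      gold_lab[i] <- length(gold_s) > 0
      pred_lab[i] <- if (fatal) NA else length(pred_s) > 0
      gold_sets[[i]] <- gold_s
      pred_sets[[i]] <- if (fatal) character(0) else pred_s
    }
    ds <- aif_dataset("fix", reports, annotations)
    m <- compute_metrics(ds, results)
    b <- brute_metrics(gold_lab, pred_lab, gold_sets, pred_sets)
    expect_equal(m$doc$precision, b$doc_precision)
    expect_equal(m$doc$recall, b$doc_recall)
    expect_equal(m$doc$f1, b$doc_f1)
    expect_equal(m$doc$accuracy, b$doc_accuracy)
    expect_identical(m$doc$confusion, b$confusion)
    expect_equal(m$sent$precision, b$sent_precision)
    expect_equal(m$sent$recall, b$sent_recall)
    expect_equal(m$sent$f1, b$sent_f1)
  }
})

test_that("aggregation gives the t-based confidence interval", {
  agg0 <- aggregate_runs(c(0.9, 0.9, 0.9))
  expect_equal(agg0$mean, 0.9)
  expect_equal(agg0$ci_half_width, 0)
  agg <- aggregate_runs(c(0.90, 0.91, 0.92))
  expect_equal(agg$mean, 0.91)
  expect_equal(agg$ci_half_width,
               stats::qt(0.975, df = 2) * stats::sd(c(0.90, 0.91, 0.92)) /
                 sqrt(3))
  expect_equal(agg$ci_half_width, 0.0248, tolerance = 2e-3)
  expect_error(aggregate_runs(0.9), "at least 2")
})

test_that("metrics objects aggregate per field and survive JSON round-trip", {
  ds <- tiny_dataset()
  res <- list(fake_result("r1", "Severe emphysema is seen in both lungs."),
              fake_result("r2", character(0)))
  m <- compute_metrics(ds, res)
  f <- withr::local_tempfile(fileext = ".json")
  write_metrics(m, f)
  m2 <- read_metrics(f)
  expect_equal(m2$doc$f1, m$doc$f1)
  expect_equal(m2$sent$tp, m$sent$tp)
  agg <- aggregate_runs(list(m, m2))
  expect_identical(nrow(agg), 7L)
  expect_true(all(agg$ci_half_width == 0))
})

test_that("Cohen's kappa matches hand-computed and null expectations", {
  a <- rep(c(1, 0), times = c(6, 4))
  expect_equal(cohens_kappa(a, a)$kappa, 1.0)

  # constructed table with p_o = 0.9, p_e = 0.5 -> kappa = 0.8
  a <- rep(c(1, 1, 0, 0), times = c(45, 5, 5, 45))
  b <- rep(c(1, 0, 1, 0), times = c(45, 5, 5, 45))
  k <- cohens_kappa(a, b)
  expect_equal(k$observed_agreement, 0.9)
  expect_equal(k$expected_agreement, 0.5)
  expect_equal(k$kappa, 0.8)

  set.seed(99)
  ra <- stats::rbinom(1e4, 1, 0.5)
  rb <- stats::rbinom(1e4, 1, 0.5)
  expect_lt(abs(cohens_kappa(ra, rb)$kappa), 0.05)
  expect_error(cohens_kappa(1:3, 1:2), "equal")
})

test_that("document accuracy degrades monotonically with label flips", {
  ds <- generate_dataset(internal_profile(120L, seed = 31L))
  tpl <- prompt_template("cot-json")
  acc <- vapply(c(0, 0.4, 0.8), function(rate) {
    accs <- vapply(1:2, function(s) {
      be <- oracle_backend(ds, "cot-json",
                           perturb = list(label_flip = rate))
      run <- run_extraction(ds, tpl, be, seed = s)
      compute_metrics(ds, run$results)$doc$accuracy
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_true(all(diff(acc) <= 0))
  expect_equal(acc[1], 1.0)
})

test_that("boundary-trim perturbation alone leaves all metrics at 1", {
  ds <- generate_dataset(internal_profile(60L, seed = 37L))
  tpl <- prompt_template("cot-json")
  be <- oracle_backend(ds, "cot-json", perturb = list(boundary_trim = 1))
  run <- run_extraction(ds, tpl, be, seed = 8L)
  m <- compute_metrics(ds, run$results)
  expect_equal(m$sent$f1, 1.0)
  expect_equal(m$doc$f1, 1.0)
  expect_equal(m$doc$accuracy, 1.0)
})
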