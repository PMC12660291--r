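#' Sentence bank for synthetic PET-CT lung-cancer reports
#'
#' Parameterised sentence templates in five disjoint categories:
#' actionable incidental findings (AIFs -- aortic aneurysm, incidental
#' nodules, *severe* emphysema, suspected synchronous malignancy),
#' non-actionable findings (mild/moderate emphysema, simple cysts,
#' degenerative change, mildly enlarged prostate), primary lung-cancer
#' disease statements, neutral per-region filler, and boilerplate.
#' Qualifier logic follows the clinical convention that an intensifying
#' qualifier ("severe") makes a finding actionable while diminishing or
#' neutral qualifiers ("mild", "moderate") do not.  Slots in angle
#' brackets (`<size>`, `<side>`, ...) are filled at generation time.
#' Region codes order sentences head (1) to legs (10) for the anatomical
#' reporting style.
#'
#' @return object of class `aif_sentence_bank`.
#' @export
default_sentence_bank <- function() {
  structure(list(
    aif = c(
      "There is severe emphysema throughout both lungs.",
      "Incidental <size> cm <side> adrenal nodule requires further characterisation.",
      "A <size> cm indeterminate nodule is seen in the <side> kidney.",
      "Infrarenal abdominal aortic aneurysm measuring <size> cm is noted.",
      "Focal avid uptake in the <colon> colon is suspicious for a synchronous primary malignancy.",
      "A <size> cm thyroid nodule with increased tracer uptake is present in the <side> lobe."
    ),
    aif_region = c(3L, 6L, 6L, 7L, 7L, 2L),
    non_aif = c(
      "Mild emphysema is noted in both upper lobes.",
      "Moderate emphysema is present bilaterally.",
      "A simple cyst is seen in the <side> kidney.",
      "Degenerative change is noted throughout the thoracic spine.",
      "The prostate is mildly enlarged.",
      "There is a small hiatus hernia.",
      "Mild coronary artery calcification is noted.",
      "A few tiny non-avid pulmonary nodules are too small to characterise."
    ),
    non_aif_region = c(3L, 3L, 6L, 5L, 8L, 5L, 4L, 3L),
    primary = c(
      "There is an intensely avid <size> cm mass in the <lobe> consistent with the known primary lung malignancy.",
      "The known <lobe> primary demonstrates intense FDG uptake.",
      "FDG-avid <side> hilar lymphadenopathy is in keeping with nodal disease."
    ),
    primary_region = c(3L, 3L, 4L),
    filler = c(
      "Physiological tracer uptake is seen in the brain.",
      "No suspicious focal uptake is identified in the head.",
      "No abnormal cervical lymphadenopathy is identified.",
      "Physiological uptake is noted in the laryngeal muscles.",
      "The remaining lung parenchyma is clear.",
      "No pleural effusion is identified.",
      "Background mediastinal blood pool activity is within normal limits.",
      "The cardiac silhouette is within normal limits.",
      "No pericardial effusion is seen.",
      "Vertebral body heights are preserved.",
      "No suspicious bone lesion is identified.",
      "A <msize> mm calcified granuloma is noted in the <lobe>.",
      "The liver demonstrates homogeneous physiological tracer distribution.",
      "The spleen and pancreas are unremarkable.",
      "Physiological excreted activity is noted in both renal collecting systems.",
      "No abnormal uptake is seen in the small or large bowel.",
      "No free fluid is identified in the abdomen or pelvis.",
      "The bladder shows physiological excreted activity.",
      "No pelvic lymphadenopathy is identified.",
      "Degenerative changes are noted in the <side> hip.",
      "No suspicious uptake is seen in the proximal femora.",
      "Visualised proximal lower limbs are unremarkable."
    ),
    filler_region = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 4L, 5L, 5L, 3L,
                      6L, 6L, 6L, 7L, 7L, 8L, 8L, 9L, 9L, 10L),
    boilerplate = list(
      clinical = "Clinical details: Known non-small cell lung cancer of the <lobe>, referred for staging.",
      technique = "Technique: Whole body FDG PET-CT from skull base to mid thigh following intravenous administration of <dose> MBq of FDG.",
      comparison = "Comparison: Correlation is made with the CT dated <date> from the referring centre.",
      interp_primary = "Appearances are in keeping with the known primary lung malignancy.",
      interp_closing = "No other significant abnormality is identified."
    )
  ), class = "aif_sentence_bank")
}

validate_sentence_bank <- function(bank) {
  for (cat in c("aif", "non_aif", "primary", "filler")) {
    if (!length(bank[[cat]])) {
      stop("sentence bank category '", cat, "' is empty", call. = FALSE)
    }
  }
  if (length(intersect(bank$aif, bank$non_aif))) {
    stop("aif and non_aif template sets must be disjoint", call. = FALSE)
  }
  invisible(bank)
}

# Fill <slot> placeholders with randomised clinically plausible values.
fill_slots <- function(template) {
  fills <- list(
    "<size>" = function() sprintf("%.1f", round(stats::runif(1, 1.2, 5.8), 1)),
    "<msize>" = function() as.character(sample(3:9, 1)),
    "<side>" = function() sample(c("left", "right"), 1),
    "<lobe>" = function() sample(c("right upper lobe", "right lower lobe",
                                   "left upper lobe", "left lower lobe"), 1),
    "<colon>" = function() sample(c("ascending", "transverse", "sigmoid"), 1),
    "<dose>" = function() as.character(sample(280:420, 1)),
    "<date>" = function() sprintf("%02d/%02d/%d", sample(1:28, 1),
                                  sample(1:12, 1), sample(2018:2025, 1))
  )
  out <- template
  for (slot in names(fills)) {
    while (grepl(slot, out, fixed = TRUE)) {
      out <- sub(slot, fills[[slot]](), fixed = TRUE, out)
    }
  }
  out
}

#' Define a synthetic dataset profile
#'
#' Target statistics a generated corpus must match: document-level
#' positive/negative ratio, mean whitespace-token length, mean AIF
#' sentences per report, and reporting style (`"priority"`: significant
#' findings first; `"anatomical"`: findings ordered head to legs).
#'
#' @param name profile name.
#' @param n_reports number of reports to generate (>= 1).
#' @param pos_neg_ratio target AIF-positive / AIF-negative report ratio.
#' @param mean_tokens target mean tokens per report (default tokenizer:
#'   whitespace tokens; see [profile_dataset()]).
#' @param mean_aif_sentences target mean AIF sentences per report.
#' @param style `"priority"` or `"anatomical"`.
#' @param seed integer seed making generation deterministic.
#' @param multi_ref_prob probability that a planted AIF is restated in the
#'   Interpretation section (a second gold sentence for the same finding).
#' @param numbered_list_prob probability that a report's findings section
#'   is rendered as a numbered list, exercising boundary normalization.
#' @return object of class `aif_profile`.
#' @export
dataset_profile <- function(name, n_reports, pos_neg_ratio, mean_tokens,
                            mean_aif_sentences, style = c("priority",
                                                          "anatomical"),
                            seed = 1L, multi_ref_prob = 0.3,
                            numbered_list_prob = 0.5) {
  assert_string(name, "name")
  assert_count(n_reports, "n_reports")
  style <- match.arg(style)
  if (!is.numeric(pos_neg_ratio) || pos_neg_ratio < 0 ||
      !is.finite(pos_neg_ratio)) {
    stop("pos_neg_ratio must be a finite non-negative number", call. = FALSE)
  }
  if (!is.numeric(mean_tokens) || mean_tokens <= 0) {
    stop("mean_tokens must be positive", call. = FALSE)
  }
  if (!is.numeric(mean_aif_sentences) || mean_aif_sentences < 0) {
    stop("mean_aif_sentences must be non-negative", call. = FALSE)
  }
  structure(
    list(name = name, n_reports = as.integer(n_reports),
         pos_neg_ratio = pos_neg_ratio, mean_tokens = mean_tokens,
         mean_aif_sentences = mean_aif_sentences, style = style,
         seed = as.integer(seed), multi_ref_prob = multi_ref_prob,
         numbered_list_prob = numbered_list_prob),
    class = "aif_profile"
  )
}

#' Internal-style dataset profile
#'
#' Priority-ordered reporting: positive/negative ratio 0.64, mean 392
#' tokens per report, mean 0.781 AIF sentences per report.
#'
#' @param n_reports number of reports.
#' @param seed integer seed.
#' @return an `aif_profile`.
#' @export
internal_profile <- function(n_reports = 500L, seed = 1L) {
  dataset_profile("internal", n_reports, pos_neg_ratio = 0.64,
                  mean_tokens = 392, mean_aif_sentences = 0.781,
                  style = "priority", seed = seed)
}

#' External-style dataset profile
#'
#' Anatomically ordered reporting: positive/negative ratio 1.64, mean
#' 570.3 tokens per report, mean 1.697 AIF sentences per report.
#'
#' @inheritParams internal_profile
#' @return an `aif_profile`.
#' @export
external_profile <- function(n_reports = 500L, seed = 1L) {
  dataset_profile("external", n_reports, pos_neg_ratio = 1.64,
                  mean_tokens = 570.3, mean_aif_sentences = 1.697,
                  style = "anatomical", seed = seed)
}

#' Read a dataset profile from a JSON config file
#'
#' @param path JSON file mirroring the [dataset_profile()] fields.
#' @return an `aif_profile`.
#' @export
read_profile <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  dataset_profile(
    name = cfg$name, n_reports = cfg$n_reports,
    pos_neg_ratio = cfg$pos_neg_ratio, mean_tokens = cfg$mean_tokens,
    mean_aif_sentences = cfg$mean_aif_sentences, style = cfg$style,
    seed = cfg$seed %||% 1L,
    multi_ref_prob = cfg$multi_ref_prob %||% 0.3,
    numbered_list_prob = cfg$numbered_list_prob %||% 0.5
  )
}

# Expected distinct AIFs per positive report implied by the profile.
aif_plan_params <- function(profile) {
  p_pos <- profile$pos_neg_ratio / (1 + profile$pos_neg_ratio)
  if (p_pos <= 0) return(list(p_pos = 0, lambda = 0))
  m_mean <- profile$mean_aif_sentences / (p_pos * (1 + profile$multi_ref_prob))
  list(p_pos = p_pos, lambda = max(0, m_mean - 1))
}

#' Generate one synthetic PET-CT report with its gold annotation
#'
#' Assembles Clinical details / Technique / Comparison / Findings /
#' Interpretation sections.  Positive reports plant `n_aif` distinct AIF
#' sentences in the findings; `n_restate` of them are restated in the
#' Interpretation section (same AIF clause verbatim, ending
#' " as noted above."), producing multi-reference gold annotations.  The
#' annotation lists every segmented sentence that references a planted AIF,
#' so gold sentences are verbatim substrings of the text by construction.
#' Priority style places primary-disease and AIF sentences first;
#' anatomical style orders all findings head to legs.  Neutral filler
#' sentences pad the report to a length target drawn around the profile
#' mean.
#'
#' @param profile an `aif_profile`.
#' @param bank an `aif_sentence_bank`.
#' @param is_positive logical; must the report contain AIFs?
#' @param seed integer seed; identical arguments give byte-identical output.
#' @param n_aif number of distinct AIFs (positives only; default drawn from
#'   the profile-implied Poisson plan).
#' @param n_restate how many planted AIFs are restated in the
#'   Interpretation (default drawn at `multi_ref_prob` per AIF).
#' @param numbered render the findings section as a numbered list (default
#'   drawn at `numbered_list_prob`).
#' @return list with elements `report` ([aif_report()]) and `annotation`
#'   ([aif_annotation()]).
#' @export
generate_report <- function(profile, bank = default_sentence_bank(),
                            is_positive = FALSE, seed = 1L, n_aif = NULL,
                            n_restate = NULL, numbered = NULL) {
  validate_sentence_bank(bank)
  with_seed(seed, {
    target <- max(60, round(stats::rnorm(1, profile$mean_tokens,
                                         0.10 * profile$mean_tokens)))
    if (is.null(numbered)) {
      numbered <- stats::runif(1) < profile$numbered_list_prob
    }
    if (is_positive) {
      if (is.null(n_aif)) {
        lambda <- aif_plan_params(profile)$lambda
        n_aif <- min(length(bank$aif), 1L + stats::rpois(1, lambda))
      }
      n_aif <- max(1L, min(as.integer(n_aif), length(bank$aif)))
      if (is.null(n_restate)) {
        n_restate <- stats::rbinom(1, n_aif, profile$multi_ref_prob)
      }
      n_restate <- max(0L, min(as.integer(n_restate), n_aif))
    } else {
      n_aif <- 0L
      n_restate <- 0L
    }

    aif_pick <- if (n_aif > 0) sample(seq_along(bank$aif), n_aif) else
      integer(0)
    aif_sent <- vapply(bank$aif[aif_pick], fill_slots, character(1),
                       USE.NAMES = FALSE)
    aif_core <- sub("\\.$", "", aif_sent)
    restate_pick <- if (n_restate > 0) sample.int(n_aif, n_restate) else
      integer(0)
    restate_sent <- paste0(aif_core[restate_pick], " as noted above.")

    n_nonaif <- 1L + stats::rpois(1, 1)
    nonaif_pick <- sample(seq_along(bank$non_aif),
                          min(n_nonaif, length(bank$non_aif)))
    nonaif_sent <- vapply(bank$non_aif[nonaif_pick], fill_slots,
                          character(1), USE.NAMES = FALSE)

    prim_pick <- sample(seq_along(bank$primary),
                        1L + (stats::runif(1) < 0.4))
    prim_sent <- vapply(bank$primary[prim_pick], fill_slots, character(1),
                        USE.NAMES = FALSE)

    clinical <- fill_slots(bank$boilerplate$clinical)
    technique <- fill_slots(bank$boilerplate$technique)
    comparison <- fill_slots(bank$boilerplate$comparison)

    interp <- c(bank$boilerplate$interp_primary, restate_sent,
                bank$boilerplate$interp_closing)

    findings <- data.frame(
      text = c(prim_sent, aif_sent, nonaif_sent),
      region = c(bank$primary_region[prim_pick], bank$aif_region[aif_pick],
                 bank$non_aif_region[nonaif_pick]),
      stringsAsFactors = FALSE
    )

    # pad with neutral filler until the whitespace-token target is reached;
    # numbered rendering adds one numeral token per findings-section sentence
    per_sent <- if (numbered) 1L else 0L
    base_tokens <- sum(count_tokens_ws(c(clinical, technique, comparison,
                                         findings$text, interp))) +
      2L +  # "Findings:" + "Interpretation:" headers
      per_sent * nrow(findings)
    filler_rows <- data.frame(text = character(0), region = integer(0),
                              stringsAsFactors = FALSE)
    total <- base_tokens
    repeat {
      cand_i <- sample(seq_along(bank$filler), 1)
      cand <- fill_slots(bank$filler[cand_i])
      cand_tokens <- count_tokens_ws(cand) + per_sent
      if (abs(total + cand_tokens - target) >= abs(total - target)) break
      filler_rows <- rbind(filler_rows,
                           data.frame(text = cand, region =
                                        bank$filler_region[cand_i],
                                      stringsAsFactors = FALSE))
      total <- total + cand_tokens
    }

    body <- rbind(findings, filler_rows)
    if (profile$style == "anatomical") {
      body <- body[order(body$region), , drop = FALSE]
    } else {
      # priority: keep findings (primary, AIF, non-AIF) first, filler after
      body <- rbind(findings, filler_rows)
    }

    body_sent <- body$text
    if (numbered) {
      body_sent <- paste0(seq_along(body_sent), ". ", body_sent)
    }

    blocks <- c(
      clinical, technique, comparison,
      paste("Findings:", paste(body_sent, collapse = " ")),
      paste("Interpretation:", paste(interp, collapse = " "))
    )
    text <- paste(blocks, collapse = " ")

    report_id <- sprintf("%s-%08d", profile$name, abs(seed) %% 1e8)
    sections <- local({
      counts <- vapply(blocks, function(b) length(segment_sentences(b)),
                       integer(1), USE.NAMES = FALSE)
      ends <- cumsum(counts)
      starts <- c(1L, utils::head(ends, -1) + 1L)
      list(`Clinical details` = c(starts[1], ends[1]),
           Technique = c(starts[2], ends[2]),
           Comparison = c(starts[3], ends[3]),
           Findings = c(starts[4], ends[4]),
           Interpretation = c(starts[5], ends[5]))
    })
    report <- aif_report(report_id, text, sections = sections)

    gold <- if (n_aif > 0) {
      hits <- vapply(report$sentences, function(s) {
        any(vapply(aif_core, grepl, logical(1), x = s, fixed = TRUE))
      }, logical(1), USE.NAMES = FALSE)
      report$sentences[hits]
    } else {
      character(0)
    }
    list(report = report,
         annotation = aif_annotation(report_id, gold, report = report))
  })
}

#' Generate a labelled synthetic dataset matching a profile
#'
#' Draws an exact positive count from the profile ratio, plans per-positive
#' AIF and restatement counts from a Poisson/Bernoulli scheme, then
#' quota-adjusts the plan so the corpus-total AIF sentence count matches
#' the profile target.  Per-report length targets are drawn around the
#' profile mean and met greedily, so realised means track the targets
#' closely.
#'
#' @param profile an `aif_profile`.
#' @param bank an `aif_sentence_bank`.
#' @return an [aif_dataset()] in which every report is annotated.
#' @export
generate_dataset <- function(profile, bank = default_sentence_bank()) {
  validate_sentence_bank(bank)
  n <- profile$n_reports
  params <- aif_plan_params(profile)
  n_pos <- round(n * params$p_pos)
  if (profile$mean_aif_sentences > 0 && n_pos == 0) {
    stop("infeasible profile: mean_aif_sentences > 0 requires positive ",
         "reports (pos_neg_ratio > 0)", call. = FALSE)
  }
  total_target <- round(n * profile$mean_aif_sentences)
  if (n_pos > 0 && total_target < n_pos) {
    stop("infeasible profile: mean_aif_sentences implies fewer than one ",
         "AIF sentence per positive report", call. = FALSE)
  }
  cap <- length(bank$aif)

  plan <- with_seed(profile$seed, {
    pos_flags <- sample(rep(c(TRUE, FALSE), c(n_pos, n - n_pos)))
    m <- pmin(cap, 1L + stats::rpois(n_pos, params$lambda))
    r <- stats::rbinom(n_pos, m, profile$multi_ref_prob)
    total <- sum(m + r)
    guard <- 0L
    while (total > total_target && guard < 10 * n + 100L) {
      guard <- guard + 1L
      cand <- which(r > 0)
      if (length(cand)) {
        i <- cand[sample.int(length(cand), 1)]
        r[i] <- r[i] - 1L
      } else {
        cand <- which(m > 1L)
        if (!length(cand)) break
        i <- cand[sample.int(length(cand), 1)]
        m[i] <- m[i] - 1L
      }
      total <- total - 1L
    }
    while (total < total_target && guard < 20 * n + 200L) {
      guard <- guard + 1L
      cand <- which(m < cap)
      if (!length(cand)) break
      i <- cand[sample.int(length(cand), 1)]
      m[i] <- m[i] + 1L
      total <- total + 1L
    }
    numbered <- stats::runif(n) < profile$numbered_list_prob
    list(pos_flags = pos_flags, m = m, r = r, numbered = numbered)
  })

  reports <- vector("list", n)
  annotations <- vector("list", n)
  pos_i <- 0L
  for (i in seq_len(n)) {
    is_pos <- plan$pos_flags[i]
    if (is_pos) pos_i <- pos_i + 1L
    gen <- generate_report(
      profile, bank, is_positive = is_pos,
      seed = profile$seed + i,
      n_aif = if (is_pos) plan$m[pos_i] else NULL,
      n_restate = if (is_pos) plan$r[pos_i] else NULL,
      numbered = plan$numbered[i]
    )
    # report ids derive from the per-report seed; make them positional
    rep <- gen$report
    id <- sprintf("%s-%05d", profile$name, i)
    rep <- aif_report(id, rep$text, sections = rep$sections)
    reports[[i]] <- rep
    annotations[[i]] <- aif_annotation(id, gen$annotation$aif_sentences,
                                       report = rep)
  }
  aif_dataset(profile$name, reports, annotations)
}

#' Realised statistics of a dataset
#'
#' @param dataset an [aif_dataset()]; every report must be annotated.
#' @param tokenizer function mapping a character vector of texts to token
#'   counts; defaults to whitespace tokens ([count_tokens_ws()]).  A
#'   model-specific tokenizer can be substituted through this hook.
#' @return list with `n`, `positives`, `negatives`, `pos_neg_ratio`
#'   (`Inf` when there are no negatives), `mean_tokens`,
#'   `mean_aif_sentences`.
#' @export
profile_dataset <- function(dataset, tokenizer = count_tokens_ws) {
  if (!length(dataset$reports)) stop("empty dataset", call. = FALSE)
  labels <- vapply(dataset$reports, function(r) {
    ann <- dataset$annotations[[r$report_id]]
    if (is.null(ann)) stop("report ", r$report_id, " is not annotated",
                           call. = FALSE)
    ann$doc_label
  }, character(1))
  n_aif <- vapply(dataset$reports, function(r) {
    length(dataset$annotations[[r$report_id]]$aif_sentences)
  }, integer(1))
  texts <- vapply(dataset$reports, function(r) r$text, character(1))
  positives <- sum(labels == "positive")
  negatives <- sum(labels == "negative")
  list(
    n = length(labels),
    positives = positives,
    negatives = negatives,
    pos_neg_ratio = if (negatives == 0) Inf else positives / negatives,
    mean_tokens = mean(tokenizer(texts)),
    mean_aif_sentences = mean(n_aif)
  )
}
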