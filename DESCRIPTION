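Package: aifpipe
Title: Actionable Incidental Finding Extraction and Evaluation for PET-CT
    Radiology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for building and evaluating a language-model pipeline
    that flags actionable incidental findings (AIFs) in free-text
    whole-body FDG PET-CT radiology reports.  Provides deterministic
    sentence segmentation and JSONL report/annotation input-output, a
    labelled synthetic report generator emulating priority-ordered and
    anatomically ordered reporting styles, chain-of-thought and standard
    prompt templating with JSON or free-text output formats, a hybrid
    decoding controller with rule-based artefact stripping, structured
    output validation and a null fallback, two-tier (document and
    sentence level) evaluation with edge normalization, multi-seed
    aggregation with t-based confidence intervals and Cohen's kappa, an
    automated soft/hard error taxonomy with grounding audit, and a
    validated QLoRA fine-tuning recipe with training-corpus emission.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
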