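---
title: "Methods: actionable incidental finding extraction and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: actionable incidental finding extraction and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aifpipe)
```

## The task and the model of it

Whole-body FDG PET-CT scans performed for cancer staging frequently reveal
*actionable incidental findings* (AIFs): abnormalities unrelated to the
indication for the scan -- an abdominal aortic aneurysm, an indeterminate
renal or adrenal nodule, severe emphysema, a suspected synchronous
malignancy -- that require clinical follow-up of their own. These findings
live only in the free-text radiology report, so surfacing them
automatically requires information extraction, not image analysis.

`aifpipe` models the extraction task exactly as an instruction-tuned
language model is asked to perform it:

* **Document level.** A report is *positive* if and only if it contains at
  least one AIF sentence. The label is always derived from the sentence
  list, never stored independently, so the two tiers cannot disagree.
* **Sentence level.** The extraction target is the set of verbatim report
  sentences describing AIFs. Sentence identity is by string, not by
  character offset: that is how generative models return evidence, and it
  makes *grounding* (every extracted sentence must occur in the source
  text) a checkable property.

The pipeline around that task has five testable stages: prompt
construction, decoding with structured-output validation, two-tier
evaluation, error taxonomy, and fine-tuning recipe emission -- plus a
synthetic report generator that makes every stage exercisable without
access to clinical data or a GPU.

## Sentence segmentation

No public tokenizer is canonical for radiology prose, and the evaluation
depends on reproducible boundaries, so segmentation is deliberately
rule-based and deterministic: split on terminal punctuation followed by
whitespace and a plausible sentence opener (capital, digit, opening
quote/bracket), with two guards. A period preceded by a purely numeric
token is treated as a numbered-list marker, so `"1. Incidental renal
nodule."` remains a single sentence including its numeral; and a short
abbreviation stop-list (`cm`, `mm`, `Dr`, `e.g.`, `vs`, ...) suppresses
false boundaries around measurements and titles. Segmentation is
idempotent and loss-free up to whitespace: concatenating the sentences
and collapsing whitespace reproduces the collapsed input. Where a learned
tokenizer would disagree with these rules, the evaluation-side edge
normalization (below) absorbs the difference; that division of labour is
the design.

## Decoding and the hybrid controller

Four decoding strategies are represented in `decoding_config()`: greedy,
nucleus (temperature and top-p), beam (a backend capability, passed
through rather than reimplemented), and the hybrid controller. Hybrid
decoding runs greedy first; if the output fails artefact stripping, JSON
parsing, or schema validation, it retries with nucleus sampling at
temperature = top-p = 0.5, each retry under a derived seed
(`seed + attempt - 1`) so fallback attempts differ deterministically.
After the attempt cap the controller returns a JSON-parsable *null*
answer -- no label, no sentences -- which downstream evaluation scores as
incorrect. The cap defaults to 6 because the five-attempt fallback limit
is read as five nucleus retries after the failed greedy attempt; the
other reading (five attempts in total) is one flag away
(`max_attempts = 5`).

The artefact parser (`strip_artefacts()`) removes code fences and returns
the first brace-balanced object span, tracking string and escape state so
braces inside JSON strings cannot truncate the payload. It is idempotent,
which the suite checks by fuzzing decorated payloads.

Two fixture backends make the controller testable without a model: a
*scripted* backend replays an explicit output sequence (for retry-path
tests), and a *gold-oracle* backend answers from the gold annotation with
configurable perturbations -- edge trimming, leading-word drops, artefact
wrapping, duplicate drops, grounded distractors, label flips, and planted
ungrounded sentences -- each applied with per-report seeded draws so every
end-to-end test has an exactly known expected score. An adapter for a
real LLM backend is intentionally out of the core surface: nothing in the
package downloads or runs a model.

## Evaluation

Document-level metrics are accuracy plus macro-averaged precision,
recall, and F1 over the positive and negative classes, with the full 2x2
confusion matrix retained. Sentence-level metrics are micro (pooled)
precision/recall/F1 over corpus-summed TP/FP/FN.

Before matching, both gold and predicted sentences are normalized by
stripping leading and trailing runs of whitespace, digits, and
punctuation (the ASCII set plus unicode dashes and curly quotes, frozen
in one constant). Interior content and case are untouched. This exactly
compensates boundary disagreements such as an omitted list numeral while
leaving the clinical content intact: the suite verifies that edge-only
perturbations on every positive report still score F1 = 1.

Three conventions are worth stating because the choice was genuinely
open:

* **Set semantics.** Sentences are deduplicated per report after
  normalization, on both sides. Duplicate-handling during matching is
  otherwise unspecified, and sets avoid double-crediting a repeated
  reference to the same finding.
* **Zero denominators.** Precision or recall with an empty denominator is
  defined as 0 (not NA), so an all-null run remains scoreable.
* **Null answers.** A fatal-null prediction is scored as the incorrect
  label against either gold label and contributes all its gold sentences
  as false negatives.

Multi-seed aggregation uses the arithmetic mean with a t-based 95%
confidence half-width, `qt(0.975, k-1) * sd / sqrt(k)` -- the appropriate
interval at k = 3 runs, where a normal interval would be anti-conservative.
Annotator agreement uses standard two-rater Cohen's kappa.

## Error taxonomy

Exact matching is a deliberate *lower bound* on performance, so the
package automates the qualitative split of residual mismatches into
*soft* errors (would not change clinical practice) and *hard* errors
(would). The cascade runs over each report's FP/FN sets, in an order that
tries soft explanations before hard ones:

1. `boundary_soft` -- an FP/FN pair where one normalized string contains
   the other (boundary disagreements beyond edge normalization, e.g. a
   dropped leading header word); pairs are consumed greedily by longest
   overlap, ties by report order.
2. `text_artefact_soft` -- an FP equal to a remaining FN after extended
   normalization (lowercase, interior whitespace collapsed).
3. `multiple_reference_soft` -- a remaining FN whose token-set Jaccard
   overlap with a matched gold sentence of the same report reaches 0.6:
   one missed mention of a finding the prediction did capture elsewhere.
4. `ungrounded` -- an FP absent from the report text (a hallucination).
5. Everything left is hard: `hard_false_positive` (which deliberately
   merges "contextual misinterpretation of actionability" with "not an
   AIF" -- separating those requires clinical judgement, not text) and
   `missed_aif_hard`.

The Jaccard threshold and cascade order are declared defaults with
overrides. `summarize_errors()` recomputes sentence metrics with soft
errors forgiven; by construction the adjusted metrics can never fall
below the unadjusted ones, and the gap measures how much exact matching
understates practical utility.

## The synthetic report generator

The generator emulates the two reporting styles whose contrast drives
the domain-shift question: an *internal* profile (findings ordered by
clinical priority; positive/negative ratio 0.64, mean 392 tokens per
report, mean 0.781 AIF sentences per report) and an *external* profile
(findings ordered anatomically head-to-legs; ratio 1.64, mean 570.3
tokens, mean 1.697 AIF sentences). Those six numbers are the generator's
fixed study conditions, not tuning knobs.

Mechanically, each report assembles Clinical details / Technique /
Comparison / Findings / Interpretation sections from disjoint sentence
banks. The AIF bank encodes only explicitly motivated exemplars
(aneurysm, incidental nodules, *severe* emphysema, suspected synchronous
malignancy); the non-AIF bank applies the qualifier rule in reverse
(*mild*/*moderate* emphysema, simple cysts, a mildly enlarged prostate as
the classic non-actionable distractor). Corpus statistics are met by
construction: the positive count is the rounded profile ratio; distinct
AIFs per positive follow a shifted Poisson whose mean is implied by the
AIF-sentence target, quota-adjusted so the corpus total lands on target;
and per-report token targets are drawn around the profile mean
(sd = 10%) and met by greedily adding neutral filler sentences while
doing so improves the fit.

Two generator behaviours exist purely to exercise downstream machinery,
with defaults chosen once so that any moderately sized corpus contains
both phenomena: a planted AIF is restated in the Interpretation section
with probability 0.3 (producing multi-reference gold annotations -- the
restatement repeats the AIF clause verbatim and appends "as noted
above.", keeping the two references distinct after normalization while
sharing well over the 0.6 token overlap), and a findings section is
rendered as a numbered list with probability 0.5 (exercising the
numeral-boundary normalization).

Token targets are counted as whitespace tokens by default. The reference
statistics were derived with a specific LLM tokenizer, which would
require a model download; `profile_dataset()` therefore takes a
tokenizer hook through which such a tokenizer can be substituted, and
the profile means are interpreted in whatever unit the hook counts.

What the generator does *not* model -- and therefore what passing tests
cannot show about clinical data: real reports have richer and noisier
language, patient-level correlation between reports (the generator's
reports are independent), genuinely ambiguous actionability, dictation
and OCR artefacts, and institution-specific section conventions. The
generator's role is to make pipeline properties (grounding, label
consistency, normalization sufficiency, metric correctness) testable
with exact expectations, not to stand in for clinical validation.

## Fine-tuning recipe

`default_finetune_config()` encodes the QLoRA recipe as data: 4-bit
quantisation, LoRA rank 16 and alpha 64, learning rate 2e-4 with linear
decay, three epochs, 8-bit AdamW, eight gradient-accumulation steps of
micro-batch one (effective batch size eight), with next-token prediction
over prompt, report, and target output. The LoRA target-module list is
not pinned by the recipe's source; the default is documented as all
attention projections and is overridable. Validation rejects
quantisation widths outside {4, 8, 16} and non-positive hyperparameters.
Executing the training run needs GPU tooling outside this package's
scope; the contract here is the validated recipe plus the training
corpus (`emit_training_corpus()`), every record of which round-trips
through the answer parser.

## Numerical and scale choices

Test and acceptance runs use corpus sizes of 80-500 reports: large
enough that realised corpus statistics sit well inside the +/-10%
(ratio) and +/-15% (means) recovery tolerances, and that every
perturbation class appears many times, while keeping the whole suite
fast on a single CPU. All randomness flows from explicit integer seeds;
generation, extraction, and the oracle's perturbation draws are
deterministic given (inputs, seed), which the suite checks
byte-for-byte. Known limitations: the segmenter's abbreviation list is
short and English-specific; the boundary-pair matcher in the taxonomy is
quadratic per report (fine at report scale); and free-text parsing
treats every non-empty line as a sentence, which is the intended
whitespace-parser semantics but cannot detect partial lines.
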