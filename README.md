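# aifpipe

Extraction and evaluation tooling for **actionable incidental findings
(AIFs)** in free-text FDG PET-CT radiology reports.

Staging PET-CT scans for lung cancer routinely surface findings unrelated
to the cancer itself — an abdominal aortic aneurysm, an indeterminate
renal or adrenal nodule, *severe* (but not *mild* or *moderate*)
emphysema, a suspected second primary — that need clinical follow-up of
their own and exist only in the report's prose. `aifpipe` implements the
full scaffolding for extracting them with an instruction-tuned language
model, and for evaluating that extraction honestly, on a single CPU and
with no clinical data: the model backends used in tests are a scripted
fixture and a gold-reading oracle with controlled error injection.

## What the pipeline computes

For a report *d* with gold AIF sentence set *G(d)* and predicted set
*P(d)* (both normalized by stripping leading/trailing whitespace,
digits, and punctuation, then deduplicated):

* **Document level** — label(d) = positive ⇔ the sentence set is
  non-empty; scored with accuracy, the 2×2 confusion matrix, and
  macro-averaged P/R/F1 over the positive and negative classes.
* **Sentence level** — micro P/R/F1 from corpus-pooled
  TP = |P∩G|, FP = |P∖G|, FN = |G∖P|.
* **Hybrid decoding** — greedy first; on invalid structured output,
  nucleus retries (temperature = top-p = 0.5) up to an attempt cap, then
  a JSON-parsable null answer scored as incorrect.
* **Error taxonomy** — residual FP/FN mismatches are classified into
  soft kinds (sentence-boundary, multiple-reference, text-artefact) and
  hard kinds (missed AIF, non-actionable extraction, ungrounded), and
  sentence metrics are recomputed with soft errors forgiven.
* **Aggregation** — mean ± t-based 95% CI half-width
  (`qt(.975, k−1)·sd/√k`) over multi-seed runs, and Cohen's kappa for
  annotator agreement.
* **QLoRA recipe** — the fine-tuning configuration (rank 16, alpha 64,
  4-bit quantisation, lr 2e-4 linear decay, 3 epochs, 8-bit AdamW,
  effective batch 8) as validated, serialisable data plus the
  prompt/target training corpus.

## Worked example

Generate an internal-style synthetic corpus, run extraction through the
gold oracle with a known error mix (30% of emitted sentences lose their
leading word, 10% of reports gain a grounded non-AIF distractor), score
it, and classify the errors:

```r
library(aifpipe)

ds  <- generate_dataset(internal_profile(200, seed = 42))
tpl <- prompt_template("cot-json")
be  <- oracle_backend(ds, "cot-json",
                      perturb = list(boundary_word_drop = 0.3,
                                     distractor_insert = 0.1))
run <- run_extraction(ds, tpl, be, seed = 42)
compute_metrics(ds, run$results)
#> Document level (macro):
#>   precision 0.943  recall 0.959  F1 0.949  accuracy 0.950
#>   confusion:          predicted +   predicted -
#>     gold positive          78             0
#>     gold negative          10           112
#> Sentence level (micro):
#>   precision 0.739  recall 0.833  F1 0.783  (TP 130, FP 46, FN 26)
#> Parsing errors: 0 retried, 0 fatal null

recs <- classify_errors_run(ds, run$results)
sm   <- summarize_errors(recs, ds, run$results)
sm$counts
#>           boundary_soft multiple_reference_soft      text_artefact_soft
#>                      26                       0                       0
#>     hard_false_positive         missed_aif_hard              ungrounded
#>                      20                       0                       0
c(unadjusted = sm$unadjusted$f1, adjusted = sm$adjusted$f1)
#> unadjusted   adjusted
#>  0.7831325  0.9404389
```

Reading the output: the word-drop perturbation produces matched FP/FN
pairs that exact matching penalises twice (26 boundary-soft pairs pull
sentence F1 down to 0.78), while the inserted distractors are genuine
hard false positives — 10 of them flip negative documents to positive,
which is exactly the document-level confusion shown. Forgiving the soft
errors recovers F1 = 0.94; the remaining gap is all hard error, as it
should be.

The same stages are scriptable from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","aifpipe.R",package="aifpipe"))')" \
  synth --profile internal --n 200 --seed 42 \
  --out reports.jsonl --gold gold.jsonl
```

with subcommands `synth`, `prompts`, `extract`, `evaluate`, `errors`,
`aggregate`, and `emit-train`; every artefact-producing command writes a
run manifest beside its output.

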