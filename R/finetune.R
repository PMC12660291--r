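#' Default QLoRA fine-tuning recipe
#'
#' The training configuration for adapting an instruction-tuned base model
#' to AIF extraction with 4-bit quantisation plus low-rank adapters:
#' rank 16, alpha 64, learning rate 2e-4 with linear decay, three epochs,
#' 8-bit AdamW, and eight gradient-accumulation steps of micro-batch one
#' (effective batch size eight).  The training objective is next-token
#' prediction over prompt, report, and target output.  Executing the
#' training run requires GPU tooling outside this package; the recipe and
#' the training corpus ([emit_training_corpus()]) are the testable
#' contract.
#'
#' @param base_model_id identifier of the base model to adapt.
#' @param prompt_strategy strategy key for the training prompts.
#' @param seed training seed.
#' @return object of class `aif_finetune_config`.
#' @export
default_finetune_config <- function(
    base_model_id = "meta-llama/Llama-3.1-8B-Instruct",
    prompt_strategy = "cot-json", seed = 0L) {
  validate_finetune_config(structure(
    list(
      lora_rank = 16L,
      lora_alpha = 64L,
      lora_target_modules = "all-attention-projections",
      quantisation_bits = 4L,
      learning_rate = 2e-4,
      lr_schedule = "linear_decay",
      epochs = 3L,
      optimiser = "adamw_8bit",
      gradient_accumulation_steps = 8L,
      micro_batch_size = 1L,
      base_model_id = base_model_id,
      prompt_strategy = as_strategy(prompt_strategy)$key,
      seed = as.integer(seed)
    ),
    class = "aif_finetune_config"
  ))
}

#' Validate a fine-tuning configuration
#'
#' Rejects non-positive hyperparameters, quantisation widths outside
#' \{4, 8, 16\} bits, and unknown schedules/strategies.
#'
#' @param config an `aif_finetune_config`.
#' @return the config, invisibly, or an error.
#' @export
validate_finetune_config <- function(config) {
  with(config, {
    if (lora_rank <= 0 || lora_alpha <= 0) {
      stop("lora_rank and lora_alpha must be positive", call. = FALSE)
    }
    if (!quantisation_bits %in% c(4L, 8L, 16L)) {
      stop("quantisation_bits must be one of 4, 8, 16", call. = FALSE)
    }
    if (learning_rate <= 0) stop("learning_rate must be positive",
                                 call. = FALSE)
    if (!identical(lr_schedule, "linear_decay")) {
      stop("unsupported lr_schedule: ", lr_schedule, call. = FALSE)
    }
    if (epochs <= 0 || gradient_accumulation_steps <= 0 ||
        micro_batch_size <= 0) {
      stop("epochs, gradient_accumulation_steps and micro_batch_size ",
           "must be positive", call. = FALSE)
    }
    as_strategy(prompt_strategy)
  })
  invisible(config)
}

#' Effective batch size of a fine-tuning configuration
#'
#' @param config an `aif_finetune_config`.
#' @return `gradient_accumulation_steps * micro_batch_size`.
#' @export
effective_batch_size <- function(config) {
  config$gradient_accumulation_steps * config$micro_batch_size
}

#' Serialise / parse a fine-tuning configuration
#'
#' @param config an `aif_finetune_config`.
#' @param path JSON file path.
#' @return `write_finetune_config`: `path` invisibly;
#'   `read_finetune_config`: the validated config.
#' @export
write_finetune_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_finetune_config
#' @export
read_finetune_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- structure(
    list(
      lora_rank = as.integer(x$lora_rank),
      lora_alpha = as.integer(x$lora_alpha),
      lora_target_modules = x$lora_target_modules,
      quantisation_bits = as.integer(x$quantisation_bits),
      learning_rate = x$learning_rate,
      lr_schedule = x$lr_schedule,
      epochs = as.integer(x$epochs),
      optimiser = x$optimiser,
      gradient_accumulation_steps =
        as.integer(x$gradient_accumulation_steps),
      micro_batch_size = as.integer(x$micro_batch_size),
      base_model_id = x$base_model_id,
      prompt_strategy = x$prompt_strategy,
      seed = as.integer(x$seed)
    ),
    class = "aif_finetune_config"
  )
  validate_finetune_config(cfg)
  cfg
}

#' Emit the fine-tuning corpus as input/target JSONL
#'
#' One record per report, in dataset order, built with
#' [build_training_example()]: `{"input": prompt, "target": gold answer}`.
#' Every report must be annotated.
#'
#' @param dataset an [aif_dataset()].
#' @param template an `aif_template`.
#' @param path output JSONL path.
#' @param negative_marker free-text negative marker.
#' @return number of records written, invisibly.
#' @export
emit_training_corpus <- function(dataset, template, path,
                                 negative_marker = "NONE") {
  if (!length(dataset$reports)) stop("empty dataset", call. = FALSE)
  records <- lapply(dataset$reports, function(r) {
    ann <- dataset$annotations[[r$report_id]]
    if (is.null(ann)) {
      stop("report ", r$report_id, " has no gold annotation",
           call. = FALSE)
    }
    build_training_example(r, ann, template, negative_marker)
  })
  write_jsonl(unname(records), path)
  invisible(length(records))
}
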