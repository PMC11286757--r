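# Ablation harness: train and evaluate the seven block combinations on
# identical splits and seeds.

ABLATION_VARIANTS <- list(
  "stem" = c(drdb = FALSE, glfeb = FALSE, csab = FALSE),
  "stem+drdb" = c(drdb = TRUE, glfeb = FALSE, csab = FALSE),
  "stem+drdb+csab" = c(drdb = TRUE, glfeb = FALSE, csab = TRUE),
  "stem+glfeb" = c(drdb = FALSE, glfeb = TRUE, csab = FALSE),
  "stem+glfeb+csab" = c(drdb = FALSE, glfeb = TRUE, csab = TRUE),
  "stem+drdb+glfeb" = c(drdb = TRUE, glfeb = TRUE, csab = FALSE),
  "ddrnet" = c(drdb = TRUE, glfeb = TRUE, csab = TRUE)
)

variant_config <- function(base_cfg, variant) {
  fl <- ABLATION_VARIANTS[[variant]]
  if (is.null(fl))
    stop(sprintf("unknown variant '%s'; valid variants: %s", variant,
                 paste(names(ABLATION_VARIANTS), collapse = ", ")))
  args <- unclass(base_cfg)
  args$use_drdb <- unname(fl["drdb"])
  args$use_glfeb <- unname(fl["glfeb"])
  args$use_csab <- unname(fl["csab"])
  do.call(model_config, args)
}

#' Run the block-ablation study
#'
#' Trains each requested architecture variant (block subsets of the full
#' network) on the identical data split with the identical seed and
#' reports train/test accuracy and trainable-parameter count per variant.
#'
#' @param data a [labeled_image_set()] with train/test split tags.
#' @param variants character vector of variant names among
#'   `names(ddrnet:::ABLATION_VARIANTS)`; default all seven.
#' @param cfg a [train_config()].
#' @param base_cfg the [model_config()] whose widths all variants share.
#' @param verbose print per-epoch progress.
#' @return Data frame with one row per variant: `variant`, `parameters`,
#'   `train_accuracy`, `test_accuracy`, `final_train_loss`.
#' @export
run_ablation <- function(data, variants = names(ABLATION_VARIANTS),
                         cfg = train_config(), base_cfg = model_config(),
                         verbose = FALSE) {
  rows <- lapply(variants, function(vn) {
    mcfg <- variant_config(base_cfg, vn)
    model <- ddrnet_init(mcfg, seed = cfg$seed)
    fit <- train_model(model, data, cfg, verbose = verbose)
    ev_test <- evaluate_model(fit$model, data, "test")
    ev_train <- evaluate_model(fit$model, data, "train")
    data.frame(variant = vn,
               parameters = count_parameters(fit$model),
               train_accuracy = ev_train$metrics$overall_accuracy,
               test_accuracy = ev_test$metrics$overall_accuracy,
               final_train_loss = tail(fit$history$train_loss, 1L))
  })
  do.call(rbind, rows)
}
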