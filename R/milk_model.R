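# Front end tying the dataset and network modules together: one network
# with four linear outputs (milk yield, protein, fat, concentrate
# intake) fitted on the normalized 21-input feature matrix.

#' Fit the milk-production model on an assembled feature matrix
#'
#' Splits the cow-day rows 70/30 (by default), normalizes inputs and
#' targets to `[-1, 1]` on the training rows, and trains a single
#' ten-hidden-neuron Bayesian-regularized network for all four targets.
#' The returned model carries the normalizers, the split and the frozen
#' column signature, so it can predict, be evaluated and be serialized
#' without external state.
#'
#' @param fm a `feature_matrix` with targets (see [assemble_features()]).
#' @param fraction training fraction of the row split.
#' @param seed seed driving both the split and the weight
#'   initialisation.
#' @param normalize_on `"train"` (default) or `"all"`; see
#'   [prepare_dataset()].
#' @param config a [train_config()]; its `seed` is overridden by `seed`.
#' @return an object of class `milk_model` (also `brann`) with the
#'   elements of [train_brann()] plus `norm_x`, `norm_t`, `split`,
#'   `signature`.
#' @export
fit_milk_model <- function(fm, fraction = 0.7, seed = 1L,
                           normalize_on = c("train", "all"),
                           config = train_config()) {
  normalize_on <- match.arg(normalize_on)
  ds <- prepare_dataset(fm, fraction, seed, normalize_on)
  config$seed <- seed
  model <- train_brann(ds$xn[ds$split$train, , drop = FALSE],
                       ds$tn[ds$split$train, , drop = FALSE],
                       config)
  model$norm_x <- ds$norm_x
  model$norm_t <- ds$norm_t
  model$split <- ds$split
  model$signature <- ds$signature
  class(model) <- c("milk_model", class(model))
  model
}

#' Predict the four production targets in original units
#'
#' @param model a fitted `milk_model`.
#' @param fm a `feature_matrix` (targets not required) whose signature
#'   matches the model's.
#' @return matrix with columns `milk_yield_kg`, `protein_pct`,
#'   `fat_pct`, `feed_intake_kg`.
#' @export
predict_targets <- function(model, fm) {
  stopifnot(inherits(model, "milk_model"), inherits(fm, "feature_matrix"))
  fm_sig <- strsplit(fm$signature, "|", fixed = TRUE)[[1]]
  mod_sig <- strsplit(model$signature, "|", fixed = TRUE)[[1]]
  if (!identical(fm_sig[seq_len(ncol(fm$inputs))],
                 mod_sig[seq_len(ncol(fm$inputs))])) {
    stop("predict_targets: feature-matrix column signature does not match the model",
         call. = FALSE)
  }
  xn <- apply_normalizer(model$norm_x, fm$inputs)
  yn <- forward(model, xn)
  y <- invert_normalizer(model$norm_t, yn)
  colnames(y) <- feature_target_cols
  y
}

#' Attainable pooled correlation given the generator's observation noise
#'
#' For synthetic cow-day records that retain their latent (noiseless)
#' target values, the pooled correlation between normalized latent and
#' observed targets is the ceiling no input-driven model can beat: it is
#' what a model that recovered the generative response exactly would
#' score. Computed on the given rows with the supplied target
#' normalizer so it is directly comparable to a model's pooled R.
#'
#' @param cow_days synthetic records carrying both observed and
#'   `latent_*` target columns, row-aligned with the feature matrix the
#'   model was fitted on.
#' @param norm_t the target normalizer of the fitted model.
#' @param rows row indices to evaluate on (e.g. the test rows).
#' @return pooled Pearson correlation.
#' @export
noise_ceiling_r <- function(cow_days, norm_t, rows = NULL) {
  latent_cols <- paste0("latent_", feature_target_cols)
  stopifnot(all(latent_cols %in% names(cow_days)))
  if (is.null(rows)) rows <- seq_len(nrow(cow_days))
  obs <- as.matrix(cow_days[rows, feature_target_cols])
  lat <- as.matrix(cow_days[rows, latent_cols])
  colnames(lat) <- feature_target_cols
  stats::cor(as.numeric(apply_normalizer(norm_t, lat)),
             as.numeric(apply_normalizer(norm_t, obs)))
}
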