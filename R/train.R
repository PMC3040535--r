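#' Training configuration
#'
#' @param residue_types Candidate residue letters (default S, T).
#' @param half_width Window half-width (default 12, i.e. 25-mers).
#' @param knn A [knn_config()].
#' @param bagging A [bagging_config()]; its seed is overridden by `seed`.
#' @param n_folds Cross-validation folds used to pool held-out negative
#'   scores for the calibration curve (default 5).
#' @param negative_policy Passed to [build_nonredundant_dataset()].
#' @param disorder_provider One of `"track_or_builtin"` (default: use a
#'   stored `"disorder"` track, fall back to the built-in heuristic),
#'   `"track"`, `"builtin"`, `"none"`.
#' @param reference_negative_cap Down-sample stored reference negatives to
#'   at most this many windows to keep models portable (default 20000).
#' @param seed Master seed for fold assignment, bagging subsampling and
#'   reference down-sampling.
#' @param name,comments Model metadata.
#' @param created Timestamp string stored in the model; defaults to the
#'   current time, pass a fixed value for reproducible archives.
#' @return Object of class `train_config`.
#' @export
train_config <- function(residue_types = c("S", "T"), half_width = 12L,
                         knn = knn_config(), bagging = bagging_config(),
                         n_folds = 5L,
                         negative_policy = "phosphoproteins_only",
                         disorder_provider = "track_or_builtin",
                         reference_negative_cap = 20000L, seed = 1L,
                         name = "unnamed model", comments = "",
                         created = NULL) {
  stopifnot(n_folds >= 2L, half_width >= 1L)
  structure(list(residue_types = sort(unique(residue_types)),
                 half_width = as.integer(half_width), knn = knn,
                 bagging = bagging, n_folds = as.integer(n_folds),
                 negative_policy = negative_policy,
                 disorder_provider = disorder_provider,
                 reference_negative_cap = as.integer(reference_negative_cap),
                 seed = as.integer(seed), name = name, comments = comments,
                 created = created),
            class = "train_config")
}

MODEL_FORMAT_VERSION <- 1L

#' Train a phosphorylation-site prediction model
#'
#' The full training pipeline: build a non-redundant window dataset,
#' compute features (KNN scores with leave-self-out, mean window disorder,
#' amino-acid frequencies), estimate the specificity calibration curve by
#' k-fold cross-validation (per fold, a bagging ensemble is trained on the
#' remaining folds and the held-out fold's negative scores are pooled),
#' then retrain the bagging ensemble on all data and package it together
#' with the feature configuration, the labelled reference windows needed to
#' recompute KNN features at prediction time, and the calibration curve.
#'
#' @param proteins List of annotated [protein()] objects (with disorder
#'   tracks, unless a provider is configured).
#' @param residue_types Overrides `config$residue_types` when given.
#' @param config A [train_config()].
#' @return Object of class `prediction_model`.
#' @export
phospred_train <- function(proteins, residue_types = NULL,
                         config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (!is.null(residue_types)) {
    config$residue_types <- sort(unique(residue_types))
  }
  proteins <- as_protein_list(proteins)
  ds <- build_nonredundant_dataset(proteins, config$residue_types,
                                   config$half_width,
                                   config$negative_policy)
  n_pos <- sum(ds$sites$label == "positive")
  if (n_pos < 30L) {
    stop("only ", n_pos, " positive sites: at least 30 required")
  }
  if (n_pos < 100L) {
    warning("only ", n_pos, " positive sites; model quality may be poor")
  }

  tracks <- lapply(proteins, resolve_disorder_track,
                   provider = config$disorder_provider)
  knn_cfg <- config$knn
  knn_cfg$exclude_self <- TRUE
  X <- compute_feature_matrix(ds$peptides, ds$sites, ds, knn_cfg,
                              tracks, config$half_width,
                              self_index = seq_along(ds$peptides))
  y <- ds$sites$label == "positive"

  # calibration by cross-validation: held-out negative scores only, so the
  # curve is never fitted to scores the final ensemble produced on its own
  # training examples
  n <- nrow(X)
  folds <- with_seed(round_seed(config$seed, 0L),
                     sample(rep_len(seq_len(config$n_folds), n)))
  neg_scores <- vector("list", config$n_folds)
  bag_cfg <- config$bagging
  for (f in seq_len(config$n_folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L) {
      stop("cross-validation fold ", f, " lost a class; dataset too small")
    }
    bag_cfg$seed <- round_seed(config$seed, f)
    ens_f <- train_bagging(X[tr, , drop = FALSE], y[tr], bag_cfg)
    ho <- which(!tr & !y)
    neg_scores[[f]] <- predict_bagging(ens_f, X[ho, , drop = FALSE])
  }
  curve <- calibration_curve(unlist(neg_scores, use.names = FALSE))

  bag_cfg$seed <- config$seed
  ensemble <- train_bagging(X, y, bag_cfg)
  ensemble$feature_layout <- feature_layout(config$knn$k_fractions)

  reference <- downsample_reference(ds, config$reference_negative_cap,
                                    round_seed(config$seed, 999L))
  structure(list(name = config$name, comments = config$comments,
                 residue_types = config$residue_types,
                 half_width = config$half_width,
                 knn_config = config$knn,
                 disorder_provider = config$disorder_provider,
                 ensemble = ensemble, calibration = curve,
                 reference = reference,
                 created = config$created %||%
                   format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                 format_version = MODEL_FORMAT_VERSION,
                 train_seed = config$seed),
            class = "prediction_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

downsample_reference <- function(ds, cap, seed) {
  neg <- which(ds$sites$label == "negative")
  if (length(neg) <= cap) return(ds)
  keep_neg <- sort(with_seed(seed, sample(neg, cap)))
  keep <- sort(c(which(ds$sites$label == "positive"), keep_neg))
  ds$sites <- ds$sites[keep, , drop = FALSE]
  rownames(ds$sites) <- NULL
  ds$peptides <- ds$peptides[keep]
  ds
}

#' @export
print.prediction_model <- function(x, ...) {
  cat(sprintf("<prediction_model '%s'> residues {%s}, %d-mer windows\n",
              x$name, paste(x$residue_types, collapse = ","),
              2L * x$half_width + 1L))
  cat(sprintf("  ensemble: %d x %s | reference: %d windows (%d positive)\n",
              length(x$ensemble$base_models),
              x$ensemble$config$base_learner,
              length(x$reference$peptides),
              sum(x$reference$sites$label == "positive")))
  cat(sprintf("  calibration: %d held-out negative scores | created %s\n",
              x$calibration$n, x$created))
  if (nzchar(x$comments)) cat("  comments: ", x$comments, "\n", sep = "")
  invisible(x)
}

#' Edit prediction-model metadata
#'
#' Renames and/or re-comments a model without touching the ensemble,
#' calibration curve or reference windows. Idempotent.
#'
#' @param model A [phospred_train()] model.
#' @param new_name,comments Optional replacements.
#' @return The edited model.
#' @export
model_edit <- function(model, new_name = NULL, comments = NULL) {
  stopifnot(inherits(model, "prediction_model"))
  if (!is.null(new_name)) model$name <- new_name
  if (!is.null(comments)) model$comments <- comments
  model
}

#' Save / load a prediction model archive
#'
#' The archive is a single RDS file holding the model list (metadata,
#' feature configuration, serialized ensemble, calibration scores and
#' reference windows). Saving the same model twice yields byte-identical
#' files.
#'
#' @param model A `prediction_model`.
#' @param path File path (conventionally `.mdl`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "prediction_model"))
  saveRDS(model, path, version = 3L)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "prediction_model")) stop("not a model archive")
  if (model$format_version > MODEL_FORMAT_VERSION) {
    stop("model format version ", model$format_version, " not supported")
  }
  model
}
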