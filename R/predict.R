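#' Predict phosphorylation sites in query proteins
#'
#' Enumerates every residue of the model's residue types in every query
#' protein, recomputes the model's features (KNN scores against the stored
#' reference windows, without self-exclusion; disorder via the stored track
#' or configured provider; amino-acid frequencies), scores sites with the
#' bagging ensemble, converts scores to estimated specificities via the
#' calibration curve, and flags sites passing the requested stringency.
#'
#' @param model A [phospred_train()] model (or a path loadable with
#'   [load_model()]).
#' @param query_proteins List of [protein()] objects (annotations not
#'   required).
#' @param stringency Requested specificity in (0, 1); default 0.95.
#' @return Object of class `prediction_result`: a data frame with columns
#'   accession, position, residue, score, est_specificity, passes, ordered
#'   by accession then position.
#' @export
phospred_classify <- function(model, query_proteins, stringency = 0.95) {
  if (is.character(model)) model <- load_model(model)
  stopifnot(inherits(model, "prediction_model"))
  query_proteins <- as_protein_list(query_proteins)
  site_list <- lapply(query_proteins, function(p) {
    s <- enumerate_candidate_sites(p, model$residue_types)
    s$label <- NULL
    s
  })
  sites <- do.call(rbind, site_list)
  thr <- threshold_for_stringency(model$calibration, stringency)
  if (is.null(sites) || nrow(sites) == 0L) {
    return(prediction_result(data.frame(
      accession = character(), position = integer(), residue = character(),
      score = numeric(), est_specificity = numeric(), passes = logical(),
      stringsAsFactors = FALSE), stringency, thr))
  }
  peptides <- unlist(lapply(query_proteins, function(p) {
    pos <- enumerate_candidate_sites(p, model$residue_types)$position
    vapply(pos, function(i) {
      extract_window(p$sequence, i, model$half_width)$peptide
    }, character(1))
  }), use.names = FALSE)
  tracks <- lapply(query_proteins, resolve_disorder_track,
                   provider = model$disorder_provider)
  knn_cfg <- model$knn_config
  knn_cfg$exclude_self <- FALSE
  X <- compute_feature_matrix(peptides, sites, model$reference, knn_cfg,
                              tracks, model$half_width)
  if (!layout_compatible(attr(X, "layout"), model$ensemble$feature_layout)) {
    stop("feature layout mismatch between query features and model")
  }
  score <- predict_bagging(model$ensemble, X)
  sites$score <- score
  sites$est_specificity <- estimate_specificity(model$calibration, score)
  sites$passes <- score >= thr
  ord <- order(sites$accession, sites$position, method = "radix")
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  prediction_result(sites, stringency, thr)
}

prediction_result <- function(df, stringency, threshold) {
  structure(df, class = c("prediction_result", "data.frame"),
            stringency = stringency, threshold = threshold)
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf(
    "<prediction_result> %d site(s), %d passing at stringency %.4g\n",
    nrow(x), sum(x$passes), attr(x, "stringency")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... ", nrow(x) - 10L, " more row(s)\n", sep = "")
  invisible(x)
}

#' Filter a prediction result
#'
#' Keeps rows whose estimated specificity reaches `min_specificity` and
#' (optionally) whose residue is in `residues`. Row order is preserved.
#'
#' @param result A [phospred_classify()] result.
#' @param min_specificity Minimum estimated specificity (default 0).
#' @param residues Optional residue letters to keep.
#' @return Filtered `prediction_result`.
#' @export
filter_predictions <- function(result, min_specificity = 0,
                               residues = NULL) {
  stopifnot(inherits(result, "prediction_result"))
  keep <- result$est_specificity >= min_specificity
  if (!is.null(residues)) keep <- keep & result$residue %in% residues
  out <- result[keep, , drop = FALSE]
  rownames(out) <- NULL
  prediction_result(out, attr(result, "stringency"),
                    attr(result, "threshold"))
}

#' Write / read a prediction table as TSV
#'
#' Deterministic tab-separated output with columns accession, position,
#' residue, score, est_specificity, passes; scores are printed with full
#' round-trip precision.
#'
#' @param result A `prediction_result`.
#' @param path Output path.
#' @return `write_predictions` returns `path` invisibly; `read_predictions`
#'   returns a data frame.
#' @export
write_predictions <- function(result, path) {
  df <- as.data.frame(result)
  df$score <- sprintf("%.17g", df$score)
  df$est_specificity <- sprintf("%.17g", df$est_specificity)
  df$passes <- ifelse(df$passes, "yes", "no")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df)) {
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$passes <- df$passes == "yes"
  df
}
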