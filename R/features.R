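feature_layout <- function(k_fractions) {
  list(knn = length(k_fractions), disorder = 1L, aa_freq = 20L,
       names = c(paste0("knn_", format(k_fractions, trim = TRUE,
                                       scientific = FALSE)),
                 "disorder", paste0("freq_", AA20)))
}

layout_compatible <- function(a, b) {
  identical(a$names, b$names)
}

#' Assemble the feature vector of one candidate site
#'
#' Fixed block order `[knn scores | disorder | amino-acid frequencies]`;
#' the layout is attached to the vector so a model can verify feature
#' compatibility at prediction time.
#'
#' @param window `SiteWindow` or peptide string.
#' @param reference `SiteDataset` of labelled reference windows.
#' @param config A [knn_config()].
#' @param track Per-residue disorder track of the source protein.
#' @param position 1-based site position in the source protein.
#' @param half_width Window half-width used for the disorder mean.
#' @param self_id Optional reference index for leave-self-out KNN.
#' @return Named numeric vector of length `length(k_fractions) + 1 + 20`
#'   with attribute `"layout"`.
#' @export
assemble_feature_vector <- function(window, reference, config, track,
                                    position, half_width,
                                    self_id = NULL) {
  v <- c(knn_scores(window, reference, config, self_id),
         disorder = disorder_feature(track, position, half_width),
         aa_frequencies(window))
  lay <- feature_layout(config$k_fractions)
  names(v) <- lay$names
  attr(v, "layout") <- lay
  v
}

# Feature matrix for all sites of a SiteDataset-like site table.
# `site_tracks` is a list of per-protein disorder tracks keyed by accession.
# `self_index` enables leave-self-out KNN for training-set features.
compute_feature_matrix <- function(peptides, sites, reference, config,
                                   site_tracks, half_width,
                                   self_index = NULL) {
  knn <- knn_score_matrix(peptides, reference$peptides,
                          reference$sites$label == "positive",
                          config$k_fractions, config$matrix,
                          self_index = self_index)
  dis <- vapply(seq_len(nrow(sites)), function(i) {
    disorder_feature(site_tracks[[sites$accession[i]]], sites$position[i],
                     half_width)
  }, numeric(1))
  freq <- t(vapply(peptides, aa_frequencies, numeric(20L),
                   USE.NAMES = FALSE))
  X <- cbind(knn, disorder = dis, freq)
  lay <- feature_layout(config$k_fractions)
  colnames(X) <- lay$names
  attr(X, "layout") <- lay
  X
}
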