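#' KNN feature configuration
#'
#' The KNN score of a candidate window, for a neighbourhood size k, is the
#' fraction of its k most similar labelled reference windows that are
#' positives. Neighbourhood sizes are expressed as fractions of the
#' reference-set size so that a model transfers across dataset scales:
#' `k = max(1, round(f * n_reference))` for each fraction `f` (after self
#' exclusion, if any).
#'
#' @param k_fractions Strictly increasing fractions in (0, 1].
#' @param matrix Symmetric 20 x 20 substitution matrix (default BLOSUM62).
#' @param exclude_self Leave-self-out flag used when scoring windows that
#'   are themselves part of the reference set (leakage guard during
#'   training).
#' @return Object of class `knn_config`.
#' @export
knn_config <- function(k_fractions = c(0.0025, 0.005, 0.01, 0.02, 0.04, 0.08),
                       matrix = default_substitution_matrix(),
                       exclude_self = FALSE) {
  stopifnot(is.numeric(k_fractions), length(k_fractions) >= 1L,
            all(k_fractions > 0), all(k_fractions <= 1),
            !is.unsorted(k_fractions, strictly = TRUE))
  structure(list(k_fractions = k_fractions,
                 matrix = extend_matrix(matrix)[AA20, AA20],
                 exclude_self = isTRUE(exclude_self)),
            class = "knn_config")
}

window_code_matrix <- function(peptides) {
  L <- nchar(peptides[[1]])
  if (!all(nchar(peptides) == L)) stop("windows of unequal length")
  matrix(aa_code(unlist(strsplit(peptides, "", fixed = TRUE))),
         ncol = L, byrow = TRUE)
}

# Sparse one-hot encoding over the 20 standard letters only: pads and
# non-standard letters get an all-zero row block, which realises the
# "contributes 0" similarity rule.
window_onehot <- function(codes) {
  n <- nrow(codes); L <- ncol(codes)
  std <- which(codes <= 20L)
  Matrix::sparseMatrix(
    i = ((std - 1L) %% n) + 1L,
    j = ((std - 1L) %/% n) * 20L + codes[std],
    x = 1, dims = c(n, 20L * L))
}

# Dense (20L x n_ref) representation of the reference windows premultiplied
# by the position-wise substitution matrix, so that a chunk of query
# similarities is a single sparse-dense product.
reference_sim_operator <- function(ref_codes, sub20) {
  L <- ncol(ref_codes)
  Bblock <- Matrix::bdiag(rep(list(Matrix::Matrix(sub20, sparse = TRUE)), L))
  Tr <- window_onehot(ref_codes) %*% Bblock
  t(as.matrix(Tr))
}

# Batch KNN scores: one row per query, one column per k fraction.
# self_index maps query rows to reference rows to exclude (NA = none).
knn_score_matrix <- function(query_peptides, ref_peptides, ref_positive,
                             k_fractions, sub20, self_index = NULL,
                             chunk_size = 1024L) {
  n_ref <- length(ref_peptides)
  n_q <- length(query_peptides)
  stopifnot(n_ref >= 1L, length(ref_positive) == n_ref)
  if (is.null(self_index)) self_index <- rep(NA_integer_, n_q)
  ref_codes <- window_code_matrix(ref_peptides)
  tTr <- reference_sim_operator(ref_codes, sub20)
  q_codes <- window_code_matrix(query_peptides)
  if (ncol(q_codes) != ncol(ref_codes)) stop("window length mismatch")

  out <- matrix(NA_real_, n_q, length(k_fractions))
  ref_pos_num <- as.numeric(ref_positive)
  for (start in seq(1L, n_q, by = chunk_size)) {
    idx <- start:min(n_q, start + chunk_size - 1L)
    S <- as.matrix(window_onehot(q_codes[idx, , drop = FALSE]) %*% tTr)
    for (j in seq_along(idx)) {
      sim <- S[j, ]
      self <- self_index[idx[j]]
      n_eff <- n_ref
      if (!is.na(self)) {
        sim[self] <- -Inf
        n_eff <- n_ref - 1L
      }
      if (n_eff < 1L) stop("reference empty after self-exclusion")
      ks <- pmax(1L, as.integer(round(k_fractions * n_eff)))
      # stable radix sort: ties keep ascending reference insertion order
      ord <- order(sim, decreasing = TRUE, method = "radix")
      cp <- cumsum(ref_pos_num[ord])
      out[idx[j], ] <- cp[ks] / ks
    }
  }
  colnames(out) <- paste0("knn_", format(k_fractions, trim = TRUE,
                                         scientific = FALSE))
  out
}

#' KNN scores of one query window against a labelled reference dataset
#'
#' For each configured k fraction, ranks the reference windows by descending
#' BLOSUM similarity to the query (ties broken by ascending reference
#' insertion order), takes the top `k = max(1, round(f * n))` and returns
#' the fraction of them that are labelled positive. With
#' `config$exclude_self` and a matching `self_id`, that reference window is
#' omitted before ranking (and `n` shrinks by one).
#'
#' @param query `SiteWindow` or peptide string.
#' @param reference A `SiteDataset` (see [build_nonredundant_dataset()]).
#' @param config A [knn_config()].
#' @param self_id Optional integer index of the query within the reference
#'   dataset.
#' @return Named numeric vector, one score in \[0, 1\] per k fraction.
#' @export
knn_scores <- function(query, reference, config = knn_config(),
                       self_id = NULL) {
  stopifnot(inherits(reference, "SiteDataset"),
            inherits(config, "knn_config"))
  if (length(reference$peptides) == 0L) stop("empty reference dataset")
  self_index <- NA_integer_
  if (config$exclude_self && !is.null(self_id)) {
    self_index <- as.integer(self_id)
  }
  drop(knn_score_matrix(window_peptide(query), reference$peptides,
                        reference$sites$label == "positive",
                        config$k_fractions, config$matrix,
                        self_index = self_index))
}
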