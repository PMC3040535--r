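# Shared fixtures and independent oracles for the test suite.

AA20_T <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

blosum62_20 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA20_T, AA20_T]
})

# Independent naive window similarity: explicit per-position lookup with the
# pad / non-standard-letter rule, no shared code with the package internals.
naive_similarity <- function(a, b, mat = blosum62_20) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  s <- 0
  for (i in seq_along(ca)) {
    if (ca[i] %in% AA20_T && cb[i] %in% AA20_T) {
      s <- s + mat[ca[i], cb[i]]
    }
  }
  s
}

# Brute-force KNN oracle: all similarities, full stable sort (ties broken
# by ascending insertion order), count positives among the top k for each
# fraction. `self` (optional index) is removed before ranking.
naive_knn <- function(query, ref_peps, ref_pos, k_fractions,
                      self = NA_integer_) {
  sims <- vapply(ref_peps, naive_similarity, numeric(1), a = query,
                 USE.NAMES = FALSE)
  keep <- seq_along(ref_peps)
  if (!is.na(self)) keep <- keep[-self]
  sims <- sims[keep]
  labs <- ref_pos[keep]
  ord <- order(-sims, seq_along(sims), method = "radix")
  vapply(k_fractions, function(f) {
    k <- max(1L, round(f * length(sims)))
    sum(labs[ord][seq_len(k)]) / k
  }, numeric(1))
}

random_peptide <- function(len, pad_left = 0L, pad_right = 0L) {
  core <- paste(sample(AA20_T, len - pad_left - pad_right, replace = TRUE),
                collapse = "")
  paste0(strrep("-", pad_left), core, strrep("-", pad_right))
}

# Random annotated protein with tracks, for round-trip property tests.
random_protein <- function(acc, min_len = 20L, max_len = 80L) {
  len <- sample(min_len:max_len, 1L)
  seq <- paste(sample(AA20_T, len, replace = TRUE), collapse = "")
  p <- protein(acc, seq,
               name = if (runif(1) < 0.5) paste("protein", acc)
                      else NA_character_)
  chars <- strsplit(seq, "")[[1]]
  st <- which(chars %in% c("S", "T", "Y"))
  if (length(st)) {
    n_ann <- sample(0:min(3L, length(st)), 1L)
    for (pos in sample(st, n_ann)) {
      p <- annotate_site(p, pos, chars[pos], "Phosphorylation",
                         source = sample(c("UniProt", "Phospho.ELM"), 1L),
                         status = sample(c("experimental", "probable",
                                           "potential", "by_similarity"),
                                         1L))
    }
  }
  if (runif(1) < 0.7) {
    p$tracks$disorder <- round(runif(len), 6)
  }
  p
}

# Small cached synthetic world shared by the train/predict tests (built
# once per test run; ~65 proteins keeps the whole suite fast).
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      prots <- generate_proteome(
        synthetic_config(n_proteins = 65, mean_length = 250, seed = 11))
      sp <- split_holdout(prots, 0.5, seed = 11)
      cfg <- train_config(seed = 11,
                          bagging = bagging_config(n_rounds = 5, seed = 11),
                          created = "1999-12-31T23:59:59")
      model <- suppressWarnings(phospred_train(sp$train, config = cfg))
      cache <<- list(proteins = prots, split = sp, config = cfg,
                     model = model)
    }
    cache
  }
})

as_plist <- function(x) {
  names(x) <- vapply(x, function(p) p$accession, character(1))
  x
}

test_labels <- function(proteins) {
  truth <- do.call(rbind, lapply(proteins, enumerate_candidate_sites))
  setNames(truth$label == "positive",
           paste(truth$accession, truth$position))
}
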