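# Background amino-acid composition (approximate UniProt/Swiss-Prot
# average frequencies), in AA20 order; renormalized at use.
BACKGROUND_AA_FREQ <- c(
  A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
  Q = 0.0393, E = 0.0674, G = 0.0708, H = 0.0227, I = 0.0593,
  L = 0.0965, K = 0.0582, M = 0.0241, F = 0.0386, P = 0.0472,
  S = 0.0660, T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0686)

#' Synthetic-proteome configuration
#'
#' States the simulated world used for end-to-end testing: random
#' background sequences, phosphosites planted on S/T at a fixed prevalence,
#' a kinase-like sequence motif (R at -3, P at +1 relative to the site)
#' carried by most positives and by a small fraction of negatives, and a
#' disorder track whose level is elevated around positive sites.
#'
#' @param n_proteins Number of proteins (default 200).
#' @param mean_length Mean sequence length, geometric spread above a
#'   minimum of 50 residues (default 400).
#' @param phospho_prevalence Fraction of S/T residues that are positives
#'   (default 0.05).
#' @param motif_strength Probability that a positive site carries the
#'   planted motif (default 0.8).
#' @param background_motif_rate Probability that a negative S/T site
#'   carries the motif (default 0.05).
#' @param disorder_pos,disorder_neg Mean disorder around positive sites and
#'   elsewhere (defaults 0.7 and 0.4).
#' @param disorder_sd Spread of both disorder components (default 0.15).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 200L, mean_length = 400L,
                             phospho_prevalence = 0.05,
                             motif_strength = 0.8,
                             background_motif_rate = 0.05,
                             disorder_pos = 0.7, disorder_neg = 0.4,
                             disorder_sd = 0.15, seed = 1L) {
  stopifnot(n_proteins >= 1L, mean_length > 60L,
            phospho_prevalence >= 0, phospho_prevalence <= 1,
            motif_strength >= 0, motif_strength <= 1,
            background_motif_rate >= 0, background_motif_rate <= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 mean_length = as.integer(mean_length),
                 phospho_prevalence = phospho_prevalence,
                 motif_strength = motif_strength,
                 background_motif_rate = background_motif_rate,
                 disorder_pos = disorder_pos, disorder_neg = disorder_neg,
                 disorder_sd = disorder_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic annotated proteome
#'
#' Produces proteins with Phosphorylation annotations (source
#' `"synthetic"`, status experimental) and a `"disorder"` track built from
#' a two-component model — values near `disorder_pos` in a +/-7 residue
#' neighbourhood of each positive site, near `disorder_neg` elsewhere —
#' smoothed with a width-11 moving average and clipped to \[0, 1\].
#'
#' @param config A [synthetic_config()].
#' @return Named list of [protein()] objects.
#' @export
generate_proteome <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_proteome_impl(config))
}

generate_proteome_impl <- function(cfg) {
  freq <- BACKGROUND_AA_FREQ / sum(BACKGROUND_AA_FREQ)
  proteins <- vector("list", cfg$n_proteins)
  for (i in seq_len(cfg$n_proteins)) {
    len <- 50L + rgeom(1L, 1 / (cfg$mean_length - 50L))
    chars <- sample(AA20, len, replace = TRUE, prob = freq)
    st <- which(chars %in% c("S", "T"))
    is_pos <- runif(length(st)) < cfg$phospho_prevalence
    pos_sites <- st[is_pos]
    neg_sites <- st[!is_pos]
    plant <- c(pos_sites[runif(length(pos_sites)) < cfg$motif_strength],
               neg_sites[runif(length(neg_sites)) <
                           cfg$background_motif_rate])
    # planting must never overwrite an annotated site's own residue
    for (s in plant) {
      if (s - 3L >= 1L && !((s - 3L) %in% pos_sites)) {
        chars[s - 3L] <- "R"
      }
      if (s + 1L <= len && !((s + 1L) %in% pos_sites)) {
        chars[s + 1L] <- "P"
      }
    }

    base <- rnorm(len, cfg$disorder_neg, cfg$disorder_sd)
    for (s in pos_sites) {
      idx <- max(1L, s - 7L):min(len, s + 7L)
      base[idx] <- rnorm(length(idx), cfg$disorder_pos, cfg$disorder_sd)
    }
    track <- pmin(1, pmax(0, moving_average(base, 11L)))

    p <- protein(sprintf("SYN%04d", i), paste(chars, collapse = ""),
                 name = sprintf("synthetic protein %d", i),
                 tracks = list(disorder = track))
    for (s in pos_sites) {
      p <- annotate_site(p, s, chars[s], "Phosphorylation",
                         source = "synthetic", status = "experimental")
    }
    proteins[[i]] <- p
  }
  as_protein_list(proteins)
}

moving_average <- function(x, width) {
  half <- (width - 1L) %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Protein-level train/test split
#'
#' Splits a protein collection at the protein level (no protein on both
#' sides), preventing near-duplicate window leakage across the split.
#'
#' @param proteins List of [protein()] objects.
#' @param fraction Fraction assigned to the training side, in (0, 1).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_holdout <- function(proteins, fraction = 0.5, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  proteins <- as_protein_list(proteins)
  n <- length(proteins)
  n_train <- round(fraction * n)
  idx <- with_seed(as.integer(seed), sample(n, n_train))
  list(train = proteins[sort(idx)],
       test = proteins[sort(setdiff(seq_len(n), idx))])
}
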