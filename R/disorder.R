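# Residue-level disorder propensity (TOP-IDP-like scale): positive values
# promote intrinsic disorder, negative values promote order.
DISORDER_PROPENSITY <- c(
  A = 0.060, R = 0.180, N = 0.007, D = 0.192, C = -0.020,
  Q = 0.318, E = 0.736, G = 0.166, H = 0.303, I = -0.486,
  L = -0.326, K = 0.586, M = -0.397, F = -0.697, P = 0.987,
  S = 0.341, T = 0.059, W = -0.884, Y = -0.510, V = -0.121)

#' Built-in heuristic disorder track
#'
#' A lightweight stand-in for an external disorder predictor: the
#' per-residue disorder propensity (a published composition scale; 0 used
#' for non-standard letters) is averaged over a sliding window of width 21
#' (clipped at the sequence ends) and passed through a logistic transform
#' `1 / (1 + exp(-steepness * mean))`, yielding scores in (0, 1) where
#' higher means more disordered.
#'
#' @param sequence Amino-acid string.
#' @param window Sliding-window width (odd, default 21).
#' @param steepness Logistic steepness (default 4).
#' @return Numeric vector of per-residue scores, same length as the
#'   sequence.
#' @export
default_disorder_track <- function(sequence, window = 21L, steepness = 4) {
  chars <- split1(toupper(sequence))
  prop <- DISORDER_PROPENSITY[chars]
  prop[is.na(prop)] <- 0
  n <- length(prop)
  if (n == 0L) return(numeric(0))
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(prop))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  avg <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  1 / (1 + exp(-steepness * avg))
}

#' Mean disorder over a site's window
#'
#' Arithmetic mean of the per-residue disorder track over the inclusive
#' window `[position - half_width, position + half_width]`, clipped at the
#' sequence ends (pads do not contribute).
#'
#' @param track Numeric per-residue track.
#' @param position 1-based centre position.
#' @param half_width Window half-width.
#' @return Single numeric value.
#' @export
disorder_feature <- function(track, position, half_width) {
  n <- length(track)
  position <- as.integer(position)
  if (position < 1L || position > n) stop("position out of track range")
  mean(track[max(1L, position - half_width):min(n, position + half_width)])
}

# Resolve the disorder track for one protein according to the provider
# policy: "track" uses a stored track only, "builtin" always computes the
# heuristic, "track_or_builtin" prefers a stored track and falls back to
# the heuristic, "none" refuses.
resolve_disorder_track <- function(protein, provider = "track_or_builtin",
                                   track_name = "disorder") {
  has <- track_name %in% names(protein$tracks)
  switch(provider,
    track = {
      if (!has) {
        stop("protein ", protein$accession, " has no '", track_name,
             "' track: run disorder prediction first ",
             "(e.g. add_disorder_tracks()) or configure a provider")
      }
      protein$tracks[[track_name]]
    },
    builtin = default_disorder_track(protein$sequence),
    track_or_builtin = {
      if (has) protein$tracks[[track_name]]
      else default_disorder_track(protein$sequence)
    },
    none = stop("no disorder provider configured: run disorder prediction ",
                "first (add_disorder_tracks()) to attach a '", track_name,
                "' track"),
    stop("unknown disorder provider: ", provider))
}

#' Attach heuristic disorder tracks to a protein collection
#'
#' Adds a `"disorder"` track (see [default_disorder_track()]) to every
#' protein that does not already carry one. Mirrors the usual
#' run-disorder-prediction-before-training step.
#'
#' @param proteins List of [protein()] objects.
#' @param overwrite Recompute even when a track is already present.
#' @return The updated protein list.
#' @export
add_disorder_tracks <- function(proteins, overwrite = FALSE) {
  proteins <- as_protein_list(proteins)
  for (i in seq_along(proteins)) {
    if (overwrite || !("disorder" %in% names(proteins[[i]]$tracks))) {
      proteins[[i]]$tracks$disorder <-
        default_disorder_track(proteins[[i]]$sequence)
    }
  }
  proteins
}
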