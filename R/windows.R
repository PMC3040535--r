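#' Extract a fixed-width sequence window around a residue
#'
#' The window covers inclusive positions `[position - half_width,
#' position + half_width]`; flanks that fall outside the sequence are padded
#' with `"-"` so the peptide always has length `2 * half_width + 1` and the
#' centre is always the residue at `position`.
#'
#' @param sequence Amino-acid string.
#' @param position 1-based centre position.
#' @param half_width Number of residues on each side of the centre.
#' @return Object of class `SiteWindow` with fields `peptide`,
#'   `half_width`, `center_index` (`half_width + 1`, 1-based) and `pad_mask`
#'   (logical, `TRUE` where padded).
#' @examples
#' extract_window("MSK", 2, 2)$peptide  # "-MSK-"
#' @export
extract_window <- function(sequence, position, half_width) {
  len <- nchar(sequence)
  position <- as.integer(position)
  if (position < 1L || position > len) {
    stop("window position ", position, " out of range 1..", len)
  }
  stopifnot(half_width >= 1L)
  lo <- position - half_width
  hi <- position + half_width
  core <- substr(sequence, max(1L, lo), min(len, hi))
  pep <- paste0(strrep(PAD, max(0L, 1L - lo)), core,
                strrep(PAD, max(0L, hi - len)))
  site_window(pep, half_width)
}

site_window <- function(peptide, half_width = (nchar(peptide) - 1L) %/% 2L) {
  stopifnot(nchar(peptide) == 2L * half_width + 1L)
  chars <- split1(peptide)
  if (chars[half_width + 1L] == PAD) {
    stop("window centre must not be the pad symbol")
  }
  structure(list(peptide = peptide, half_width = half_width,
                 center_index = half_width + 1L,
                 pad_mask = chars == PAD),
            class = "SiteWindow")
}

window_peptide <- function(w) {
  if (inherits(w, "SiteWindow")) w$peptide else as.character(w)
}

#' BLOSUM window similarity between two equal-length windows
#'
#' Sum over aligned positions of the substitution score of the two residues;
#' a position where either symbol is the pad `"-"` or a non-standard letter
#' (X, U, B, Z) contributes 0.
#'
#' @param a,b `SiteWindow` objects or plain peptide strings of equal length.
#' @param matrix Symmetric substitution matrix over the 20 standard letters
#'   (default BLOSUM62).
#' @return A single numeric score.
#' @examples
#' window_similarity("AC", "AC")  # 4 + 9 = 13 under BLOSUM62
#' @export
window_similarity <- function(a, b, matrix = default_substitution_matrix()) {
  a <- window_peptide(a); b <- window_peptide(b)
  if (nchar(a) != nchar(b)) stop("window length mismatch")
  ext <- extend_matrix(matrix)
  ca <- aa_code(split1(a)); cb <- aa_code(split1(b))
  sum(ext[cbind(ca, cb)])
}

# 25 x 25 matrix over AA_ALPHABET: the 20x20 block from `matrix`, zero rows
# and columns for X/U/B/Z and the pad symbol.
extend_matrix <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == 20L, ncol(matrix) == 20L)
  m <- matrix[AA20, AA20]
  if (!isTRUE(all.equal(m, t(m)))) stop("substitution matrix not symmetric")
  ext <- matrix(0, length(AA_ALPHABET), length(AA_ALPHABET),
                dimnames = list(AA_ALPHABET, AA_ALPHABET))
  ext[AA20, AA20] <- m
  ext
}

#' Amino-acid frequencies of a window
#'
#' Counts of each of the 20 standard letters over all non-pad positions
#' (centre included), divided by the number of positions counted.
#' Non-standard letters (X, U, B, Z) are excluded from both numerator and
#' denominator, so the result sums to 1 whenever the window holds at least
#' one standard residue.
#'
#' @param window `SiteWindow` or peptide string.
#' @return Named numeric vector of length 20 (order `A R N D ... V`).
#' @export
aa_frequencies <- function(window) {
  chars <- split1(window_peptide(window))
  chars <- chars[chars %in% AA20]
  out <- setNames(numeric(20L), AA20)
  if (length(chars)) {
    t <- table(factor(chars, levels = AA20))
    out[] <- as.numeric(t) / length(chars)
  }
  out
}
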