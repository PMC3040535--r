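#' Construct a protein record
#'
#' A `Protein` bundles an identified amino-acid sequence with its PTM
#' annotations and optional per-residue numeric score tracks (for example a
#' disorder track). Positions are 1-based throughout.
#'
#' @param accession Unique string identifier (e.g. a UniProt accession).
#' @param sequence Amino-acid string; lowercase input is uppercased. The 20
#'   standard letters plus `X`, `U`, `B`, `Z` are tolerated.
#' @param name Optional descriptive name.
#' @param annotations Annotation data frame as produced by
#'   [empty_annotations()]; normally populated through [annotate_site()].
#' @param tracks Named list of numeric vectors, each exactly as long as the
#'   sequence.
#' @return An object of class `Protein`.
#' @examples
#' p <- protein("P1", "MSTSY")
#' p <- annotate_site(p, 2, "S", source = "UniProt")
#' @export
protein <- function(accession, sequence, name = NA_character_,
                    annotations = empty_annotations(), tracks = list()) {
  stopifnot(is.character(accession), length(accession) == 1L,
            nzchar(accession))
  sequence <- toupper(sequence)
  bad <- setdiff(unique(split1(sequence)), c(AA20, AA_EXTRA))
  if (length(bad)) {
    stop("protein ", accession, ": invalid sequence letter(s): ",
         paste(bad, collapse = ", "))
  }
  p <- structure(
    list(accession = accession, name = name, sequence = sequence,
         annotations = annotations, tracks = tracks),
    class = "Protein")
  validate_protein(p)
}

#' @export
print.Protein <- function(x, ...) {
  cat(sprintf("<Protein %s> %d aa, %d annotation(s), %d track(s)\n",
              x$accession, nchar(x$sequence), nrow(x$annotations),
              length(x$tracks)))
  invisible(x)
}

#' Empty annotation table
#'
#' Annotations are stored as a data frame with one row per
#' (position, ptm_type) pair: `position` (1-based integer), `residue`
#' (single letter), `ptm_type` (canonical `"Phosphorylation"`), `status`
#' (one of experimental, probable, potential, by_similarity) and a
#' list-column `sources` of character vectors.
#'
#' @return Zero-row annotation data frame.
#' @export
empty_annotations <- function() {
  data.frame(position = integer(), residue = character(),
             ptm_type = character(), status = character(),
             sources = I(list()), stringsAsFactors = FALSE)
}

validate_protein <- function(p) {
  len <- nchar(p$sequence)
  a <- p$annotations
  if (nrow(a)) {
    if (any(a$position < 1L | a$position > len)) {
      stop("protein ", p$accession, ": annotation position out of range")
    }
    seq_chars <- split1(p$sequence)
    mism <- a$residue != seq_chars[a$position]
    if (any(mism)) {
      stop("protein ", p$accession, ": annotation residue mismatch at ",
           "position(s) ", paste(a$position[mism], collapse = ", "))
    }
    if (anyDuplicated(paste(a$position, a$ptm_type))) {
      stop("protein ", p$accession,
           ": duplicate (position, ptm_type) annotation")
    }
    if (any(lengths(a$sources) == 0L)) {
      stop("protein ", p$accession, ": annotation with empty source set")
    }
    if (!all(a$status %in% PTM_STATUSES)) {
      stop("protein ", p$accession, ": invalid annotation status")
    }
  }
  for (nm in names(p$tracks)) {
    if (length(p$tracks[[nm]]) != len) {
      stop("protein ", p$accession, ": track '", nm,
           "' length != sequence length")
    }
  }
  p
}

canonicalize_annotations <- function(a) {
  if (!nrow(a)) return(a)
  a$sources <- I(lapply(a$sources, function(s) sort(unique(s))))
  a <- a[order(a$position, a$ptm_type), , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' Add (or merge) a PTM annotation on a protein
#'
#' Adding the same (position, ptm_type) again is idempotent: source sets are
#' merged and the strongest status is kept
#' (experimental > probable > potential > by_similarity).
#'
#' @param protein A [protein()].
#' @param position 1-based residue position.
#' @param residue Expected residue letter; must match the sequence.
#' @param ptm_type PTM type label, canonical `"Phosphorylation"`.
#' @param source Annotation source string (e.g. `"UniProt"`).
#' @param status Annotation status, one of
#'   `c("experimental", "probable", "potential", "by_similarity")`.
#' @return The updated `Protein`.
#' @export
annotate_site <- function(protein, position, residue,
                          ptm_type = "Phosphorylation",
                          source = "unknown",
                          status = "experimental") {
  stopifnot(inherits(protein, "Protein"))
  status <- match.arg(status, PTM_STATUSES)
  position <- as.integer(position)
  len <- nchar(protein$sequence)
  if (position < 1L || position > len) {
    stop("protein ", protein$accession, ": position ", position,
         " out of range 1..", len)
  }
  residue <- unname(toupper(residue))
  actual <- substr(protein$sequence, position, position)
  if (actual != residue) {
    stop("protein ", protein$accession, ": inconsistent annotation at ",
         position, ": sequence has ", actual, ", annotation says ",
         residue)
  }
  a <- protein$annotations
  hit <- which(a$position == position & a$ptm_type == ptm_type)
  if (length(hit)) {
    a$sources[[hit]] <- sort(unique(c(a$sources[[hit]], source)))
    if (STATUS_RANK[[status]] > STATUS_RANK[[a$status[hit]]]) {
      a$status[hit] <- status
    }
  } else {
    a <- rbind(a, data.frame(position = position, residue = toupper(residue),
                             ptm_type = ptm_type, status = status,
                             sources = I(list(source)),
                             stringsAsFactors = FALSE))
  }
  protein$annotations <- canonicalize_annotations(a)
  protein
}

as_protein_list <- function(proteins) {
  if (inherits(proteins, "Protein")) proteins <- list(proteins)
  stopifnot(all(vapply(proteins, inherits, logical(1), "Protein")))
  names(proteins) <- vapply(proteins, `[[`, character(1), "accession")
  proteins
}

#' Merge PTM annotations from two protein collections
#'
#' Proteins are matched by accession; annotation sets are unioned with the
#' source-merging and status rules of [annotate_site()]. Proteins unique to
#' either input are retained. Score tracks are unioned by name (first input
#' wins on a name clash).
#'
#' @param primary,secondary Lists of [protein()] objects.
#' @return Named list of merged `Protein` objects (primary order first, then
#'   new accessions in secondary order).
#' @export
merge_annotations <- function(primary, secondary) {
  primary <- as_protein_list(primary)
  secondary <- as_protein_list(secondary)
  out <- primary
  for (acc in names(secondary)) {
    q <- secondary[[acc]]
    if (is.null(out[[acc]])) {
      out[[acc]] <- q
      next
    }
    p <- out[[acc]]
    if (!identical(p$sequence, q$sequence)) {
      stop("merge_annotations: accession ", acc,
           " has different sequences in the two inputs")
    }
    if (nrow(q$annotations)) {
      for (i in seq_len(nrow(q$annotations))) {
        row <- q$annotations[i, ]
        for (src in row$sources[[1]]) {
          p <- annotate_site(p, row$position, row$residue, row$ptm_type,
                             source = src, status = row$status)
        }
      }
    }
    if (is.na(p$name) && !is.na(q$name)) p$name <- q$name
    p$tracks <- c(p$tracks, q$tracks[setdiff(names(q$tracks),
                                             names(p$tracks))])
    out[[acc]] <- p
  }
  out
}

#' Enumerate candidate sites on a protein
#'
#' Every residue of a requested type is a candidate site. It is labelled
#' `positive` when a Phosphorylation annotation sits at that position and
#' `negative` otherwise; with `unlabeled_if_unannotated = TRUE` sites on a
#' protein carrying no phospho-annotation at all are labelled `unlabeled`
#' (negatives-from-phosphoproteins-only policy).
#'
#' @param protein A [protein()].
#' @param residue_types Character vector of residue letters (default S, T).
#' @param ptm_type PTM type defining positives.
#' @param unlabeled_if_unannotated See description.
#' @return Data frame with columns accession, position, residue, label, in
#'   ascending position order.
#' @export
enumerate_candidate_sites <- function(protein, residue_types = c("S", "T"),
                                      ptm_type = "Phosphorylation",
                                      unlabeled_if_unannotated = FALSE) {
  stopifnot(inherits(protein, "Protein"), length(residue_types) >= 1L)
  chars <- split1(protein$sequence)
  pos <- which(chars %in% residue_types)
  a <- protein$annotations
  ppos <- a$position[a$ptm_type == ptm_type]
  label <- ifelse(pos %in% ppos, "positive", "negative")
  if (unlabeled_if_unannotated && length(ppos) == 0L) {
    label[] <- "unlabeled"
  }
  data.frame(accession = rep(protein$accession, length(pos)),
             position = pos,
             residue = chars[pos],
             label = label,
             stringsAsFactors = FALSE)
}

#' Site statistics over a protein collection
#'
#' @param proteins List of [protein()] objects.
#' @param ptm_type PTM type to count (default `"Phosphorylation"`).
#' @return Object of class `SiteStatistics`: `n_proteins`,
#'   `n_phosphoproteins` (proteins with at least one annotation of
#'   `ptm_type`) and `per_residue_site_counts` (named integer vector).
#' @export
site_statistics <- function(proteins, ptm_type = "Phosphorylation") {
  proteins <- as_protein_list(proteins)
  counts <- integer(0)
  n_mod <- 0L
  for (p in proteins) {
    a <- p$annotations
    res <- a$residue[a$ptm_type == ptm_type]
    if (length(res)) {
      n_mod <- n_mod + 1L
      t <- table(res)
      for (r in names(t)) {
        counts[r] <- (if (r %in% names(counts)) counts[[r]] else 0L) +
          as.integer(t[[r]])
      }
    }
  }
  structure(list(n_proteins = length(proteins),
                 n_phosphoproteins = n_mod,
                 per_residue_site_counts =
                   if (length(counts)) counts[order(names(counts))]
                   else counts,
                 ptm_type = ptm_type),
            class = "SiteStatistics")
}

#' @export
print.SiteStatistics <- function(x, ...) {
  cat(sprintf("Site statistics (%s)\n", x$ptm_type))
  cat(sprintf("  proteins:              %d\n", x$n_proteins))
  cat(sprintf("  modified proteins:     %d\n", x$n_phosphoproteins))
  if (length(x$per_residue_site_counts)) {
    for (r in names(x$per_residue_site_counts)) {
      cat(sprintf("  sites on %s:            %d\n", r,
                  x$per_residue_site_counts[[r]]))
    }
  } else {
    cat("  sites:                 0\n")
  }
  invisible(x)
}
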