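#' Build a non-redundant site dataset from annotated proteins
#'
#' Enumerates candidate sites of the requested residue types, extracts their
#' sequence windows and then (a) collapses exact-duplicate window peptides
#' with equal labels to a single instance, (b) resolves peptides occurring
#' with both labels by keeping the positive and dropping the negative
#' (an unannotated site is an unverified absence, so a verified positive
#' dominates), and (c) under `negative_policy = "phosphoproteins_only"`
#' draws negatives only from proteins that carry at least one
#' phospho-annotation.
#'
#' @param proteins List of [protein()] objects.
#' @param residue_types Candidate residue letters (default S, T).
#' @param half_width Window half-width (default 12, i.e. 25-mers).
#' @param negative_policy `"phosphoproteins_only"` (default) or
#'   `"all_proteins"`.
#' @param ptm_type PTM type defining positives.
#' @return Object of class `SiteDataset`: `sites` (data frame accession /
#'   position / residue / label), `peptides` (parallel character vector of
#'   window peptides), `residue_types`, `half_width`.
#' @export
build_nonredundant_dataset <- function(proteins,
                                       residue_types = c("S", "T"),
                                       half_width = 12L,
                                       negative_policy =
                                         c("phosphoproteins_only",
                                           "all_proteins"),
                                       ptm_type = "Phosphorylation") {
  negative_policy <- match.arg(negative_policy)
  stopifnot(half_width >= 1L)
  proteins <- as_protein_list(proteins)
  site_list <- vector("list", length(proteins))
  pep_list <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    p <- proteins[[i]]
    s <- enumerate_candidate_sites(p, residue_types, ptm_type)
    if (negative_policy == "phosphoproteins_only" &&
        !any(p$annotations$ptm_type == ptm_type)) {
      s <- s[s$label == "positive", , drop = FALSE]  # always empty here
    }
    if (nrow(s)) {
      pep_list[[i]] <- vapply(s$position, function(pos) {
        extract_window(p$sequence, pos, half_width)$peptide
      }, character(1))
    } else {
      pep_list[[i]] <- character(0)
    }
    site_list[[i]] <- s
  }
  sites <- do.call(rbind, site_list)
  peptides <- unlist(pep_list, use.names = FALSE)
  if (is.null(sites) || !any(sites$label == "positive")) {
    stop("no positive sites for residue types ",
         paste(residue_types, collapse = ","),
         ": dataset is untrainable")
  }

  # label-conflict resolution: a peptide seen positive anywhere stays
  # positive only; then exact-duplicate (peptide, label) pairs collapse to
  # their first occurrence.
  pos_peps <- unique(peptides[sites$label == "positive"])
  drop_neg <- sites$label == "negative" & peptides %in% pos_peps
  sites <- sites[!drop_neg, , drop = FALSE]
  peptides <- peptides[!drop_neg]
  keep <- !duplicated(paste(peptides, sites$label))
  sites <- sites[keep, , drop = FALSE]
  peptides <- peptides[keep]
  rownames(sites) <- NULL

  structure(list(sites = sites, peptides = peptides,
                 residue_types = sort(unique(residue_types)),
                 half_width = as.integer(half_width)),
            class = "SiteDataset")
}

#' @export
print.SiteDataset <- function(x, ...) {
  cat(sprintf(
    "<SiteDataset> %d windows (%d positive / %d negative), %d-mers on {%s}\n",
    nrow(x$sites), sum(x$sites$label == "positive"),
    sum(x$sites$label == "negative"), 2L * x$half_width + 1L,
    paste(x$residue_types, collapse = ",")))
  invisible(x)
}
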