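#' Read a FASTA file into protein records
#'
#' The accession is the first whitespace-delimited token of each header;
#' any remainder becomes the protein name. Sequences are uppercased and
#' wrapped lines are concatenated.
#'
#' @param path FASTA file path.
#' @return Named list of [protein()] objects in file order (empty list for
#'   an empty file).
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0L) return(as_protein_list(list()))
  xs <- Biostrings::readBStringSet(path)
  headers <- names(xs)
  seqs <- unname(as.character(xs))
  proteins <- vector("list", length(xs))
  for (i in seq_along(xs)) {
    if (!nzchar(seqs[i])) {
      stop("FASTA record with empty sequence: ", headers[i])
    }
    tok <- regmatches(headers[i], regexpr("^\\S+", headers[i]))
    rest <- trimws(sub("^\\S+\\s*", "", headers[i]))
    proteins[[i]] <- protein(tok, toupper(seqs[i]),
                             name = if (nzchar(rest)) rest
                                    else NA_character_)
  }
  as_protein_list(proteins)
}

#' Write protein records to a FASTA file
#'
#' Headers are `>accession name` (name omitted when absent); sequence lines
#' wrap at 60 columns. `read_fasta(write_fasta(x))` reproduces accessions,
#' names and sequences exactly.
#'
#' @param proteins List of [protein()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  proteins <- as_protein_list(proteins)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (p in proteins) {
    hdr <- if (is.na(p$name)) p$accession else paste(p$accession, p$name)
    writeLines(paste0(">", hdr), con)
    n <- nchar(p$sequence)
    starts <- seq(1L, n, by = 60L)
    writeLines(substring(p$sequence, starts, pmin(starts + 59L, n)), con)
  }
  invisible(path)
}
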