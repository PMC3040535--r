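# PTM XML dialect (UTF-8, 1-based positions):
#   <ptmset>
#     <protein accession="..." name="...">
#       <sequence>MST...</sequence>
#       <ptm type="Phosphorylation" position="12" residue="S"
#            status="experimental"><source>UniProt</source>...</ptm>
#       <track name="disorder">0.41,0.44,...</track>
#     </protein>
#   </ptmset>

#' Read / write the PTM XML dialect
#'
#' The package's native annotation format: proteins with sequences, typed
#' PTM annotations (position, residue, status, source set) and named
#' per-residue score tracks. `read_ptm_xml(write_ptm_xml(x))` is the
#' identity on accessions, names, sequences, annotations and tracks.
#'
#' @param path XML file path.
#' @return Named list of [protein()] objects in document order.
#' @export
read_ptm_xml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "ptmset") {
    stop("not a PTM XML document (root must be <ptmset>)")
  }
  nodes <- xml2::xml_find_all(doc, "./protein")
  proteins <- lapply(nodes, function(node) {
    acc <- xml2::xml_attr(node, "accession")
    nm <- xml2::xml_attr(node, "name")
    seq <- gsub("\\s", "", xml2::xml_text(
      xml2::xml_find_first(node, "./sequence")))
    p <- protein(acc, seq, name = if (is.na(nm) || !nzchar(nm))
                                    NA_character_ else nm)
    for (ptm in xml2::xml_find_all(node, "./ptm")) {
      pos <- as.integer(xml2::xml_attr(ptm, "position"))
      res <- xml2::xml_attr(ptm, "residue")
      type <- xml2::xml_attr(ptm, "type")
      status <- xml2::xml_attr(ptm, "status")
      sources <- xml2::xml_text(xml2::xml_find_all(ptm, "./source"))
      if (!length(sources)) sources <- "unknown"
      ok <- try(for (src in sources) {
        p <- annotate_site(p, pos, res, type, src, status)
      }, silent = TRUE)
      if (inherits(ok, "try-error")) {
        stop("invalid annotation in ", acc, " at position ", pos, ": ",
             attr(ok, "condition")$message)
      }
    }
    for (tr in xml2::xml_find_all(node, "./track")) {
      vals <- as.numeric(strsplit(xml2::xml_text(tr), ",", fixed = TRUE)[[1]])
      tname <- xml2::xml_attr(tr, "name")
      if (length(vals) != nchar(p$sequence)) {
        stop("track '", tname, "' on ", acc, " has wrong length")
      }
      p$tracks[[tname]] <- vals
    }
    p
  })
  as_protein_list(proteins)
}

#' @rdname read_ptm_xml
#' @param proteins List of [protein()] objects.
#' @export
write_ptm_xml <- function(proteins, path) {
  proteins <- as_protein_list(proteins)
  doc <- xml2::xml_new_root("ptmset")
  for (p in proteins) {
    node <- xml2::xml_add_child(doc, "protein", accession = p$accession)
    if (!is.na(p$name)) xml2::xml_set_attr(node, "name", p$name)
    xml2::xml_add_child(node, "sequence", p$sequence)
    a <- p$annotations
    for (i in seq_len(nrow(a))) {
      ptm <- xml2::xml_add_child(node, "ptm", type = a$ptm_type[i],
                                 position = as.character(a$position[i]),
                                 residue = a$residue[i],
                                 status = a$status[i])
      for (src in a$sources[[i]]) xml2::xml_add_child(ptm, "source", src)
    }
    for (tname in names(p$tracks)) {
      xml2::xml_add_child(node, "track",
                          paste(sprintf("%.17g", p$tracks[[tname]]),
                                collapse = ","),
                          name = tname)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

UNIPROT_PHOSPHO_RESIDUE <- c(Phosphoserine = "S", Phosphothreonine = "T",
                             Phosphotyrosine = "Y")

#' Convert UniProt XML entries to annotated proteins
#'
#' Each `<entry>` becomes one protein keyed by its primary accession. Every
#' `modified residue` feature whose description starts with "Phospho"
#' yields a Phosphorylation annotation (residue inferred from
#' Phosphoserine/-threonine/-tyrosine and checked against the sequence);
#' other modified residues are retained with the description text as their
#' PTM type. Evidence qualifiers in the description map to statuses:
#' `"; by similarity"`, `"; probable"`, `"; potential"`, none =
#' experimental. Annotations whose status is outside `status_filter` are
#' dropped; residue/description disagreements are skipped with a warning
#' and counted in the `"skipped"` attribute of the result.
#'
#' @param path UniProt XML file.
#' @param status_filter Statuses to keep (default: all four).
#' @return Named list of [protein()] objects with a `"skipped"` attribute.
#' @export
convert_uniprot_xml <- function(path, status_filter = PTM_STATUSES) {
  status_filter <- match.arg(status_filter, PTM_STATUSES,
                             several.ok = TRUE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  entries <- xml2::xml_find_all(doc, "//entry")
  skipped <- 0L
  proteins <- lapply(entries, function(entry) {
    acc <- xml2::xml_text(xml2::xml_find_first(entry, "./accession"))
    nm <- xml2::xml_text(xml2::xml_find_first(entry, "./name"))
    seq <- gsub("\\s", "", xml2::xml_text(
      xml2::xml_find_first(entry, "./sequence")))
    p <- protein(acc, seq, name = if (is.na(nm)) NA_character_ else nm)
    feats <- xml2::xml_find_all(entry,
                                "./feature[@type='modified residue']")
    for (f in feats) {
      desc <- xml2::xml_attr(f, "description")
      pos <- as.integer(xml2::xml_attr(
        xml2::xml_find_first(f, "./location/position"), "position"))
      if (is.na(pos) || is.na(desc)) next
      status <- uniprot_status(desc)
      base <- sub(";.*$", "", desc)
      if (startsWith(base, "Phospho")) {
        res <- UNIPROT_PHOSPHO_RESIDUE[base]
        if (is.na(res)) {
          warning("unrecognized phospho description '", desc, "' on ",
                  acc, "; skipped")
          skipped <<- skipped + 1L
          next
        }
        if (!(status %in% status_filter)) next
        ok <- try(annotate_site(p, pos, res, "Phosphorylation",
                                source = "UniProt", status = status),
                  silent = TRUE)
      } else {
        if (!(status %in% status_filter)) next
        actual <- substr(p$sequence, pos, pos)
        ok <- try(annotate_site(p, pos, actual, base, source = "UniProt",
                                status = status), silent = TRUE)
      }
      if (inherits(ok, "try-error")) {
        warning("annotation '", desc, "' at ", pos, " on ", acc,
                " disagrees with the sequence; skipped")
        skipped <<- skipped + 1L
      } else {
        p <- ok
      }
    }
    p
  })
  out <- as_protein_list(proteins)
  attr(out, "skipped") <- skipped
  out
}

uniprot_status <- function(desc) {
  d <- tolower(desc)
  if (grepl("by similarity", d, fixed = TRUE)) return("by_similarity")
  if (grepl("probable", d, fixed = TRUE)) return("probable")
  if (grepl("potential", d, fixed = TRUE)) return("potential")
  "experimental"
}

#' Read a Phospho.ELM-style tab-delimited report
#'
#' Expects a header line; required columns (configurable via `columns`):
#' `acc` (accession), `sequence`, `position`, `code` (residue letter). One
#' Phosphorylation annotation per row, source `"Phospho.ELM"`, status
#' experimental. Rows whose residue disagrees with the sequence are skipped
#' with a warning and counted in the `"skipped"` attribute.
#'
#' @param path TSV file path.
#' @param columns Named mapping from the canonical roles `acc`, `sequence`,
#'   `position`, `code` to the file's column names.
#' @return Named list of [protein()] objects with a `"skipped"` attribute.
#' @export
read_phosphoelm_report <- function(path,
                                   columns = c(acc = "acc",
                                               sequence = "sequence",
                                               position = "position",
                                               code = "code")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    out <- as_protein_list(list())
    attr(out, "skipped") <- 0L
    return(out)
  }
  missing_cols <- setdiff(unname(columns), colnames(df))
  if (length(missing_cols)) {
    stop("report is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  proteins <- list()
  skipped <- 0L
  for (i in seq_len(nrow(df))) {
    acc <- as.character(df[[columns[["acc"]]]][i])
    seq <- toupper(as.character(df[[columns[["sequence"]]]][i]))
    pos <- as.integer(df[[columns[["position"]]]][i])
    code <- toupper(as.character(df[[columns[["code"]]]][i]))
    if (is.null(proteins[[acc]])) proteins[[acc]] <- protein(acc, seq)
    ok <- try(annotate_site(proteins[[acc]], pos, code, "Phosphorylation",
                            source = "Phospho.ELM",
                            status = "experimental"), silent = TRUE)
    if (inherits(ok, "try-error")) {
      warning("row ", i, " (", acc, " position ", pos,
              "): residue mismatch; skipped")
      skipped <- skipped + 1L
    } else {
      proteins[[acc]] <- ok
    }
  }
  out <- as_protein_list(proteins)
  attr(out, "skipped") <- skipped
  out
}
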