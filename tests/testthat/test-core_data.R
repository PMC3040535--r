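test_that("candidate-site enumeration scans residues in order with labels", {
  p <- protein("p1", "MSTSY")
  s <- enumerate_candidate_sites(p, c("S", "T"))
  expect_equal(s$position, c(2L, 3L, 4L))
  expect_equal(s$residue, c("S", "T", "S"))
  expect_equal(s$label, rep("negative", 3))

  expect_equal(nrow(enumerate_candidate_sites(protein("p2", "MKR"),
                                              c("S", "T"))), 0L)

  p <- annotate_site(p, 2, "S", source = "UniProt")
  s <- enumerate_candidate_sites(p, c("S", "T"))
  expect_equal(s$label, c("positive", "negative", "negative"))

  # unlabeled policy applies only to proteins with no phospho-annotation
  q <- protein("p3", "MSTSY")
  expect_equal(unique(enumerate_candidate_sites(
    q, c("S", "T"), unlabeled_if_unannotated = TRUE)$label), "unlabeled")
})

test_that("annotate_site is idempotent, merges sources, keeps strongest status", {
  p <- protein("p1", "MSK")
  p <- annotate_site(p, 2, "S", source = "UniProt",
                     status = "by_similarity")
  expect_equal(nrow(p$annotations), 1L)
  p2 <- annotate_site(p, 2, "S", source = "UniProt",
                      status = "by_similarity")
  expect_identical(p2$annotations, p$annotations)

  p3 <- annotate_site(p, 2, "S", source = "Phospho.ELM",
                      status = "experimental")
  expect_equal(nrow(p3$annotations), 1L)
  expect_setequal(p3$annotations$sources[[1]], c("UniProt", "Phospho.ELM"))
  expect_equal(p3$annotations$status, "experimental")

  # weaker status never downgrades
  p4 <- annotate_site(p3, 2, "S", source = "x", status = "potential")
  expect_equal(p4$annotations$status, "experimental")

  expect_error(annotate_site(p, 1, "S"), "inconsistent")
  expect_error(annotate_site(p, 9, "S"), "out of range")
})

test_that("merge_annotations unions sites and keeps proteins unique to either side", {
  a <- annotate_site(protein("P1", "MSTSYKT"), 2, "S", source = "UniProt")
  b <- annotate_site(protein("P1", "MSTSYKT"), 7, "T",
                     source = "Phospho.ELM")
  only_b <- annotate_site(protein("P9", "MSK"), 2, "S", source = "Phospho.ELM")

  m <- merge_annotations(list(a), list(b, only_b))
  expect_setequal(names(m), c("P1", "P9"))
  expect_equal(m$P1$annotations$position, c(2L, 7L))
  expect_identical(m$P9$annotations, only_b$annotations)

  # same site from two sources -> one annotation, two sources
  b2 <- annotate_site(protein("P1", "MSTSYKT"), 2, "S",
                      source = "Phospho.ELM")
  m2 <- merge_annotations(list(a), list(b2))
  expect_equal(nrow(m2$P1$annotations), 1L)
  expect_setequal(m2$P1$annotations$sources[[1]],
                  c("UniProt", "Phospho.ELM"))

  expect_error(
    merge_annotations(list(protein("P1", "MSK")),
                      list(protein("P1", "MSR"))), "P1")
})

test_that("merge order does not change the final annotation set", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      a <- random_protein("PX")
      b <- random_protein("PX")
      b$sequence <- a$sequence
      b$annotations <- empty_annotations()
      chars <- strsplit(a$sequence, "")[[1]]
      sty <- which(chars %in% c("S", "T", "Y"))
      for (pos in head(sty, 2)) {
        b <- annotate_site(b, pos, chars[pos], source = "srcB",
                           status = "probable")
      }
      ab <- merge_annotations(list(a), list(b))$PX$annotations
      ba <- merge_annotations(list(b), list(a))$PX$annotations
      expect_equal(ab, ba)
    }
  })
})

test_that("site_statistics matches a brute-force recount", {
  p1 <- protein("A", "MSSTY")
  p1 <- annotate_site(p1, 2, "S")
  p1 <- annotate_site(p1, 3, "S")
  p1 <- annotate_site(p1, 4, "T")
  p2 <- protein("B", "MKK")
  st <- site_statistics(list(p1, p2))
  expect_equal(st$n_proteins, 2L)
  expect_equal(st$n_phosphoproteins, 1L)
  expect_equal(st$per_residue_site_counts, c(S = 2L, T = 1L))

  empty <- site_statistics(list())
  expect_equal(empty$n_proteins, 0L)
  expect_equal(empty$n_phosphoproteins, 0L)
  expect_length(empty$per_residue_site_counts, 0L)

  # brute-force recount over random proteins
  withr::with_seed(7, {
    prots <- lapply(sprintf("R%02d", 1:8), random_protein)
    st <- site_statistics(prots)
    ann <- do.call(rbind, lapply(prots, function(p) p$annotations))
    ann <- ann[ann$ptm_type == "Phosphorylation", ]
    expect_equal(sum(st$per_residue_site_counts), nrow(ann))
    for (r in names(st$per_residue_site_counts)) {
      expect_equal(st$per_residue_site_counts[[r]], sum(ann$residue == r))
    }
  })
})

test_that("non-redundant dataset dedupes, resolves conflicts, applies policy", {
  # identical positive windows in two proteins collapse to one instance;
  # flanking context is identical by construction
  ctx <- "AAAAAAAAAAAA"
  seqA <- paste0(ctx, "S", ctx)
  p1 <- annotate_site(protein("A", seqA), 13, "S")
  p2 <- annotate_site(protein("B", seqA), 13, "S")
  ds <- build_nonredundant_dataset(list(p1, p2), c("S", "T"), 12)
  expect_equal(sum(ds$sites$label == "positive"), 1L)

  # same peptide positive in one protein, negative in another: keep positive
  p3 <- protein("C", seqA)  # unannotated; needs all_proteins policy to count
  ds2 <- build_nonredundant_dataset(list(p1, p3), c("S", "T"), 12,
                                    negative_policy = "all_proteins")
  pep_pos <- ds2$peptides[ds2$sites$label == "positive"]
  expect_false(any(ds2$peptides[ds2$sites$label == "negative"] %in% pep_pos))
  expect_equal(sum(ds2$sites$label == "positive"), 1L)

  # phosphoproteins_only excludes negatives from unannotated proteins
  p4 <- protein("D", "MSTSTSTST")
  ds3 <- build_nonredundant_dataset(list(p1, p4), c("S", "T"), 3)
  expect_false("D" %in% ds3$sites$accession)
  ds4 <- build_nonredundant_dataset(list(p1, p4), c("S", "T"), 3,
                                    negative_policy = "all_proteins")
  expect_true("D" %in% ds4$sites$accession)

  expect_error(build_nonredundant_dataset(list(p4), c("S", "T"), 3),
               "untrainable")
})

test_that("dataset invariants hold on generated proteomes", {
  prots <- generate_proteome(synthetic_config(n_proteins = 15,
                                              mean_length = 150, seed = 3))
  ds <- build_nonredundant_dataset(prots, c("S", "T"), 12)
  expect_equal(nrow(ds$sites), length(ds$peptides))
  # no duplicate peptides at all after dedup + conflict resolution
  expect_false(anyDuplicated(ds$peptides) > 0)
  expect_true(all(nchar(ds$peptides) == 25L))
  expect_true(all(substr(ds$peptides, 13, 13) %in% c("S", "T")))
})
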