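test_that("window extraction pads symmetrically and centres the residue", {
  expect_equal(extract_window("MSK", 2, 2)$peptide, "-MSK-")
  expect_equal(extract_window("MSK", 1, 1)$peptide, "-MS")
  expect_equal(extract_window("MSK", 3, 1)$peptide, "SK-")
  w <- extract_window("ACDEFGHIKL", 5, 3)
  expect_equal(w$peptide, "CDEFGHI")
  expect_equal(w$center_index, 4L)
  expect_false(any(w$pad_mask))
  expect_error(extract_window("MSK", 0, 2), "out of range")
  expect_error(extract_window("MSK", 4, 2), "out of range")

  withr::with_seed(5, {
    for (i in 1:20) {
      seq <- paste(sample(AA20_T, sample(5:40, 1), replace = TRUE),
                   collapse = "")
      pos <- sample(nchar(seq), 1)
      hw <- sample(1:12, 1)
      w <- extract_window(seq, pos, hw)
      expect_equal(nchar(w$peptide), 2L * hw + 1L)
      expect_equal(substr(w$peptide, hw + 1L, hw + 1L),
                   substr(seq, pos, pos))
      # pads only as contiguous prefix/suffix
      runs <- rle(w$pad_mask)
      expect_lte(length(runs$values[runs$values]), 2L)
    }
  })
})

test_that("window similarity matches the naive oracle and the pad rule", {
  expect_equal(window_similarity("AC", "AC"), 13)  # 4 + 9 under BLOSUM62
  expect_equal(window_similarity("--", "AC"), 0)
  expect_equal(window_similarity("A-", "AC"), 4)
  expect_error(window_similarity("AC", "ACD"), "mismatch")

  withr::with_seed(9, {
    for (i in 1:30) {
      a <- random_peptide(9, sample(0:2, 1), sample(0:2, 1))
      b <- random_peptide(9, sample(0:2, 1), sample(0:2, 1))
      expect_equal(window_similarity(a, b), naive_similarity(a, b))
    }
  })
  # self-similarity maximality over same pad pattern (diagonal dominance)
  withr::with_seed(10, {
    a <- random_peptide(9)
    for (i in 1:15) {
      b <- random_peptide(9)
      expect_gte(window_similarity(a, a), window_similarity(a, b))
    }
  })
})

test_that("knn_scores equals the brute-force oracle, with and without self", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      n <- sample(10:120, 1)
      ref_peps <- vapply(seq_len(n), function(i) random_peptide(9),
                         character(1))
      ref_pos <- runif(n) < 0.3
      ds <- structure(list(
        sites = data.frame(accession = "r", position = seq_len(n),
                           residue = "S",
                           label = ifelse(ref_pos, "positive", "negative")),
        peptides = ref_peps, residue_types = "S", half_width = 4L),
        class = "SiteDataset")
      kf <- c(0.0025, 0.005, 0.01, 0.02, 0.04, 0.08, 0.3)
      q <- random_peptide(9)
      expect_equal(unname(knn_scores(q, ds, knn_config(k_fractions = kf))),
                   naive_knn(q, ref_peps, ref_pos, kf))
      # leave-self-out on a reference member
      j <- sample(n, 1)
      got <- knn_scores(ref_peps[j], ds,
                        knn_config(k_fractions = kf, exclude_self = TRUE),
                        self_id = j)
      expect_equal(unname(got), naive_knn(ref_peps[j], ref_peps, ref_pos,
                                          kf, self = j))
    }
  })
})

test_that("knn_scores respects the documented tie rule and degenerate cases", {
  # identical reference windows force ties: insertion order decides
  ds <- structure(list(
    sites = data.frame(accession = "r", position = 1:4, residue = "S",
                       label = c("positive", "negative", "negative",
                                 "positive")),
    peptides = c("ASA", "ASA", "ASA", "ASA"),
    residue_types = "S", half_width = 1L), class = "SiteDataset")
  got <- knn_scores("ASA", ds, knn_config(k_fractions = c(0.25, 0.5, 0.75)))
  # k=1 -> first inserted (positive); k=2 -> {1,2}; k=3 -> {1,2,3}
  expect_equal(unname(got), c(1, 1/2, 1/3))

  # all nearest neighbours positive -> 1.0
  ds$sites$label <- rep("positive", 4)
  expect_equal(unname(knn_scores("ASA", ds, knn_config())), rep(1, 6))
})

test_that("aa_frequencies normalizes over non-pad standard residues", {
  expect_equal(unname(aa_frequencies("AAAA")["A"]), 1)
  f <- aa_frequencies("-MS")
  expect_equal(unname(f[c("M", "S")]), c(0.5, 0.5))
  expect_equal(sum(f), 1)
  # non-standard letters excluded from numerator and denominator
  f2 <- aa_frequencies("AXUA")
  expect_equal(unname(f2["A"]), 1)
  withr::with_seed(17, {
    for (i in 1:20) {
      w <- random_peptide(11, sample(0:3, 1), sample(0:3, 1))
      expect_equal(sum(aa_frequencies(w)), 1, tolerance = 1e-9)
    }
  })
})

test_that("builtin disorder track is in [0,1] and ranks poly-E above poly-W", {
  seq <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 5), collapse = "")
  tr <- default_disorder_track(seq)
  expect_length(tr, nchar(seq))
  expect_true(all(tr >= 0 & tr <= 1))
  expect_gt(mean(default_disorder_track(strrep("E", 40))),
            mean(default_disorder_track(strrep("W", 40))))
})

test_that("disorder_feature means the clipped window", {
  expect_equal(disorder_feature(rep(0.5, 30), 10, 5), 0.5)
  tr <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7)
  expect_equal(disorder_feature(tr, 4, 2), mean(tr[2:6]))
  # clipping at the start: positions 1..6 only
  expect_equal(disorder_feature(tr, 1, 5), mean(tr[1:6]))
  expect_error(disorder_feature(tr, 9, 2), "range")
})

test_that("assembled feature vector has the documented layout", {
  withr::with_seed(19, {
    prots <- generate_proteome(synthetic_config(n_proteins = 6,
                                                mean_length = 120,
                                                seed = 19))
    ds <- build_nonredundant_dataset(prots, c("S", "T"), 12)
    p1 <- prots[[ds$sites$accession[1]]]
    v <- assemble_feature_vector(ds$peptides[1], ds, knn_config(),
                                 p1$tracks$disorder, ds$sites$position[1],
                                 12)
    expect_length(v, 27L)  # 6 knn + 1 disorder + 20 frequencies
    expect_equal(names(v)[7], "disorder")
    expect_true(all(startsWith(names(v)[1:6], "knn_")))
    expect_true(all(startsWith(names(v)[8:27], "freq_")))
    expect_equal(sum(v[8:27]), 1, tolerance = 1e-9)
    # bit-for-bit reproducible
    v2 <- assemble_feature_vector(ds$peptides[1], ds, knn_config(),
                                  p1$tracks$disorder,
                                  ds$sites$position[1], 12)
    expect_identical(v, v2)
  })
})
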