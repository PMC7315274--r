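test_that("TCR-contact positions exclude the anchors", {
  expect_identical(tcr_contact_positions("SIINFEKLM"), 3:8)
  expect_identical(tcr_contact_positions("SIINFEKL"), 3:7)
  expect_identical(tcr_contact_positions(4L), 3L)
  expect_error(tcr_contact_positions("ACD"), "at least 4")
})

test_that("scale averages match hand-computed and brute-force values", {
  # contact residues of SIINFEKL are I N F E K
  expect_equal(compute_scale_feature("SIINFEKL", "C1"), -0.72)
  # homopolymer average equals the single residue value
  expect_equal(compute_scale_feature("AAAAAAAA", "C1"),
               get_scale("C1")[["A"]])
  withr::with_seed(421, {
    peps <- random_peptides(1000)
  })
  for (id in c("C1", "C7", "C14")) {
    s <- get_scale(id)
    expect_equal(compute_scale_feature(peps, s),
                 vapply(peps, oracle_scale_feature, numeric(1), scale = s,
                        USE.NAMES = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("anchor positions never influence sequence features", {
  fm <- strong_features()$fm
  withr::with_seed(17, {
    base <- random_peptides(50, lengths = 9:11)
  })
  # rewrite positions 1, 2 and len with different residues
  mutated <- vapply(base, function(s) {
    len <- nchar(s)
    swap <- function(ch) AAS[(match(ch, AAS)) %% 20 + 1]
    paste0(swap(substr(s, 1, 1)), swap(substr(s, 2, 2)),
           substr(s, 3, len - 1), swap(substr(s, len, len)))
  }, character(1), USE.NAMES = FALSE)
  expect_false(any(base == mutated))
  for (id in c("C1", "C10", "C21")) {
    expect_equal(compute_scale_feature(base, id),
                 compute_scale_feature(mutated, id), tolerance = 1e-14)
  }
  expect_equal(frequency_score(base, fm), frequency_score(mutated, fm),
               tolerance = 1e-14)
  expect_equal(peptide_entropy(base, fm), peptide_entropy(mutated, fm),
               tolerance = 1e-14)
})

test_that("frequency model estimation pools contact residues per class", {
  peps <- tibble::tibble(
    sequence = c("AAAAAAAAA", "LLLLLLLLL"),
    label = c("immunogenic", "nonimmunogenic"))
  m0 <- estimate_contact_frequencies(peps, pseudocount = 0)
  expect_equal(m0$f_pos[["A"]], 1)
  expect_equal(m0$f_neg[["L"]], 1)

  m1 <- estimate_contact_frequencies(peps)  # smoothed
  expect_equal(sum(m1$f_pos), 1, tolerance = 1e-9)
  expect_equal(sum(m1$f_neg), 1, tolerance = 1e-9)
  expect_equal(sum(m1$f_background), 1, tolerance = 1e-9)
  expect_true(all(m1$f_pos > 0) && all(m1$f_neg > 0))

  # identical peptide multisets in both classes give identical tables
  same <- tibble::tibble(
    sequence = rep(c("SIINFEKLM", "ALAKAAAAM"), 2),
    label = rep(c("immunogenic", "nonimmunogenic"), each = 2))
  ms <- estimate_contact_frequencies(same)
  expect_equal(ms$f_pos, ms$f_neg, tolerance = 1e-12)

  expect_error(estimate_contact_frequencies(
    tibble::tibble(sequence = "SIINFEKLM", label = "immunogenic")),
    "one immunogenic and one nonimmunogenic")
})

test_that("frequency score is the plain contact-site sum of class differences", {
  fm <- strong_features()$fm
  # constructed model: 6 contact L residues at +0.06 each
  fm2 <- fm
  fm2$f_pos[] <- 0.05
  fm2$f_neg[] <- 0.05
  fm2$f_pos[["L"]] <- 0.10
  fm2$f_neg[["L"]] <- 0.04
  expect_equal(frequency_score("ALLLLLLLV", fm2), 6 * 0.06,
               tolerance = 1e-12)
  # identical class tables score 0 everywhere
  fm3 <- fm
  fm3$f_neg <- fm3$f_pos
  withr::with_seed(5, peps <- random_peptides(25))
  expect_equal(frequency_score(peps, fm3), rep(0, 25), tolerance = 1e-12)
  # swapping the class tables negates every score
  fm4 <- fm
  fm4$f_pos <- fm$f_neg
  fm4$f_neg <- fm$f_pos
  expect_equal(frequency_score(peps, fm4), -frequency_score(peps, fm),
               tolerance = 1e-12)
  # brute-force position oracle
  expect_equal(frequency_score(peps, fm),
               vapply(peps, oracle_frequency_score, numeric(1),
                      f_pos = fm$f_pos, f_neg = fm$f_neg, USE.NAMES = FALSE),
               tolerance = 1e-12)
})

test_that("peptide entropy follows the background-frequency formula", {
  uniform <- setNames(rep(0.05, 20), AAS)
  # homopolymer: every summand is -f log2 f, the length cancels
  expect_equal(peptide_entropy("AAAAAAAAA", uniform), -0.05 * log2(0.05),
               tolerance = 1e-12)
  f25 <- uniform; f25[["L"]] <- 0.25
  expect_equal(peptide_entropy("LLLLLLLLL", f25), 0.5, tolerance = 1e-12)
  # under a uniform background every peptide has the same entropy
  withr::with_seed(31, peps <- random_peptides(40))
  expect_equal(peptide_entropy(peps, uniform),
               rep(-0.05 * log2(0.05), 40), tolerance = 1e-4)
  # brute-force oracle and non-negativity under the shipped background
  bg <- background_frequencies()
  vals <- peptide_entropy(peps, bg)
  expect_equal(vals, vapply(peps, oracle_entropy, numeric(1), f_bg = bg,
                            USE.NAMES = FALSE), tolerance = 1e-12)
  expect_true(all(vals >= 0))
  expect_error(peptide_entropy("SIINFEKLM", setNames(rep(0, 20), AAS)),
               "strictly positive")
})

test_that("feature assembly produces the full 24-feature schema", {
  fx <- strong_features()
  feats <- fx$features
  expect_named(feats, c("id", "label", paste0("C", 1:24)))
  expect_false(anyNA(as.matrix(feats[paste0("C", 1:24)])))
  expect_equal(feats$C24, fx$peptides$rank_percent)
  # deterministic: identical on recomputation
  expect_identical(feats, peptide_features(fx$peptides, fx$fm))
  # missing rank column is a user-facing error
  norank <- fx$peptides[, c("id", "sequence", "label")]
  expect_error(peptide_features(norank, fx$fm), "rank_percent")
})

test_that("cross-fitted C22 is label-leakage free on label-free data", {
  fx <- strong_features()
  # unlabeled (single-class) input falls back to plain model scoring
  unseen <- tibble::tibble(id = "new", sequence = "SIINFEKLM",
                           rank_percent = 0.3)
  auto <- peptide_features(unseen, fx$fm)
  plain <- peptide_features(unseen, fx$fm, c22 = "model")
  expect_equal(auto$C22, plain$C22, tolerance = 1e-12)
  expect_error(peptide_features(unseen, fx$fm, c22 = "cross_fit"),
               "both classes")
  # on a labeled training set the two scoring routes differ
  cf <- peptide_features(fx$peptides, fx$fm, c22 = "cross_fit")
  pl <- peptide_features(fx$peptides, fx$fm, c22 = "model")
  expect_false(isTRUE(all.equal(cf$C22, pl$C22, tolerance = 1e-12)))

  # with no class signal, the cross-fitted score does not separate the
  # classes, while scoring a set against frequencies estimated from that
  # same set does (estimation noise leaks the label)
  null_peps <- simulate_peptides(sim_config(n_pos = 500, n_neg = 500,
                                            effect = 0, seed = 77))
  fm0 <- estimate_contact_frequencies(null_peps)
  f_cf <- peptide_features(null_peps, fm0, c22 = "cross_fit")
  f_pl <- peptide_features(null_peps, fm0, c22 = "model")
  y <- as.integer(f_cf$label == "immunogenic")
  expect_lt(abs(roc_auc(f_cf$C22, y)$auc - 0.5), 0.05)
  expect_gt(abs(roc_auc(f_pl$C22, y)$auc - 0.5),
            abs(roc_auc(f_cf$C22, y)$auc - 0.5))
})
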