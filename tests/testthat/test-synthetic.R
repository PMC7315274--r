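test_that("generated datasets satisfy the peptide contract and the config", {
  cfg <- sim_config(n_pos = 80, n_neg = 120, effect = "medium", seed = 2)
  peps <- simulate_peptides(cfg)
  expect_identical(nrow(peps), 200L)
  expect_identical(sum(peps$label == "immunogenic"), 80L)
  expect_silent(validate_peptides(peps, min_len = 8, max_len = 11))
  expect_true(all(nchar(peps$sequence) %in% 8:11))
  expect_true(all(peps$rank_percent > 0))
  # the whole set survives the curation length filter
  expect_identical(nrow(filter_by_length(peps)), 200L)
})

test_that("generation is deterministic given the config seed", {
  cfg <- sim_config(n_pos = 50, n_neg = 50, effect = "weak", seed = 33)
  expect_identical(simulate_peptides(cfg), simulate_peptides(cfg))
  expect_identical(simulate_mutant_pairs(cfg, anchor_fraction = 0.4),
                   simulate_mutant_pairs(cfg, anchor_fraction = 0.4))
  # a different seed changes the draw
  cfg2 <- sim_config(n_pos = 50, n_neg = 50, effect = "weak", seed = 34)
  expect_false(identical(simulate_peptides(cfg), simulate_peptides(cfg2)))
})

test_that("anchors follow the allele motifs", {
  peps <- simulate_peptides(sim_config(n_pos = 120, n_neg = 0 + 1,
                                       effect = 0, seed = 6))
  a2 <- peps[peps$hla_allele == "A02:01", ]
  expect_gt(nrow(a2), 10)
  expect_true(all(substr(a2$sequence, 2, 2) %in% c("L", "M")))
  last <- substr(a2$sequence, nchar(a2$sequence), nchar(a2$sequence))
  expect_true(all(last %in% c("I", "L", "V")))
})

test_that("effect size controls the class contrast at contact sites", {
  # effect 0: identical class distributions by construction
  cfg0 <- sim_config(n_pos = 400, n_neg = 400, effect = 0, seed = 9)
  fm0 <- estimate_contact_frequencies(simulate_peptides(cfg0))
  expect_lt(max(abs(fm0$f_pos - fm0$f_neg)), 0.03)  # sampling noise only

  cfgS <- sim_config(n_pos = 400, n_neg = 400, effect = "strong", seed = 9)
  fmS <- estimate_contact_frequencies(simulate_peptides(cfgS))
  expect_gt(fmS$f_pos[["L"]], fmS$f_neg[["L"]])
  expect_gt(fmS$f_neg[["D"]], fmS$f_pos[["D"]])
  # ranks separate in the right direction
  pepsS <- simulate_peptides(cfgS)
  expect_lt(median(pepsS$rank_percent[pepsS$label == "immunogenic"]),
            median(pepsS$rank_percent[pepsS$label == "nonimmunogenic"]))
})

test_that("mutant pairs honor the anchor fraction and are always valid", {
  cfg <- sim_config(n_pos = 60, n_neg = 60, effect = "medium", seed = 13)
  all_interior <- simulate_mutant_pairs(cfg, anchor_fraction = 0)
  all_anchor <- simulate_mutant_pairs(cfg, anchor_fraction = 1)
  flag <- function(p) anchor_mutation_flag(p$mutation_position,
                                           nchar(p$wt_sequence))
  expect_true(all(flag(validate_pairs(all_interior)) == 0L))
  expect_true(all(flag(validate_pairs(all_anchor)) == 1L))

  n500 <- simulate_mutant_pairs(cfg, n_pairs = 500)
  expect_identical(nrow(n500), 500L)
  expect_silent(validate_pairs(n500))  # every pair passes find_mutation
})

test_that("configs validate their distributions", {
  expect_error(sim_config(length_probs = c("9" = 0.5)), "summing to 1")
  expect_error(sim_config(supertype_mix = c("Z99:99" = 1)), "motif")
  expect_error(sim_config(effect = -1), "non-negative")
  expect_error(sim_config(effect = "huge"), "none")
})
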