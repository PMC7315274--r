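test_that("allele names normalize across common notations", {
  expect_identical(normalize_allele(c("HLA-A*02:01", "A*02:01", "A0201",
                                      "A02:01", "a2:01")),
                   c("A02:01", "A02:01", "A02:01", "A02:01", "A02:01"))
  expect_identical(normalize_allele(NA), NA_character_)
})

test_that("the bundled supertype map covers the training alleles", {
  map <- hla_supertypes()
  expect_gte(nrow(map), 17)
  expect_identical(map_allele_to_supertype("A02:01"), "A2")
  expect_identical(map_allele_to_supertype("B08:01"), "B8")
  expect_identical(map_allele_to_supertype("C07:02"), NA_character_)
  expect_setequal(unique(map$supertype),
                  c("A1", "A2", "A3", "A24", "B7", "B8", "B27", "B44",
                    "B58", "B62"))
})

test_that("the rank filter removes only negatives strictly above threshold", {
  peps <- toy_peptides(
    labels = c("immunogenic", "immunogenic", "nonimmunogenic",
               "nonimmunogenic", "nonimmunogenic"),
    ranks = c(3.0, 0.5, 3.0, 2.0, 1.0))
  out <- filter_negatives_by_rank(peps)
  expect_identical(out$id, peps$id[c(1, 2, 4, 5)])  # only the rank-3 negative
  rep <- curation_report(out)
  expect_identical(rep$removed$id, peps$id[3])
  expect_match(rep$removed$reason, "rank")
  expect_error(filter_negatives_by_rank(peps[, c("id", "sequence", "label")]),
               "rank_percent")
})

test_that("the proteome filter removes only exact-substring negatives", {
  peps <- tibble::tibble(
    id = c("p1", "n1", "n2"),
    sequence = c("SIINFEKLM", "SIINFEKLM", "SIINFEKLA"),
    rank_percent = 1,
    label = c("immunogenic", "nonimmunogenic", "nonimmunogenic"))
  proteome <- c("MKTAYIAKQRSIINFEKLMGG", "MAAAAA")
  out <- filter_negatives_by_proteome(peps, proteome)
  # the positive and the one-residue-different negative survive
  expect_identical(out$id, c("p1", "n2"))
  expect_error(filter_negatives_by_proteome(peps, character(0)), "non-empty")
})

test_that("deduplication keys on (sequence, allele) and prefers positives", {
  peps <- tibble::tibble(
    id = paste0("r", 1:5),
    sequence = c("SIINFEKLM", "SIINFEKLM", "SIINFEKLM", "ALAKAAAAM",
                 "ALAKAAAAM"),
    hla_allele = c("A02:01", "A02:01", "B07:02", "A02:01", "A02:01"),
    rank_percent = 1,
    label = c("nonimmunogenic", "immunogenic", "nonimmunogenic",
              "nonimmunogenic", "nonimmunogenic"))
  out <- deduplicate_peptides(peps)
  # conflict resolved to the immunogenic record; distinct alleles kept
  expect_setequal(out$id, c("r2", "r3", "r4"))
  expect_identical(out$label[out$sequence == "SIINFEKLM" &
                               out$hla_allele == "A02:01"], "immunogenic")
})

test_that("the length filter applies its bounds inclusively", {
  peps <- tibble::tibble(id = c("a", "b", "c"),
                         sequence = c(strrep("A", 9), strrep("L", 12),
                                      strrep("K", 8)),
                         label = "immunogenic")
  expect_identical(filter_by_length(peps)$id, c("a", "c"))
  expect_identical(filter_by_length(peps, max = 12)$id, c("a", "b", "c"))
})

test_that("the supertype filter drops unmapped or disallowed alleles", {
  peps <- toy_peptides(rep("immunogenic", 3), rep(1, 3),
                       alleles = c("A02:01", "C07:02", "B08:01"))
  out <- filter_by_supertype(peps, allowed = c("A2", "B8"))
  expect_identical(out$hla_allele, c("A02:01", "B08:01"))
  out2 <- filter_by_supertype(peps)  # all mapped supertypes allowed
  expect_identical(out2$hla_allele, c("A02:01", "B08:01"))
})

test_that("the cascade is monotone, fully attributed and idempotent", {
  withr::with_seed(12, {
    base <- random_peptides(40, lengths = 9)
  })
  peps <- tibble::tibble(
    id = sprintf("c%02d", 1:46),
    sequence = c(base, strrep("A", 13), strrep("C", 7), base[1:4]),
    hla_allele = c(rep(c("A02:01", "A01:01"), 20), rep("A02:01", 6)),
    rank_percent = c(rep(c(0.4, 1.1, 2.0, 3.5), 10), rep(1, 6)),
    label = c(rep(c("immunogenic", "nonimmunogenic"), 20),
              rep("nonimmunogenic", 6)))
  proteome <- paste0("MSTART", base[2], "END")  # contains one negative
  cur <- curate_peptides(peps, proteome = proteome,
                         allowed_supertypes = c("A1", "A2"))
  rep <- curation_report(cur)

  # per-class counts never increase along the cascade
  for (cl in unique(rep$stages$class)) {
    st <- rep$stages[rep$stages$class == cl, ]
    expect_true(all(st$n_after <= st$n_before))
    expect_true(all(diff(st$n_before) <= 0))
  }
  # every dropped record is attributed exactly once
  expect_setequal(c(rep$removed$id, cur$id), peps$id)
  expect_identical(nrow(rep$removed) + nrow(cur), nrow(peps))
  # positives are never removed by the negative-only filters
  neg_only <- rep$removed[rep$removed$stage %in% c("rank", "proteome"), ]
  expect_true(all(peps$label[match(neg_only$id, peps$id)] ==
                    "nonimmunogenic"))
  # idempotence: the cascade removes nothing from its own output
  again <- curate_peptides(cur, proteome = proteome,
                           allowed_supertypes = c("A1", "A2"))
  expect_identical(again$id, cur$id)
  expect_identical(nrow(curation_report(again)$removed), 0L)
})
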