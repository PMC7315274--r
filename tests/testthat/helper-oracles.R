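# Independent brute-force oracles and tiny data builders shared by the
# tests.  The oracles deliberately reimplement the formulas step by step,
# without reusing any package internals, so they can certify the
# vectorized implementations.

AAS <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

random_peptides <- function(n, lengths = 8:12) {
  len <- sample(rep(lengths, 2), n, replace = TRUE)
  vapply(seq_len(n), function(i) {
    paste(sample(AAS, len[i], replace = TRUE), collapse = "")
  }, character(1))
}

# Eq-by-position oracle for the scale-average feature
oracle_scale_feature <- function(sequence, scale) {
  chars <- strsplit(sequence, "")[[1]]
  len <- length(chars)
  total <- 0
  for (pos in seq_len(len)) {
    if (pos == 1 || pos == 2 || pos == len) next  # anchor sites
    total <- total + scale[[chars[pos]]]
  }
  total / (len - 3)
}

# Position-by-position oracle for the frequency score
oracle_frequency_score <- function(sequence, f_pos, f_neg) {
  chars <- strsplit(sequence, "")[[1]]
  len <- length(chars)
  total <- 0
  for (pos in seq_len(len)) {
    if (pos == 1 || pos == 2 || pos == len) next
    total <- total + f_pos[[chars[pos]]] - f_neg[[chars[pos]]]
  }
  total
}

# Position-by-position oracle for the background entropy
oracle_entropy <- function(sequence, f_bg) {
  chars <- strsplit(sequence, "")[[1]]
  len <- length(chars)
  total <- 0
  for (pos in seq_len(len)) {
    if (pos == 1 || pos == 2 || pos == len) next
    f <- f_bg[[chars[pos]]]
    total <- total + f * log2(f)
  }
  -total / (len - 3)
}

# Pairwise-counting AUC oracle: concordant pairs + half the ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Linear-scan oracle for the mutation position
oracle_find_mutation <- function(wt, mut) {
  a <- strsplit(wt, "")[[1]]
  b <- strsplit(mut, "")[[1]]
  for (i in seq_along(a)) if (a[i] != b[i]) return(i)
  NA_integer_
}

# Small labeled peptide table with chosen ranks (valid 9-mers)
toy_peptides <- function(labels, ranks, alleles = "A02:01", seed = 99) {
  n <- length(labels)
  withr::with_seed(seed, {
    tibble::tibble(
      id = sprintf("t%03d", seq_len(n)),
      sequence = random_peptides(n, lengths = 9),
      hla_allele = rep_len(alleles, n),
      rank_percent = ranks,
      label = labels
    )
  })
}

# Cache for expensive simulated fixtures shared across test files
.fixture_cache <- new.env(parent = emptyenv())

strong_features <- function() {
  if (is.null(.fixture_cache$strong)) {
    peps <- simulate_peptides(sim_config(n_pos = 150, n_neg = 150,
                                         effect = "strong", seed = 11))
    fm <- estimate_contact_frequencies(peps)
    .fixture_cache$strong <- list(peptides = peps, fm = fm,
                                  features = peptide_features(peps, fm))
  }
  .fixture_cache$strong
}
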