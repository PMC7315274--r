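# Synthetic labeled epitope data with the statistical structure the method
# assumes: supertype-consistent anchor residues, class-dependent amino-acid
# usage at TCR-contact sites (hydrophobic enrichment in immunogenic
# peptides, charged D/K enrichment in nonimmunogenic ones), and
# class-dependent eluted-ligand rank distributions.

# Anchor motif sets per allele (positions 1, 2 and the C-terminus only;
# positions without a set draw from the background distribution).
.anchor_motifs <- function() {
  list(
    "A01:01" = list(p2 = c("S", "T"), cterm = "Y"),
    "A26:01" = list(p1 = c("D", "E"), p2 = c("I", "T", "V"),
                    cterm = c("F", "M", "Y")),
    "A02:01" = list(p2 = c("L", "M"), cterm = c("I", "L", "V")),
    "A11:01" = list(p2 = c("I", "M", "S", "T", "V"), cterm = "K"),
    "A03:01" = list(p2 = c("I", "L", "M", "T", "V"), cterm = "K"),
    "A24:02" = list(p2 = c("W", "Y"), cterm = c("F", "I", "W")),
    "A23:01" = list(p2 = c("W", "Y"), cterm = "F"),
    "B35:01" = list(p2 = "P", cterm = c("F", "M", "Y")),
    "B07:02" = list(p2 = "P", cterm = c("F", "L", "M")),
    "B51:01" = list(p2 = "P", cterm = c("I", "V")),
    "B08:01" = list(cterm = c("F", "I", "L", "M", "V")),
    "B27:05" = list(p1 = c("R", "Y"), p2 = "R"),
    "B44:02" = list(p2 = "E", cterm = c("F", "I", "W", "Y")),
    "B58:01" = list(p2 = c("A", "S", "T"), cterm = "W"),
    "B15:01" = list(p2 = c("L", "M", "Q"), cterm = c("F", "Y"))
  )
}

# Residues enriched at contact sites of immunogenic (+1) and
# nonimmunogenic (-1) peptides
.contact_tilt <- function() {
  t <- setNames(rep(0, 20), AA20)
  t[c("L", "W", "P", "A", "V", "M")] <- 1
  t[c("D", "K")] <- -1
  t
}

.effect_value <- function(effect) {
  if (is.numeric(effect)) {
    if (effect < 0) abort("`effect` must be non-negative.")
    return(effect)
  }
  lv <- c(none = 0, weak = 0.2, medium = 0.4, strong = 0.8)
  if (!effect %in% names(lv)) {
    abort("`effect` must be numeric or one of 'none', 'weak', 'medium', 'strong'.")
  }
  unname(lv[effect])
}

#' Configuration for the synthetic epitope generator
#'
#' Defines the study conditions the generator emulates.  The effect size
#' interpolates between identical class distributions (0) and a strongly
#' hydrophobic-enriched immunogenic class: contact residues are drawn from
#' the background distribution exponentially tilted by
#' \code{exp(+-effect)} on the hydrophobic set \{L, W, P, A, V, M\} (up in
#' positives) and on \{D, K\} (up in negatives), and eluted-ligand ranks
#' are log-normal with a class location shift of \code{-+ effect *
#' rank_shift} on the log scale (positives bind better).  At effect 0 both
#' classes are statistically identical in every respect.
#'
#' @param n_pos,n_neg Peptides per class.
#' @param effect Effect size: non-negative numeric, or \code{"none"} (0),
#'   \code{"weak"} (0.2), \code{"medium"} (0.4), \code{"strong"} (0.8).
#' @param length_probs Named probability vector over peptide lengths
#'   (default 8--11, 9-mers dominant, as in curated HLA-I epitope sets).
#' @param supertype_mix Named probability vector over HLA alleles with
#'   bundled anchor motifs (defaults to five common alleles, A02:01
#'   heaviest).
#' @param rank_meanlog,rank_sdlog Log-normal parameters of the rank(%)
#'   distribution at effect 0.
#' @param rank_shift Class location shift per unit effect on the log-rank
#'   scale.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A \code{sim_config} list, validated.
#' @export
sim_config <- function(n_pos = 500L, n_neg = 500L, effect = "medium",
                       length_probs = c("8" = 0.15, "9" = 0.55,
                                        "10" = 0.20, "11" = 0.10),
                       supertype_mix = c("A02:01" = 0.35, "A01:01" = 0.20,
                                         "A03:01" = 0.20, "A24:02" = 0.15,
                                         "B07:02" = 0.10),
                       rank_meanlog = 0, rank_sdlog = 0.8,
                       rank_shift = 0.75, seed = 1L) {
  if (n_pos < 1L || n_neg < 1L) abort("Need at least one peptide per class.")
  if (abs(sum(length_probs) - 1) > 1e-9 || any(length_probs < 0)) {
    abort("`length_probs` must be a probability vector summing to 1.")
  }
  if (abs(sum(supertype_mix) - 1) > 1e-9 || any(supertype_mix < 0)) {
    abort("`supertype_mix` must be a probability vector summing to 1.")
  }
  unknown <- setdiff(names(supertype_mix), names(.anchor_motifs()))
  if (length(unknown) > 0L) {
    abort(paste0("No bundled anchor motif for allele(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(as.integer(names(length_probs)) < 8L)) {
    abort("Generated lengths must be at least 8.")
  }
  structure(list(
    n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
    effect = .effect_value(effect),
    length_probs = length_probs, supertype_mix = supertype_mix,
    rank_meanlog = rank_meanlog, rank_sdlog = rank_sdlog,
    rank_shift = rank_shift, seed = as.integer(seed)
  ), class = "sim_config")
}

# Class-conditional contact-site distributions under a config
.contact_distributions <- function(config) {
  bg <- background_frequencies()
  tilt <- .contact_tilt()
  f_pos <- bg * exp(config$effect * tilt)
  f_neg <- bg * exp(-config$effect * tilt)
  list(pos = f_pos / sum(f_pos), neg = f_neg / sum(f_neg))
}

.draw_peptides <- function(n, class, config, dists) {
  if (n == 0L) return(character(0))
  bg <- background_frequencies()
  motifs <- .anchor_motifs()
  lens <- as.integer(sample(names(config$length_probs), n, replace = TRUE,
                            prob = config$length_probs))
  alleles <- sample(names(config$supertype_mix), n, replace = TRUE,
                    prob = config$supertype_mix)
  f_contact <- if (class == "immunogenic") dists$pos else dists$neg
  seqs <- vapply(seq_len(n), function(i) {
    len <- lens[i]
    motif <- motifs[[alleles[i]]]
    res <- character(len)
    draw_anchor <- function(set) {
      if (is.null(set)) sample(AA20, 1L, prob = bg) else
        if (length(set) == 1L) set else sample(set, 1L)
    }
    res[1] <- draw_anchor(motif$p1)
    res[2] <- draw_anchor(motif$p2)
    res[len] <- draw_anchor(motif$cterm)
    k <- len - 3L
    res[3:(len - 1L)] <- sample(AA20, k, replace = TRUE, prob = f_contact)
    paste(res, collapse = "")
  }, character(1))
  shift <- if (class == "immunogenic") -1 else 1
  ranks <- rlnorm(n, meanlog = config$rank_meanlog +
                    shift * config$effect * config$rank_shift,
                  sdlog = config$rank_sdlog)
  tibble::tibble(sequence = seqs, hla_allele = alleles,
                 rank_percent = ranks, label = class)
}

#' Generate a labeled synthetic peptide dataset
#'
#' Draws \code{n_pos + n_neg} peptides under a [sim_config()]: anchors from
#' the allele's motif (background elsewhere), contact residues from the
#' class-conditional tilted distribution, and ranks from the class
#' log-normal.  Reproducible given the config seed.
#'
#' @param config A [sim_config()].
#' @return Peptide tibble with \code{id}, \code{sequence},
#'   \code{hla_allele}, \code{rank_percent}, \code{label}; passes
#'   [validate_peptides()] and the default curation length filter.
#' @examples
#' simulate_peptides(sim_config(n_pos = 5, n_neg = 5, seed = 42))
#' @export
simulate_peptides <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  dists <- .contact_distributions(config)
  withr::with_seed(config$seed, {
    out <- dplyr::bind_rows(
      .draw_peptides(config$n_pos, "immunogenic", config, dists),
      .draw_peptides(config$n_neg, "nonimmunogenic", config, dists)
    )
  })
  out$id <- sprintf("pep%04d", seq_len(nrow(out)))
  out[, c("id", "sequence", "hla_allele", "rank_percent", "label")]
}

#' Generate synthetic single-substitution neoantigen pairs
#'
#' Wild-type sequences are drawn with class-neutral contact composition;
#' one position is mutated (an anchor position with probability
#' \code{anchor_fraction}, otherwise a uniformly chosen contact position).
#' For immunogenic pairs the substituted residue is drawn from the
#' positive-class contact distribution and the mutant's rank is shifted
#' down (better binding) by the config effect, so the DAI is informative;
#' nonimmunogenic pairs mirror this.
#'
#' @param config A [sim_config()]; \code{n_pos}/\code{n_neg} set the class
#'   sizes unless \code{n_pairs} is given.
#' @param n_pairs Optional total pair count (split by the config class
#'   proportions).
#' @param anchor_fraction Probability that the mutation falls on an anchor
#'   position (1, 2 or the C-terminus).
#' @return Pair tibble with \code{id}, \code{wt_sequence},
#'   \code{mut_sequence}, \code{hla_allele}, \code{wt_rank_percent},
#'   \code{mut_rank_percent}, \code{label}; every row passes
#'   [find_mutation()].
#' @export
simulate_mutant_pairs <- function(config = sim_config(), n_pairs = NULL,
                                  anchor_fraction = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  if (anchor_fraction < 0 || anchor_fraction > 1) {
    abort("`anchor_fraction` must lie in [0, 1].")
  }
  n_pos <- config$n_pos; n_neg <- config$n_neg
  if (!is.null(n_pairs)) {
    n_pos <- round(n_pairs * config$n_pos / (config$n_pos + config$n_neg))
    n_neg <- n_pairs - n_pos
  }
  dists <- .contact_distributions(config)
  bg <- background_frequencies()
  draw_class <- function(n, class) {
    if (n == 0L) return(tibble::tibble())
    # wild types are class-neutral; the mutation carries the signal
    neutral <- sim_config(n_pos = max(n, 1L), n_neg = 1L, effect = 0,
                          length_probs = config$length_probs,
                          supertype_mix = config$supertype_mix,
                          rank_meanlog = config$rank_meanlog,
                          rank_sdlog = config$rank_sdlog, seed = config$seed)
    d0 <- .contact_distributions(neutral)
    wt <- .draw_peptides(n, "immunogenic", neutral, d0)
    len <- nchar(wt$sequence)
    at_anchor <- runif(n) < anchor_fraction
    pos <- integer(n)
    for (i in seq_len(n)) {
      pos[i] <- if (at_anchor[i]) {
        sample(c(1L, 2L, len[i]), 1L)
      } else {
        sample(seq.int(3L, len[i] - 1L), 1L)
      }
    }
    f_sub <- if (class == "immunogenic") dists$pos else dists$neg
    mut <- vapply(seq_len(n), function(i) {
      old <- substr(wt$sequence[i], pos[i], pos[i])
      pool <- setdiff(AA20, old)
      w <- if (at_anchor[i]) rep(1, length(pool)) else f_sub[pool]
      new <- sample(pool, 1L, prob = w)
      s <- wt$sequence[i]
      paste0(substr(s, 1, pos[i] - 1L), new, substr(s, pos[i] + 1L, len[i]))
    }, character(1))
    shift <- if (class == "immunogenic") -1 else 1
    tibble::tibble(
      wt_sequence = wt$sequence, mut_sequence = mut,
      hla_allele = wt$hla_allele,
      wt_rank_percent = rlnorm(n, config$rank_meanlog, config$rank_sdlog),
      mut_rank_percent = rlnorm(n, config$rank_meanlog +
                                  shift * config$effect * config$rank_shift,
                                config$rank_sdlog),
      label = class)
  }
  withr::with_seed(config$seed, {
    out <- dplyr::bind_rows(draw_class(n_pos, "immunogenic"),
                            draw_class(n_neg, "nonimmunogenic"))
  })
  out$id <- sprintf("pair%04d", seq_len(nrow(out)))
  out[, c("id", "wt_sequence", "mut_sequence", "hla_allele",
          "wt_rank_percent", "mut_rank_percent", "label")]
}
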