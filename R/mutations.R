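# Neoantigen (single-substitution) mutation features.
#
# C25  Kyte-Doolittle hydrophobicity change at the mutated position
# C26  differential agretopicity index on the rank(%) scale (wt - mut)
# C27  1 if the mutation falls on an anchor position {1, 2, len}, else 0
#
# C1-C24 of a pair are computed on the mutant sequence (the candidate
# neoepitope is the presented species); C24 is the mutant's rank(%).

#' Locate the single substitution between a wild-type/mutant pair
#'
#' @param wt,mut Character vectors of equal-length sequences (recycled
#'   pairwise).
#' @return Integer vector of 1-based mutation positions.  Errors if a pair
#'   has unequal lengths, is identical, or differs at more than one
#'   position (only single-substitution neoantigens are supported).
#' @examples
#' find_mutation("SIINFEKL", "SIINFEKI")  # 8
#' @export
find_mutation <- function(wt, mut) {
  if (length(wt) != length(mut)) {
    if (length(wt) == 1L) wt <- rep(wt, length(mut))
    else if (length(mut) == 1L) mut <- rep(mut, length(wt))
    else abort("`wt` and `mut` must have the same length.")
  }
  mapply(function(w, m, i) {
    if (nchar(w) != nchar(m)) {
      abort(paste0("Pair ", i, ": wild-type and mutant sequences must have ",
                   "equal length (", nchar(w), " vs ", nchar(m), ")."))
    }
    d <- which(strsplit(w, "")[[1]] != strsplit(m, "")[[1]])
    if (length(d) == 0L) {
      abort(paste0("Pair ", i, ": identical sequences; a neoantigen pair ",
                   "must differ at exactly one position."))
    }
    if (length(d) > 1L) {
      abort(paste0("Pair ", i, ": sequences differ at ", length(d),
                   " positions; only single-substitution neoantigens are ",
                   "supported."))
    }
    d
  }, wt, mut, seq_along(wt), USE.NAMES = FALSE)
}

#' Hydrophobicity change on mutation (C25)
#'
#' Kyte-Doolittle hydropathy of the mutant residue minus that of the
#' wild-type residue at the mutated position.
#'
#' @param wt_aa,mut_aa One-letter codes of the substituted residues
#'   (vectorized).
#' @return Numeric vector of deltas; antisymmetric under swapping the two
#'   residues.
#' @examples
#' hydrophobicity_delta("D", "I")  # 8
#' @export
hydrophobicity_delta <- function(wt_aa, mut_aa) {
  kd <- get_scale("C1")
  if (!all(wt_aa %in% AA20) || !all(mut_aa %in% AA20)) {
    abort("Residues must be standard one-letter amino-acid codes.")
  }
  unname(kd[mut_aa] - kd[wt_aa])
}

#' Differential agretopicity index (C26)
#'
#' Difference in MHC-binding percentile rank between the wild-type and the
#' mutant peptide, \code{wt_rank - mut_rank}.  Positive values mean the
#' mutant is the better binder (lower rank).  Operates on the rank(%)
#' scale this package ingests; if you have affinity values instead, pass
#' them here the same way (wt minus mut).
#'
#' @param wt_rank,mut_rank Non-negative numeric vectors.
#' @return Numeric vector.
#' @examples
#' dai(5.0, 0.3)  # 4.7
#' @export
dai <- function(wt_rank, mut_rank) {
  if (anyNA(wt_rank) || anyNA(mut_rank)) {
    abort("Both `wt_rank` and `mut_rank` are required to compute the DAI.")
  }
  wt_rank - mut_rank
}

#' Anchor-mutation flag (C27)
#'
#' 1 when the mutation position is an anchor site (position 1, 2 or the
#' C-terminus), 0 otherwise.
#'
#' @param position 1-based mutation position(s).
#' @param length Peptide length(s).
#' @return Integer vector of 0/1 flags.
#' @examples
#' anchor_mutation_flag(2, 9)  # 1
#' anchor_mutation_flag(5, 9)  # 0
#' @export
anchor_mutation_flag <- function(position, length) {
  as.integer(position == 1L | position == 2L | position == length)
}

#' Validate a wild-type/mutant pair table
#'
#' @param pairs Data frame with columns \code{wt_sequence},
#'   \code{mut_sequence} and optionally \code{id}, \code{hla_allele},
#'   \code{wt_rank_percent}, \code{mut_rank_percent}, \code{label}.
#' @param require_rank Require both rank columns (default \code{TRUE}).
#' @return Tibble with a derived \code{mutation_position} column.
#' @export
validate_pairs <- function(pairs, require_rank = TRUE) {
  need <- c("wt_sequence", "mut_sequence")
  if (!is.data.frame(pairs) || !all(need %in% names(pairs))) {
    abort("`pairs` needs `wt_sequence` and `mut_sequence` columns.")
  }
  out <- tibble::as_tibble(pairs)
  if (!"id" %in% names(out)) out$id <- paste0("pair", seq_len(nrow(out)))
  if (nrow(out) == 0L) return(out)
  if (!all(.valid_sequence(out$wt_sequence)) ||
      !all(.valid_sequence(out$mut_sequence))) {
    abort("Sequences restricted to the 20 standard amino acids.")
  }
  if (require_rank) {
    miss <- setdiff(c("wt_rank_percent", "mut_rank_percent"), names(out))
    if (length(miss) > 0L || anyNA(out$wt_rank_percent) ||
        anyNA(out$mut_rank_percent)) {
      abort(paste0("Complete `wt_rank_percent` and `mut_rank_percent` ",
                   "columns are required for neoantigen pairs."))
    }
  }
  out$mutation_position <- find_mutation(out$wt_sequence, out$mut_sequence)
  out
}

#' Assemble the neoantigen feature vector (C1-C27)
#'
#' C1-C23 are computed on the mutant sequence, C24 is the mutant's
#' rank(%), and C25-C27 are the mutation features.  Because C1-C23 ignore
#' anchor positions, a pair mutated at an anchor has a C1-C23 block
#' identical to its wild type's.
#'
#' @param pairs Pair table (see [validate_pairs()]) with both rank columns.
#' @param model A [estimate_contact_frequencies()] fit.
#' @param c22 Passed to [peptide_features()] for the C22 block
#'   (\code{"auto"} cross-fits when the pairs are labeled).
#' @return Tibble with \code{id}, \code{label} (if present) and
#'   \code{C1}..\code{C27}; exactly 27 feature columns per pair.
#' @export
neo_features <- function(pairs, model, c22 = c("auto", "cross_fit", "model")) {
  pairs <- validate_pairs(pairs, require_rank = TRUE)
  mut_pep <- tibble::tibble(
    id = pairs$id,
    sequence = pairs$mut_sequence,
    rank_percent = pairs$mut_rank_percent
  )
  if ("label" %in% names(pairs)) mut_pep$label <- pairs$label
  out <- peptide_features(mut_pep, model, c22 = c22)
  pos <- pairs$mutation_position
  len <- nchar(pairs$wt_sequence)
  wt_aa <- substr(pairs$wt_sequence, pos, pos)
  mut_aa <- substr(pairs$mut_sequence, pos, pos)
  out$C25 <- hydrophobicity_delta(wt_aa, mut_aa)
  out$C26 <- dai(pairs$wt_rank_percent, pairs$mut_rank_percent)
  out$C27 <- anchor_mutation_flag(pos, len)
  out
}
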