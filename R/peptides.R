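# Peptide records and the anchor/TCR-contact position convention.
#
# Positions are 1-based.  The N-terminal residue, position 2 and the
# C-terminal residue sit in the HLA binding groove ("anchor" sites) and are
# assumed unavailable to the T-cell receptor; every sequence feature is
# computed over the remaining positions 3..(len-1).

.valid_sequence <- function(sequence) {
  grepl(paste0("^[", paste(AA20, collapse = ""), "]+$"), sequence)
}

#' TCR-contact positions of a peptide
#'
#' Anchor sites (position 1, position 2 and the C-terminus) are excluded;
#' the remaining positions \code{3:(len-1)} are the assumed TCR-contact
#' sites.  There are always \code{len - 3} of them.
#'
#' @param sequence A single peptide sequence (uppercase, standard 20-letter
#'   alphabet), or just its length as an integer.
#' @return Integer vector of 1-based contact positions, ascending.
#' @examples
#' tcr_contact_positions("SIINFEKL")  # 3 4 5 6 7
#' @export
tcr_contact_positions <- function(sequence) {
  len <- if (is.character(sequence)) nchar(sequence) else as.integer(sequence)
  if (length(len) != 1L || is.na(len)) {
    abort("`sequence` must be a single peptide or length.")
  }
  if (len < 4L) {
    abort(paste0("Peptide length ", len, " has no TCR-contact positions; ",
                 "at least 4 residues are required."))
  }
  seq.int(3L, len - 1L)
}

#' Validate a peptide table
#'
#' Checks that a data frame of peptide records satisfies the input contract:
#' a \code{sequence} column over the 20 standard one-letter amino-acid codes
#' with lengths inside \code{[min_len, max_len]}, and (optionally present)
#' well-formed \code{id}, \code{hla_allele}, \code{rank_percent} and
#' \code{label} columns.  \code{label}, when present, must be one of
#' \code{"immunogenic"}, \code{"nonimmunogenic"}, \code{"unlabeled"} or
#' \code{NA}.
#'
#' @param peptides Data frame with at least a \code{sequence} column.
#' @param min_len,max_len Allowed sequence length range.  Defaults follow
#'   the tool's recommended prediction range of 8--12 residues; the hard
#'   lower limit for any feature computation is 4.
#' @param require_rank If \code{TRUE}, a complete non-negative
#'   \code{rank_percent} column is required.
#' @return The input as a tibble (invisibly unchanged apart from class),
#'   with an \code{id} column added if absent.
#' @export
validate_peptides <- function(peptides, min_len = 8L, max_len = 12L,
                              require_rank = FALSE) {
  if (!is.data.frame(peptides) || !"sequence" %in% names(peptides)) {
    abort("`peptides` must be a data frame with a `sequence` column.")
  }
  out <- tibble::as_tibble(peptides)
  if (!"id" %in% names(out)) out$id <- paste0("pep", seq_len(nrow(out)))
  if (nrow(out) == 0L) return(out)
  if (any(is.na(out$sequence)) || !all(.valid_sequence(out$sequence))) {
    bad <- out$id[is.na(out$sequence) | !.valid_sequence(out$sequence)]
    abort(paste0("Sequences restricted to the 20 standard amino acids; ",
                 "invalid record(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  len <- nchar(out$sequence)
  if (min_len < 4L) abort("`min_len` must be at least 4.")
  if (any(len < min_len | len > max_len)) {
    bad <- out$id[len < min_len | len > max_len]
    abort(paste0("Sequence length outside [", min_len, ", ", max_len,
                 "] for record(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  if ("label" %in% names(out)) {
    ok <- is.na(out$label) |
      out$label %in% c("immunogenic", "nonimmunogenic", "unlabeled")
    if (!all(ok)) {
      abort("`label` must be 'immunogenic', 'nonimmunogenic', 'unlabeled' or NA.")
    }
  }
  if (require_rank) {
    if (!"rank_percent" %in% names(out) || any(is.na(out$rank_percent))) {
      abort(paste0("A complete `rank_percent` column (eluted-ligand ",
                   "percentile rank from an MHC-binding predictor) is ",
                   "required; supply it with your input."))
    }
    if (any(out$rank_percent < 0)) abort("`rank_percent` must be non-negative.")
  }
  out
}

# Split sequences into a list of per-position residue vectors (internal)
.residues <- function(sequences) strsplit(sequences, "", fixed = TRUE)

# Contact residues of each sequence as a list (internal)
.contact_residues <- function(sequences) {
  lapply(.residues(sequences), function(r) {
    if (length(r) < 4L) {
      abort("Peptides shorter than 4 residues have no TCR-contact positions.")
    }
    r[seq.int(3L, length(r) - 1L)]
  })
}
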