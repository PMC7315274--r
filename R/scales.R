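# Embedded amino-acid property scales (C1-C21).
# Values are frozen transcriptions of the ProtScale/ExPASy renderings of the
# cited literature scales; see inst/extdata/aa_scales.tsv for the exact
# variant shipped (minor numeric variants of some scales exist across
# references).

.scales_env <- new.env(parent = emptyenv())

.load_scales <- function() {
  if (!is.null(.scales_env$tbl)) return(.scales_env$tbl)
  path <- system.file("extdata", "aa_scales.tsv", package = "immunopep",
                      mustWork = TRUE)
  tbl <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  .scales_env$tbl <- tbl
  tbl
}

#' Amino-acid property scales bundled with the package
#'
#' The 21 per-residue physicochemical characteristics (identifiers
#' \code{C1}--\code{C21}) used as sequence features: Kyte--Doolittle
#' hydropathy, molecular weight, bulkiness, polarity, recognition factors,
#' hydrophobicity, HPLC retention, hetero end/side ratio, flexibility,
#' secondary-structure propensities, mutability, codon count, refractivity,
#' transmembrane tendency, accessibility and buried area.  Each scale assigns
#' one real number to each of the 20 standard amino acids.
#'
#' @return A tibble with columns \code{scale_id}, \code{scale_name},
#'   \code{citation}, \code{aa}, \code{value} (420 rows: 21 scales x 20
#'   residues).
#' @examples
#' aa_scales()
#' @export
aa_scales <- function() .load_scales()

#' Look up one amino-acid scale by identifier
#'
#' @param id Scale identifier, one of \code{"C1"} ... \code{"C21"}.
#' @return A named numeric vector of length 20 (names are one-letter
#'   amino-acid codes) with attributes \code{id}, \code{scale_name} and
#'   \code{citation}.
#' @examples
#' kd <- get_scale("C1")
#' kd[["I"]]  # 4.5
#' @export
get_scale <- function(id) {
  tbl <- .load_scales()
  ids <- unique(tbl$scale_id)
  if (!is.character(id) || length(id) != 1L || !id %in% ids) {
    abort(paste0("Unknown scale id ", deparse(id), ". Valid identifiers: ",
                 paste(ids, collapse = ", ")))
  }
  sub <- tbl[tbl$scale_id == id, ]
  v <- setNames(sub$value, sub$aa)[AA20]
  structure(v, id = id, scale_name = sub$scale_name[1],
            citation = sub$citation[1])
}

# All 21 scales as a named list of named vectors (internal fast path)
.all_scales <- function() {
  if (is.null(.scales_env$list)) {
    tbl <- .load_scales()
    ids <- unique(tbl$scale_id)
    .scales_env$list <- lapply(setNames(ids, ids), get_scale)
  }
  .scales_env$list
}

#' Background amino-acid frequencies of the human proteome
#'
#' Frozen default table of relative amino-acid frequencies in the human
#' reference proteome, used as the background distribution for the peptide
#' entropy feature when no proteome FASTA is supplied.  Values are
#' approximate published human-proteome frequencies, renormalized to sum
#' to one.
#'
#' @return A named numeric vector over the 20 standard amino acids summing
#'   to 1.
#' @examples
#' sum(background_frequencies())  # 1
#' @export
background_frequencies <- function() {
  if (is.null(.scales_env$bg)) {
    path <- system.file("extdata", "background_aa_freqs.tsv",
                        package = "immunopep", mustWork = TRUE)
    tbl <- read.delim(path, stringsAsFactors = FALSE)
    bg <- setNames(tbl$freq, tbl$aa)[AA20]
    .scales_env$bg <- bg / sum(bg)
  }
  .scales_env$bg
}
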