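# Dataset curation: length filter, deduplication, negative-set filters
# (binding rank, proteome identity), and HLA allele -> supertype mapping.
#
# Fixed cascade order: length -> dedup -> rank -> proteome -> supertype.
# Rationale for the negative-only filters: a nonimmunogenic call can be an
# artifact of non-presentation (rank(%) > 2 means the peptide is predicted
# not to bind the HLA molecule at all) or of central tolerance (the peptide
# occurs verbatim in the human proteome), so such records are not
# informative negatives for TCR recognition.

.supertype_table <- function() {
  tibble::tribble(
    ~allele,  ~supertype,
    "A01:01", "A1",
    "A26:01", "A1",
    "A02:01", "A2",
    "A11:01", "A3",
    "A03:01", "A3",
    "A24:02", "A24",
    "A23:01", "A24",
    "B35:01", "B7",
    "B07:02", "B7",
    "B51:01", "B7",
    "B08:01", "B8",
    "B27:05", "B27",
    "B37:01", "B44",
    "B40:01", "B44",
    "B44:02", "B44",
    "B58:01", "B58",
    "B15:01", "B62"
  )
}

#' Bundled HLA allele to supertype map
#'
#' The 17 HLA class-I alleles covered by the training design, grouped into
#' functional supertypes (A1, A2, A3, A24, B7, B8, B27, B44, B58, B62).
#'
#' @return Tibble with columns \code{allele} (normalized, e.g.
#'   \code{"A02:01"}) and \code{supertype}.
#' @export
hla_supertypes <- function() .supertype_table()

#' Normalize an HLA allele name
#'
#' Canonicalizes the common notations \code{"HLA-A*02:01"},
#' \code{"A*02:01"}, \code{"A0201"} and \code{"A02:01"} to
#' \code{"A02:01"}.
#'
#' @param allele Character vector of allele names (NA passed through).
#' @return Character vector of normalized names.
#' @examples
#' normalize_allele(c("HLA-A*02:01", "B8:01"))
#' @export
normalize_allele <- function(allele) {
  x <- toupper(trimws(as.character(allele)))
  x <- sub("^HLA-", "", x)
  x <- gsub("[*]", "", x)
  # insert colon into bare 4-digit forms like A0201
  x <- sub("^([ABC])([0-9]{2})([0-9]{2})$", "\\1\\2:\\3", x)
  # left-pad 1-digit group fields like A2:01
  x <- sub("^([ABC])([0-9]):", "\\1 0\\2:", x)
  x <- gsub(" ", "", x)
  x[is.na(allele)] <- NA_character_
  x
}

#' Map HLA alleles to supertypes
#'
#' @param allele Character vector of allele names (any common notation).
#' @param map Supertype map tibble, by default the bundled
#'   [hla_supertypes()] table.
#' @return Character vector of supertype labels; \code{NA} for unmapped
#'   alleles so callers can filter on it.
#' @examples
#' map_allele_to_supertype("HLA-A*02:01")  # "A2"
#' @export
map_allele_to_supertype <- function(allele, map = hla_supertypes()) {
  norm <- normalize_allele(allele)
  map$supertype[match(norm, map$allele)]
}

# --- curation report plumbing -------------------------------------------

.empty_report <- function() {
  list(stages = tibble::tibble(stage = character(), class = character(),
                               n_before = integer(), n_removed = integer(),
                               n_after = integer()),
       removed = tibble::tibble(id = character(), stage = character(),
                                reason = character()))
}

.get_report <- function(df) {
  rep <- attr(df, "curation_report")
  if (is.null(rep)) .empty_report() else rep
}

# revalidate without losing the accumulated report attribute
.revalidate <- function(records, ...) {
  rep <- attr(records, "curation_report")
  out <- validate_peptides(records, ...)
  if (!is.null(rep)) attr(out, "curation_report") <- rep
  out
}

.record_stage <- function(df_before, keep, stage, reason) {
  df_after <- df_before[keep, , drop = FALSE]
  rep <- .get_report(df_before)
  cls <- function(d) {
    if ("label" %in% names(d)) ifelse(is.na(d$label), "unlabeled", d$label)
    else rep("unlabeled", nrow(d))
  }
  cb <- cls(df_before); ca <- cb[keep]
  classes <- sort(unique(cb))
  if (length(classes) == 0L) classes <- "unlabeled"
  stage_rows <- tibble::tibble(
    stage = stage, class = classes,
    n_before = vapply(classes, function(k) sum(cb == k), integer(1)),
    n_after = vapply(classes, function(k) sum(ca == k), integer(1))
  )
  stage_rows$n_removed <- stage_rows$n_before - stage_rows$n_after
  stage_rows <- stage_rows[, c("stage", "class", "n_before", "n_removed", "n_after")]
  removed_rows <- tibble::tibble(
    id = as.character(df_before$id[!keep]), stage = stage, reason = reason
  )
  rep$stages <- dplyr::bind_rows(rep$stages, stage_rows)
  rep$removed <- dplyr::bind_rows(rep$removed, removed_rows)
  attr(df_after, "curation_report") <- rep
  df_after
}

#' Retrieve the curation report accumulated on a peptide table
#'
#' Each curation filter annotates its output with a running report.  The
#' report lists, per cascade stage and label class, the record counts
#' before and after the stage (monotonically non-increasing), and the id
#' and removal reason of every dropped record.
#'
#' @param records A table returned by one of the curation filters.
#' @return A list with tibbles \code{stages} and \code{removed}.
#' @export
curation_report <- function(records) .get_report(records)

# --- filters -------------------------------------------------------------

#' Length filter
#'
#' Retains records whose sequence length lies in \code{[min, max]}.  The
#' training default is 8--11 residues; prediction accepts up to 12.
#'
#' @param records Peptide table.
#' @param min,max Inclusive length bounds.
#' @return Filtered tibble carrying a [curation_report()].
#' @export
filter_by_length <- function(records, min = 8L, max = 11L) {
  records <- .revalidate(records, min_len = 4L, max_len = 1000L)
  len <- nchar(records$sequence)
  .record_stage(records, len >= min & len <= max, "length",
                paste0("length outside [", min, ", ", max, "]"))
}

#' Deduplicate peptide records
#'
#' One record is kept per (sequence, HLA allele) key.  When duplicates
#' carry conflicting labels the immunogenic record wins: any validated
#' T-cell response marks the peptide immunogenic.
#'
#' @param records Peptide table.
#' @return Filtered tibble carrying a [curation_report()].
#' @export
deduplicate_peptides <- function(records) {
  records <- .revalidate(records, min_len = 4L, max_len = 1000L)
  allele <- if ("hla_allele" %in% names(records)) {
    normalize_allele(records$hla_allele)
  } else rep("", nrow(records))
  key <- paste0(records$sequence, "|", allele)
  lab <- if ("label" %in% names(records)) records$label else rep(NA, nrow(records))
  # within each key prefer the immunogenic record, then first occurrence
  pref <- ifelse(!is.na(lab) & lab == "immunogenic", 0L, 1L)
  ord <- order(pref, seq_len(nrow(records)))
  keep_first <- !duplicated(key[ord])
  keep <- logical(nrow(records))
  keep[ord] <- keep_first
  .record_stage(records, keep, "dedup", "duplicate (sequence, allele) record")
}

#' Negative-set binding-rank filter
#'
#' Removes nonimmunogenic records whose eluted-ligand percentile rank
#' exceeds the threshold (strictly greater than 2 by default): such
#' peptides are predicted not to be presented at all, so their lack of a
#' T-cell response says nothing about TCR recognition.  Immunogenic records
#' are retained regardless of rank.
#'
#' @param records Peptide table with a complete \code{rank_percent} column.
#' @param threshold Removal threshold; a negative with
#'   \code{rank_percent > threshold} is dropped (rank exactly equal to the
#'   threshold is retained).
#' @return Filtered tibble carrying a [curation_report()].
#' @export
filter_negatives_by_rank <- function(records, threshold = 2) {
  records <- .revalidate(records, min_len = 4L, max_len = 1000L,
                               require_rank = TRUE)
  lab <- if ("label" %in% names(records)) records$label else rep(NA, nrow(records))
  drop <- !is.na(lab) & lab == "nonimmunogenic" & records$rank_percent > threshold
  .record_stage(records, !drop, "rank",
                paste0("nonimmunogenic with rank(%) > ", threshold))
}

#' Negative-set human-proteome identity filter
#'
#' Removes nonimmunogenic records whose sequence occurs verbatim as a
#' substring of any protein in the reference proteome (immune tolerance to
#' exact self peptides).  Immunogenic records are retained regardless.
#'
#' @param records Peptide table.
#' @param proteome Character vector of protein sequences (e.g. read from a
#'   FASTA with [read_proteome()]).
#' @return Filtered tibble carrying a [curation_report()].
#' @export
filter_negatives_by_proteome <- function(records, proteome) {
  records <- .revalidate(records, min_len = 4L, max_len = 1000L)
  if (length(proteome) == 0L) abort("`proteome` must be non-empty.")
  proteome <- toupper(proteome)
  lab <- if ("label" %in% names(records)) records$label else rep(NA, nrow(records))
  is_neg <- !is.na(lab) & lab == "nonimmunogenic"
  in_proteome <- vapply(records$sequence, function(s) {
    any(vapply(proteome, function(p) grepl(s, p, fixed = TRUE), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  drop <- is_neg & in_proteome
  .record_stage(records, !drop, "proteome",
                "nonimmunogenic, 100% match to human reference proteome")
}

#' Supertype filter
#'
#' Removes records whose HLA allele is unmapped or maps to a supertype
#' outside the allowed set (peptides presented by supertypes absent from
#' the training set cannot be scored consistently).
#'
#' @param records Peptide table with an \code{hla_allele} column.
#' @param allowed Character vector of allowed supertype labels; default all
#'   supertypes in \code{map}.
#' @param map Supertype map, default [hla_supertypes()].
#' @return Filtered tibble carrying a [curation_report()].
#' @export
filter_by_supertype <- function(records, allowed = NULL,
                                map = hla_supertypes()) {
  records <- .revalidate(records, min_len = 4L, max_len = 1000L)
  if (is.null(allowed)) allowed <- unique(map$supertype)
  if (length(allowed) == 0L) abort("`allowed` must be non-empty.")
  if (!"hla_allele" %in% names(records)) {
    abort("`records` needs an `hla_allele` column for the supertype filter.")
  }
  st <- map_allele_to_supertype(records$hla_allele, map)
  keep <- !is.na(st) & st %in% allowed
  .record_stage(records, keep, "supertype",
                "allele unmapped or supertype outside training set")
}

#' Run the full curation cascade
#'
#' Applies, in fixed order: length filter, deduplication, negative
#' binding-rank filter, negative proteome-identity filter (if a proteome is
#' given) and supertype filter (if requested).  The cascade is idempotent:
#' re-running it on its own output removes nothing.
#'
#' @param records Labeled peptide table.
#' @param proteome Optional character vector of protein sequences.
#' @param min_len,max_len Length bounds (training defaults 8--11).
#' @param rank_threshold Negative-set rank(%) removal threshold.
#' @param allowed_supertypes \code{NULL} to skip the supertype filter, or a
#'   character vector of supertype labels (use
#'   \code{unique(hla_supertypes()$supertype)} for "all mapped").
#' @param map Supertype map.
#' @return Curated tibble; inspect the cascade with [curation_report()].
#' @export
curate_peptides <- function(records, proteome = NULL, min_len = 8L,
                            max_len = 11L, rank_threshold = 2,
                            allowed_supertypes = NULL,
                            map = hla_supertypes()) {
  attr(records, "curation_report") <- NULL  # each cascade reports afresh
  out <- filter_by_length(records, min = min_len, max = max_len)
  out <- deduplicate_peptides(out)
  out <- filter_negatives_by_rank(out, threshold = rank_threshold)
  if (!is.null(proteome)) out <- filter_negatives_by_proteome(out, proteome)
  if (!is.null(allowed_supertypes)) {
    out <- filter_by_supertype(out, allowed = allowed_supertypes, map = map)
  }
  out
}
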