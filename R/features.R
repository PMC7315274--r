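# Sequence-derived immunogenicity features.
#
# Every feature is computed over TCR-contact positions only (3..len-1).
# C1-C21  mean physicochemical scale value over contact positions
# C22     class-conditional contact-site frequency score (unnormalized sum)
# C23     background-frequency peptide entropy, length-normalized
# C24     eluted-ligand percentile rank, supplied with the input

#' Mean scale value over TCR-contact positions
#'
#' For a peptide \eqn{P} and a per-residue characteristic \eqn{c}, computes
#' \deqn{P_c = \sum_{x \in contact} c(A_x) / (len(P) - 3)}
#' where the contact positions exclude the two N-terminal-side anchors
#' (positions 1 and 2) and the C-terminus.
#'
#' @param sequences Character vector of peptide sequences.
#' @param scale A scale identifier (\code{"C1"}..\code{"C21"}) or a named
#'   numeric vector mapping one-letter residue codes to values (as returned
#'   by [get_scale()]).
#' @return Numeric vector, one value per sequence.
#' @examples
#' compute_scale_feature("SIINFEKL", "C1")  # -0.72
#' @export
compute_scale_feature <- function(sequences, scale) {
  if (is.character(scale) && length(scale) == 1L) scale <- get_scale(scale)
  if (is.null(names(scale)) || !all(AA20 %in% names(scale))) {
    abort("`scale` must cover all 20 standard amino acids.")
  }
  contacts <- .contact_residues(sequences)
  vapply(seq_along(contacts), function(i) {
    res <- contacts[[i]]
    v <- scale[res]
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort(paste0("Residue '", res[bad], "' at contact position ",
                   bad + 2L, " of sequence ", i, " has no scale value."))
    }
    sum(v) / length(v)
  }, numeric(1))
}

#' Estimate class-conditional contact-site amino-acid frequencies
#'
#' Pools the TCR-contact residues of all immunogenic and all nonimmunogenic
#' peptides and estimates one amino-acid frequency table per class, plus a
#' background table from a reference proteome.  Laplace smoothing
#' (\code{pseudocount} per residue) keeps every frequency strictly positive,
#' so the entropy feature is defined for all residues and the frequency
#' score is stable for rare residues.
#'
#' @param peptides Data frame with \code{sequence} and \code{label} columns
#'   (labels \code{"immunogenic"} / \code{"nonimmunogenic"}; other rows are
#'   ignored for the class tables).
#' @param background Either \code{NULL} (use the shipped human-proteome
#'   table, see [background_frequencies()]), a named frequency vector over
#'   the 20 residues, or a character vector of protein sequences whose
#'   pooled residue composition is used.
#' @param pseudocount Laplace pseudocount added per amino acid (default 1;
#'   0 disables smoothing for the class tables).
#' @return An object of class \code{frequency_model}: smoothed frequency
#'   vectors \code{f_pos}, \code{f_neg}, \code{f_background}, the raw
#'   contact-residue counts per class, and bookkeeping needed to apply
#'   leave-one-out corrections when scoring the very peptides the model was
#'   estimated from.
#' @examples
#' peps <- tibble::tibble(
#'   sequence = c("SIINFEKLL", "ALAKAAAAM"),
#'   label = c("immunogenic", "nonimmunogenic"))
#' m <- estimate_contact_frequencies(peps)
#' sum(m$f_pos)  # 1
#' @export
estimate_contact_frequencies <- function(peptides, background = NULL,
                                         pseudocount = 1) {
  peptides <- validate_peptides(peptides, min_len = 4L, max_len = 1000L)
  if (!"label" %in% names(peptides)) {
    abort("`peptides` must carry a `label` column to estimate class frequencies.")
  }
  pos <- peptides[!is.na(peptides$label) & peptides$label == "immunogenic", ]
  neg <- peptides[!is.na(peptides$label) & peptides$label == "nonimmunogenic", ]
  if (nrow(pos) == 0L || nrow(neg) == 0L) {
    abort("At least one immunogenic and one nonimmunogenic peptide are required.")
  }
  count_class <- function(df) {
    res <- unlist(.contact_residues(df$sequence))
    cnt <- table(factor(res, levels = AA20))
    setNames(as.numeric(cnt), AA20)
  }
  counts_pos <- count_class(pos)
  counts_neg <- count_class(neg)
  smooth <- function(cnt, pc) (cnt + pc) / (sum(cnt) + 20 * pc)

  if (is.null(background)) {
    f_bg <- background_frequencies()
  } else if (is.numeric(background)) {
    if (!all(AA20 %in% names(background))) {
      abort("A numeric `background` must be named over the 20 amino acids.")
    }
    f_bg <- background[AA20]
    f_bg <- (f_bg + pseudocount * 1e-12) / sum(f_bg + pseudocount * 1e-12)
  } else {
    res <- unlist(strsplit(toupper(background), "", fixed = TRUE))
    res <- res[res %in% AA20]
    if (length(res) == 0L) abort("`background` proteome contains no standard residues.")
    cnt <- setNames(as.numeric(table(factor(res, levels = AA20))), AA20)
    f_bg <- smooth(cnt, max(pseudocount, 1))  # background must be strictly > 0
  }
  if (any(f_bg <= 0)) abort("Background frequencies must be strictly positive.")

  structure(list(
    f_pos = smooth(counts_pos, pseudocount),
    f_neg = smooth(counts_neg, pseudocount),
    f_background = f_bg / sum(f_bg),
    counts_pos = counts_pos,
    counts_neg = counts_neg,
    n_pos = sum(counts_pos), n_neg = sum(counts_neg),
    n_peptides_pos = nrow(pos), n_peptides_neg = nrow(neg),
    pseudocount = pseudocount
  ), class = "frequency_model")
}

#' @export
print.frequency_model <- function(x, ...) {
  cat("<frequency_model>\n")
  cat("  contact residues: ", x$n_pos, " immunogenic (", x$n_peptides_pos,
      " peptides), ", x$n_neg, " nonimmunogenic (", x$n_peptides_neg,
      " peptides)\n", sep = "")
  cat("  pseudocount:", x$pseudocount, "\n")
  top <- sort(x$f_pos - x$f_neg, decreasing = TRUE)
  cat("  largest positive-class enrichments:",
      paste0(names(top)[1:3], " (", sprintf("%+.3f", top[1:3]), ")",
             collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn estimate_contact_frequencies Long-format tidy view of a
#'   frequency model: one row per amino acid with the positive-class,
#'   negative-class and background frequencies and their difference.
#' @param x A \code{frequency_model}.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.frequency_model <- function(x, ...) {
  tibble::tibble(
    aa = AA20,
    f_pos = unname(x$f_pos),
    f_neg = unname(x$f_neg),
    f_background = unname(x$f_background),
    difference = unname(x$f_pos - x$f_neg)
  )
}

#' Contact-site frequency score (C22)
#'
#' Sum, over the TCR-contact positions of a peptide, of the difference
#' between the immunogenic-class and nonimmunogenic-class frequency of the
#' residue at that position:
#' \deqn{P_{score} = \sum_{x \in contact} [f^+(A_x) - f^-(A_x)]}
#' The sum is not length-normalized by default.
#'
#' @param sequences Character vector of peptides.
#' @param model A [estimate_contact_frequencies()] fit.
#' @param normalize Divide by \code{len - 3}?  Off by default (the score is
#'   defined as a plain sum); provided for sensitivity analyses.
#' @return Numeric vector of scores.
#' @export
frequency_score <- function(sequences, model, normalize = FALSE) {
  stopifnot(inherits(model, "frequency_model"))
  diff <- model$f_pos - model$f_neg
  contacts <- .contact_residues(sequences)
  vapply(contacts, function(res) {
    s <- sum(diff[res])
    if (normalize) s / length(res) else s
  }, numeric(1))
}

#' Background-frequency peptide entropy (C23)
#'
#' Length-normalized information score of the contact residues under the
#' background (human-proteome) amino-acid distribution:
#' \deqn{P_H = -\sum_{x \in contact} f(A_x)\,\log_2 f(A_x) \; / \; (len - 3)}
#' Each residue contributes according to its background frequency, so the
#' score is non-negative whenever all background frequencies lie in (0, 1].
#'
#' @param sequences Character vector of peptides.
#' @param background A \code{frequency_model} (its \code{f_background} is
#'   used) or a named strictly-positive frequency vector over the 20
#'   residues.
#' @return Numeric vector of entropies (bits).
#' @export
peptide_entropy <- function(sequences, background) {
  f <- if (inherits(background, "frequency_model")) {
    background$f_background
  } else background
  if (is.null(names(f)) || !all(AA20 %in% names(f))) {
    abort("`background` must cover all 20 standard amino acids.")
  }
  f <- f[AA20]
  if (any(f <= 0)) {
    abort("Background frequency of every residue must be strictly positive.")
  }
  term <- -f * log2(f)
  contacts <- .contact_residues(sequences)
  vapply(contacts, function(res) sum(term[res]) / length(res), numeric(1))
}

# Cross-fitted frequency score for a labeled table.  A peptide's own class
# frequencies must not be estimated from data that includes the peptide,
# or the shared estimation noise couples the score to the label and a
# downstream classifier can exploit it even on label-free data.  The table
# is therefore dealt into `folds` interleaved folds within each class, and
# every fold is scored against frequencies estimated from the other folds
# only.  Deterministic (no RNG).
.cross_fit_c22 <- function(peptides, pseudocount = 1, folds = 10L,
                           normalize = FALSE) {
  lab <- peptides$label
  contacts <- .contact_residues(peptides$sequence)
  count_rows <- function(rows) {
    res <- unlist(contacts[rows])
    if (length(res) == 0L) return(setNames(numeric(20), AA20))
    setNames(as.numeric(table(factor(res, levels = AA20))), AA20)
  }
  is_pos <- !is.na(lab) & lab == "immunogenic"
  is_neg <- !is.na(lab) & lab == "nonimmunogenic"
  folds <- max(2L, min(folds, sum(is_pos), sum(is_neg)))
  fold <- integer(nrow(peptides))
  fold[is_pos] <- (seq_len(sum(is_pos)) - 1L) %% folds + 1L
  fold[is_neg] <- (seq_len(sum(is_neg)) - 1L) %% folds + 1L
  cp_fold <- lapply(seq_len(folds), function(k) count_rows(is_pos & fold == k))
  cn_fold <- lapply(seq_len(folds), function(k) count_rows(is_neg & fold == k))
  cp_tot <- Reduce(`+`, cp_fold)
  cn_tot <- Reduce(`+`, cn_fold)
  smooth <- function(cnt) (cnt + pseudocount) / (sum(cnt) + 20 * pseudocount)
  full_diff <- smooth(cp_tot) - smooth(cn_tot)
  out <- numeric(nrow(peptides))
  for (k in seq_len(folds)) {
    diff_k <- smooth(cp_tot - cp_fold[[k]]) - smooth(cn_tot - cn_fold[[k]])
    rows <- which(fold == k)
    out[rows] <- vapply(contacts[rows],
                        function(res) sum(diff_k[res]), numeric(1))
  }
  unlabeled <- which(fold == 0L)
  out[unlabeled] <- vapply(contacts[unlabeled],
                           function(res) sum(full_diff[res]), numeric(1))
  if (normalize) out / lengths(contacts) else out
}

#' Assemble the antigen feature vector (C1-C24)
#'
#' Computes the full 24-feature description of each peptide: the 21 scale
#' averages, the contact-site frequency score, the background entropy, and
#' the supplied eluted-ligand percentile rank.  All sequence features depend
#' only on the TCR-contact positions, so records differing solely at anchor
#' positions get identical C1-C23 blocks.
#'
#' When a labeled table is scored against frequencies estimated from that
#' same table, C22 is cross-fitted by default: the table is split into
#' interleaved folds per class and each fold is scored with class
#' frequencies estimated from the other folds only, so no peptide's score
#' depends on its own label.  Prediction-time assembly against a stored
#' training model uses \code{c22 = "model"} (plain scoring).
#'
#' @param peptides Peptide table with \code{id}, \code{sequence},
#'   \code{rank_percent} and optionally \code{label}.
#' @param model A [estimate_contact_frequencies()] fit supplying the class
#'   and background frequency tables.
#' @param c22 How to compute the frequency score: \code{"auto"} (the
#'   default; cross-fit when both classes are present in \code{peptides},
#'   otherwise score against \code{model}), \code{"cross_fit"}, or
#'   \code{"model"}.
#' @param cross_fit_folds Folds for the cross-fitted score (default 10).
#' @param normalize_frequency_score Length-normalize C22 (default
#'   \code{FALSE}, the score is a plain sum).
#' @return Tibble with \code{id}, \code{label} (if present) and columns
#'   \code{C1}..\code{C24}; one row per peptide, no missing values.
#' @export
peptide_features <- function(peptides, model,
                             c22 = c("auto", "cross_fit", "model"),
                             cross_fit_folds = 10L,
                             normalize_frequency_score = FALSE) {
  c22 <- match.arg(c22)
  peptides <- validate_peptides(peptides, min_len = 4L, max_len = 1000L,
                                require_rank = TRUE)
  stopifnot(inherits(model, "frequency_model"))
  both_classes <- "label" %in% names(peptides) &&
    all(c("immunogenic", "nonimmunogenic") %in% peptides$label)
  if (c22 == "auto") c22 <- if (both_classes) "cross_fit" else "model"
  if (c22 == "cross_fit" && !both_classes) {
    abort("Cross-fitted C22 needs both classes present; use c22 = \"model\".")
  }
  scales <- .all_scales()
  out <- tibble::tibble(id = peptides$id)
  if ("label" %in% names(peptides)) out$label <- peptides$label
  for (sid in names(scales)) {
    out[[sid]] <- compute_scale_feature(peptides$sequence, scales[[sid]])
  }
  out$C22 <- if (c22 == "cross_fit") {
    .cross_fit_c22(peptides, pseudocount = model$pseudocount,
                   folds = cross_fit_folds,
                   normalize = normalize_frequency_score)
  } else {
    frequency_score(peptides$sequence, model,
                    normalize = normalize_frequency_score)
  }
  out$C23 <- peptide_entropy(peptides$sequence, model)
  out$C24 <- peptides$rank_percent
  out
}

# Feature column ids per mode (internal)
.feature_ids <- function(mode = c("antigen", "neoantigen")) {
  mode <- match.arg(mode)
  base <- paste0("C", 1:24)
  if (mode == "neoantigen") c(base, "C25", "C26", "C27") else base
}
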