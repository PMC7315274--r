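# Random-forest training with repeated stratified cross-validation,
# score-band prediction, and rank-sum ROC/AUC.

POSITIVE_CLASS <- "immunogenic"

.as_label_factor <- function(label) {
  if (is.factor(label)) label <- as.character(label)
  if (is.logical(label)) {
    label <- ifelse(label, POSITIVE_CLASS, "nonimmunogenic")
  }
  if (is.numeric(label)) label <- ifelse(label > 0, POSITIVE_CLASS, "nonimmunogenic")
  factor(label, levels = c("nonimmunogenic", POSITIVE_CLASS))
}

# Stratified fold assignment: within each class, shuffle and deal into folds
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Rank-sum ROC curve and AUC
#'
#' AUC by the Mann--Whitney formulation: the probability that a random
#' positive scores above a random negative, with ties counted half.  Curve
#' points (FPR, TPR) are emitted at every distinct score threshold for
#' plotting.
#'
#' @param scores Numeric prediction scores (higher = more immunogenic).
#' @param labels Class labels: \code{"immunogenic"}/\code{"nonimmunogenic"},
#'   logical, or 0/1.
#' @return Object of class \code{ep_roc}: \code{auc}, a \code{curve}
#'   tibble (\code{threshold}, \code{fpr}, \code{tpr}) and class counts.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc  # 1
#' @export
roc_auc <- function(scores, labels) {
  y <- .as_label_factor(labels)
  if (anyNA(scores) || anyNA(y)) abort("`scores` and `labels` must be complete.")
  pos <- y == POSITIVE_CLASS
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    abort("Both classes must be present to compute an ROC curve.")
  }
  r <- rank(scores)  # average ranks handle ties as half-weight pairs
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & pos), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !pos), numeric(1))
  curve <- tibble::tibble(
    threshold = c(Inf, thr),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "ep_roc")
}

#' @export
print.ep_roc <- function(x, ...) {
  cat("<ep_roc> AUC = ", sprintf("%.4f", x$auc), " (", x$n_pos,
      " positives, ", x$n_neg, " negatives)\n", sep = "")
  invisible(x)
}

#' @describeIn roc_auc ROC curve with the AUC in the caption.
#' @param object An \code{ep_roc}.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.ep_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = "ROC curve",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Score bands for predicted immunogenicity
#'
#' Maps a forest vote fraction to the reporting categories: scores above
#' 0.5 are \code{"positive-high"}, scores in \eqn{[0.4, 0.5]} are
#' \code{"positive-low"}, scores below 0.4 are \code{"negative-high"}.
#' Boundary values land in \code{"positive-low"}.
#'
#' @param score Numeric scores in \eqn{[0, 1]}.
#' @param low,high Band boundaries (defaults 0.4 and 0.5).
#' @return Character vector of categories.
#' @examples
#' categorize(c(0.60, 0.45, 0.30))
#' @export
categorize <- function(score, low = 0.4, high = 0.5) {
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    abort("Scores must lie in [0, 1].")
  }
  dplyr::case_when(
    score > high ~ "positive-high",
    score >= low ~ "positive-low",
    .default = "negative-high"
  )
}

#' Train the immunogenicity random forest with repeated cross-validation
#'
#' Fits a random-forest classifier after estimating out-of-fold performance
#' by repeated stratified k-fold cross-validation (default 3 x 5-fold).
#' Within a repeat every record is scored exactly once by a forest that
#' never saw it; out-of-fold scores are pooled per repeat into one AUC and
#' the repeat AUCs averaged.  The returned bundle is refit on all data.
#'
#' \code{data} may be either a raw table or a pre-assembled feature table:
#' \itemize{
#'   \item a labeled peptide table (has a \code{sequence} column) or
#'     mutant-pair table (has \code{mut_sequence}): features are assembled
#'     internally and, crucially, the class frequency tables behind C22 are
#'     re-estimated inside every cross-validation training fold, so
#'     held-out folds are scored by a frequency model that never saw them.
#'     This is the recommended path: it keeps the cross-validated AUC free
#'     of frequency-estimation leakage.
#'   \item a feature tibble with \code{label} and \code{C1...} columns:
#'     used as-is.  If its C22 was computed against frequencies estimated
#'     from the same records without cross-fitting, the CV estimate can be
#'     optimistic; assemble with [peptide_features()] (which cross-fits by
#'     default) to avoid this.
#' }
#'
#' @param data Labeled peptide table, mutant-pair table, or feature tibble
#'   (see Details); \code{id} optional.
#' @param mode \code{"antigen"} or \code{"neoantigen"}; sets the default
#'   feature schema and \code{mtry} (15 and 14 respectively).  Inferred
#'   from the input columns for raw tables.
#' @param features Feature columns to use; default the full schema of the
#'   mode (pass [confirmed_features()] output to train on a screened
#'   subset).
#' @param mtry Variables tried per split; default 15 (antigen) / 14
#'   (neoantigen), capped at the number of features.
#' @param n_trees Trees in each forest (default 500).
#' @param folds,repeats Cross-validation geometry (default 5-fold, 3
#'   repeats).
#' @param freq_model For feature-table input only: an optional
#'   [estimate_contact_frequencies()] fit to store in the bundle so
#'   prediction-time assembly can reuse the training frequencies.  For raw
#'   input the full-data frequency model is estimated and stored
#'   automatically.
#' @param background Background source for frequency estimation on raw
#'   input (passed to [estimate_contact_frequencies()]).
#' @param seed Master integer seed driving fold assignment and forests.
#' @return Object of class \code{ep_model}: the fitted forest, feature
#'   list, score thresholds, frequency-model snapshot and an \code{ep_cv}
#'   cross-validation result under \code{$cv}.
#' @export
ep_train <- function(data, mode = c("antigen", "neoantigen"), features = NULL,
                     mtry = NULL, n_trees = 500L, folds = 5L, repeats = 3L,
                     freq_model = NULL, background = NULL, seed = 1L) {
  raw <- if ("sequence" %in% names(data)) "peptides" else
    if ("mut_sequence" %in% names(data)) "pairs" else "features"
  if (raw == "peptides" && missing(mode)) mode <- "antigen"
  if (raw == "pairs" && missing(mode)) mode <- "neoantigen"
  mode <- match.arg(mode)
  if (!"label" %in% names(data)) abort("`data` must carry a `label` column.")
  y <- .as_label_factor(data$label)
  if (anyNA(y)) abort("All records must be labeled to train.")

  # raw input: assemble features; C22 is re-estimated per CV fold below
  pep_tbl <- NULL
  if (raw != "features") {
    pep_tbl <- if (raw == "pairs") {
      pairs <- validate_pairs(data, require_rank = TRUE)
      tibble::tibble(id = pairs$id, sequence = pairs$mut_sequence,
                     rank_percent = pairs$mut_rank_percent,
                     label = pairs$label)
    } else {
      validate_peptides(data, min_len = 4L, max_len = 1000L,
                        require_rank = TRUE)
    }
    freq_model <- estimate_contact_frequencies(pep_tbl,
                                               background = background)
    data <- if (raw == "pairs") {
      neo_features(pairs, freq_model, c22 = "cross_fit")
    } else {
      peptide_features(pep_tbl, freq_model, c22 = "cross_fit")
    }
  }

  if (is.null(features)) {
    features <- intersect(.feature_ids(mode), names(data))
  }
  missing_f <- setdiff(features, names(data))
  if (length(missing_f) > 0L) {
    abort(paste0("Feature column(s) absent from `data`: ",
                 paste(missing_f, collapse = ", ")))
  }
  n <- nrow(data)
  if (n < 25L || min(table(y)) < 5L) {
    abort("Training needs at least 25 records and 5 per class for 5-fold CV.")
  }
  if (is.null(mtry)) mtry <- if (mode == "antigen") 15L else 14L
  mtry <- min(mtry, length(features))
  X <- as.matrix(data[, features, drop = FALSE])
  ids <- if ("id" %in% names(data)) as.character(data$id) else as.character(seq_len(n))
  refit_c22 <- !is.null(pep_tbl) && "C22" %in% features

  oof <- vector("list", repeats)
  withr::with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- .stratified_folds(y, folds)
      score <- numeric(n)
      for (k in seq_len(folds)) {
        tr <- fold != k
        Xtr <- X[tr, , drop = FALSE]
        Xte <- X[!tr, , drop = FALSE]
        if (refit_c22) {
          # frequency tables from the training fold only: cross-fitted
          # scores inside the fold, plain model scores for the held-out set
          fm_k <- estimate_contact_frequencies(pep_tbl[tr, ],
                                               background = background)
          Xtr[, "C22"] <- .cross_fit_c22(pep_tbl[tr, ],
                                         pseudocount = fm_k$pseudocount)
          Xte[, "C22"] <- frequency_score(pep_tbl$sequence[!tr], fm_k)
        }
        rf <- randomForest::randomForest(Xtr, y[tr],
                                         ntree = n_trees, mtry = mtry)
        score[!tr] <- predict(rf, Xte, type = "prob")[, POSITIVE_CLASS]
      }
      oof[[r]] <- tibble::tibble(repeat_ = r, fold = fold, id = ids,
                                 label = as.character(y), score = score)
    }
    final_rf <- randomForest::randomForest(X, y, ntree = n_trees, mtry = mtry,
                                           importance = TRUE)
  })
  oof <- dplyr::bind_rows(oof)

  auc_by_repeat <- oof |>
    dplyr::group_by(.data$repeat_) |>
    dplyr::summarise(auc = roc_auc(.data$score, .data$label)$auc)
  auc_by_fold <- oof |>
    dplyr::group_by(.data$repeat_, .data$fold) |>
    dplyr::summarise(auc = roc_auc(.data$score, .data$label)$auc,
                     .groups = "drop")
  pred_pos <- oof$score > 0.5
  is_pos <- oof$label == POSITIVE_CLASS
  cv <- structure(list(
    oof = oof,
    auc = mean(auc_by_repeat$auc),
    auc_by_repeat = auc_by_repeat,
    auc_by_fold = auc_by_fold,
    sensitivity = sum(pred_pos & is_pos) / sum(is_pos),
    specificity = sum(!pred_pos & !is_pos) / sum(!is_pos),
    folds = folds, repeats = repeats
  ), class = "ep_cv")

  structure(list(
    forest = final_rf,
    features = features,
    mode = mode,
    mtry = mtry, n_trees = n_trees, folds = folds, repeats = repeats,
    thresholds = c(low = 0.4, high = 0.5),
    freq_model = freq_model,
    cv = cv,
    seed = seed,
    schema_version = 1L,
    package_version = as.character(utils::packageVersion("immunopep")),
    fingerprint = rlang::hash(list(X, as.character(y)))
  ), class = "ep_model")
}

#' @export
print.ep_cv <- function(x, ...) {
  cat("<ep_cv> ", x$repeats, " x ", x$folds, "-fold cross-validation\n",
      sep = "")
  cat(sprintf("  pooled AUC (mean over repeats): %.4f\n", x$auc))
  cat(sprintf("  sensitivity %.3f / specificity %.3f at score 0.5\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
print.ep_model <- function(x, ...) {
  cat("<ep_model> ", x$mode, " mode, ", length(x$features),
      " features, mtry = ", x$mtry, ", ", x$n_trees, " trees\n", sep = "")
  print(x$cv)
  invisible(x)
}

#' Predict immunogenicity scores and categories
#'
#' Scores new feature vectors with a trained bundle.  The score is the
#' fraction of trees voting for the immunogenic class; categories follow
#' [categorize()].  When a \code{C24} (rank(%)) column is present, records
#' with rank at or above 2 are flagged: the peptide is predicted not to be
#' presented by the given HLA, so the immunogenicity score is unreliable.
#'
#' @param object A trained [ep_train()] bundle.
#' @param newdata Feature tibble covering the bundle's feature list.
#' @param ... Unused.
#' @return Tibble with \code{id}, \code{score}, \code{category} and logical
#'   \code{rank_warning}.
#' @export
predict.ep_model <- function(object, newdata, ...) {
  missing_f <- setdiff(object$features, names(newdata))
  extra_f <- setdiff(grep("^C[0-9]+$", names(newdata), value = TRUE),
                     object$features)
  if (length(missing_f) > 0L || length(extra_f) > 0L) {
    abort(paste0(
      "Feature schema mismatch with the trained bundle.",
      if (length(missing_f)) paste0(" Missing: ",
                                    paste(missing_f, collapse = ", "), "."),
      if (length(extra_f)) paste0(" Unexpected: ",
                                  paste(extra_f, collapse = ", "), ".")))
  }
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  score <- as.numeric(predict(object$forest, X,
                              type = "prob")[, POSITIVE_CLASS])
  tibble::tibble(
    id = if ("id" %in% names(newdata)) as.character(newdata$id) else
      as.character(seq_len(nrow(newdata))),
    score = score,
    category = categorize(score, object$thresholds[["low"]],
                          object$thresholds[["high"]]),
    rank_warning = if ("C24" %in% names(newdata)) newdata$C24 >= 2 else
      rep(FALSE, nrow(newdata))
  )
}

#' @describeIn ep_train Per-feature importance of the final forest.
#' @param x An \code{ep_model}.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ep_model <- function(x, ...) {
  imp <- x$forest$importance
  tibble::tibble(
    feature = rownames(imp),
    mean_decrease_accuracy = unname(imp[, "MeanDecreaseAccuracy"]),
    mean_decrease_gini = unname(imp[, "MeanDecreaseGini"])
  ) |> dplyr::arrange(dplyr::desc(.data$mean_decrease_accuracy))
}

#' @describeIn ep_train One-row model summary with the cross-validated AUC.
#' @exportS3Method generics::glance
glance.ep_model <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, n_features = length(x$features), mtry = x$mtry,
    n_trees = x$n_trees, cv_auc = x$cv$auc,
    cv_sensitivity = x$cv$sensitivity, cv_specificity = x$cv$specificity
  )
}

#' @describeIn ep_train Per-fold out-of-fold AUCs of the cross-validation.
#' @exportS3Method generics::tidy
tidy.ep_cv <- function(x, ...) x$auc_by_fold

#' @describeIn ep_train One-row cross-validation summary.
#' @exportS3Method generics::glance
glance.ep_cv <- function(x, ...) {
  tibble::tibble(folds = x$folds, repeats = x$repeats, auc = x$auc,
                 sensitivity = x$sensitivity, specificity = x$specificity)
}

#' @describeIn ep_train Pooled out-of-fold ROC curve of the first CV repeat.
#' @param object An \code{ep_cv}.
#' @exportS3Method ggplot2::autoplot
autoplot.ep_cv <- function(object, ...) {
  first <- object$oof[object$oof$repeat_ == 1, ]
  autoplot(roc_auc(first$score, first$label)) +
    ggplot2::labs(subtitle = sprintf(
      "repeat 1 pooled AUC shown; mean over %d repeats = %.3f",
      object$repeats, object$auc))
}
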