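# Shadow-feature relevance screen (Boruta-style all-relevant selection).
#
# Each iteration duplicates every still-active feature, permutes the
# duplicates ("shadows"), trains a random forest on real + shadow features,
# and scores a hit for a real feature whose importance Z score exceeds the
# best shadow's.  Hits accumulate across iterations and are tested against
# Binomial(iterations, 1/2) with a two-sided binomial test, Bonferroni-
# corrected over the starting feature set; significantly-above-chance
# features are confirmed, significantly-below rejected (and removed from
# subsequent forests), the rest stay tentative at the iteration cap.

#' Shadow-feature relevance screen
#'
#' Decides, for every feature, whether it carries more information about
#' the label than a random probe.  The importance measure is the
#' permutation-importance Z score (mean decrease in accuracy divided by its
#' standard deviation across trees); Gini impurity importance is available
#' as an alternative.
#'
#' @param data Data frame holding a \code{label} column (two classes) and
#'   numeric feature columns; \code{id} is ignored if present.
#' @param alpha Two-sided significance level for the binomial hit test
#'   (Bonferroni-corrected over the initial number of features).
#' @param max_iter Maximum shadow iterations; features still undecided then
#'   are reported \code{"tentative"}.
#' @param n_trees Trees per screening forest.
#' @param importance \code{"permutation"} (default) or \code{"gini"}.
#' @param seed Integer seed driving shadow permutations and forests.
#' @return Object of class \code{shadow_selection}: a \code{decision}
#'   tibble (feature, status, hits, iterations, p value), the per-iteration
#'   importance \code{history}, and the screen settings.
#' @export
shadow_select <- function(data, alpha = 0.01, max_iter = 30L, n_trees = 300L,
                          importance = c("permutation", "gini"), seed = 1L) {
  importance <- match.arg(importance)
  if (!"label" %in% names(data)) abort("`data` must have a `label` column.")
  y <- factor(data$label)
  if (nlevels(y) < 2L) abort("The label must have two classes for screening.")
  feats <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                   c("id", "label"))
  if (length(feats) == 0L) abort("No numeric feature columns found.")
  X <- as.matrix(data[, feats, drop = FALSE])
  n <- nrow(X)
  p0 <- length(feats)

  hits <- setNames(integer(p0), feats)
  trials <- setNames(integer(p0), feats)
  status <- setNames(rep("tentative", p0), feats)
  history <- vector("list", max_iter)

  imp_z <- function(rf, cols) {
    if (importance == "gini") {
      rf$importance[cols, "MeanDecreaseGini"]
    } else {
      m <- rf$importance[cols, "MeanDecreaseAccuracy"]
      s <- rf$importanceSD[cols, "MeanDecreaseAccuracy"]
      ifelse(s > 0, m / s, 0)
    }
  }

  withr::with_seed(seed, {
    for (it in seq_len(max_iter)) {
      active <- names(status)[status != "rejected"]
      if (!any(status == "tentative")) break
      Xa <- X[, active, drop = FALSE]
      shadows <- apply(Xa, 2, sample)
      colnames(shadows) <- paste0("shadow_", active)
      Xfull <- cbind(Xa, shadows)
      rf <- randomForest::randomForest(
        Xfull, y, ntree = n_trees,
        importance = (importance == "permutation"))
      z_real <- imp_z(rf, active)
      z_shadow <- imp_z(rf, colnames(shadows))
      shadow_max <- max(z_shadow)
      hit <- z_real > shadow_max
      undecided <- active[status[active] == "tentative"]
      hits[undecided] <- hits[undecided] + hit[undecided]
      trials[undecided] <- trials[undecided] + 1L
      history[[it]] <- tibble::tibble(
        iteration = it, feature = active,
        importance = unname(z_real), shadow_max = shadow_max,
        hit = unname(hit))
      for (f in undecided) {
        pv <- binom.test(hits[f], trials[f], 0.5,
                         alternative = "two.sided")$p.value
        if (pv * p0 < alpha) {
          status[f] <- if (hits[f] > trials[f] / 2) "confirmed" else "rejected"
        }
      }
    }
  })

  p_final <- vapply(feats, function(f) {
    if (trials[f] == 0L) return(NA_real_)
    min(1, binom.test(hits[f], trials[f], 0.5)$p.value * p0)
  }, numeric(1))

  structure(list(
    decision = tibble::tibble(
      feature = feats, status = unname(status), hits = unname(hits),
      iterations = unname(trials), p_adjusted = unname(p_final)),
    history = dplyr::bind_rows(history),
    alpha = alpha, max_iter = max_iter, n_trees = n_trees,
    importance = importance, seed = seed
  ), class = "shadow_selection")
}

#' @export
print.shadow_selection <- function(x, ...) {
  k <- table(factor(x$decision$status,
                    levels = c("confirmed", "tentative", "rejected")))
  cat("<shadow_selection> ", sum(k), " features screened (alpha = ",
      x$alpha, ", ", x$importance, " importance)\n", sep = "")
  cat("  confirmed: ", k[["confirmed"]], "  tentative: ", k[["tentative"]],
      "  rejected: ", k[["rejected"]], "\n", sep = "")
  if (k[["confirmed"]] > 0) {
    cat("  confirmed features:",
        paste(x$decision$feature[x$decision$status == "confirmed"],
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn shadow_select One row per feature with its final status,
#'   hit count and adjusted p value.
#' @param x A \code{shadow_selection}.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.shadow_selection <- function(x, ...) x$decision

#' @describeIn shadow_select One-row summary: counts per status and the
#'   settings used.
#' @exportS3Method generics::glance
glance.shadow_selection <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$decision),
    n_confirmed = sum(x$decision$status == "confirmed"),
    n_rejected = sum(x$decision$status == "rejected"),
    n_tentative = sum(x$decision$status == "tentative"),
    iterations = max(x$decision$iterations),
    alpha = x$alpha
  )
}

#' Selected (confirmed) features of a screen
#'
#' @param selection A [shadow_select()] result.
#' @param include_tentative Keep tentative features too (default
#'   \code{FALSE}).
#' @return Character vector of feature names.
#' @export
confirmed_features <- function(selection, include_tentative = FALSE) {
  stopifnot(inherits(selection, "shadow_selection"))
  keep <- c("confirmed", if (include_tentative) "tentative")
  selection$decision$feature[selection$decision$status %in% keep]
}

#' @describeIn shadow_select Importance-history boxplot per feature, with
#'   the shadow-maximum distribution as reference; confirmed features are
#'   highlighted.
#' @param object A \code{shadow_selection}.
#' @exportS3Method ggplot2::autoplot
autoplot.shadow_selection <- function(object, ...) {
  h <- object$history
  ord <- h |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(m = stats::median(.data$importance)) |>
    dplyr::arrange(.data$m)
  h$feature <- factor(h$feature, levels = ord$feature)
  dec <- object$decision[, c("feature", "status")]
  h <- dplyr::left_join(h, dec, by = "feature")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$feature, y = .data$importance,
                                  fill = .data$status)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = stats::median(h$shadow_max),
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "importance Z score",
                  title = "Shadow-feature screen",
                  subtitle = "dashed line: median of the best shadow probe") +
    ggplot2::theme_minimal()
}
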