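#' Fit a two-class Fisher linear discriminant
#'
#' Weights are proportional to `pooled-covariance^-1 (mean1 - mean2)`; a
#' sample is assigned to the first group when its discriminant score
#' exceeds the prior-adjusted midpoint of the projected class means.
#' Features are z-scored on the training data by default (qPCR dCT scales
#' differ between assays); a ridge term of `1e-6 * trace(S) / p` is added
#' when the pooled covariance is singular, and recorded on the model.
#'
#' @param expr Wide expression tibble (features x samples).
#' @param design Tibble with `sample_id`, `group`.
#' @param features Optional feature subset to fit on.
#' @param prior `"frequency"` (training class frequencies, default) or
#'   `"equal"`.
#' @param standardize Z-score features on the training samples first.
#' @return A `mir_lda` model object.
#' @export
fit_lda <- function(expr, design, features = NULL,
                    prior = c("frequency", "equal"), standardize = TRUE) {
  prior <- match.arg(prior)
  m <- expr_matrix(expr)
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(m))
    if (length(missing)) abort(paste0("unknown feature(s): ",
                                      paste(missing, collapse = ", ")))
    m <- m[features, , drop = FALSE]
  }
  d <- check_design(design, colnames(m))
  x <- t(m)  # samples x features
  if (anyNA(x)) abort("discriminant fitting requires complete expression values.")
  g1 <- x[d$g1, , drop = FALSE]
  g2 <- x[d$g2, , drop = FALSE]
  if (nrow(g1) < 2 || nrow(g2) < 2) abort("need >= 2 samples per group.")

  center <- if (standardize) colMeans(x) else rep(0, ncol(x))
  scl <- if (standardize) apply(x, 2, sd) else rep(1, ncol(x))
  if (any(scl == 0)) abort("constant feature(s); cannot standardize.")
  g1 <- sweep(sweep(g1, 2, center), 2, scl, "/")
  g2 <- sweep(sweep(g2, 2, center), 2, scl, "/")

  mu1 <- colMeans(g1); mu2 <- colMeans(g2)
  n1 <- nrow(g1); n2 <- nrow(g2)
  S <- (crossprod(sweep(g1, 2, mu1)) + crossprod(sweep(g2, 2, mu2))) /
    (n1 + n2 - 2)
  ridge <- 0
  if (rcond(S) < 1e-10) {
    ridge <- 1e-6 * sum(diag(S)) / ncol(S)
    S <- S + diag(ridge, ncol(S))
  }
  w <- solve(S, mu1 - mu2)
  pri <- if (prior == "frequency") c(n1, n2) / (n1 + n2) else c(0.5, 0.5)
  # assign to group 1 when w.x > midpoint + log(pi2/pi1)
  cutoff <- 0.5 * sum(w * (mu1 + mu2)) + log(pri[2] / pri[1])
  structure(list(
    features = colnames(x), weights = setNames(w, colnames(x)),
    cutoff = cutoff, prior = setNames(pri, d$levels), groups = d$levels,
    center = center, scale = scl, standardize = standardize,
    ridge = ridge, n = c(n1, n2)), class = "mir_lda")
}

#' Predict group membership with a fitted discriminant
#'
#' @param object A `mir_lda` model.
#' @param expr Wide expression tibble containing the model's features.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `score` (discriminant projection) and
#'   `predicted` group label.
#' @export
predict.mir_lda <- function(object, expr, ...) {
  m <- expr_matrix(expr)
  missing <- setdiff(object$features, rownames(m))
  if (length(missing)) abort(paste0("expression table lacks model feature(s): ",
                                    paste(missing, collapse = ", ")))
  x <- t(m[object$features, , drop = FALSE])
  x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  score <- unname(drop(x %*% object$weights))
  tibble::tibble(
    sample_id = rownames(x), score = score,
    predicted = ifelse(score > object$cutoff, object$groups[1], object$groups[2]))
}

#' @export
print.mir_lda <- function(x, ...) {
  cat("<mir_lda>", length(x$features), "feature(s); groups",
      paste(x$groups, collapse = " vs "), "\n")
  cat("  priors:", paste(sprintf("%s=%.3f", names(x$prior), x$prior),
                         collapse = ", "),
      if (x$ridge > 0) sprintf("; ridge %.3g applied", x$ridge) else "", "\n")
  invisible(x)
}

#' @rdname fit_lda
#' @param x A `mir_lda` model.
#' @param ... Unused.
#' @export
tidy.mir_lda <- function(x, ...) {
  tibble::tibble(feature = x$features, weight = unname(x$weights))
}

#' @rdname fit_lda
#' @export
glance.mir_lda <- function(x, ...) {
  tibble::tibble(n_features = length(x$features), n_group1 = x$n[1],
                 n_group2 = x$n[2], prior_group1 = unname(x$prior[1]),
                 ridge = x$ridge, standardized = x$standardize)
}

#' Resubstitution accuracy of a fitted discriminant
#'
#' Reclassifies the training samples with the fitted model and reports the
#' apparent accuracy and the misclassified sample ids.
#'
#' @param model A `mir_lda` model.
#' @param expr Wide expression tibble (the training data).
#' @param design Tibble with `sample_id`, `group`.
#' @return List with `accuracy`, `misclassified` (sample ids) and the
#'   per-sample `predictions` tibble.
#' @export
resubstitution_report <- function(model, expr, design) {
  pred <- predict(model, expr)
  pred <- dplyr::inner_join(pred, design, by = "sample_id")
  wrong <- pred$sample_id[pred$predicted != pred$group]
  list(accuracy = 1 - length(wrong) / nrow(pred),
       misclassified = wrong, predictions = pred)
}

#' Leave-one-out cross-validated discriminant accuracy
#'
#' For each sample, the discriminant is refitted on the remaining `n - 1`
#' samples (standardisation recomputed on the training fold) and the
#' held-out sample is classified. Reports per-group and overall accuracy.
#'
#' @inheritParams fit_lda
#' @return List with `per_group` (tibble `group`, `n`, `n_correct`,
#'   `accuracy`), `overall` accuracy and `predictions` (per-sample tibble).
#' @export
loocv_report <- function(expr, design, features = NULL,
                         prior = c("frequency", "equal"), standardize = TRUE) {
  prior <- match.arg(prior)
  d <- check_design(design)
  samples <- design$sample_id
  if (any(table(design$group) < 3)) abort("LOOCV needs >= 3 samples per group.")
  rows <- lapply(samples, function(s) {
    train_design <- design[design$sample_id != s, ]
    train_expr <- expr[, c(names(expr)[1], setdiff(names(expr)[-1], s))]
    fit <- fit_lda(train_expr, train_design, features = features,
                   prior = prior, standardize = standardize)
    test_expr <- expr[, c(names(expr)[1], s)]
    predict(fit, test_expr)
  })
  pred <- dplyr::bind_rows(rows) |>
    dplyr::inner_join(design, by = "sample_id") |>
    dplyr::mutate(correct = .data$predicted == .data$group)
  per_group <- pred |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), n_correct = sum(.data$correct),
                     accuracy = mean(.data$correct), .groups = "drop")
  list(per_group = per_group, overall = mean(pred$correct), predictions = pred)
}

#' Plot discriminant scores per sample
#'
#' A cross-validation-style classification plot: each sample's discriminant
#' score against its index, coloured and shaped by true group, with the
#' decision boundary drawn as a horizontal line.
#'
#' @param object A `mir_lda` model.
#' @param expr Wide expression tibble.
#' @param design Tibble with `sample_id`, `group`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mir_lda <- function(object, expr, design, ...) {
  pred <- predict(object, expr) |>
    dplyr::inner_join(design, by = "sample_id") |>
    dplyr::mutate(index = dplyr::row_number())
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$index, y = .data$score,
                                     colour = .data$group,
                                     shape = .data$group)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_hline(yintercept = object$cutoff, linetype = 2) +
    ggplot2::labs(x = "sample index", y = "discriminant score",
                  colour = "group", shape = "group") +
    ggplot2::theme_minimal()
}
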