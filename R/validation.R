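#' Validate an algorithm against a panel of human raters
#'
#' The main analysis entry point.  Given a selection matrix containing
#' the human experts and the algorithm as a pseudo-rater, it computes
#' the full agreement framework: consensus action weights, per-case
#' expert-vs-expert (E-E) and expert-vs-algorithm (E-LaD) pairwise
#' sensitivity (unadjusted and weighted) and false-positive rates,
#' small-sample summaries of each statistic across cases, pairwise
#' selection correlations with per-rater and overall reliability
#' coefficients, Welch comparisons of the E-E and E-LaD score sets, and
#' the confidence-interval border ranking of the expert group against
#' the algorithm.
#'
#' Incompletely answered cases are dropped first (see
#' [filter_complete_cases()]); percentages are reported on the 0-100
#' scale.
#'
#' @param matrix A [selection_matrix()] whose raters include the human
#'   experts and the `algorithm` pseudo-rater.
#' @param algorithm Label of the algorithm rater (default `"LaD"`).
#' @param human_raters Human rater labels; defaults to all raters except
#'   `algorithm`.
#' @return An object of class `lad_validation`; see Details.  Use
#'   `print()`, `summary()`, `coef()` (reliability coefficients) and
#'   `plot()` (per-case sensitivity profiles) on the result.
#' @details The returned list contains `per_case` (data frame of
#'   per-case scores by statistic), `summaries` (named list of
#'   [summarize_agreement()] objects for the six statistic rows),
#'   `weights`, `correlations`, `reliability`, `comparisons` (Welch
#'   tests E-E vs E-LaD), `ranking`, and bookkeeping fields `algorithm`,
#'   `human_raters`, `cases`, `dropped_cases`.
#' @examples
#' panel <- simulate(lad_panel(seed = 7))
#' cfg <- lad_config()
#' fit <- lad_validation(attach_algorithm(panel, rep(list(1:8), 5)))
#' fit
#' @export
lad_validation <- function(matrix, algorithm = "LaD",
                           human_raters = NULL) {
  stopifnot(inherits(matrix, "selection_matrix"))
  raters <- dimnames(matrix)$rater
  if (!algorithm %in% raters) {
    stop("validation error: algorithm rater '", algorithm,
         "' not present in the matrix", call. = FALSE)
  }
  human_raters <- human_raters %||% setdiff(raters, algorithm)
  matrix <- filter_complete_cases(matrix, human_raters, algorithm)
  cases <- dimnames(matrix)$case
  if (!length(cases)) {
    stop("validation error: no complete cases to analyze", call. = FALSE)
  }
  w <- action_weights(matrix, human_raters, algorithm)

  score_row <- function(kind, stat, weights = NULL) {
    vapply(cases, function(cs) {
      100 * as.numeric(per_case_group_score(
        matrix, cs, kind = kind, stat = stat, weights = weights,
        human_raters = human_raters, algorithm = algorithm))
    }, 0)
  }
  per_case <- rbind(
    data.frame(statistic = "EE_sensitivity_unadjusted", case = cases,
               value = score_row("EE", "sensitivity")),
    data.frame(statistic = "ELaD_sensitivity_unadjusted", case = cases,
               value = score_row("ELaD", "sensitivity")),
    data.frame(statistic = "EE_sensitivity_weighted", case = cases,
               value = score_row("EE", "sensitivity", w)),
    data.frame(statistic = "ELaD_sensitivity_weighted", case = cases,
               value = score_row("ELaD", "sensitivity", w)),
    data.frame(statistic = "EE_fpr", case = cases,
               value = score_row("EE", "fpr")),
    data.frame(statistic = "ELaD_fpr", case = cases,
               value = score_row("ELaD", "fpr")))
  rownames(per_case) <- NULL

  stats_by <- split(per_case$value, per_case$statistic)
  summaries <- lapply(stats_by, summarize_agreement)

  correlations <- panel_correlations(matrix, human_raters, algorithm)
  reliability <- reliability_from_correlations(correlations,
                                               k = length(human_raters))

  comparisons <- list(
    sensitivity_unadjusted = compare_means(
      stats_by$ELaD_sensitivity_unadjusted,
      stats_by$EE_sensitivity_unadjusted),
    sensitivity_weighted = compare_means(
      stats_by$ELaD_sensitivity_weighted,
      stats_by$EE_sensitivity_weighted),
    fpr = compare_means(stats_by$ELaD_fpr, stats_by$EE_fpr))

  ranking <- rank_evaluators(list(
    experts = list(sensitivity = summaries$EE_sensitivity_weighted,
                   fpr = summaries$EE_fpr),
    algorithm = list(sensitivity = summaries$ELaD_sensitivity_weighted,
                     fpr = summaries$ELaD_fpr)))

  structure(list(per_case = per_case, summaries = summaries,
                 weights = w, correlations = correlations,
                 reliability = reliability, comparisons = comparisons,
                 ranking = ranking, algorithm = algorithm,
                 human_raters = human_raters, cases = cases,
                 dropped_cases = attr(matrix, "dropped_cases"),
                 matrix = matrix),
            class = "lad_validation")
}

#' Attach algorithm recommendations to a panel's selection matrix
#'
#' Adds the algorithm as an extra pseudo-rater whose selections per case
#' are the given action-id sets (e.g. from [recommend_actions()] on the
#' sampled scenarios).
#'
#' @param matrix A [selection_matrix()] of human raters.
#' @param recommendations List of integer action-id vectors, one per
#'   case (in case order), or a named list keyed by case label.
#' @param algorithm Label for the new rater (default `"LaD"`).
#' @return A `selection_matrix` with one additional rater.
#' @export
attach_algorithm <- function(matrix, recommendations, algorithm = "LaD") {
  dn <- dimnames(matrix)
  stopifnot(length(recommendations) == length(dn$case))
  if (!is.null(names(recommendations))) {
    recommendations <- recommendations[dn$case]
  }
  n_actions <- attr(matrix, "n_actions")
  arr <- array(NA, dim = dim(matrix) + c(1L, 0L, 0L),
               dimnames = list(rater = c(dn$rater, algorithm),
                               case = dn$case, action = dn$action))
  arr[dn$rater, , ] <- unclass(matrix)
  for (i in seq_along(dn$case)) {
    sel <- rep(FALSE, n_actions)
    sel[recommendations[[i]]] <- TRUE
    arr[algorithm, dn$case[i], ] <- sel
  }
  selection_matrix(arr, n_actions = n_actions,
                   max_select = attr(matrix, "max_select"))
}

#' @export
print.lad_validation <- function(x, ...) {
  cat("Expert-panel validation:", length(x$human_raters),
      "human raters vs", x$algorithm, "on", length(x$cases), "cases\n")
  if (length(x$dropped_cases)) {
    cat("  (dropped incomplete case(s):",
        paste(x$dropped_cases, collapse = ", "), ")\n")
  }
  lab <- c(EE_sensitivity_unadjusted = "E-E sensitivity, unadjusted ",
           ELaD_sensitivity_unadjusted = "E-LaD sensitivity, unadjusted",
           EE_sensitivity_weighted = "E-E sensitivity, weighted   ",
           ELaD_sensitivity_weighted = "E-LaD sensitivity, weighted ",
           EE_fpr = "E-E FPR                     ",
           ELaD_fpr = "E-LaD FPR                   ")
  for (nm in names(lab)) {
    s <- x$summaries[[nm]]
    cat(sprintf("  %s mean %5.1f (SD %5.2f; 95%% CI %5.1f-%5.1f)\n",
                lab[[nm]], s$mean, s$sd, s$ci_low, s$ci_high))
  }
  r <- x$reliability
  cat(sprintf("  mean r_selection %.2f; overall alpha %.2f\n",
              r$mean_r, r$alpha_overall))
  invisible(x)
}

#' @export
summary.lad_validation <- function(object, ...) {
  print(object)
  cat("\nPer-rater reliability:\n")
  pr <- object$reliability$per_rater
  pr$R <- round(pr$R, 3); pr$alpha <- round(pr$alpha, 3)
  print(pr, row.names = FALSE)
  cat("\nWelch comparisons (algorithm minus experts):\n")
  for (nm in names(object$comparisons)) {
    cm <- object$comparisons[[nm]]
    cat(sprintf("  %-24s diff %6.1f (95%% CI %6.1f to %5.1f, P = %.2f)\n",
                nm, cm$difference, cm$ci_low, cm$ci_high, cm$p_value))
  }
  cat("\n")
  print(object$ranking)
  invisible(object)
}

#' @export
coef.lad_validation <- function(object, ...) {
  pr <- object$reliability$per_rater
  c(stats::setNames(pr$alpha, paste0("alpha_", pr$rater)),
    alpha_overall = object$reliability$alpha_overall)
}

#' @export
plot.lad_validation <- function(x, ...) {
  pc <- x$per_case
  stats4 <- c("EE_sensitivity_unadjusted", "ELaD_sensitivity_unadjusted",
              "EE_sensitivity_weighted", "ELaD_sensitivity_weighted")
  mat <- sapply(stats4, function(s) pc$value[pc$statistic == s])
  graphics::matplot(seq_along(x$cases), mat, type = "b", pch = 1:4,
                    lty = 1:4, col = 1:4, xaxt = "n",
                    xlab = "case", ylab = "pairwise sensitivity (%)",
                    ylim = c(0, 100), ...)
  graphics::axis(1, at = seq_along(x$cases), labels = x$cases)
  graphics::legend("bottomleft",
                   legend = c("E-E unadjusted", "E-LaD unadjusted",
                              "E-E weighted", "E-LaD weighted"),
                   pch = 1:4, lty = 1:4, col = 1:4, cex = 0.8)
  invisible(x)
}
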