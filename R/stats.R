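#' Consensus weights for candidate actions
#'
#' For each case and action, the weight is the fraction of *human*
#' raters that selected the action: with five experts an action weighs
#' 1.0 if all five selected it, 0.6 if three did, and 0 if none did.
#' Weights never use the algorithm's selections, so algorithm-selected
#' actions may carry weight 0.
#'
#' @param matrix A [selection_matrix()] with complete cases (see
#'   [filter_complete_cases()]).
#' @param human_raters Rater labels of the human experts (k >= 2);
#'   defaults to all raters except `algorithm`.
#' @param algorithm Label of the algorithm pseudo-rater (default
#'   `"LaD"`).
#' @return A numeric case x action matrix of class `action_weights`
#'   with values in \{0, 1/k, ..., 1\}.
#' @export
action_weights <- function(matrix, human_raters = NULL, algorithm = "LaD") {
  human_raters <- human_raters %||%
    setdiff(dimnames(matrix)$rater, algorithm)
  if (length(human_raters) < 2L) {
    stop("validation error: need at least 2 human raters", call. = FALSE)
  }
  sub <- unclass(matrix)[human_raters, , , drop = FALSE]
  if (anyNA(sub)) {
    stop("validation error: unanswered human rater-case blocks; ",
         "apply filter_complete_cases() first", call. = FALSE)
  }
  w <- apply(sub, c(2L, 3L), mean)
  structure(w, k = length(human_raters), class = "action_weights")
}

#' Directed pairwise sensitivity between two raters
#'
#' The sensitivity of the `test` rater with respect to the `reference`
#' rater on one case: the fraction of the reference's selected actions
#' that the test rater also selected.  With consensus `weights`, both
#' numerator and denominator sum the per-action weights instead of
#' counting.  Undefined when the reference selected nothing (or has
#' zero weighted total): returns `NA` so callers can exclude rather
#' than impute.
#'
#' @inheritParams action_weights
#' @param reference,test Rater labels; the reference acts as the truth
#'   standard.
#' @param case Case label.
#' @param weights Optional [action_weights()] matrix for the weighted
#'   variant.
#' @return A fraction in `[0, 1]`, or `NA` if undefined.
#' @export
pairwise_sensitivity <- function(matrix, reference, test, case,
                                 weights = NULL) {
  ref <- selected_actions(matrix, reference, case)
  tst <- selected_actions(matrix, test, case)
  if (is.null(ref) || is.null(tst)) return(NA_real_)
  if (is.null(weights)) {
    if (!length(ref)) return(NA_real_)
    length(intersect(tst, ref)) / length(ref)
  } else {
    denom <- sum(weights[case, ref])
    if (!length(ref) || denom == 0) return(NA_real_)
    sum(weights[case, intersect(tst, ref)]) / denom
  }
}

#' Directed pairwise false-positive rate between two raters
#'
#' The fraction of actions the reference rater did *not* select that the
#' test rater selected, out of the `n_actions - |reference|` actions the
#' reference deemed unnecessary.  Undefined when the reference selected
#' every candidate action.
#'
#' @inheritParams pairwise_sensitivity
#' @return A fraction in `[0, 1]`, or `NA` if undefined.
#' @export
pairwise_fpr <- function(matrix, reference, test, case) {
  ref <- selected_actions(matrix, reference, case)
  tst <- selected_actions(matrix, test, case)
  if (is.null(ref) || is.null(tst)) return(NA_real_)
  n_actions <- attr(matrix, "n_actions")
  denom <- n_actions - length(ref)
  if (denom == 0L) return(NA_real_)
  length(setdiff(tst, ref)) / denom
}

#' Per-case group agreement score
#'
#' Averages a directed pairwise statistic over a comparison group for
#' one case.  `"EE"` averages over all ordered pairs of human raters
#' (reference != test; 20 pairs for five experts); `"ELaD"` averages
#' over the human raters as reference with the algorithm as test.
#' Undefined pair scores are excluded from the mean; the number of
#' exclusions is attached as attribute `n_undefined`.
#'
#' @inheritParams pairwise_sensitivity
#' @param kind `"EE"` (expert vs expert) or `"ELaD"` (expert reference
#'   vs algorithm).
#' @param stat `"sensitivity"` or `"fpr"`.
#' @return Mean score in `[0, 1]` (or `NA` if every pair is undefined)
#'   with attribute `n_undefined`.
#' @export
per_case_group_score <- function(matrix, case, kind = c("EE", "ELaD"),
                                 stat = c("sensitivity", "fpr"),
                                 weights = NULL, human_raters = NULL,
                                 algorithm = "LaD") {
  kind <- match.arg(kind)
  stat <- match.arg(stat)
  human_raters <- human_raters %||%
    setdiff(dimnames(matrix)$rater, algorithm)
  if (kind == "EE" && length(human_raters) < 2L) {
    stop("validation error: E-E scores need at least 2 human raters",
         call. = FALSE)
  }
  pairs <- if (kind == "EE") {
    expand.grid(reference = human_raters, test = human_raters,
                stringsAsFactors = FALSE)
  } else {
    data.frame(reference = human_raters, test = algorithm,
               stringsAsFactors = FALSE)
  }
  pairs <- pairs[pairs$reference != pairs$test, , drop = FALSE]
  vals <- mapply(function(r, t) {
    if (stat == "sensitivity") {
      pairwise_sensitivity(matrix, r, t, case, weights = weights)
    } else {
      pairwise_fpr(matrix, r, t, case)
    }
  }, pairs$reference, pairs$test)
  n_undef <- sum(is.na(vals))
  out <- if (n_undef == length(vals)) NA_real_ else mean(vals, na.rm = TRUE)
  attr(out, "n_undefined") <- n_undef
  out
}

#' Selection correlation between two raters
#'
#' A symmetric agreement measure for one case: the geometric mean of the
#' two directed pairwise sensitivities,
#' `r = sqrt(sens(a -> b) * sens(b -> a))` (the selectivity of a test
#' rater against a reference equals the sensitivity with the roles
#' swapped).  Used instead of kappa-type statistics because candidate
#' actions are not selected independently of one another.
#'
#' @inheritParams pairwise_sensitivity
#' @param rater_a,rater_b Rater labels.
#' @return A value in `[0, 1]`, or `NA` if either direction is
#'   undefined.
#' @export
r_selection <- function(matrix, rater_a, rater_b, case) {
  s_ab <- pairwise_sensitivity(matrix, rater_a, rater_b, case)
  s_ba <- pairwise_sensitivity(matrix, rater_b, rater_a, case)
  if (is.na(s_ab) || is.na(s_ba)) return(NA_real_)
  sqrt(s_ab * s_ba)
}

#' Spearman-Brown type reliability coefficient
#'
#' `alpha = k R / (1 + (k - 1) R)` for `k` raters with mean pairwise
#' selection correlation `R`.  For `R` in `[0, 1]` alpha lies in
#' `[0, 1]` and increases with `R` at fixed `k`.
#'
#' @param k Number of raters (>= 2).
#' @param R Mean pairwise correlation, in `[-1/(k-1), 1]`.
#' @return A list of class `reliability_result` with elements `k`, `R`
#'   and `alpha`.
#' @examples
#' reliability_alpha(5, 0.55275)$alpha  # 0.861
#' @export
reliability_alpha <- function(k, R) {
  if (!is.numeric(k) || length(k) != 1L || k < 2L) {
    stop("validation error: k must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(R) || length(R) != 1L || R < -1 / (k - 1) || R > 1) {
    stop("validation error: R must lie in [-1/(k-1), 1]", call. = FALSE)
  }
  structure(list(k = as.integer(k), R = R,
                 alpha = k * R / (1 + (k - 1) * R)),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat("Reliability: k =", x$k, " mean pairwise r =", round(x$R, 4),
      " alpha =", round(x$alpha, 3), "\n")
  invisible(x)
}

#' Per-expert and overall reliability from a pairwise correlation table
#'
#' Given per-case pairwise selection correlations in long format
#' (`reference`, `test`, `case`, `r`), computes for each reference rater
#' the mean of its correlations with every partner across all cases,
#' applies [reliability_alpha()] with `k` raters to that mean, and
#' averages the per-rater alphas into the overall coefficient.
#'
#' @param correlations Data frame with columns `reference`, `test`,
#'   `case` and `r` (one row per directed pair and case).
#' @param k Number of raters; defaults to the number of distinct
#'   reference raters.
#' @return A list with `per_rater` (data frame: rater, R, alpha),
#'   `alpha_overall`, `per_case_mean_r` (named vector) and `mean_r`.
#' @export
reliability_from_correlations <- function(correlations, k = NULL) {
  stopifnot(all(c("reference", "test", "case", "r") %in%
                names(correlations)))
  raters <- unique(correlations$reference)
  k <- k %||% length(raters)
  per <- lapply(raters, function(rt) {
    R <- mean(correlations$r[correlations$reference == rt], na.rm = TRUE)
    alpha <- if (is.finite(R)) reliability_alpha(k, R)$alpha else NA_real_
    data.frame(rater = rt, R = R, alpha = alpha, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_rater = per,
       alpha_overall = mean(per$alpha, na.rm = TRUE),
       per_case_mean_r = tapply(correlations$r, correlations$case, mean,
                                na.rm = TRUE),
       mean_r = mean(correlations$r, na.rm = TRUE))
}

#' Pairwise selection correlations for a whole panel
#'
#' Computes [r_selection()] for every ordered pair of human raters and
#' every case, in the long format consumed by
#' [reliability_from_correlations()].  (The measure itself is symmetric;
#' the ordered layout mirrors the per-reference-rater block structure
#' used in reliability computations.)
#'
#' @inheritParams action_weights
#' @return Data frame with columns `reference`, `test`, `case`, `r`.
#' @export
panel_correlations <- function(matrix, human_raters = NULL,
                               algorithm = "LaD") {
  human_raters <- human_raters %||%
    setdiff(dimnames(matrix)$rater, algorithm)
  cases <- dimnames(matrix)$case
  grid <- expand.grid(test = human_raters, reference = human_raters,
                      case = cases, stringsAsFactors = FALSE)
  grid <- grid[grid$reference != grid$test,
               c("reference", "test", "case")]
  grid$r <- mapply(function(a, b, cs) r_selection(matrix, a, b, cs),
                   grid$reference, grid$test, grid$case)
  rownames(grid) <- NULL
  grid
}

#' Small-sample summary of per-case statistics
#'
#' Mean, sample standard deviation (n - 1 denominator) and the t-based
#' 95% confidence interval `mean +/- t(0.975, n-1) * sd / sqrt(n)` of a
#' set of per-case scores.
#'
#' @param values Numeric vector of per-case statistics (n >= 2; `NA`s
#'   are dropped with a warning).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `agreement_summary`: a list with
#'   `values`, `n`, `mean`, `sd`, `ci_low`, `ci_high`, `conf_level`.
#' @examples
#' summarize_agreement(c(65.9, 56.5, 55.0, 45.6, 62.8))
#' @export
summarize_agreement <- function(values, conf_level = 0.95) {
  if (anyNA(values)) {
    warning("dropping NA values from summary", call. = FALSE)
    values <- values[!is.na(values)]
  }
  n <- length(values)
  if (n < 2L) {
    stop("validation error: need at least 2 values to summarize",
         call. = FALSE)
  }
  m <- mean(values)
  s <- stats::sd(values)
  hw <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1L) * s / sqrt(n)
  structure(list(values = values, n = n, mean = m, sd = s,
                 ci_low = m - hw, ci_high = m + hw,
                 conf_level = conf_level),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, digits = 2, ...) {
  cat(sprintf("mean %.*f (SD %.*f; %g%% CI %.*f-%.*f; n = %d)\n",
              digits, x$mean, digits, x$sd, 100 * x$conf_level,
              digits, x$ci_low, digits, x$ci_high, x$n))
  invisible(x)
}

#' Compare two groups of per-case scores
#'
#' Welch's unpaired t comparison of two sets of per-case statistics
#' (difference of means, its confidence interval and p-value), via
#' [stats::t.test()].
#'
#' @param x,y Numeric vectors of per-case scores.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `difference`, `ci_low`, `ci_high`, `p_value`.
#' @export
compare_means <- function(x, y, conf_level = 0.95) {
  tt <- stats::t.test(x, y, conf.level = conf_level)
  list(difference = unname(tt$estimate[1L] - tt$estimate[2L]),
       ci_low = tt$conf.int[1L], ci_high = tt$conf.int[2L],
       p_value = tt$p.value)
}

#' Rank evaluators by confidence-interval borders
#'
#' Orders evaluators by the lower border of their sensitivity
#' confidence interval (larger is better), breaking ties by the upper
#' border of their false-positive-rate confidence interval (smaller is
#' better).  Evaluators whose intervals overlap on both criteria are
#' statistically indistinguishable and reported as such.
#'
#' @param summaries Named list; each element is a list with components
#'   `sensitivity` and `fpr`, both [summarize_agreement()] objects.
#' @return A list of class `lad_ranking` with `ranking` (data frame:
#'   evaluator, sens_ci_low, fpr_ci_high, rank) and `indistinguishable`
#'   (data frame of evaluator pairs whose CIs overlap on both criteria).
#' @export
rank_evaluators <- function(summaries) {
  stopifnot(length(summaries) >= 1L, !is.null(names(summaries)))
  rows <- lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(evaluator = nm,
               sens_ci_low = s$sensitivity$ci_low,
               sens_ci_high = s$sensitivity$ci_high,
               fpr_ci_low = s$fpr$ci_low,
               fpr_ci_high = s$fpr$ci_high,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ord <- order(-df$sens_ci_low, df$fpr_ci_high)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL

  overlap <- function(lo1, hi1, lo2, hi2) lo1 <= hi2 && lo2 <= hi1
  pairs <- list()
  if (nrow(df) > 1L) {
    for (i in seq_len(nrow(df) - 1L)) {
      for (j in seq(i + 1L, nrow(df))) {
        both <- overlap(df$sens_ci_low[i], df$sens_ci_high[i],
                        df$sens_ci_low[j], df$sens_ci_high[j]) &&
                overlap(df$fpr_ci_low[i], df$fpr_ci_high[i],
                        df$fpr_ci_low[j], df$fpr_ci_high[j])
        if (both) {
          pairs[[length(pairs) + 1L]] <- data.frame(
            evaluator_a = df$evaluator[i], evaluator_b = df$evaluator[j],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  indist <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(evaluator_a = character(), evaluator_b = character(),
               stringsAsFactors = FALSE)
  structure(list(
    ranking = df[, c("evaluator", "sens_ci_low", "fpr_ci_high", "rank")],
    intervals = df,
    indistinguishable = indist), class = "lad_ranking")
}

#' @export
print.lad_ranking <- function(x, ...) {
  cat("Evaluator ranking (by sensitivity CI lower border, then FPR CI",
      "upper border):\n")
  print(x$ranking, row.names = FALSE)
  if (nrow(x$indistinguishable)) {
    cat("Statistically indistinguishable pairs (CIs overlap on both",
        "criteria):\n")
    for (i in seq_len(nrow(x$indistinguishable))) {
      cat("  ", x$indistinguishable$evaluator_a[i], "~",
          x$indistinguishable$evaluator_b[i], "\n")
    }
  }
  invisible(x)
}
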