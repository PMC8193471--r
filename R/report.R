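#' Render a validation report
#'
#' Serializes a [lad_validation()] fit into a machine-readable structure
#' (and optionally JSON on disk) plus a deterministic human-readable
#' table text mirroring the statistic-by-case layout of the study
#' report: one row per statistic with the per-case percentages, the
#' mean (SD) and the 95% CI, followed by the reliability block.
#' Numbers are formatted at the published precision (one decimal for
#' percentages, three for correlations) only at this reporting layer.
#'
#' @param fit A [lad_validation()] object.
#' @param json_path Optional path; when given, the JSON report is
#'   written there.
#' @return Invisibly, a list with `report` (nested list mirroring every
#'   printed cell) and `text` (character vector of formatted lines).
#' @export
render_report <- function(fit, json_path = NULL) {
  stopifnot(inherits(fit, "lad_validation"))
  lines <- character()
  report <- list(cases = fit$cases, statistics = list())
  header <- sprintf("%-28s %s  %14s  %14s", "statistic",
                    paste(sprintf("%6s", fit$cases), collapse = " "),
                    "mean (SD)", "95% CI")
  lines <- c(lines, header)
  for (nm in names(fit$summaries)) {
    s <- fit$summaries[[nm]]
    vals <- fit$per_case$value[fit$per_case$statistic == nm]
    lines <- c(lines, sprintf(
      "%-28s %s  %6.1f (%5.2f)  %6.1f to %5.1f", nm,
      paste(sprintf("%6.1f", vals), collapse = " "),
      s$mean, s$sd, s$ci_low, s$ci_high))
    report$statistics[[nm]] <- list(
      per_case = round(vals, 1), mean = round(s$mean, 1),
      sd = round(s$sd, 2), ci_low = round(s$ci_low, 1),
      ci_high = round(s$ci_high, 1))
  }
  rel <- fit$reliability
  lines <- c(lines, sprintf("mean r_selection %.3f; overall alpha %.3f",
                            rel$mean_r, rel$alpha_overall))
  report$reliability <- list(
    per_rater = data.frame(rater = rel$per_rater$rater,
                           R = round(rel$per_rater$R, 3),
                           alpha = round(rel$per_rater$alpha, 3),
                           stringsAsFactors = FALSE),
    alpha_overall = round(rel$alpha_overall, 3),
    per_case_mean_r = round(rel$per_case_mean_r, 3))
  report$ranking <- fit$ranking$ranking
  report$indistinguishable <- fit$ranking$indistinguishable
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(list(report = report, text = lines))
}
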