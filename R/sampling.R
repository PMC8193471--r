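#' Stratify scenarios by amniotic fluid status
#'
#' Partitions an enumerated scenario space into the three amniotic-fluid
#' strata (membranes intact, fluid clear, fluid opaque or foul smelling)
#' used to stratify validation case sampling.
#'
#' @param scenarios A data frame from [enumerate_scenarios()], or any
#'   data frame with `scenario_id` and the stratification column.
#' @param by Name of the stratification factor column
#'   (default `"amniotic_status"`).
#' @param strata Names of the expected strata in order; a stratum with no
#'   members is kept (empty) with a warning.
#' @return A named list of class `lad_strata`: one integer vector of
#'   member `scenario_id`s per stratum.
#' @examples
#' st <- stratify(enumerate_scenarios(lad_config()))
#' lengths(st)  # 384 384 384
#' @export
stratify <- function(scenarios, by = "amniotic_status",
                     strata = c("membranes_intact", "fluid_clear",
                                "fluid_opaque_or_foul")) {
  if (!nrow(scenarios)) {
    stop("validation error: empty scenario list", call. = FALSE)
  }
  if (!by %in% names(scenarios)) {
    stop("validation error: scenarios lack a '", by, "' column",
         call. = FALSE)
  }
  out <- lapply(strata, function(s) {
    scenarios$scenario_id[scenarios[[by]] == s]
  })
  names(out) <- strata
  empty <- strata[lengths(out) == 0L]
  if (length(empty)) {
    warning("empty stratum: ", paste(empty, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(scenarios[[by]]), strata)
  if (length(unknown)) {
    stop("validation error: unexpected ", by, " state(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(out, class = "lad_strata")
}

#' Draw a stratified random sample of case scenarios
#'
#' Samples `per_stratum` scenarios uniformly without replacement from
#' each stratum, using a Fisher-Yates partial shuffle driven by a
#' seedable generator, so the same seed always reproduces the same case
#' sample.  The validation design draws 2 cases from each of the 3
#' amniotic-fluid strata, giving 6 patient case scenarios.
#'
#' @param strata A [stratify()] result (named list of scenario id
#'   vectors).
#' @param per_stratum Number of cases to draw from each stratum.
#' @param seed Integer seed; required, and recorded in the result.
#' @return A list of class `lad_case_sample` with elements `seed`,
#'   `per_stratum` (named list of sampled ids by stratum) and `cases`
#'   (data frame: `case_label` P1, P2, ..., `scenario_id`, `stratum`).
#' @examples
#' st <- stratify(enumerate_scenarios(lad_config()))
#' sample_cases(st, per_stratum = 2, seed = 42)
#' @export
sample_cases <- function(strata, per_stratum, seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("validation error: an explicit integer seed is required",
         call. = FALSE)
  }
  per_stratum <- as.integer(per_stratum)
  too_small <- names(strata)[lengths(strata) < per_stratum]
  if (length(too_small)) {
    stop("validation error: per_stratum = ", per_stratum,
         " exceeds the size of stratum ",
         paste(too_small, collapse = ", "), call. = FALSE)
  }
  drawn <- with_seed(as.integer(seed), {
    lapply(strata, function(ids) fisher_yates_draw(ids, per_stratum))
  })
  cases <- data.frame(
    case_label = paste0("P", seq_len(length(drawn) * per_stratum)),
    scenario_id = unlist(drawn, use.names = FALSE),
    stratum = rep(names(strata), each = per_stratum),
    stringsAsFactors = FALSE)
  structure(list(seed = as.integer(seed), per_stratum = drawn,
                 cases = cases),
            class = "lad_case_sample")
}

#' @export
print.lad_case_sample <- function(x, ...) {
  cat("Stratified case sample (seed ", x$seed, "):\n", sep = "")
  print(x$cases, row.names = FALSE)
  invisible(x)
}

# Internal: uniform without-replacement draw of n items by a partial
# Fisher-Yates shuffle (first n positions of the shuffled vector).
fisher_yates_draw <- function(x, n) {
  m <- length(x)
  for (i in seq_len(n)) {
    j <- i + floor(stats::runif(1) * (m - i + 1))
    tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
  }
  x[seq_len(n)]
}

# Internal: run code under a local RNG seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
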