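#' Classify a raw observation against a parameter specification
#'
#' Maps a raw measured value onto one of the parameter's classification
#' states using the normal ranges in the configuration.  Continuous
#' parameters are binned by the configured break points (left-closed
#' intervals); categorical parameters are matched through the alias map;
#' composite parameters (blood pressure) are normal only if every
#' component lies below its `normal_below` threshold.
#'
#' @param config A [lad_config()] object.
#' @param parameter Name of a monitored parameter, e.g.
#'   `"fetal_heart_rate"`.
#' @param value The raw value: a numeric scalar for continuous
#'   parameters, a character label for categorical ones, or a named
#'   numeric vector (e.g. `c(systolic = 150, diastolic = 95)`) for
#'   composite ones.
#' @return A single classification state (character scalar).
#' @examples
#' cfg <- lad_config()
#' classify_observation(cfg, "fetal_heart_rate", 120)  # "normal"
#' classify_observation(cfg, "fetal_heart_rate", 100)  # "abnormal_low"
#' classify_observation(cfg, "amniotic_fluid", "foul") # "opaque_or_foul"
#' @export
classify_observation <- function(config, parameter, value) {
  stopifnot(inherits(config, "lad_config"))
  spec <- config$parameters[[parameter]]
  if (is.null(spec)) {
    stop("configuration error: unknown parameter '", parameter, "'",
         call. = FALSE)
  }
  switch(spec$kind,
    continuous = {
      if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
        stop("validation error: '", parameter,
             "' expects a single numeric value", call. = FALSE)
      }
      pr <- unlist(spec$physical_range)
      if (value < pr[1L] || value > pr[2L]) {
        stop("validation error: value ", value, " for '", parameter,
             "' outside physical range [", pr[1L], ", ", pr[2L], "]",
             call. = FALSE)
      }
      idx <- findInterval(value, unlist(spec$breaks)) + 1L
      spec$states[[idx]]
    },
    categorical = {
      if (!is.character(value) || length(value) != 1L) {
        stop("validation error: '", parameter,
             "' expects a single category label", call. = FALSE)
      }
      state <- spec$aliases[[value]]
      if (is.null(state)) {
        stop("validation error: unknown category '", value, "' for '",
             parameter, "'", call. = FALSE)
      }
      state
    },
    composite = {
      comp <- spec$components
      if (!is.numeric(value) || !all(names(comp) %in% names(value))) {
        stop("validation error: '", parameter,
             "' expects a named numeric vector with components ",
             paste(names(comp), collapse = ", "), call. = FALSE)
      }
      abnormal <- FALSE
      for (cn in names(comp)) {
        v <- value[[cn]]
        pr <- unlist(comp[[cn]]$physical_range)
        if (v < pr[1L] || v > pr[2L]) {
          stop("validation error: ", cn, " = ", v,
               " outside physical range [", pr[1L], ", ", pr[2L], "]",
               call. = FALSE)
        }
        if (v >= comp[[cn]]$normal_below) abnormal <- TRUE
      }
      if (abnormal) setdiff(spec$states, spec$normal_states)[[1L]]
      else spec$normal_states[[1L]]
    }
  )
}

#' Parameters due for observation
#'
#' Returns the monitored parameters whose next observation is due, given
#' the time of each parameter's last observation.  A parameter is due
#' when it applies to the current labor stage and either has never been
#' observed or its configured monitoring interval has elapsed.
#'
#' @inheritParams classify_observation
#' @param last_observed Named numeric vector mapping parameter names to
#'   the time (minutes since monitoring start) of their last
#'   observation.  Parameters absent from this vector are treated as
#'   never observed and are always due.
#' @param now Current time in minutes since monitoring start.
#' @param stage Labor stage, `"first"` or `"second"`.
#' @return Character vector of due parameter names (possibly empty), in
#'   configuration order.
#' @examples
#' cfg <- lad_config()
#' next_due(cfg, c(fetal_heart_rate = 0), now = 30, stage = "first")
#' @export
next_due <- function(config, last_observed = numeric(), now, stage) {
  stopifnot(inherits(config, "lad_config"))
  stage <- match.arg(stage, c("first", "second"))
  if (!is.numeric(now) || length(now) != 1L || now < 0) {
    stop("validation error: 'now' must be a single non-negative time",
         call. = FALSE)
  }
  if (length(last_observed) && any(last_observed > now)) {
    stop("validation error: last_observed times exceed 'now'", call. = FALSE)
  }
  due <- character()
  for (p in config$parameters) {
    if (p$stage != "both" && p$stage != stage) next
    last <- last_observed[p$name]
    if (is.na(last) || (now - last) >= p$interval_minutes) {
      due <- c(due, p$name)
    }
  }
  due
}

#' Enumerate the full patient scenario space
#'
#' Builds the Cartesian product of the configured factor states in
#' lexicographic order of factor definition (the first factor varies
#' slowest).  Under the default configuration this yields exactly 1152
#' scenarios; `scenario_id` is the zero-based position in enumeration
#' order.
#'
#' @inheritParams classify_observation
#' @return A data frame of class `lad_scenarios` with a `scenario_id`
#'   column followed by one character column per factor.
#' @examples
#' sc <- enumerate_scenarios(lad_config())
#' nrow(sc)  # 1152
#' @export
enumerate_scenarios <- function(config) {
  stopifnot(inherits(config, "lad_config"))
  facs <- config$factorization
  if (!length(facs)) stop("validation error: empty factorization", call. = FALSE)
  states <- lapply(facs, function(f) unlist(f$states))
  # first factor most significant: reverse for expand.grid, then reorder cols
  grid <- expand.grid(rev(states), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(states)), drop = FALSE]
  names(grid) <- names(facs)
  out <- cbind(scenario_id = seq_len(nrow(grid)) - 1L, grid)
  rownames(out) <- NULL
  class(out) <- c("lad_scenarios", "data.frame")
  out
}

# Internal: one scenario row (named character vector of factor states).
scenario_coords <- function(scenarios, scenario_id) {
  row <- scenarios[scenarios$scenario_id == scenario_id, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("validation error: unknown scenario_id ", scenario_id, call. = FALSE)
  }
  unlist(row[, setdiff(names(row), "scenario_id"), drop = FALSE])
}

#' Manage one abnormal parameter in a scenario
#'
#' Applies the configured management rule for a non-normal factor
#' coordinate and reports whether the subabnormality resolves.
#' Resolution is a deterministic property of the scenario coordinate
#' (e.g. a "responding" versus "persistent" state), not a random draw.
#'
#' @inheritParams classify_observation
#' @param state Named character vector of factor states (one scenario's
#'   coordinates), or a single-row subset of [enumerate_scenarios()].
#' @param parameter Factor name whose coordinate is abnormal.
#' @return A list of class `lad_management_outcome` with elements
#'   `parameter`, `attempted_rule` (the `"factor:state"` rule id),
#'   `actions` and `resolved`.
#' @export
manage_abnormality <- function(config, state, parameter) {
  stopifnot(inherits(config, "lad_config"))
  state <- as_coords(config, state)
  fac <- config$factorization[[parameter]]
  if (is.null(fac)) {
    stop("configuration error: unknown factor '", parameter, "'",
         call. = FALSE)
  }
  s <- state[[parameter]]
  if (s %in% fac$normal_states) {
    stop("precondition violation: '", parameter, "' is in normal state '",
         s, "'; nothing to manage", call. = FALSE)
  }
  rid <- paste(parameter, s, sep = ":")
  rule <- config$rules[[rid]]
  if (is.null(rule)) {
    stop("configuration error: no management rule for (", parameter, ", ",
         s, ")", call. = FALSE)
  }
  structure(list(parameter = parameter, attempted_rule = rid,
                 actions = as.integer(unlist(rule$actions)),
                 resolved = isTRUE(rule$resolved),
                 critical = isTRUE(rule$critical)),
            class = "lad_management_outcome")
}

#' Recommend actions for a patient scenario
#'
#' Evaluates the LaD decision logic on one scenario: each abnormal
#' coordinate is managed independently by its configured rule, and the
#' final labor management decision combines the per-abnormality
#' outcomes — if every subabnormality resolves (or none is present) the
#' routine-monitoring track is taken, while any unresolved critical
#' abnormality forces the escalation/delivery track.  The recommendation
#' is the union of the rule actions and the final-decision actions,
#' capped by construction at the configured per-case maximum.
#'
#' @inheritParams manage_abnormality
#' @param state A scenario: either a `scenario_id` (single integer), a
#'   named character vector of factor states, or a single-row subset of
#'   [enumerate_scenarios()].
#' @param scenarios Optional pre-computed [enumerate_scenarios()] result,
#'   used to resolve integer `scenario_id`s without re-enumerating.
#' @return A list of class `lad_recommendation` with elements
#'   `scenario_id` (or `NA` if the scenario was given as coordinates),
#'   `actions` (sorted integer action ids), `rationale` (data frame of
#'   parameter, state, rule_id) and `escalated` (logical).
#' @examples
#' cfg <- lad_config()
#' recommend_actions(cfg, 0)           # all-normal scenario: routine track
#' @export
recommend_actions <- function(config, state, scenarios = NULL) {
  stopifnot(inherits(config, "lad_config"))
  sid <- NA_integer_
  if (is.numeric(state) && length(state) == 1L && is.null(names(state))) {
    sid <- as.integer(state)
    if (is.null(scenarios)) scenarios <- enumerate_scenarios(config)
    state <- scenario_coords(scenarios, sid)
  } else {
    state <- as_coords(config, state)
  }

  actions <- integer()
  rationale <- list()
  any_unresolved_critical <- FALSE
  for (fname in names(config$factorization)) {
    fac <- config$factorization[[fname]]
    s <- state[[fname]]
    if (is.null(s) || !s %in% fac$states) {
      stop("configuration error: scenario coordinate '", fname,
           "' missing or not a valid state", call. = FALSE)
    }
    if (s %in% fac$normal_states) next
    out <- manage_abnormality(config, state, fname)
    actions <- union(actions, out$actions)
    if (!out$resolved && out$critical) any_unresolved_critical <- TRUE
    rationale[[length(rationale) + 1L]] <-
      data.frame(parameter = fname, state = s, rule_id = out$attempted_rule,
                 resolved = out$resolved, stringsAsFactors = FALSE)
  }
  fd <- config$final_decision
  if (any_unresolved_critical) {
    actions <- union(actions, as.integer(unlist(fd$escalation_actions)))
  } else {
    actions <- union(actions, as.integer(unlist(fd$routine_actions)))
  }
  actions <- sort(actions)
  if (length(actions) > config$max_actions_per_case) {
    stop("configuration error: recommendation for scenario exceeds ",
         config$max_actions_per_case, " actions", call. = FALSE)
  }
  rationale <- if (length(rationale)) do.call(rbind, rationale) else
    data.frame(parameter = character(), state = character(),
               rule_id = character(), resolved = logical(),
               stringsAsFactors = FALSE)
  structure(list(scenario_id = sid, actions = actions,
                 rationale = rationale,
                 escalated = any_unresolved_critical),
            class = "lad_recommendation")
}

#' @export
print.lad_recommendation <- function(x, ...) {
  cat("LaD recommendation",
      if (!is.na(x$scenario_id)) paste0("(scenario ", x$scenario_id, ")"),
      "\n")
  cat("  track:  ", if (x$escalated) "escalation/delivery" else
      "routine monitoring", "\n")
  cat("  actions:", paste(x$actions, collapse = ", "), "\n")
  if (nrow(x$rationale)) {
    cat("  abnormalities managed:\n")
    for (i in seq_len(nrow(x$rationale))) {
      cat("    -", x$rationale$rule_id[i],
          if (x$rationale$resolved[i]) "[resolved]" else "[unresolved]", "\n")
    }
  }
  invisible(x)
}

# Internal: coerce a scenario row / named vector to named character coords.
as_coords <- function(config, state) {
  if (is.data.frame(state)) {
    stopifnot(nrow(state) == 1L)
    state <- unlist(state[, setdiff(names(state), "scenario_id"),
                          drop = FALSE])
  }
  if (is.null(names(state))) {
    stop("validation error: scenario coordinates must be named by factor",
         call. = FALSE)
  }
  as.list(state)
}
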