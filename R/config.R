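#' Load a LaD algorithm configuration
#'
#' Reads a YAML configuration describing the monitored parameters, the
#' scenario-space factorization, the candidate action catalog, the
#' per-abnormality management rules and the final-decision mapping, and
#' validates it.  The default configuration tracks six intrapartum
#' parameters (fetal heart rate, amniotic fluid, cervical dilatation,
#' uterine contractions, maternal blood pressure and, in second stage,
#' the fetal station) and factorizes the patient state space into 1152
#' scenarios.
#'
#' Validation enforces, among other things: exactly six parameter
#' specifications with monitoring intervals in \{30, 60, 120, 240\}
#' minutes; a non-empty proper subset of normal states per parameter and
#' per factor; an action catalog of `n_actions` entries with ids
#' `1:n_actions`; a management rule for every non-normal factor state;
#' and, when `expect_total_scenarios` is set, that the product of factor
#' cardinalities equals it.
#'
#' @param path Path to a YAML configuration file.  The default
#'   configuration shipped with the package is used when `path` is `NULL`.
#' @return An object of class `lad_config`: a named list with elements
#'   `name`, `parameters`, `factorization`, `actions`, `rules`,
#'   `final_decision`, `n_actions`, `max_actions_per_case` and
#'   `active_phase_start_cm`.
#' @examples
#' cfg <- lad_config()
#' cfg
#' @export
lad_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lad_default.yaml", package = "ladmonitor")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  validate_lad_config(raw)
}

#' @rdname lad_config
#' @param x For `print`, a `lad_config` object.
#' @param ... Unused.
#' @export
print.lad_config <- function(x, ...) {
  cat("LaD algorithm configuration:", x$name, "\n")
  cat("  parameters:   ", length(x$parameters), "monitored (",
      paste(vapply(x$parameters, `[[`, "", "name"), collapse = ", "), ")\n")
  card <- vapply(x$factorization, function(f) length(f$states), 0L)
  cat("  factorization:", paste(card, collapse = " x "), "=",
      prod(card), "scenarios\n")
  cat("  actions:      ", length(x$actions),
      "(max", x$max_actions_per_case, "selectable per case)\n")
  cat("  rules:        ", length(x$rules), "management rules\n")
  invisible(x)
}

# Internal: full structural validation; returns the classed config.
validate_lad_config <- function(cfg) {
  stopifnot(is.list(cfg))
  for (field in c("parameters", "factorization", "actions", "rules",
                  "final_decision")) {
    if (is.null(cfg[[field]])) {
      stop("configuration error: missing section '", field, "'", call. = FALSE)
    }
  }
  cfg$n_actions <- cfg$n_actions %||% 22L
  cfg$max_actions_per_case <- cfg$max_actions_per_case %||% 16L
  cfg$active_phase_start_cm <- cfg$active_phase_start_cm %||% 5

  # parameter specifications
  if (length(cfg$parameters) != 6L) {
    stop("configuration error: expected exactly 6 parameter specifications, got ",
         length(cfg$parameters), call. = FALSE)
  }
  for (p in cfg$parameters) {
    nm <- p$name %||% "<unnamed>"
    if (!p$kind %in% c("continuous", "categorical", "composite")) {
      stop("configuration error: parameter '", nm, "' has unknown kind '",
           p$kind, "'", call. = FALSE)
    }
    if (!length(p$states) || !length(p$normal_states) ||
        !all(p$normal_states %in% p$states) ||
        length(p$normal_states) >= length(p$states)) {
      stop("configuration error: parameter '", nm,
           "': normal_states must be a non-empty proper subset of states",
           call. = FALSE)
    }
    if (!p$interval_minutes %in% c(30L, 60L, 120L, 240L)) {
      stop("configuration error: parameter '", nm,
           "': interval_minutes must be one of 30, 60, 120, 240", call. = FALSE)
    }
    if (!p$stage %in% c("first", "second", "both")) {
      stop("configuration error: parameter '", nm, "': invalid stage '",
           p$stage, "'", call. = FALSE)
    }
    if (p$kind == "continuous" && length(p$breaks) != length(p$states) - 1L) {
      stop("configuration error: parameter '", nm,
           "': breaks must have one fewer entry than states", call. = FALSE)
    }
  }
  names(cfg$parameters) <- vapply(cfg$parameters, `[[`, "", "name")

  # factorization
  if (!length(cfg$factorization)) {
    stop("validation error: factorization must have at least one factor",
         call. = FALSE)
  }
  for (f in cfg$factorization) {
    if (length(f$states) < 2L) {
      stop("configuration error: factor '", f$name,
           "' must have at least 2 states", call. = FALSE)
    }
    if (!length(f$normal_states) || !all(f$normal_states %in% f$states)) {
      stop("configuration error: factor '", f$name,
           "': normal_states must be a subset of states", call. = FALSE)
    }
  }
  names(cfg$factorization) <- vapply(cfg$factorization, `[[`, "", "name")
  total <- prod(vapply(cfg$factorization, function(f) length(f$states), 0L))
  if (!is.null(cfg$expect_total_scenarios) &&
      total != cfg$expect_total_scenarios) {
    stop("configuration error: factor cardinalities multiply to ", total,
         ", expected ", cfg$expect_total_scenarios, call. = FALSE)
  }

  # action catalog
  ids <- vapply(cfg$actions, function(a) as.integer(a$id), 0L)
  if (length(cfg$actions) != cfg$n_actions ||
      !identical(sort(ids), seq_len(cfg$n_actions))) {
    stop("configuration error: action catalog must contain exactly ",
         cfg$n_actions, " actions with ids 1..", cfg$n_actions, call. = FALSE)
  }
  cats <- vapply(cfg$actions, `[[`, "", "category")
  if (!all(cats %in% c("observe", "intervene", "escalate", "deliver"))) {
    stop("configuration error: unknown action category", call. = FALSE)
  }

  # management rules must cover every non-normal factor state
  rule_key <- function(factor, state) paste(factor, state, sep = ":")
  keys <- vapply(cfg$rules, function(r) rule_key(r$factor, r$state), "")
  if (anyDuplicated(keys)) {
    stop("configuration error: duplicate management rule for ",
         keys[duplicated(keys)][1L], call. = FALSE)
  }
  names(cfg$rules) <- keys
  uncovered <- character()
  for (f in cfg$factorization) {
    for (s in setdiff(f$states, f$normal_states)) {
      if (!rule_key(f$name, s) %in% keys) {
        uncovered <- c(uncovered, rule_key(f$name, s))
      }
    }
  }
  if (length(uncovered)) {
    stop("configuration error: no management rule for ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  for (r in cfg$rules) {
    if (!all(unlist(r$actions) %in% ids)) {
      stop("configuration error: rule ", rule_key(r$factor, r$state),
           " references unknown action ids", call. = FALSE)
    }
    if (!is.logical(r$resolved) || !is.logical(r$critical)) {
      stop("configuration error: rule ", rule_key(r$factor, r$state),
           " must set logical 'resolved' and 'critical'", call. = FALSE)
    }
  }
  fd <- cfg$final_decision
  if (!all(unlist(fd$routine_actions) %in% ids) ||
      !all(unlist(fd$escalation_actions) %in% ids)) {
    stop("configuration error: final_decision references unknown action ids",
         call. = FALSE)
  }

  structure(cfg, class = "lad_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
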