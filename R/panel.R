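#' Synthetic expert-panel model
#'
#' Defines a generative model for panels of raters selecting candidate
#' actions, with a tunable consensus structure, mirroring the validation
#' study design (five experts, five analyzable cases, 22 candidate
#' actions, at most 16 selectable per case).  For each (case, action) a
#' latent selection probability `p` is drawn from the symmetric
#' two-parameter Beta(1/c, 1/c) distribution, where
#' `c = consensus_concentration`: large `c` pushes `p` towards \{0, 1\}
#' so raters agree almost perfectly, while `c` near 0 pushes `p`
#' towards 1/2 so raters behave like independent coin flips.  Each
#' rater then selects each action independently with probability `p`;
#' if a rater-case block exceeds `max_select`, the lowest-probability
#' selections are dropped (deterministically, given the draw), which
#' preserves high-consensus actions.
#'
#' @param k Number of raters (default 5).
#' @param n_cases Number of cases (default 5).
#' @param n_actions Number of candidate actions (default 22).
#' @param max_select Maximum selections per rater-case block
#'   (default 16).
#' @param consensus_concentration Positive real controlling consensus
#'   (default 1, i.e. p ~ Uniform(0, 1)).
#' @param seed Integer seed used by [simulate.lad_panel()] when no
#'   `seed` argument is supplied there.
#' @return An object of class `lad_panel`.
#' @examples
#' m <- lad_panel(consensus_concentration = 4, seed = 1)
#' panel <- simulate(m)
#' @export
lad_panel <- function(k = 5L, n_cases = 5L, n_actions = 22L,
                      max_select = 16L, consensus_concentration = 1,
                      seed = NULL) {
  stopifnot(k >= 2L, n_cases >= 1L, n_actions >= 1L)
  if (max_select <= 0L) {
    stop("validation error: max_select must be positive", call. = FALSE)
  }
  if (consensus_concentration <= 0) {
    stop("validation error: consensus_concentration must be positive",
         call. = FALSE)
  }
  structure(list(k = as.integer(k), n_cases = as.integer(n_cases),
                 n_actions = as.integer(n_actions),
                 max_select = as.integer(max_select),
                 consensus_concentration = consensus_concentration,
                 seed = seed),
            class = "lad_panel")
}

#' @export
print.lad_panel <- function(x, ...) {
  cat("Synthetic panel model: k =", x$k, "raters,", x$n_cases, "cases,",
      x$n_actions, "actions (max", x$max_select, "per case),",
      "consensus concentration", x$consensus_concentration, "\n")
  invisible(x)
}

#' Simulate selection matrices from a panel model
#'
#' Draws `nsim` independent panels from a [lad_panel()] model.  The
#' simulation is a pure function of the model and seed: the same seed
#' always reproduces the same matrices.
#'
#' @param object A [lad_panel()] model.
#' @param nsim Number of panels to draw (default 1).
#' @param seed Integer seed; defaults to the model's `seed` field,
#'   which must then be set.
#' @param ... Unused.
#' @return A single [selection_matrix()] when `nsim = 1`, otherwise a
#'   list of them.  Raters are labelled `E1..Ek`, cases `P1..Pn`.
#' @export
simulate.lad_panel <- function(object, nsim = 1, seed = NULL, ...) {
  seed <- seed %||% object$seed
  if (is.null(seed)) {
    stop("validation error: a seed is required for panel simulation",
         call. = FALSE)
  }
  out <- with_seed(as.integer(seed), {
    lapply(seq_len(nsim), function(i) draw_panel(object))
  })
  if (nsim == 1) out[[1L]] else out
}

# Internal: one panel draw using the current RNG stream.
draw_panel <- function(model) {
  shape <- 1 / model$consensus_concentration
  arr <- array(FALSE,
               dim = c(model$k, model$n_cases, model$n_actions),
               dimnames = list(rater = paste0("E", seq_len(model$k)),
                               case = paste0("P", seq_len(model$n_cases)),
                               action = seq_len(model$n_actions)))
  for (cs in seq_len(model$n_cases)) {
    p <- stats::rbeta(model$n_actions, shape, shape)
    for (r in seq_len(model$k)) {
      sel <- stats::runif(model$n_actions) < p
      if (sum(sel) > model$max_select) {
        keep <- order(p, decreasing = TRUE)
        keep <- keep[keep %in% which(sel)][seq_len(model$max_select)]
        sel <- rep(FALSE, model$n_actions)
        sel[keep] <- TRUE
      }
      arr[r, cs, ] <- sel
    }
  }
  selection_matrix(arr, n_actions = model$n_actions,
                   max_select = model$max_select)
}

#' Agreement statistics across consensus levels
#'
#' Parameter-recovery harness for the panel model: simulates
#' `replicates` panels at each consensus concentration, computes the
#' mean pairwise selection correlation and the overall reliability
#' coefficient of each panel, and averages them per level.  Mean
#' agreement is an increasing function of the concentration.
#'
#' @param model A [lad_panel()] template (its concentration field is
#'   overridden level by level).
#' @param concentrations Numeric vector of consensus concentrations
#'   (>= 1 value).
#' @param replicates Panels per level (>= 2).
#' @param seed Integer seed.
#' @return Data frame with columns `concentration`, `mean_r`,
#'   `mean_alpha`.
#' @export
recover_agreement <- function(model, concentrations, replicates = 200L,
                              seed = 1L) {
  stopifnot(replicates >= 2L, length(concentrations) >= 1L)
  rows <- lapply(seq_along(concentrations), function(i) {
    m <- model
    m$consensus_concentration <- concentrations[i]
    panels <- simulate(m, nsim = replicates, seed = seed + i)
    stats <- vapply(panels, function(p) {
      cors <- panel_correlations(p, algorithm = character())
      rel <- reliability_from_correlations(cors, k = m$k)
      c(r = rel$mean_r, alpha = rel$alpha_overall)
    }, c(r = 0, alpha = 0))
    data.frame(concentration = concentrations[i],
               mean_r = mean(stats["r", ], na.rm = TRUE),
               mean_alpha = mean(stats["alpha", ], na.rm = TRUE))
  })
  do.call(rbind, rows)
}
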