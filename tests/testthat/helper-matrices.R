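# Build a selection_matrix from per-rater lists of selected action-id
# vectors (one vector per case; NULL = case not answered).
make_sel <- function(raters, n_cases = 1L, n_actions = 22L,
                     max_select = 16L) {
  cases <- paste0("P", seq_len(n_cases))
  arr <- array(NA, dim = c(length(raters), n_cases, n_actions),
               dimnames = list(rater = names(raters), case = cases,
                               action = seq_len(n_actions)))
  for (r in seq_along(raters)) {
    sets <- raters[[r]]
    if (!is.list(sets)) sets <- list(sets)
    for (cs in seq_len(n_cases)) {
      if (is.null(sets[[cs]])) next
      v <- rep(FALSE, n_actions)
      v[sets[[cs]]] <- TRUE
      arr[r, cs, ] <- v
    }
  }
  selection_matrix(arr, n_actions = n_actions, max_select = max_select)
}

# Random panel with iid Bernoulli(prob) selections, independent of the
# package's own simulator (used as an oracle-side generator).
random_sel <- function(k = 3L, n_cases = 2L, n_actions = 10L,
                       prob = 0.4) {
  arr <- array(stats::runif(k * n_cases * n_actions) < prob,
               dim = c(k, n_cases, n_actions),
               dimnames = list(rater = paste0("E", seq_len(k)),
                               case = paste0("P", seq_len(n_cases)),
                               action = seq_len(n_actions)))
  selection_matrix(arr, n_actions = n_actions, max_select = n_actions)
}
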