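#' Construct a rater x case x action selection matrix
#'
#' The central data structure of the validation framework: a 3-d logical
#' array with dimensions rater, case and action, `TRUE` where a rater
#' selected an action for a case.  A rater-case block that was never
#' answered is all-`NA` (distinct from an answered block with no
#' selections).  At most `max_select` actions may be selected per
#' rater-case block; the default validation design offers 22 candidate
#' actions of which up to 16 may be selected.
#'
#' @param selections A 3-d logical array (rater x case x action) with
#'   dimnames, or a long data frame with columns `rater`, `case`,
#'   `action_id` and `selected`.
#' @param raters,cases Optional orderings of rater / case labels; by
#'   default taken from the data.
#' @param n_actions Number of candidate actions (default 22).
#' @param max_select Maximum selectable actions per rater-case block
#'   (default 16).
#' @return An object of class `selection_matrix` (a logical array with
#'   attributes `n_actions` and `max_select`).
#' @export
selection_matrix <- function(selections, raters = NULL, cases = NULL,
                             n_actions = 22L, max_select = 16L) {
  if (max_select <= 0L) {
    stop("validation error: max_select must be positive", call. = FALSE)
  }
  if (is.data.frame(selections)) {
    df <- selections
    need <- c("rater", "case", "action_id", "selected")
    if (!all(need %in% names(df))) {
      stop("validation error: long-format selections need columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    if (!all(df$selected %in% c(0L, 1L))) {
      stop("validation error: 'selected' must be 0 or 1", call. = FALSE)
    }
    if (!all(df$action_id %in% seq_len(n_actions))) {
      stop("validation error: action_id outside 1..", n_actions,
           call. = FALSE)
    }
    key <- paste(df$rater, df$case, df$action_id)
    if (anyDuplicated(key)) {
      stop("validation error: duplicate (rater, case, action) rows",
           call. = FALSE)
    }
    raters <- raters %||% unique(df$rater)
    cases <- cases %||% unique(df$case)
    arr <- array(NA, dim = c(length(raters), length(cases), n_actions),
                 dimnames = list(rater = raters, case = cases,
                                 action = seq_len(n_actions)))
    # any row for a (rater, case) marks the block answered; absent
    # actions within an answered block default to not-selected
    blocks <- unique(df[, c("rater", "case")])
    for (i in seq_len(nrow(blocks))) {
      arr[blocks$rater[i], blocks$case[i], ] <- FALSE
    }
    arr[cbind(match(df$rater, raters), match(df$case, cases),
              df$action_id)] <- as.logical(df$selected)
  } else {
    arr <- selections
    stopifnot(is.array(arr), length(dim(arr)) == 3L)
    if (dim(arr)[3L] != n_actions) {
      stop("validation error: third dimension must have ", n_actions,
           " actions", call. = FALSE)
    }
    storage.mode(arr) <- "logical"
    names(dimnames(arr)) <- c("rater", "case", "action")
  }
  counts <- apply(arr, c(1L, 2L), sum)
  over <- which(!is.na(counts) & counts > max_select, arr.ind = TRUE)
  if (nrow(over)) {
    stop("validation error: more than ", max_select,
         " selections in block (",
         dimnames(arr)$rater[over[1L, 1L]], ", ",
         dimnames(arr)$case[over[1L, 2L]], ")", call. = FALSE)
  }
  structure(arr, n_actions = as.integer(n_actions),
            max_select = as.integer(max_select),
            class = "selection_matrix")
}

#' @export
print.selection_matrix <- function(x, ...) {
  d <- dim(x)
  cat("Selection matrix:", d[1L], "raters x", d[2L], "cases x", d[3L],
      "actions\n")
  counts <- apply(unclass(x), c(1L, 2L), sum)
  cat("Selections per rater-case block (NA = case not answered):\n")
  print(counts)
  invisible(x)
}

#' Selected action ids for one rater-case block
#'
#' @param matrix A [selection_matrix()].
#' @param rater,case Rater and case labels.
#' @return Integer vector of selected action ids, or `NULL` if the block
#'   was not answered.
#' @export
selected_actions <- function(matrix, rater, case) {
  v <- unclass(matrix)[rater, case, ]
  if (anyNA(v)) return(NULL)
  as.integer(which(v))
}

#' Keep only cases answered by every human rater
#'
#' The validation design drops incompletely answered cases before any
#' statistic is computed (in the original panel, one of six cases was
#' answered by only two of five experts and was excluded).
#'
#' @param matrix A [selection_matrix()].
#' @param human_raters Raters that must have answered; defaults to all
#'   raters except `algorithm`.
#' @param algorithm Label of the algorithm pseudo-rater (default
#'   `"LaD"`), excluded from the completeness requirement.
#' @return The filtered `selection_matrix`; dropped case labels are
#'   attached as attribute `dropped_cases` and reported via `message()`.
#' @export
filter_complete_cases <- function(matrix, human_raters = NULL,
                                  algorithm = "LaD") {
  raters <- dimnames(matrix)$rater
  human_raters <- human_raters %||% setdiff(raters, algorithm)
  answered <- !apply(unclass(matrix)[human_raters, , , drop = FALSE],
                     c(1L, 2L), anyNA)
  complete <- apply(answered, 2L, all)
  dropped <- dimnames(matrix)$case[!complete]
  if (length(dropped)) {
    message("dropping incompletely answered case(s): ",
            paste(dropped, collapse = ", "))
  }
  if (!any(complete)) warning("no complete cases remain", call. = FALSE)
  out <- selection_matrix(
    unclass(matrix)[, complete, , drop = FALSE],
    n_actions = attr(matrix, "n_actions"),
    max_select = attr(matrix, "max_select"))
  attr(out, "dropped_cases") <- dropped
  out
}

#' Read / write the long-format selection CSV dialect
#'
#' The on-disk dialect is a long CSV with header
#' `rater,case,action_id,selected` and `selected` in \{0, 1\}.  Writing
#' emits every action row of every answered block in rater, case, action
#' order, so that `write_selection_csv(read_selection_csv(f))` is
#' byte-identical for canonical files.
#'
#' @param path File path.
#' @inheritParams selection_matrix
#' @return `read_selection_csv` returns a [selection_matrix()];
#'   `write_selection_csv` invisibly returns `path`.
#' @export
read_selection_csv <- function(path, n_actions = 22L, max_select = 16L) {
  if (!file.exists(path)) {
    stop("validation error: file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(
      rater = "character", case = "character", action_id = "integer",
      selected = "integer")),
    error = function(e) {
      stop("validation error: malformed selection CSV: ",
           conditionMessage(e), call. = FALSE)
    })
  if (!nrow(df)) {
    stop("validation error: empty selection file", call. = FALSE)
  }
  selection_matrix(df, n_actions = n_actions, max_select = max_select)
}

#' @rdname read_selection_csv
#' @param matrix A [selection_matrix()] to write.
#' @export
write_selection_csv <- function(matrix, path) {
  dn <- dimnames(matrix)
  rows <- list()
  for (r in dn$rater) {
    for (cs in dn$case) {
      sel <- unclass(matrix)[r, cs, ]
      if (anyNA(sel)) next
      rows[[length(rows) + 1L]] <- data.frame(
        rater = r, case = cs, action_id = seq_along(sel),
        selected = as.integer(sel), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
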