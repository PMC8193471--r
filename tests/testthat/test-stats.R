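test_that("consensus weights equal the fraction of selecting experts", {
  m <- make_sel(list(E1 = 1:4, E2 = c(1, 2, 5), E3 = c(1, 3),
                     E4 = 1, E5 = c(1, 2)))
  w <- action_weights(m)
  expect_equal(unname(w["P1", 1]), 1.0)   # all 5 selected
  expect_equal(unname(w["P1", 2]), 0.6)   # 3 of 5 selected
  expect_equal(unname(w["P1", 3]), 0.4)
  expect_equal(unname(w["P1", 6]), 0)     # none selected
  expect_true(all(w %in% seq(0, 1, by = 0.2)))
  expect_error(action_weights(m, human_raters = "E1"), "at least 2")
})

test_that("weighted selection totals are bounded by raw counts", {
  # each own selection carries weight >= 1/k, so raw/k <= total <= raw
  set.seed(21)
  for (rep in 1:20) {
    m <- random_sel(k = 5, n_cases = 2, n_actions = 22)
    w <- action_weights(m, algorithm = character())
    for (r in dimnames(m)$rater) {
      for (cs in dimnames(m)$case) {
        sel <- selected_actions(m, r, cs)
        total <- sum(w[cs, sel])
        expect_gte(total, length(sel) / 5 - 1e-12)
        expect_lte(total, length(sel) + 1e-12)
      }
    }
  }
})

test_that("directed sensitivity follows the set-overlap definition", {
  m <- make_sel(list(A = 1:4, B = c(1, 2, 5), C = integer(), D = 1))
  expect_equal(pairwise_sensitivity(m, "A", "B", "P1"), 0.5)
  expect_equal(pairwise_sensitivity(m, "A", "A", "P1"), 1.0)
  expect_equal(pairwise_sensitivity(m, "D", "C", "P1"), 0.0)
  # empty reference is undefined, not zero
  expect_true(is.na(pairwise_sensitivity(m, "C", "A", "P1")))
})

test_that("weighted sensitivity sums consensus weights over the overlap", {
  m <- make_sel(list(E1 = 1:4, E2 = c(1, 2, 5), E3 = c(1, 3),
                     E4 = 1, E5 = c(1, 2)))
  w <- action_weights(m)
  # reference E1 = {1,2,3,4}: weights 1.0, 0.6, 0.4, 0.2; test E2 hits {1,2}
  expect_equal(pairwise_sensitivity(m, "E1", "E2", "P1", w),
               (1.0 + 0.6) / (1.0 + 0.6 + 0.4 + 0.2))
})

test_that("false-positive rate uses the reference complement", {
  m <- make_sel(list(A = 1:4, B = c(1:4, 7), C = 1:2, D = 5:8),
                n_actions = 22)
  expect_equal(pairwise_fpr(m, "A", "B", "P1"), 1 / 18)
  expect_equal(pairwise_fpr(m, "A", "C", "P1"), 0)          # subset
  m2 <- make_sel(list(A = 1:3, B = 4:8), n_actions = 8)
  expect_equal(pairwise_fpr(m2, "A", "B", "P1"), 1)          # complement
  m3 <- make_sel(list(A = 1:8, B = 1:2), n_actions = 8, max_select = 8)
  expect_true(is.na(pairwise_fpr(m3, "A", "B", "P1")))       # undefined
})

test_that("group scores equal a brute-force average over ordered pairs", {
  m <- make_sel(list(E1 = 1:4, E2 = c(1, 2, 5), E3 = c(2, 3, 6),
                     E4 = c(1, 4), E5 = c(3, 5, 7), LaD = c(1, 2, 3)))
  humans <- paste0("E", 1:5)
  # independent oracle: explicit double loop over ordered human pairs
  oracle <- function(stat_fun) {
    vals <- c()
    for (r in humans) for (t in setdiff(humans, r)) {
      vals <- c(vals, stat_fun(r, t))
    }
    mean(vals, na.rm = TRUE)
  }
  ee_sens <- oracle(function(r, t) pairwise_sensitivity(m, r, t, "P1"))
  expect_equal(as.numeric(per_case_group_score(m, "P1", "EE",
                                               "sensitivity")), ee_sens)
  ee_fpr <- oracle(function(r, t) pairwise_fpr(m, r, t, "P1"))
  expect_equal(as.numeric(per_case_group_score(m, "P1", "EE", "fpr")),
               ee_fpr)
  elad <- mean(vapply(humans, function(r)
    pairwise_sensitivity(m, r, "LaD", "P1"), 0))
  expect_equal(as.numeric(per_case_group_score(m, "P1", "ELaD",
                                               "sensitivity")), elad)
})

test_that("identical raters give perfect group sensitivity", {
  m <- make_sel(list(E1 = c(2, 5, 9), E2 = c(2, 5, 9)))
  expect_equal(as.numeric(per_case_group_score(m, "P1", "EE",
                                               "sensitivity")), 1.0)
  # algorithm equal to each reference's own set
  m2 <- make_sel(list(E1 = 1:3, E2 = 1:3, LaD = 1:3))
  expect_equal(as.numeric(per_case_group_score(m2, "P1", "ELaD",
                                               "sensitivity")), 1.0)
})

test_that("undefined pair scores are excluded with a reported count", {
  m <- make_sel(list(E1 = integer(), E2 = 1:2, E3 = c(1, 3)))
  s <- per_case_group_score(m, "P1", "EE", "sensitivity")
  expect_equal(attr(s, "n_undefined"), 2)  # E1 as reference, twice
  m_all_empty <- make_sel(list(E1 = integer(), E2 = integer()))
  s2 <- per_case_group_score(m_all_empty, "P1", "EE", "sensitivity")
  expect_true(is.na(as.numeric(s2)))
})

test_that("selection correlation is the geometric mean of directions", {
  m <- make_sel(list(A = 1:4, B = 1:2, C = 5:6))
  expect_equal(r_selection(m, "A", "B", "P1"), sqrt(0.5 * 1.0))
  expect_equal(r_selection(m, "A", "A", "P1"), 1.0)
  expect_equal(r_selection(m, "A", "C", "P1"), 0.0)
})

test_that("selection correlation is symmetric on random panels", {
  set.seed(31)
  for (rep in 1:50) {
    m <- random_sel(k = 4, n_cases = 2, n_actions = 12, prob = 0.5)
    for (cs in dimnames(m)$case) {
      for (a in dimnames(m)$rater) for (b in dimnames(m)$rater) {
        expect_identical(r_selection(m, a, b, cs),
                         r_selection(m, b, a, cs))
      }
    }
  }
})

test_that("reliability coefficient follows the Spearman-Brown form", {
  expect_equal(reliability_alpha(5, 0)$alpha, 0)
  expect_equal(reliability_alpha(5, 1)$alpha, 1)
  expect_equal(reliability_alpha(5, 0.55275)$alpha,
               5 * 0.55275 / (1 + 4 * 0.55275))
  # increasing in R at fixed k
  rs <- seq(0, 1, by = 0.1)
  alphas <- vapply(rs, function(r) reliability_alpha(5, r)$alpha, 0)
  expect_true(all(diff(alphas) > 0))
  expect_error(reliability_alpha(1, 0.5), "k must be")
  expect_error(reliability_alpha(5, 1.2), "R must lie")
})

test_that("summaries use the sample SD and t-based 95% CI", {
  s <- summarize_agreement(c(65.9, 56.5, 55.0, 45.6, 62.8))
  expect_equal(s$mean, 57.16)
  expect_equal(s$sd, sd(c(65.9, 56.5, 55.0, 45.6, 62.8)))
  hw <- qt(0.975, 4) * s$sd / sqrt(5)
  expect_equal(s$ci_low, s$mean - hw)
  expect_equal(s$ci_high, s$mean + hw)
  # degenerate: constant values collapse the interval
  s0 <- summarize_agreement(c(4, 4, 4))
  expect_equal(s0$sd, 0)
  expect_equal(c(s0$ci_low, s0$ci_high), c(4, 4))
  expect_error(summarize_agreement(5), "at least 2")
  expect_warning(summarize_agreement(c(1, 2, NA)), "NA")
})

test_that("adding a matching action never decreases sensitivity", {
  set.seed(41)
  for (rep in 1:30) {
    m <- random_sel(k = 2, n_cases = 1, n_actions = 12, prob = 0.4)
    ref <- selected_actions(m, "E1", "P1")
    tst <- selected_actions(m, "E2", "P1")
    if (!length(ref)) next
    base <- pairwise_sensitivity(m, "E1", "E2", "P1")
    missing_match <- setdiff(ref, tst)
    if (length(missing_match)) {
      arr <- unclass(m)
      arr["E2", "P1", missing_match[1]] <- TRUE
      m2 <- selection_matrix(arr, n_actions = 12, max_select = 12)
      expect_gte(pairwise_sensitivity(m2, "E1", "E2", "P1"), base)
    }
    # adding a non-reference action never decreases the FPR
    base_fpr <- pairwise_fpr(m, "E1", "E2", "P1")
    extra <- setdiff(setdiff(1:12, ref), tst)
    if (length(extra) && !is.na(base_fpr)) {
      arr <- unclass(m)
      arr["E2", "P1", extra[1]] <- TRUE
      m2 <- selection_matrix(arr, n_actions = 12, max_select = 12)
      expect_gte(pairwise_fpr(m2, "E1", "E2", "P1"), base_fpr)
    }
  }
})

test_that("evaluator ranking orders by CI borders and flags overlap", {
  mk <- function(vals) summarize_agreement(vals)
  # A dominates B on both borders
  a <- list(sensitivity = mk(c(60, 70, 80)), fpr = mk(c(10, 15, 20)))
  b <- list(sensitivity = mk(c(30, 50, 70)), fpr = mk(c(15, 25, 35)))
  rk <- rank_evaluators(list(A = a, B = b))
  expect_identical(rk$ranking$evaluator, c("A", "B"))
  # identical summaries tie and are flagged indistinguishable
  rk2 <- rank_evaluators(list(A = a, B = a))
  expect_equal(nrow(rk2$indistinguishable), 1)
})

test_that("the published group CIs overlap on both criteria", {
  mkfix <- function(mean, lo, hi) {
    structure(list(mean = mean, ci_low = lo, ci_high = hi),
              class = "agreement_summary")
  }
  rk <- rank_evaluators(list(
    experts = list(sensitivity = mkfix(68.2, 59.6, 76.8),
                   fpr = mkfix(23.9, 12.6, 35.2)),
    algorithm = list(sensitivity = mkfix(69.4, 47.1, 91.7),
                     fpr = mkfix(26.3, 13.3, 39.3))))
  expect_equal(nrow(rk$indistinguishable), 1)
})

test_that("incompletely answered cases are dropped before analysis", {
  sets <- function(full) {
    if (full) rep(list(1:3), 6) else c(rep(list(1:3), 5), list(NULL))
  }
  m <- make_sel(list(E1 = sets(TRUE), E2 = sets(TRUE), E3 = sets(FALSE),
                     E4 = sets(FALSE), E5 = sets(FALSE)),
                n_cases = 6)
  expect_message(f <- filter_complete_cases(m, algorithm = character()),
                 "P6")
  expect_equal(dim(f)[2], 5)
  expect_identical(attr(f, "dropped_cases"), "P6")
  # all-complete matrices pass through unchanged
  m2 <- make_sel(list(E1 = list(1:2, 2:3), E2 = list(1:2, 2:3)),
                 n_cases = 2)
  f2 <- filter_complete_cases(m2, algorithm = character())
  expect_equal(dim(f2), dim(m2))
  # no complete case at all
  m3 <- make_sel(list(E1 = list(1:2, NULL), E2 = list(NULL, 1:2)),
                 n_cases = 2)
  expect_warning(expect_message(filter_complete_cases(m3,
    algorithm = character())), "no complete cases")
})

test_that("Welch comparison matches t.test output structure", {
  x <- c(65.9, 56.5, 55.0, 45.6, 62.8)
  y <- c(44.4, 74.0, 85.6, 58.7, 50.3)
  cm <- compare_means(x, y)
  expect_equal(cm$difference, mean(x) - mean(y))
  expect_true(cm$ci_low < cm$difference && cm$difference < cm$ci_high)
})
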