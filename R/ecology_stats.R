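# Count-table statistics for the isolate survey: chi-square independence on
# 2x2 ratio comparisons between locations, goodness-of-fit for mating-type
# ratios, one-way ANOVA with Tukey-Kramer post-hoc tests, proportion tables
# and the inhaled-conidia exposure estimator.
#
# Deliberately no Yates continuity correction and no exact test: the original
# survey analysis used plain Pearson statistics, and the published p-values
# (including small-count cells) reproduce exactly under that choice. Cells
# with expected counts < 5 are annotated with a warning flag, never switched
# to another method.

test_result <- function(statistic, df, p_value, method, note = NA_character_) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), method = method, note = note),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic, digits = 6),
      " df =", paste(x$df, collapse = ", "),
      " p =", format(x$p_value, digits = 4), "\n")
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Classical R x C Pearson test without continuity correction:
#' X^2 = sum (O-E)^2 / E with E from the margins, df = (R-1)(C-1), upper-tail
#' p-value.
#'
#' @param table integer matrix of counts, at least 2 x 2.
#' @return a `test_result` (statistic, df, p_value, method, note). The note
#'   flags expected cells < 5.
#' @export
chi2_independence <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stop("need an R x C table, R,C >= 2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin: expected counts undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  note <- if (any(ct$expected < 5)) {
    "expected count < 5 in at least one cell; chi-square approximation is rough"
  } else NA_character_
  test_result(ct$statistic, ct$parameter, ct$p.value,
              "Pearson chi-square test of independence (no continuity correction)",
              note)
}

#' Chi-square goodness-of-fit test against a fixed ratio
#'
#' @param observed vector of category counts (>= 2 categories).
#' @param expected_ratio expected ratio between the categories (default 1:1:...),
#'   rescaled internally to probabilities.
#' @return a `test_result` with df = categories - 1.
#' @export
#' @examples
#' chi2_goodness_of_fit(c(13, 11))  # mating types vs a 1:1 ratio
chi2_goodness_of_fit <- function(observed,
                                 expected_ratio = rep(1, length(observed))) {
  if (length(observed) < 2) stop("need at least two categories")
  if (length(expected_ratio) != length(observed)) {
    stop("expected_ratio length (", length(expected_ratio),
         ") does not match observed (", length(observed), ")")
  }
  if (any(expected_ratio <= 0)) stop("expected ratio entries must be > 0")
  p <- expected_ratio / sum(expected_ratio)
  ct <- suppressWarnings(stats::chisq.test(observed, p = p))
  note <- if (any(ct$expected < 5)) {
    "expected count < 5 in at least one cell; chi-square approximation is rough"
  } else NA_character_
  test_result(ct$statistic, ct$parameter, ct$p.value,
              "Pearson chi-square goodness-of-fit test", note)
}

#' Pairwise ratio-comparison matrices between locations
#'
#' For each requested ratio and every pair of locations, builds the 2x2 table
#' of the two category counts and applies [chi2_independence()]. Ratios are
#' written over the columns `C` (chrysogenum), `R` (rubens) and `O` (other):
#' `"C:R"`, `"C:O"`, `"R:O"` and `"C+R:O"` (complex total vs other).
#'
#' @param counts matrix of location x species counts with columns named
#'   `chrysogenum`, `rubens`, `other` (see [london_survey_counts()]).
#' @param comparisons character vector of ratio labels.
#' @return named list of upper-triangular p-value matrices (rows = all but
#'   the last location, columns = all but the first); `NA` marks pairs where
#'   a location has zero total for the chosen ratio.
#' @export
ratio_comparison_matrix <- function(counts,
                                    comparisons = c("C:R", "C:O", "R:O",
                                                    "C+R:O")) {
  counts <- as.matrix(counts)
  need <- c("chrysogenum", "rubens", "other")
  if (!all(need %in% colnames(counts))) {
    stop("counts must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(counts) < 2) stop("need at least two locations")
  locs <- rownames(counts)
  ratio_cols <- function(cmp) {
    parts <- strsplit(cmp, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed comparison '", cmp, "'")
    side <- function(p) {
      keys <- strsplit(p, "+", fixed = TRUE)[[1]]
      map <- c(C = "chrysogenum", R = "rubens", O = "other")
      cols <- map[trimws(keys)]
      if (anyNA(cols)) stop("unknown category in comparison '", cmp, "'")
      cols
    }
    list(a = side(parts[1]), b = side(parts[2]))
  }
  out <- list()
  for (cmp in comparisons) {
    rc <- ratio_cols(cmp)
    m <- matrix(NA_real_, nrow = length(locs) - 1, ncol = length(locs) - 1,
                dimnames = list(locs[-length(locs)], locs[-1]))
    for (i in seq_len(length(locs) - 1)) {
      for (j in seq(i + 1, length(locs))) {
        tab <- rbind(c(sum(counts[i, rc$a]), sum(counts[i, rc$b])),
                     c(sum(counts[j, rc$a]), sum(counts[j, rc$b])))
        m[locs[i], locs[j]] <- if (any(rowSums(tab) == 0) ||
                                   any(colSums(tab) == 0)) NA_real_
          else chi2_independence(tab)$p_value
      }
    }
    out[[cmp]] <- m
  }
  out
}

#' One-way analysis of variance
#'
#' Classical fixed-effects F test on k groups:
#' F = MSB/MSW with df = (k-1, N-k).
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, every
#'   group non-empty, N-k >= 1).
#' @return a `test_result`; `df` is the pair (df1, df2).
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("empty group")
  n <- sum(sizes); k <- length(groups)
  if (n - k < 1) stop("no within-group degrees of freedom")
  all_x <- unlist(groups, use.names = FALSE)
  grand <- mean(all_x)
  ssb <- sum(sizes * (vapply(groups, mean, numeric(1)) - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- if (msw == 0) { if (msb == 0) 0 else Inf } else msb / msw
  p <- if (msw == 0 && msb == 0) 1 else stats::pf(f, k - 1, n - k,
                                                  lower.tail = FALSE)
  test_result(f, c(k - 1, n - k), p, "one-way ANOVA")
}

#' Tukey-Kramer pairwise comparisons
#'
#' Studentized-range post-hoc test after a one-way layout, with the Kramer
#' adjustment for unequal group sizes:
#' q_ij = |mean_i - mean_j| / sqrt(MSW * (1/n_i + 1/n_j) / 2), compared to the
#' studentized-range quantile at (k, N-k, alpha).
#'
#' @param groups list of numeric vectors (named or not), as [one_way_anova()].
#' @param alpha family-wise significance level in (0, 1).
#' @return data.frame with one row per group pair: group_i, group_j,
#'   difference, se, q, p_adj (studentized-range upper tail), q_critical,
#'   significant.
#' @export
tukey_kramer <- function(groups, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("empty group")
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  k <- length(groups); n <- sum(sizes)
  means <- vapply(groups, mean, numeric(1))
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                    numeric(1))) / (n - k)
  qcrit <- stats::qtukey(1 - alpha, k, n - k)
  out <- list()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    se <- sqrt(msw * 0.5 * (1 / sizes[i] + 1 / sizes[j]))
    diffv <- means[i] - means[j]
    q <- if (se == 0) { if (diffv == 0) 0 else Inf } else abs(diffv) / se
    p <- stats::ptukey(q, k, n - k, lower.tail = FALSE)
    out[[length(out) + 1]] <- data.frame(
      group_i = names(groups)[i], group_j = names(groups)[j],
      difference = unname(diffv), se = unname(se), q = unname(q),
      p_adj = unname(p), q_critical = qcrit,
      significant = q > qcrit, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Parameters of the inhaled-conidia exposure estimator
#'
#' @param tidal_volume_l tidal volume of one breath (litres, default 0.5).
#' @param breaths_per_min respiratory rate (default 15).
#' @return list of class `exposure_params`.
#' @export
exposure_params <- function(tidal_volume_l = 0.5, breaths_per_min = 15) {
  if (tidal_volume_l <= 0 || breaths_per_min <= 0) {
    stop("exposure parameters must be > 0")
  }
  structure(list(tidal_volume_l = tidal_volume_l,
                 breaths_per_min = breaths_per_min),
            class = "exposure_params")
}

#' Viable conidia inhaled per minute
#'
#' Converts a colony count from an air sample into an exposure rate:
#' (colonies / sampled air volume) x tidal volume x breaths per minute.
#'
#' @param colony_count number of viable colonies counted (>= 0).
#' @param air_volume_l volume of air sampled (litres, > 0).
#' @param params an [exposure_params()] list.
#' @return conidia inhaled per minute.
#' @export
#' @examples
#' exposure_rate(53, 500)  # 0.795 conidia per minute
exposure_rate <- function(colony_count, air_volume_l,
                          params = exposure_params()) {
  if (any(colony_count < 0)) stop("colony count must be >= 0")
  if (any(air_volume_l <= 0)) stop("air volume must be > 0")
  (colony_count / air_volume_l) * params$tidal_volume_l *
    params$breaths_per_min
}

#' Percentages of row totals
#'
#' Expresses every cell of a count table as a percentage of its row total,
#' reported to one decimal place. Rows with zero total get `NA`.
#'
#' @param counts matrix of counts with dimnames.
#' @return numeric matrix of percentages (one decimal).
#' @export
proportion_table <- function(counts) {
  counts <- as.matrix(counts)
  totals <- rowSums(counts)
  pct <- sweep(counts, 1, totals, "/") * 100
  pct[totals == 0, ] <- NA_real_
  round(pct, 1)
}
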