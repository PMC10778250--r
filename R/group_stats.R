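#' Shapiro-Wilk normality check
#'
#' Thin wrapper over `stats::shapiro.test`, used to justify the
#' nonparametric descriptives and rank tests applied to the bin
#' percentages and demographics.
#'
#' @param values Numeric sample, 3 <= n <= 5000.
#' @return List with `W` and `p`.
#' @export
normality_check <- function(values) {
  values <- as.numeric(values)
  if (length(unique(values)) == 1L) stop("constant sample: W undefined")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Kruskal-Wallis test with Dunn pairwise comparisons
#'
#' The tie-corrected Kruskal-Wallis H (via `stats::kruskal.test`) with a
#' chi-square (g-1 df) p-value, plus Dunn's z for every group pair:
#' `z = (Rbar_i - Rbar_j) / sqrt(V * (1/n_i + 1/n_j))` with the
#' tie-corrected variance `V = N(N+1)/12 - sum(t^3 - t) / (12 (N - 1))`.
#' Two-sided raw p-values; Bonferroni adjustment multiplies by the number
#' of pairs (capped at 1).
#'
#' @param groups List of numeric samples (>= 2 groups, total n >= 3), or
#'   a numeric vector with `labels`.
#' @param labels Optional grouping vector when `groups` is a vector.
#' @param adjustment `"bonferroni"` (default) or `"none"`.
#' @return Object of class `kw_result`: `H`, `df`, `p`, and `pairwise`
#'   (data.frame: group_i, group_j, z, p_raw, p_adjusted), with the
#'   adjustment recorded as attribute `"adjustment"`.
#' @export
kruskal_wallis <- function(groups, labels = NULL,
                           adjustment = c("bonferroni", "none")) {
  adjustment <- match.arg(adjustment)
  if (!is.list(groups)) {
    stopifnot(!is.null(labels))
    groups <- split(as.numeric(groups), labels)
  }
  g <- length(groups)
  if (g < 2L) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("every group needs at least one observation")
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  if (N < 3L) stop("need at least 3 observations in total")
  if (length(unique(x)) == 1L)
    stop("degenerate ties: all observations identical")
  lab <- factor(rep(seq_len(g), sizes))
  ht <- stats::kruskal.test(x, lab)
  # Dunn pairwise z with tie-corrected variance
  r <- rank(x)
  rbar <- tapply(r, lab, mean)
  ties <- table(x)
  V <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(g, 2L)
  n_pairs <- ncol(pairs)
  z <- p_raw <- numeric(n_pairs)
  for (c_i in seq_len(n_pairs)) {
    i <- pairs[1, c_i]; j <- pairs[2, c_i]
    se <- sqrt(V * (1 / sizes[i] + 1 / sizes[j]))
    z[c_i] <- (rbar[i] - rbar[j]) / se
    p_raw[c_i] <- 2 * stats::pnorm(-abs(z[c_i]))
  }
  p_adj <- if (adjustment == "bonferroni") pmin(1, p_raw * n_pairs) else p_raw
  grp_names <- if (!is.null(names(groups))) names(groups) else as.character(seq_len(g))
  pw <- data.frame(group_i = grp_names[pairs[1, ]],
                   group_j = grp_names[pairs[2, ]],
                   z = z, p_raw = p_raw, p_adjusted = p_adj,
                   stringsAsFactors = FALSE)
  attr(pw, "adjustment") <- adjustment
  structure(list(H = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, pairwise = pw),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("<kw_result> H = %.4f, df = %d, p = %.4g\n", x$H, x$df, x$p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Dunn's multiple comparisons
#'
#' Convenience accessor: runs [kruskal_wallis()] and returns only the
#' pairwise table.
#'
#' @inheritParams kruskal_wallis
#' @return data.frame of pairwise rows (group_i, group_j, z, p_raw,
#'   p_adjusted).
#' @export
dunn_posthoc <- function(groups, labels = NULL,
                         adjustment = c("bonferroni", "none")) {
  kruskal_wallis(groups, labels, adjustment)$pairwise
}

#' Box-plot descriptives
#'
#' Median and quartiles (linear interpolation between order statistics,
#' the default quantile convention) with whiskers at the minimum and
#' maximum: no outlier trimming.
#'
#' @param values Numeric sample, n >= 1.
#' @return List with `minimum`, `lower_quartile`, `median`,
#'   `upper_quartile`, `maximum`.
#' @export
describe_box <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty sample")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(minimum = min(values), lower_quartile = q[1], median = q[2],
       upper_quartile = q[3], maximum = max(values))
}

#' Cohort descriptive statistics
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' age, height and body condition score from a demographics table such as
#' [cohort_fixture()].
#'
#' @param table data.frame with numeric columns `age_years`, `height_cm`,
#'   `bcs`.
#' @return data.frame with variable, mean, sd, min, max.
#' @export
descriptive_cohort <- function(table) {
  if (!nrow(table)) stop("empty demographics table")
  vars <- c("age_years", "height_cm", "bcs")
  missing_vars <- setdiff(vars, names(table))
  if (length(missing_vars))
    stop("missing columns: ", paste(missing_vars, collapse = ", "))
  do.call(rbind, lapply(vars, function(v) {
    x <- table[[v]]
    if (anyNA(x)) stop("incomplete records in ", v)
    data.frame(variable = v, mean = mean(x), sd = stats::sd(x),
               min = min(x), max = max(x), stringsAsFactors = FALSE)
  }))
}

#' Compact letter display from pairwise p-values
#'
#' Deterministic insert-and-absorb assignment of lowercase letters:
#' groups not sharing a letter differ at `alpha`. Groups are processed in
#' their given order; letters are assigned greedily.
#'
#' @param pairwise data.frame with columns group_i, group_j and a p-value
#'   column.
#' @param groups Character vector of group names in display order.
#' @param alpha Significance level (default 0.05).
#' @param p_col Name of the p-value column (default `"p_adjusted"`).
#' @return Named character vector of letter strings, one per group.
#' @export
compact_letters <- function(pairwise, groups, alpha = 0.05,
                            p_col = "p_adjusted") {
  g <- length(groups)
  differs <- matrix(FALSE, g, g, dimnames = list(groups, groups))
  for (r in seq_len(nrow(pairwise))) {
    i <- pairwise$group_i[r]; j <- pairwise$group_j[r]
    if (pairwise[[p_col]][r] < alpha) differs[i, j] <- differs[j, i] <- TRUE
  }
  # each letter = a maximal set of mutually non-different groups
  # (maximal cliques of the "not different" graph, enumerated exhaustively:
  # the comparison families here have at most a handful of groups)
  if (g > 15L) stop("compact_letters supports up to 15 groups")
  sets <- list()
  for (code in seq_len(2^g - 1L)) {
    members <- which(bitwAnd(code, 2^(seq_len(g) - 1L)) > 0L)
    ok <- !any(differs[members, members])
    if (ok) sets[[length(sets) + 1L]] <- members
  }
  is_maximal <- vapply(seq_along(sets), function(a) {
    !any(vapply(seq_along(sets), function(b) {
      b != a && length(sets[[b]]) > length(sets[[a]]) &&
        all(sets[[a]] %in% sets[[b]])
    }, logical(1)))
  }, logical(1))
  sets <- sets[is_maximal]
  # deterministic letter order: by first member, then size
  ord <- order(vapply(sets, min, integer(1)),
               -vapply(sets, length, integer(1)))
  sets <- sets[ord]
  letters_out <- rep("", g)
  for (s in seq_along(sets))
    letters_out[sets[[s]]] <- paste0(letters_out[sets[[s]]], letters[s])
  stats::setNames(letters_out, groups)
}
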