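#' Goodall-style Procrustes ANOVA for shape
#'
#' Decomposes the summed squared Procrustes deviations of the superimposed
#' coordinates into a between-group and a within-group part:
#' `SS_effect = sum_g n_g * d^2(mean_g, grand mean)` and
#' `SS_residual = sum_i d^2(x_i, mean_g(i))`, with degrees of freedom
#' `(g - 1) * m` and `(n - g) * m` where `m = shape_dimension(k, 2)` (56
#' for 30 two-dimensional landmarks). The Goodall F is the ratio of mean
#' squares, with a parametric F p-value by default or a label-permutation
#' p-value on request.
#'
#' @param fit A [gpa()] fit.
#' @param labels Grouping vector (factor or character), one per specimen.
#' @param p_method `"parametric"` (F distribution, default) or
#'   `"permutation"`.
#' @param n_permutations Number of label permutations when
#'   `p_method = "permutation"`.
#' @param seed Optional seed for the permutation stream.
#' @return One-row data.frame of class `anova_row`: effect, SS, MS, df, F,
#'   p, plus residual SS/MS/df as attributes `residual`.
#' @export
procrustes_anova_shape <- function(fit, labels,
                                   p_method = c("parametric", "permutation"),
                                   n_permutations = 10000L, seed = NULL) {
  stopifnot(inherits(fit, "procrustes_fit"))
  p_method <- match.arg(p_method)
  X <- .flatten_fit(fit)
  labels <- as.factor(labels)
  if (length(labels) != nrow(X)) stop("labels must match specimens")
  if (nlevels(droplevels(labels)) < 2L) stop("need at least 2 groups")
  labels <- droplevels(labels)
  if (any(table(labels) < 1L)) stop("every group must be non-empty")
  m <- shape_dimension(dim(fit$aligned)[1], 2L)
  res <- .goodall_decomposition(X, labels)
  g <- nlevels(labels); n <- nrow(X)
  df_eff <- (g - 1L) * m
  df_res <- (n - g) * m
  MS_eff <- res$ss_effect / df_eff
  MS_res <- res$ss_resid / df_res
  if (res$ss_resid <= 0) {
    warning("zero residual sum of squares; p reported at boundary")
    Fval <- Inf; pval <- 0
  } else {
    Fval <- MS_eff / MS_res
    pval <- stats::pf(Fval, df_eff, df_res, lower.tail = FALSE)
  }
  if (p_method == "permutation" && is.finite(Fval)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    count <- 0L
    for (b in seq_len(n_permutations)) {
      perm <- sample(labels)
      rp <- .goodall_decomposition(X, perm)
      Fp <- (rp$ss_effect / df_eff) / (rp$ss_resid / df_res)
      if (Fp >= Fval) count <- count + 1L
    }
    pval <- (count + 1L) / (n_permutations + 1L)
  }
  .anova_row("shape", res$ss_effect, df_eff, Fval, pval,
             res$ss_resid, df_res)
}

# between/within sums of squares over rows of X grouped by labels
.goodall_decomposition <- function(X, labels) {
  grand <- colMeans(X)
  ss_effect <- 0; ss_resid <- 0
  for (lv in levels(labels)) {
    rows <- X[labels == lv, , drop = FALSE]
    mu_g <- colMeans(rows)
    ss_effect <- ss_effect + nrow(rows) * sum((mu_g - grand)^2)
    ss_resid <- ss_resid + sum(sweep(rows, 2L, mu_g)^2)
  }
  list(ss_effect = ss_effect, ss_resid = ss_resid)
}

.anova_row <- function(effect, ss, df, Fval, pval, ss_res, df_res) {
  row <- data.frame(effect = effect, SS = ss, MS = ss / df, df = df,
                    F = Fval, p = pval, stringsAsFactors = FALSE)
  attr(row, "residual") <- data.frame(SS = ss_res, MS = ss_res / df_res,
                                      df = df_res)
  class(row) <- c("anova_row", "data.frame")
  row
}

#' One-way ANOVA of centroid size
#'
#' Standard one-way ANOVA of the (pre-scaling) centroid sizes across
#' classifier groups, with `g - 1` effect and `n - g` residual degrees of
#' freedom; delegates the fit to `stats::lm`/`stats::anova`.
#'
#' @param sizes Positive numeric vector of centroid sizes.
#' @param labels Grouping vector, one per size.
#' @return One-row data.frame of class `anova_row` (see
#'   [procrustes_anova_shape()]).
#' @export
anova_centroid_size <- function(sizes, labels) {
  labels <- droplevels(as.factor(labels))
  if (length(sizes) != length(labels)) stop("lengths differ")
  if (nlevels(labels) < 2L) stop("need at least 2 groups")
  if (any(table(labels) < 1L)) stop("every group must be non-empty")
  tab <- stats::anova(stats::lm(sizes ~ labels))
  if (tab["Residuals", "Sum Sq"] <= 0)
    warning("zero within-group variance everywhere; p at boundary")
  .anova_row("centroid size", tab["labels", "Sum Sq"], tab["labels", "Df"],
             tab["labels", "F value"], tab["labels", "Pr(>F)"],
             tab["Residuals", "Sum Sq"], tab["Residuals", "Df"])
}

#' Per-class consensus shapes
#'
#' Arithmetic mean of the superimposed coordinates within each classifier
#' level, paired with the grand consensus; the pairs drive the wireframe
#' deformation displays of average observations.
#'
#' @param fit A [gpa()] fit.
#' @param labels Grouping vector, one per specimen.
#' @return Named list of k x 2 matrices (one per level, in level order)
#'   with the grand consensus as attribute `"grand"`.
#' @export
consensus_by_class <- function(fit, labels) {
  stopifnot(inherits(fit, "procrustes_fit"))
  labels <- as.factor(labels)
  if (any(table(labels) < 1L)) stop("every class must be non-empty")
  out <- lapply(levels(labels), function(lv) {
    idx <- which(labels == lv)
    m <- apply(fit$aligned[, , idx, drop = FALSE], c(1L, 2L), mean)
    dimnames(m) <- list(NULL, c("x", "y"))
    m
  })
  names(out) <- levels(labels)
  attr(out, "grand") <- fit$consensus
  out
}
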