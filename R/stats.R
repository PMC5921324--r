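# Group-level inference: permutation test for correlation-network topology,
# ANCOVA for subject-level network metrics, partial correlation with
# cognitive scores, demographics tests, normality checks, multiplicity.

# Fast evaluator used inside the permutation loop: from a subjects x regions
# value matrix, compute (Cp, Lp) of the thresholded correlation network at
# every sparsity on the grid. The edge ranking is computed once per matrix;
# the per-sparsity graphs are nested prefixes of it.
cor_topology_stats <- function(X, grid, mode = "weighted", rank = "abs") {
  N <- ncol(X)
  C <- suppressWarnings(stats::cor(X))
  C[!is.finite(C)] <- 0
  diag(C) <- 0
  ut <- which(upper.tri(C))
  ij <- arrayInd(ut, dim(C))
  w <- C[ut]
  rv <- if (rank == "positive") pmax(w, 0) else abs(w)
  o <- order(-rv, ij[, 1], ij[, 2])
  idx <- ut[o]; io <- ij[o, 1]; jo <- ij[o, 2]; vo <- rv[o]
  weighted <- mode == "weighted"
  # Onnela-normalised weights (w / max)^(1/3), shared across the sweep since
  # the maximum |r| is the first ranked entry
  voh <- if (weighted && vo[1] > 0) (vo / vo[1])^(1 / 3) else rep(1, length(vo))
  npairs <- N * (N - 1) / 2
  out <- matrix(NA_real_, 2, length(grid),
                dimnames = list(c("Cp", "Lp"), sprintf("%.2f", grid)))
  for (s in seq_along(grid)) {
    K <- floor(grid[s] * npairs)
    sel <- seq_len(K)
    Wh <- matrix(0, N, N)
    Wh[idx[sel]] <- voh[sel]
    Wh[cbind(jo[sel], io[sel])] <- voh[sel]
    k <- rowSums(Wh > 0)
    cyc <- rowSums((Wh %*% Wh) * Wh) # = diag(Wh^3)
    ci <- ifelse(k >= 2, cyc / (k * (k - 1)), 0)
    g <- igraph::make_empty_graph(N, directed = FALSE)
    g <- igraph::add_edges(g, rbind(io[sel], jo[sel]))
    dw <- if (weighted) {
      pos <- vo[sel] > 0
      if (!all(pos)) { # zero-|r| edges cannot carry finite distance
        g <- igraph::delete_edges(g, which(!pos))
      }
      1 / vo[sel][pos]
    } else NULL
    d <- igraph::distances(g, weights = dw)
    d <- d[upper.tri(d)]
    fin <- is.finite(d)
    out[1, s] <- mean(ci)
    out[2, s] <- if (any(fin)) mean(d[fin]) else NA_real_
  }
  out
}

#' Permutation test for group differences in correlation-network topology
#'
#' Implements the full-pipeline randomisation procedure: Cp and Lp of each
#' group's thresholded correlation network are computed at every sparsity
#' on the grid; then group labels are shuffled (preserving group sizes),
#' the correlation matrix, threshold and metrics are recomputed for each
#' permuted group, and a two-tailed p-value is derived per sparsity as
#' `(1 + #{|null diff| >= |observed diff|}) / (n_perm + 1)`.
#'
#' Graphs default to weighted mode (edge weight |r|, distance 1/|r|,
#' Onnela clustering), matching the convention of thresholding to a
#' weighted matrix at the same sparsity as the real networks.
#'
#' @param tableA,tableB [regional_metric_table()] objects for the two
#'   groups (e.g. patients and controls); differences are A - B.
#' @param grid sparsity grid (default 0.06 to 0.40 by 0.01).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @param mode `"weighted"` (default) or `"binary"` thresholded graphs.
#' @param rank how negative correlations rank; see [threshold_by_sparsity()].
#' @param alpha significance level used to report significant-sparsity
#'   ranges (default 0.05).
#' @return an object of class `permutation_result`: per attribute (Cp, Lp) a
#'   data.frame of `sparsity`, `valueA`, `valueB`, `diff`, `p`, plus
#'   `significant_ranges`, `n_perm` and `seed`.
#' @export
gm_permutation_test <- function(tableA, tableB,
                                grid = seq(0.06, 0.40, by = 0.01),
                                n_perm = 1000, seed = 1,
                                mode = c("weighted", "binary"),
                                rank = c("abs", "positive"),
                                alpha = 0.05) {
  mode <- match.arg(mode)
  rank <- match.arg(rank)
  stopifnot(inherits(tableA, "regional_metric_table"),
            inherits(tableB, "regional_metric_table"))
  if (!identical(tableA$regions, tableB$regions))
    stop("tables do not share region labels")
  if (n_perm < 1) stop("n_perm must be at least 1")
  XA <- tableA$values; XB <- tableB$values
  nA <- nrow(XA); nB <- nrow(XB)
  if (nA + nB < 6) stop("need at least 6 subjects in total")

  statsA <- cor_topology_stats(XA, grid, mode, rank)
  statsB <- cor_topology_stats(XB, grid, mode, rank)
  obs <- statsA - statsB

  X <- rbind(XA, XB)
  count <- matrix(1, 2, length(grid))
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      idx <- sample.int(nA + nB)
      nul <- cor_topology_stats(X[idx[seq_len(nA)], , drop = FALSE], grid, mode, rank) -
        cor_topology_stats(X[idx[-seq_len(nA)], , drop = FALSE], grid, mode, rank)
      count <- count + (abs(nul) >= abs(obs))
    }
  })
  pmat <- count / (n_perm + 1)

  per_attr <- lapply(c(Cp = 1, Lp = 2), function(k) {
    df <- data.frame(sparsity = grid, valueA = statsA[k, ], valueB = statsB[k, ],
                     diff = obs[k, ], p = pmat[k, ])
    rownames(df) <- NULL
    df
  })
  structure(list(
    Cp = per_attr$Cp, Lp = per_attr$Lp,
    significant_ranges = lapply(per_attr, function(df)
      significant_runs(df$sparsity, df$p < alpha)),
    n_perm = n_perm, seed = seed, mode = mode, rank = rank, alpha = alpha
  ), class = "permutation_result")
}

# Maximal contiguous runs of TRUE over an ordered grid, as a data.frame of
# (lo, hi) sparsity bounds.
significant_runs <- function(grid, sig) {
  if (!any(sig)) return(data.frame(lo = numeric(0), hi = numeric(0)))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(lo = grid[starts[keep]], hi = grid[ends[keep]])
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d permutations, %d sparsities (%s graphs)\n",
              x$n_perm, nrow(x$Cp), x$mode))
  for (a in c("Cp", "Lp")) {
    rr <- x$significant_ranges[[a]]
    txt <- if (nrow(rr)) paste(sprintf("%.0f%%<=S<=%.0f%%", 100 * rr$lo, 100 * rr$hi),
                               collapse = ", ") else "none"
    cat(sprintf("  %s: significant (p<%.2f) at %s\n", a, x$alpha, txt))
  }
  invisible(x)
}

#' ANCOVA for a group effect on a subject-level network metric
#'
#' Fits `value ~ group + age + sex` and reports the partial (type-II) F
#' test for the group term. Constant covariates are dropped with a message;
#' a covariate collinear with the remaining design is an error. With no
#' covariates this reduces exactly to the one-way ANOVA F (the square of
#' the pooled two-sample t statistic).
#'
#' @param values numeric vector, one network metric value per subject.
#' @param group two-level factor or character vector.
#' @param age,sex optional covariates (numeric / factor).
#' @return an object of class `ancova_result`: `F`, `df1`, `df2`, `p`,
#'   `covariates`.
#' @export
ancova_group_effect <- function(values, group, age = NULL, sex = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (min(table(group)) < 3) stop("need at least 3 subjects per group")
  dat <- data.frame(value = values, group = group)
  covs <- character(0)
  for (nm in c("age", "sex")) {
    v <- get(nm)
    if (is.null(v)) next
    if (length(unique(v)) < 2) {
      message(sprintf("covariate '%s' is constant; dropped from the model", nm))
      next
    }
    dat[[nm]] <- if (is.character(v)) factor(v) else v
    covs <- c(covs, nm)
  }
  form <- stats::reformulate(c("group", covs), response = "value")
  fit <- stats::lm(form, data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  reduced <- stats::update(fit, . ~ . - group)
  an <- stats::anova(reduced, fit)
  structure(list(F = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
                 p = an$`Pr(>F)`[2], covariates = covs),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("<ancova_result> F(%d, %d) = %.4f, p = %.4g (covariates: %s)\n",
              x$df1, x$df2, x$F, x$p,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after linear
#' regression on the covariates; the p-value uses the t reference with
#' `n - k - 2` degrees of freedom (k covariate columns). With no
#' covariates this equals the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame/matrix of covariates, or NULL.
#' @return an object of class `partial_correlation_result`: `r`, `df`, `p`,
#'   `evaluable`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  Z <- if (is.null(covariates)) matrix(numeric(0), n, 0) else {
    Z <- as.data.frame(covariates)
    stats::model.matrix(~ ., data = Z)[, -1, drop = FALSE]
  }
  k <- ncol(Z)
  if (n <= k + 2) stop("need n > k + 2 observations")
  M <- cbind(1, Z)
  res <- function(v) stats::lm.fit(M, v)$residuals
  rx <- res(x); ry <- res(y)
  sx <- sqrt(sum(rx^2)); sy <- sqrt(sum(ry^2))
  tol <- 1e-10 * max(1, stats::sd(x), stats::sd(y))
  if (sx < tol || sy < tol) {
    return(structure(list(r = NA_real_, df = n - k - 2, p = NA_real_,
                          evaluable = FALSE, n = n, k = k),
                     class = "partial_correlation_result"))
  }
  r <- sum(rx * ry) / (sx * sy)
  df <- n - k - 2
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  structure(list(r = r, df = df, p = p, evaluable = TRUE, n = n, k = k),
            class = "partial_correlation_result")
}

#' @export
print.partial_correlation_result <- function(x, ...) {
  if (!x$evaluable) cat("<partial_correlation_result> not evaluable (degenerate residuals)\n")
  else cat(sprintf("<partial_correlation_result> r = %.4f (df %d), p = %.4g\n",
                   x$r, x$df, x$p))
  invisible(x)
}

#' Compare demographics and clinical scores between groups
#'
#' Continuous variables get the pooled two-sample t-test (equal variances)
#' with group summaries formatted as mean (±SD); the sex variable gets the
#' chi-square test on the 2 x 2 contingency table.
#'
#' @param covariates data.frame with columns `group`, `sex`, and any
#'   continuous variables (e.g. `age`, `MMSE`, `MoCA`).
#' @param continuous names of the continuous columns to test.
#' @return a data.frame with one row per variable: per-group summaries,
#'   test statistic and p-value.
#' @export
demographics_compare <- function(covariates,
                                 continuous = intersect(c("age", "MMSE", "MoCA"),
                                                        names(covariates))) {
  g <- factor(covariates$group)
  if (nlevels(g) != 2) stop("two groups required")
  if (min(table(g)) < 2) stop("each group needs at least 2 subjects")
  lv <- levels(g)
  rows <- lapply(continuous, function(v) {
    x1 <- covariates[[v]][g == lv[1]]; x2 <- covariates[[v]][g == lv[2]]
    tt <- stats::t.test(x1, x2, var.equal = TRUE)
    data.frame(variable = v,
               group1 = sprintf("%.2f (±%.2f)", mean(x1), stats::sd(x1)),
               group2 = sprintf("%.2f (±%.2f)", mean(x2), stats::sd(x2)),
               test = "t", statistic = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  if ("sex" %in% names(covariates)) {
    tab <- table(g, covariates$sex)
    ct <- suppressWarnings(stats::chisq.test(tab))
    fmt <- function(i) paste(tab[i, ], collapse = "/")
    rows <- c(rows, list(data.frame(
      variable = "sex", group1 = fmt(1), group2 = fmt(2),
      test = "chi-square", statistic = unname(ct$statistic), p = ct$p.value,
      stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  names(out)[2:3] <- lv
  rownames(out) <- NULL
  out
}

#' Kolmogorov-Smirnov normality check per group
#'
#' One-sample KS test of each group's values against a normal distribution
#' with the group's sample mean and SD. Because the parameters are
#' estimated from the same sample, the test is conservative (noted in the
#' output). Constant values are degenerate and flagged instead of tested.
#'
#' @param values numeric vector.
#' @param group group label per value.
#' @return data.frame with one row per group: `n`, `statistic`, `p`,
#'   `degenerate`, `note`.
#' @export
normality_check <- function(values, group) {
  g <- factor(group)
  rows <- lapply(levels(g), function(lv) {
    x <- values[g == lv]
    if (length(x) < 4) stop("need n >= 4 per group")
    if (stats::sd(x) == 0) {
      return(data.frame(group = lv, n = length(x), statistic = NA_real_,
                        p = NA_real_, degenerate = TRUE,
                        note = "constant values", stringsAsFactors = FALSE))
    }
    ks <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    data.frame(group = lv, n = length(x), statistic = unname(ks$statistic),
               p = ks$p.value, degenerate = FALSE,
               note = "normal parameters estimated from the sample",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg by default; `"bonferroni"` and `"none"` available.
#'
#' @param p vector of p-values in (0, 1].
#' @param method `"BH"`, `"bonferroni"` or `"none"`.
#' @return adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  if (method == "none") return(p)
  stats::p.adjust(p, method = method)
}
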