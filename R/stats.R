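# Group-comparison battery: skewness screen, Levene's test, one-way ANOVA
# with the Brown-Forsythe extension, Scheffe and Tamhane T2 post-hocs, and
# Kruskal-Wallis with Dunn's post-hoc.

validate_groups <- function(groups, min_n = 2L) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (any(vapply(groups, length, integer(1)) < min_n)) {
    stop("every group needs at least ", min_n, " values", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  groups
}

groups_long <- function(groups) {
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups),
                                vapply(groups, length, integer(1)))))
}

#' Sample skewness (adjusted Fisher--Pearson coefficient)
#'
#' `G1 = g1 * sqrt(n (n - 1)) / (n - 2)` with
#' `g1 = m3 / m2^(3/2)`, the convention SPSS reports.
#'
#' @param values Numeric sample of at least 3 values.
#' @return Dimensionless skewness coefficient.
#' @export
#' @examples
#' skewness(c(-1, 0, 1))  # 0 by symmetry
skewness <- function(values) {
  values <- as.numeric(values[!is.na(values)])
  n <- length(values)
  if (n < 3) stop("skewness needs at least 3 values", call. = FALSE)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  if (m2 == 0) stop("skewness undefined for a constant sample",
                    call. = FALSE)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on the absolute deviations of each value from its group
#' centre (mean by default; median gives the Brown--Forsythe variant of the
#' variance test).
#'
#' @param groups List of numeric vectors.
#' @param center `"mean"` or `"median"`.
#' @return List with `W` (the F statistic on deviations), `df1`, `df2`, `p`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- validate_groups(groups)
  cfun <- if (center == "mean") mean else stats::median
  dev <- lapply(groups, function(g) abs(g - cfun(g)))
  if (all(vapply(dev, stats::var, numeric(1)) == 0)) {
    stop("degenerate input: no variation in absolute deviations",
         call. = FALSE)
  }
  long <- groups_long(dev)
  ft <- stats::oneway.test(value ~ group, long, var.equal = TRUE)
  list(W = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = ft$p.value, center = center)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects ANOVA (pooled variance).
#'
#' @param groups List of numeric vectors.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  groups <- validate_groups(groups)
  if (all(vapply(groups, stats::var, numeric(1)) == 0)) {
    stop("degenerate input: zero within-group variance everywhere",
         call. = FALSE)
  }
  long <- groups_long(groups)
  ft <- stats::oneway.test(value ~ group, long, var.equal = TRUE)
  list(F = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = ft$p.value)
}

#' Brown--Forsythe test for equality of means
#'
#' Robust-to-heteroscedasticity one-way F:
#' `F* = sum n_i (xbar_i - xbar)^2 / sum (1 - n_i/N) s_i^2`
#' with numerator df `k - 1` and Satterthwaite denominator df.
#'
#' @param groups List of numeric vectors.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
brown_forsythe <- function(groups) {
  groups <- validate_groups(groups)
  n <- vapply(groups, length, integer(1))
  s2 <- vapply(groups, stats::var, numeric(1))
  if (all(s2 == 0)) {
    stop("degenerate input: zero within-group variance everywhere",
         call. = FALSE)
  }
  N <- sum(n)
  k <- length(groups)
  xb <- vapply(groups, mean, numeric(1))
  grand <- sum(n * xb) / N
  num <- sum(n * (xb - grand)^2)
  w <- (1 - n / N) * s2
  den <- sum(w)
  Fstar <- num / den
  c_i <- w / den
  df2 <- 1 / sum(c_i^2 / (n - 1))
  list(F = Fstar, df1 = k - 1, df2 = df2,
       p = stats::pf(Fstar, k - 1, df2, lower.tail = FALSE))
}

all_pairs <- function(labels) {
  k <- length(labels)
  pairs <- utils::combn(k, 2)
  data.frame(group1 = labels[pairs[1, ]], group2 = labels[pairs[2, ]])
}

#' Scheffe post-hoc pairwise comparisons
#'
#' For each pair, `F_s = t_pair^2 / (k - 1)` with the pooled-variance t, and
#' `p = P(F_{k-1, N-k} >= F_s)`; simultaneous over all contrasts. For two
#' groups this reduces exactly to the ANOVA p-value.
#'
#' @param groups List of numeric vectors.
#' @return Data frame with `group1`, `group2`, `statistic`, `p_adjusted`,
#'   `method`.
#' @export
scheffe_posthoc <- function(groups) {
  groups <- validate_groups(groups)
  n <- vapply(groups, length, integer(1))
  xb <- vapply(groups, mean, numeric(1))
  k <- length(groups)
  N <- sum(n)
  mse <- sum((n - 1) * vapply(groups, stats::var, numeric(1))) / (N - k)
  if (mse == 0) stop("degenerate input: zero pooled variance", call. = FALSE)
  out <- all_pairs(names(groups))
  stat <- p <- numeric(nrow(out))
  for (r in seq_len(nrow(out))) {
    i <- out$group1[r]
    j <- out$group2[r]
    t2 <- (xb[i] - xb[j])^2 / (mse * (1 / n[i] + 1 / n[j]))
    stat[r] <- t2 / (k - 1)
    p[r] <- stats::pf(stat[r], k - 1, N - k, lower.tail = FALSE)
  }
  out$statistic <- stat
  out$p_adjusted <- p
  out$method <- "scheffe"
  out
}

#' Tamhane T2 post-hoc pairwise comparisons
#'
#' Welch t-test per pair (unpooled variances, Satterthwaite df), with a
#' Sidak correction over all `k (k - 1) / 2` comparisons:
#' `p_adj = 1 - (1 - p)^m`.
#'
#' @param groups List of numeric vectors.
#' @return Data frame with `group1`, `group2`, `statistic`, `df`,
#'   `p_unadjusted`, `p_adjusted`, `method`.
#' @export
tamhane_t2_posthoc <- function(groups) {
  groups <- validate_groups(groups)
  n <- vapply(groups, length, integer(1))
  xb <- vapply(groups, mean, numeric(1))
  s2 <- vapply(groups, stats::var, numeric(1))
  out <- all_pairs(names(groups))
  m <- nrow(out)
  stat <- df <- pu <- numeric(m)
  for (r in seq_len(m)) {
    i <- out$group1[r]
    j <- out$group2[r]
    se2 <- s2[i] / n[i] + s2[j] / n[j]
    if (se2 == 0) stop("degenerate input: zero variance in a pair",
                       call. = FALSE)
    stat[r] <- (xb[i] - xb[j]) / sqrt(se2)
    df[r] <- se2^2 / ((s2[i] / n[i])^2 / (n[i] - 1) +
                        (s2[j] / n[j])^2 / (n[j] - 1))
    pu[r] <- 2 * stats::pt(abs(stat[r]), df[r], lower.tail = FALSE)
  }
  out$statistic <- stat
  out$df <- df
  out$p_unadjusted <- pu
  out$p_adjusted <- pmin(1, 1 - (1 - pu)^m)
  out$method <- "tamhane_t2"
  out
}

#' Kruskal--Wallis rank test
#'
#' Mid-rank H statistic with tie correction (delegates to
#' [stats::kruskal.test()]).
#'
#' @param groups List of numeric vectors.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- validate_groups(groups)
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1) {
    stop("degenerate input: all values identical", call. = FALSE)
  }
  long <- groups_long(groups)
  kt <- stats::kruskal.test(value ~ group, long)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Dunn's post-hoc rank comparisons
#'
#' Pairwise z from the difference of mean mid-ranks with tie-corrected
#' variance
#' `z = (Rbar_i - Rbar_j) / sqrt((N (N + 1) / 12 - T) (1/n_i + 1/n_j))`,
#' `T = sum(t^3 - t) / (12 (N - 1))`, followed by a multiplicity
#' adjustment (Bonferroni by default).
#'
#' @param groups List of numeric vectors.
#' @param adjust Adjustment method, any [stats::p.adjust()] method.
#' @return Data frame with `group1`, `group2`, `z`, `p_unadjusted`,
#'   `p_adjusted`, `method`.
#' @export
dunn_posthoc <- function(groups, adjust = "bonferroni") {
  groups <- validate_groups(groups)
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1) {
    stop("degenerate input: all values identical", call. = FALSE)
  }
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  rk <- rank(vals)
  grp <- rep(names(groups), n)
  rbar <- tapply(rk, grp, mean)
  ties <- table(vals)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  out <- all_pairs(names(groups))
  z <- numeric(nrow(out))
  for (r in seq_len(nrow(out))) {
    i <- out$group1[r]
    j <- out$group2[r]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / n[i] + 1 / n[j]))
    z[r] <- (rbar[i] - rbar[j]) / se
  }
  out$z <- z
  out$p_unadjusted <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  out$p_adjusted <- stats::p.adjust(out$p_unadjusted, adjust)
  out$method <- paste0("dunn_", adjust)
  out
}

#' Group-comparison battery for one response parameter
#'
#' Mirrors the study's decision tree. Each group's skewness is screened
#' against `|G1| < skew_limit`; parameters passing the screen go down the
#' ANOVA branch (Levene's test, one-way ANOVA, plus the Brown--Forsythe
#' extension when Levene rejects), the rest down the Kruskal--Wallis branch
#' with Dunn's post-hoc. Post-hoc choice on the ANOVA branch: conventionally
#' Scheffe under homogeneous variances and Tamhane T2 otherwise;
#' `posthoc_assignment = "as_published"` swaps the two.
#'
#' @param groups List (or named list) of numeric vectors, one per
#'   temperature treatment.
#' @param alpha Significance level (default 0.05).
#' @param skew_limit Absolute skewness limit for the normal-theory branch.
#' @param posthoc_assignment `"conventional"` or `"as_published"`.
#' @param dunn_adjust Adjustment method for Dunn's test.
#' @return An object of class `stats_report`: list with `branch`
#'   (`"anova"` or `"kruskal_wallis"`), `assumptions` (per-group skewness,
#'   Levene), `omnibus` (test name, statistic, df, p), `brown_forsythe`
#'   (when computed), `pairwise` (data frame of adjusted p-values),
#'   `alpha`, `significant`.
#' @export
group_stats <- function(groups, alpha = 0.05, skew_limit = 2,
                        posthoc_assignment = c("conventional",
                                               "as_published"),
                        dunn_adjust = "bonferroni") {
  posthoc_assignment <- match.arg(posthoc_assignment)
  groups <- validate_groups(groups)
  skew <- vapply(groups, function(g) {
    if (length(g) >= 3 && stats::var(g) > 0) skewness(g) else 0
  }, numeric(1))
  normal_ok <- all(abs(skew) < skew_limit)

  if (normal_ok) {
    lev <- levene_test(groups)
    om <- one_way_anova(groups)
    bf <- NULL
    homogeneous <- lev$p >= alpha
    if (!homogeneous) bf <- brown_forsythe(groups)
    use_scheffe <- if (posthoc_assignment == "conventional") {
      homogeneous
    } else {
      # published assignment: Tamhane under even variances, Scheffe under
      # uneven
      !homogeneous
    }
    pairwise <- if (use_scheffe) {
      scheffe_posthoc(groups)
    } else {
      tamhane_t2_posthoc(groups)
    }
    omnibus <- list(test = "one_way_anova", statistic = om$F,
                    df1 = om$df1, df2 = om$df2, p = om$p)
    report <- list(branch = "anova",
                   assumptions = list(skewness = skew, levene = lev),
                   omnibus = omnibus, brown_forsythe = bf,
                   pairwise = pairwise)
  } else {
    kw <- kruskal_wallis(groups)
    report <- list(branch = "kruskal_wallis",
                   assumptions = list(skewness = skew, levene = NULL),
                   omnibus = list(test = "kruskal_wallis",
                                  statistic = kw$H, df1 = kw$df,
                                  df2 = NA_real_, p = kw$p),
                   brown_forsythe = NULL,
                   pairwise = dunn_posthoc(groups, dunn_adjust))
  }
  report$alpha <- alpha
  report$significant <- report$omnibus$p < alpha
  class(report) <- "stats_report"
  report
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Group comparison (", x$branch, " branch)\n", sep = "")
  cat("  omnibus", x$omnibus$test, ": statistic =",
      signif(x$omnibus$statistic, 4), ", p =", signif(x$omnibus$p, 4),
      if (x$significant) "(significant)" else "", "\n")
  cat("  pairwise (", x$pairwise$method[1], "):\n", sep = "")
  for (r in seq_len(nrow(x$pairwise))) {
    cat("   ", x$pairwise$group1[r], "vs", x$pairwise$group2[r], ": p =",
        signif(x$pairwise$p_adjusted[r], 4), "\n")
  }
  invisible(x)
}
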