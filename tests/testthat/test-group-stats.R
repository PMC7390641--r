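test_that("skewness follows the adjusted Fisher-Pearson convention", {
  expect_equal(skewness(c(-1, 0, 1)), 0)
  # direct-formula oracle for an asymmetric sample
  x <- c(1, 2, 3, 4, 100)
  n <- length(x)
  g1 <- mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5
  expect_equal(skewness(x), g1 * sqrt(n * (n - 1)) / (n - 2))
  expect_equal(skewness(x), 2.232395911636, tolerance = 1e-10)
  # mirrored sample flips the sign
  expect_equal(skewness(-x), -skewness(x))
  expect_error(skewness(c(1, 2)), "at least 3")
  if (requireNamespace("e1071", quietly = TRUE)) {
    expect_equal(skewness(x), e1071::skewness(x, type = 2))
  }
})

test_that("Levene's test is location invariant and matches car", {
  set.seed(2)
  g <- list(a = rnorm(8), b = rnorm(8, sd = 3), c = rnorm(8, sd = 0.5))
  lv <- levene_test(g)
  shifted <- lapply(seq_along(g), function(i) g[[i]] + i * 10)
  expect_equal(levene_test(shifted)$W, lv$W)
  expect_true(lv$p >= 0 && lv$p <= 1)
  if (requireNamespace("car", quietly = TRUE)) {
    long <- data.frame(y = unlist(g),
                       grp = factor(rep(names(g), lengths(g))))
    ref <- car::leveneTest(y ~ grp, long, center = mean)
    expect_equal(lv$W, ref[1, "F value"], tolerance = 1e-10)
    expect_equal(lv$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("two-group ANOVA equals the squared pooled t test", {
  set.seed(4)
  g <- list(a = rnorm(10), b = rnorm(12, 1))
  an <- one_way_anova(g)
  tt <- t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(an$F, unname(tt$statistic)^2)
  expect_equal(an$p, tt$p.value)
  expect_error(one_way_anova(list(a = rep(1, 5), b = rep(2, 5))),
               "degenerate")
})

test_that("Brown-Forsythe reduces to Welch for two groups", {
  set.seed(6)
  g <- list(a = rnorm(10, sd = 1), b = rnorm(15, 1, sd = 4))
  bf <- brown_forsythe(g)
  w <- oneway.test(y ~ grp,
                   data.frame(y = unlist(g),
                              grp = factor(rep(c("a", "b"), c(10, 15)))),
                   var.equal = FALSE)
  expect_equal(bf$F, unname(w$statistic))
  expect_equal(bf$df2, unname(w$parameter[2]))
  expect_equal(bf$p, w$p.value)
})

test_that("ANOVA p agrees with a permutation oracle", {
  set.seed(10)
  g <- list(a = rnorm(5), b = rnorm(5, 1.2), c = rnorm(5, 0.5))
  an <- one_way_anova(g)
  kw <- kruskal_wallis(g)
  vals <- unlist(g)
  lab <- rep(1:3, each = 5)
  fstat <- function(y) {
    gl <- split(y, lab)
    one_way_anova(gl)$F
  }
  hstat <- function(y) kruskal_wallis(split(y, lab))$H
  nperm <- 4000
  fs <- hs <- numeric(nperm)
  for (i in seq_len(nperm)) {
    y <- sample(vals)
    fs[i] <- fstat(y)
    hs[i] <- hstat(y)
  }
  mc_tol <- 4 * sqrt(0.5 * 0.5 / nperm) + 0.01
  expect_lt(abs(mean(fs >= an$F - 1e-12) - an$p), mc_tol)
  expect_lt(abs(mean(hs >= kw$H - 1e-12) - kw$p), mc_tol + 0.02)
})

test_that("Scheffe reduces to the ANOVA p for two groups", {
  set.seed(12)
  g <- list(a = rnorm(9), b = rnorm(11, 0.8))
  sc <- scheffe_posthoc(g)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$p_adjusted, one_way_anova(g)$p)
  # equal group means: all pairwise p = 1
  eq <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(2, 1, 3))
  expect_true(all(scheffe_posthoc(eq)$p_adjusted == 1))
})

test_that("Tamhane T2 matches the frozen Welch-Sidak oracle", {
  g <- list(`1` = c(1.1, 2.3, 1.9, 2.8, 1.4),
            `2` = c(3.1, 2.9, 4.0, 3.5, 3.3),
            `3` = c(5.0, 4.2, 6.1, 5.5, 4.8))
  tt <- tamhane_t2_posthoc(g)
  # per-pair Welch t and Sidak-adjusted p, computed independently
  expect_equal(tt$statistic, c(-4.0712931217, -7.2658282867, -4.7206876709),
               tolerance = 1e-9)
  expect_equal(tt$p_adjusted,
               c(0.015665735149, 0.000263807604, 0.007994339325),
               tolerance = 1e-9)
  expect_true(all(tt$p_adjusted >= tt$p_unadjusted))
  # the same fixture's omnibus tests, against independent references
  expect_equal(one_way_anova(g)$F, 33.61551724137934, tolerance = 1e-10)
  expect_equal(kruskal_wallis(g)$H, 12.5, tolerance = 1e-10)
})

test_that("Kruskal-Wallis attains the enumeration maximum at separation", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  kw <- kruskal_wallis(g)
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2)
  # exhaustive enumeration oracle: H over every assignment of ranks 1..9
  # into three groups of three never exceeds the separated arrangement
  hmax <- 0
  combs1 <- utils::combn(9, 3)
  for (i in seq_len(ncol(combs1))) {
    g1 <- combs1[, i]
    rest <- setdiff(1:9, g1)
    combs2 <- utils::combn(rest, 3)
    for (j in seq_len(ncol(combs2))) {
      g2 <- combs2[, j]
      g3 <- setdiff(rest, g2)
      h <- kruskal_wallis(list(a = g1, b = g2, c = g3))$H
      hmax <- max(hmax, h)
    }
  }
  expect_equal(hmax, 7.2)
})

test_that("tie-corrected H stays consistent under duplication", {
  g <- list(a = c(1, 2, 3, 4), b = c(2, 4, 5, 7), c = c(6, 7, 8, 9))
  dup <- lapply(g, rep, each = 2)
  kw <- kruskal_wallis(dup)
  # permutation oracle on the duplicated (tied) data
  set.seed(14)
  vals <- unlist(dup)
  lab <- rep(1:3, each = 8)
  hs <- replicate(3000, kruskal_wallis(split(sample(vals), lab))$H)
  expect_lt(abs(mean(hs >= kw$H - 1e-12) - kw$p), 0.04)
})

test_that("two-group H equals the squared standardised rank statistic", {
  set.seed(16)
  g <- list(a = rnorm(12), b = rnorm(15, 0.6))
  kw <- kruskal_wallis(g)
  n1 <- 12; n2 <- 15; N <- n1 + n2
  rk <- rank(unlist(g))
  U <- sum(rk[1:n1]) - n1 * (n1 + 1) / 2
  z <- (U - n1 * n2 / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(kw$H, z^2)
  # Dunn z for the pair reproduces the same standardised difference
  dn <- dunn_posthoc(g)
  expect_equal(dn$z^2, kw$H)
  expect_true(all(dn$p_adjusted >= dn$p_unadjusted))
})

test_that("rank tests are invariant under monotone transforms and relabeling", {
  set.seed(18)
  g <- list(a = rlnorm(7), b = rlnorm(7, 0.5), c = rlnorm(7, 1))
  kw <- kruskal_wallis(g)
  expect_equal(kruskal_wallis(lapply(g, log))$H, kw$H)
  perm <- g[c(3, 1, 2)]
  expect_equal(kruskal_wallis(perm)$H, kw$H)
  expect_equal(one_way_anova(perm)$p, one_way_anova(g)$p)
  expect_equal(sort(dunn_posthoc(perm)$p_adjusted),
               sort(dunn_posthoc(g)$p_adjusted))
})

test_that("the battery routes parameters by the skewness screen", {
  set.seed(20)
  normal <- list(`18` = rnorm(15, 10), `23` = rnorm(15, 9),
                 `28` = rnorm(15, 8))
  rep1 <- group_stats(normal)
  expect_equal(rep1$branch, "anova")
  expect_equal(rep1$omnibus$test, "one_way_anova")
  expect_equal(nrow(rep1$pairwise), 3)
  expect_true(all(abs(rep1$assumptions$skewness) < 2))
  # heavily skewed groups go down the rank branch
  skewed <- lapply(list(0, 0.5, 1), function(m) {
    c(rlnorm(20, m, 0.4), 60 + m)
  })
  names(skewed) <- c("18", "23", "28")
  rep2 <- group_stats(skewed)
  expect_equal(rep2$branch, "kruskal_wallis")
  expect_match(rep2$pairwise$method[1], "dunn")
})

test_that("post-hoc assignment switches between conventions", {
  set.seed(22)
  uneven <- list(a = rnorm(12, 0, 0.2), b = rnorm(12, 1, 3),
                 c = rnorm(12, 2, 3))
  lev <- levene_test(uneven)
  expect_lt(lev$p, 0.05)  # variances genuinely uneven
  conv <- group_stats(uneven, posthoc_assignment = "conventional")
  pub <- group_stats(uneven, posthoc_assignment = "as_published")
  expect_equal(conv$pairwise$method[1], "tamhane_t2")
  expect_equal(pub$pairwise$method[1], "scheffe")
  expect_false(is.null(conv$brown_forsythe))
  even <- list(a = rnorm(12, 0), b = rnorm(12, 1), c = rnorm(12, 2))
  conv2 <- group_stats(even)
  expect_equal(conv2$pairwise$method[1], "scheffe")
  expect_null(conv2$brown_forsythe)
})

test_that("group validation rejects malformed inputs", {
  expect_error(group_stats(list(a = 1:5)), "2 groups")
  expect_error(one_way_anova(list(a = 1:5, b = 2)), "at least 2")
  expect_error(kruskal_wallis(list(a = c(1, 1), b = c(1, 1))),
               "degenerate")
})
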