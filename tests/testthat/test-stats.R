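test_that("pooled t-test reproduces published summary-statistics examples", {
  r <- ttest_ind(39.03, 12.14, 40, 39.83, 11.79, 40)
  expect_equal(round(r$t, 2), -0.30)
  expect_equal(round(r$ci95, 2), c(-6.13, 4.53))
  expect_equal(r$df, 78)
  r2 <- ttest_ind(58.30, 5.75, 40, 58.10, 5.278, 40)
  expect_equal(round(r2$t, 2), 0.16)
  expect_equal(round(r2$ci95, 2), c(-2.26, 2.66))
})

test_that("t-test from summaries equals t.test on matching raw data", {
  set.seed(13)
  x <- rnorm(15, 2, 1)
  y <- rnorm(20, 1, 2)
  mine <- ttest_ind(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$ci95, unname(ref$conf.int), tolerance = 1e-12,
               ignore_attr = TRUE)
  same <- ttest_ind(5, 1, 10, 5, 1, 10)
  expect_equal(same$t, 0)
  expect_equal(same$ci95[1], -same$ci95[2])
  expect_error(ttest_ind(1, 0, 10, 2, 1, 10), "positive")
  expect_error(ttest_ind(1, 1, 1, 2, 1, 10), "two observations")
})

test_that("bonferroni adjustment is capped, monotone, order-preserving", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 3), 1)
  set.seed(14)
  p <- runif(50)
  adj <- bonferroni(p, 50)
  expect_true(all(adj >= p))
  expect_equal(order(adj[adj < 1]), order(p[adj < 1]))
  expect_equal(adj, p.adjust(p, "bonferroni"), tolerance = 1e-12)
})

test_that("split-plot F statistics equal the aov projection oracle", {
  set.seed(15)
  for (rep in 1:3) {
    d <- expand.grid(participant = paste0("s", 1:10),
                     A = paste0("a", 1:3), B = paste0("b", 1:2),
                     stringsAsFactors = FALSE)
    d$group <- ifelse(d$participant %in% paste0("s", 1:5), "g1", "g2")
    d$value <- rnorm(nrow(d)) + 0.4 * (d$A == "a2") +
      0.3 * (d$group == "g1") * (d$B == "b2")
    fit <- mixed_rmanova(d, "value", "participant", "group", c("A", "B"))
    oracle <- aov_oracle(d, "value", "participant", "group", c("A", "B"))
    for (eff in names(oracle)) {
      row <- fit$table[fit$table$effect == eff, ]
      expect_equal(row$F, oracle[[eff]]$F, tolerance = 1e-9, label = eff)
      expect_equal(row$ss, oracle[[eff]]$ss, tolerance = 1e-9, label = eff)
      expect_equal(row$df, oracle[[eff]]$df, label = eff)
    }
  }
})

test_that("one-within-factor and unequal-n designs match the oracle", {
  set.seed(16)
  d <- expand.grid(participant = paste0("s", 1:11), W = paste0("w", 1:4),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$participant %in% paste0("s", 1:5), "g1", "g2")
  d$value <- rnorm(nrow(d)) + 0.5 * (d$W == "w1")
  fit <- mixed_rmanova(d, "value", "participant", "group", "W")
  oracle <- aov_oracle(d, "value", "participant", "group", "W")
  for (eff in names(oracle)) {
    expect_equal(fit$table$F[fit$table$effect == eff], oracle[[eff]]$F,
                 tolerance = 1e-9, label = eff)
  }
})

test_that("Greenhouse-Geisser epsilon matches the car oracle", {
  skip_if_not_installed("car")
  set.seed(17)
  n <- 12
  # correlated within-cells to force epsilon < 1
  base <- rnorm(n)
  Y <- cbind(w1 = base + rnorm(n, sd = 0.3),
             w2 = base + rnorm(n, sd = 0.8),
             w3 = 0.5 * base + rnorm(n, sd = 1.5),
             w4 = rnorm(n, sd = 2))
  group <- rep(c("g1", "g2"), each = n / 2)
  d <- data.frame(participant = rep(paste0("s", 1:n), 4),
                  W = rep(colnames(Y), each = n),
                  group = rep(group, 4), value = as.vector(Y))
  fit <- mixed_rmanova(d, "value", "participant", "group", "W")
  mlm <- lm(Y ~ group)
  idata <- data.frame(W = factor(colnames(Y)))
  ca <- car::Anova(mlm, idata = idata, idesign = ~W, type = 3)
  cs <- summary(ca, multivariate = FALSE)
  eps_car <- cs$pval.adjustments["W", "GG eps"]
  eps_mine <- fit$table$epsilon[fit$table$effect == "W"]
  expect_equal(eps_mine, unname(eps_car), tolerance = 1e-9)
  expect_lt(eps_mine, 1)
  # corrected p value uses the fractional dfs
  row <- fit$table[fit$table$effect == "W", ]
  expect_equal(row$p, pf(row$F, row$df_gg, row$df_error_gg,
                         lower.tail = FALSE), tolerance = 1e-12)
})

test_that("two-level within factors have epsilon exactly 1", {
  set.seed(18)
  d <- expand.grid(participant = paste0("s", 1:8), W = c("w1", "w2"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$participant %in% paste0("s", 1:4), "g1", "g2")
  d$value <- rnorm(nrow(d))
  fit <- mixed_rmanova(d, "value", "participant", "group", "W")
  expect_identical(fit$table$epsilon[fit$table$effect == "W"], 1)
  expect_equal(fit$table$p[fit$table$effect == "W"],
               fit$table$p_uncorrected[fit$table$effect == "W"])
})

test_that("partial eta squared is affine-invariant and bounded", {
  set.seed(19)
  d <- expand.grid(participant = paste0("s", 1:8), W = paste0("w", 1:3),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$participant %in% paste0("s", 1:4), "g1", "g2")
  d$value <- rnorm(nrow(d)) + (d$W == "w1")
  f1 <- mixed_rmanova(d, "value", "participant", "group", "W")
  d$value2 <- 3.7 * d$value - 11
  f2 <- mixed_rmanova(d, "value2", "participant", "group", "W")
  expect_equal(f1$table$pes, f2$table$pes, tolerance = 1e-9)
  expect_true(all(f1$table$pes >= 0 & f1$table$pes <= 1))
  expect_true(all(f1$table$F >= 0))
})

test_that("unbalanced or duplicated observations raise explicit errors", {
  d <- expand.grid(participant = paste0("s", 1:4), W = c("w1", "w2"),
                   stringsAsFactors = FALSE)
  d$group <- "g1"
  d$value <- rnorm(nrow(d))
  expect_error(mixed_rmanova(d[-1, ], "value", "participant", NULL, "W"),
               "unbalanced")
  expect_error(mixed_rmanova(rbind(d, d[1, ]), "value", "participant",
                             NULL, "W"), "unbalanced")
  d$group[1] <- "g2" # one participant in two groups
  expect_error(mixed_rmanova(d, "value", "participant", "group", "W"),
               "single group")
  expect_error(mixed_rmanova(d, "value", "participant", "missing", "W"),
               "not found")
})

test_that("permuted group labels keep the between-group test at its level", {
  set.seed(20)
  n <- 16
  d0 <- expand.grid(participant = paste0("s", 1:n), W = paste0("w", 1:3),
                    stringsAsFactors = FALSE)
  d0$value <- rnorm(nrow(d0)) + rep(rnorm(n), 3) # subject intercepts, no group effect
  hits <- 0
  n_perm <- 400
  for (i in seq_len(n_perm)) {
    g <- sample(rep(c("g1", "g2"), each = n / 2))
    d0$group <- g[match(d0$participant, paste0("s", 1:n))]
    fit <- mixed_rmanova(d0, "value", "participant", "group", "W")
    hits <- hits + (fit$table$p[fit$table$effect == "group"] < 0.05)
  }
  expect_lt(abs(hits / n_perm - 0.05), 0.03)
})

test_that("GG-corrected within test holds its level under nonsphericity", {
  set.seed(23)
  n <- 20
  reps <- 600
  hits <- 0
  # strongly nonspherical null: heterogeneous variances, shared intercept
  for (i in seq_len(reps)) {
    base <- rnorm(n)
    Y <- cbind(base + rnorm(n, sd = 0.2), base + rnorm(n, sd = 0.2),
               base + rnorm(n, sd = 2.5))
    d <- data.frame(participant = rep(seq_len(n), 3),
                    W = rep(c("w1", "w2", "w3"), each = n),
                    group = rep(rep(c("g1", "g2"), each = n / 2), 3),
                    value = as.vector(Y))
    fit <- mixed_rmanova(d, "value", "participant", "group", "W")
    hits <- hits + (fit$table$p[fit$table$effect == "W"] < 0.05)
  }
  expect_lt(abs(hits / reps - 0.05), 0.02)
})

test_that("pairwise post hocs agree with base t-tests and are adjusted", {
  set.seed(24)
  d <- expand.grid(participant = paste0("s", 1:10), W = paste0("w", 1:3),
                   stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d)) + (d$W == "w3")
  ph <- posthoc_pairwise(d, "value", "participant", "W", paired = TRUE)
  expect_equal(nrow(ph), 3)
  x <- d$value[d$W == "w1"][order(d$participant[d$W == "w1"])]
  y <- d$value[d$W == "w2"][order(d$participant[d$W == "w2"])]
  ref <- t.test(x, y, paired = TRUE)
  row <- ph[ph$level1 == "w1" & ph$level2 == "w2", ]
  expect_equal(row$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(row$p_adj, bonferroni(row$p_raw, 3))
})
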