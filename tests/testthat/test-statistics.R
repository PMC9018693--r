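test_that("ANOVA matches the textbook formula on random inputs", {
  for (sd in 1:100) {
    withr::with_seed(sd, {
      g <- rep(c("P1", "P15", "P60"), each = sample(3:6, 1))
      v <- rnorm(length(g), mean = as.integer(factor(g)), sd = 1)
    })
    res <- anova_oneway(v, g)
    orc <- oracle_anova_f(v, g)
    expect_equal(res$statistic, orc$f, tolerance = 1e-10)
    expect_equal(res$p_value, orc$p, tolerance = 1e-10)
  }
})

test_that("ANOVA edge cases: equal means give F = 0; zero within-variance is flagged", {
  v <- c(-1, 1, -2, 2)
  g <- c("a", "a", "b", "b")
  expect_equal(anova_oneway(v, g)$statistic, 0)
  res <- anova_oneway(c(0, 0, 1, 1), g)
  expect_match(res$note, "zero within-group variance")
  expect_lt(res$p_value, 1e-10)
})

test_that("pairwise t tests enumerate pairs and match hand computation", {
  withr::with_seed(5, {
    v <- rnorm(9, rep(c(0, 1, 3), each = 3))
  })
  g <- rep(c("P1", "P15", "P60"), each = 3)
  out <- pairwise_t_tests(v, g)
  expect_equal(nrow(out), 3)
  expect_identical(paste(out$group1, out$group2),
                   c("P1 P15", "P1 P60", "P15 P60"))
  for (i in 1:3) {
    orc <- oracle_welch_t(v[g == out$group1[i]], v[g == out$group2[i]])
    expect_equal(out$t[i], orc$t, tolerance = 1e-10)
    expect_equal(out$p_value[i], orc$p, tolerance = 1e-10)
  }
  # identical groups: t = 0, p = 1
  same <- pairwise_t_tests(c(1, 2, 3, 1, 2, 3), rep(c("x", "y"), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # holm correction is monotone non-decreasing on the raw p-values
  outh <- pairwise_t_tests(v, g, correction = "holm")
  expect_true(all(outh$p_adjusted >= outh$p_value - 1e-15))
})

test_that("two-group pooled ANOVA satisfies F = t^2", {
  for (sd in 1:20) {
    withr::with_seed(100 + sd, {
      v <- rnorm(12, rep(c(0, 0.8), each = 6))
    })
    g <- rep(c("a", "b"), each = 6)
    f <- anova_oneway(v, g)$statistic
    t <- pairwise_t_tests(v, g, var_equal = TRUE)$t
    expect_equal(f, t^2, tolerance = 1e-10)
    expect_equal(anova_oneway(v, g)$p_value,
                 pairwise_t_tests(v, g, var_equal = TRUE)$p_value,
                 tolerance = 1e-10)
  }
})

test_that("Pearson correlation matches the closed form and handles degeneracy", {
  x <- c(1, 2, 3, 5, 8)
  res <- methylation_expression_correlation(x, -x)
  expect_equal(res$estimate, -1)
  for (sd in 1:100) {
    withr::with_seed(200 + sd, { x <- rnorm(9); y <- rnorm(9) })
    res <- methylation_expression_correlation(x, y)
    orc <- oracle_pearson(x, y)
    expect_equal(res$estimate, orc$r, tolerance = 1e-10)
    expect_equal(res$p_value, orc$p, tolerance = 1e-10)
  }
  cst <- methylation_expression_correlation(c(1, 2, 3), c(4, 4, 4))
  expect_true(is.na(cst$estimate))
  expect_match(cst$note, "constant")
})

test_that("negative coupling is recovered through the expression layer", {
  hits <- 0L
  for (sd in 1:200) {
    meth <- withr::with_seed(1000 + sd, runif(9, 0.05, 0.5))
    names(meth) <- paste0("s", 1:9)
    expr <- delta_ct_table(
      simulate_expression(meth, coupling = -1.5, noise_sd = 0.05,
                          seed = 2000 + sd))
    r <- methylation_expression_correlation(
      meth, expr$rel_expr[match(names(meth), expr$sample_id)])$estimate
    if (r < -0.7) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("class heatmap shows the silencing signature on constructed data", {
  # expression strictly decreasing in mean methylation, monotone classes
  k <- 3L
  n <- 6L
  meth <- seq(0.1, 0.6, length.out = n)
  cls <- cbind(`0` = 1 - meth, `1` = meth * 0.4, `2` = meth * 0.3,
               `3` = meth * 0.3)
  rownames(cls) <- paste0("s", 1:n)
  expr <- 2 - meth
  hm <- class_expression_heatmap(cls, expr, tissue = rep("brain", n))
  expect_gt(hm$r["0", "brain"], 0)
  expect_true(all(hm$r[c("1", "2", "3"), "brain"] < 0))
  expect_true(all(hm$r >= -1 & hm$r <= 1, na.rm = TRUE))
  # fewer than 3 samples per tissue is an error
  expect_error(class_expression_heatmap(cls[1, , drop = FALSE], expr[1],
                                        tissue = "brain"), "n >= 3")
  # r is invariant to positive rescaling of expression
  hm2 <- class_expression_heatmap(cls, expr * 37.5, rep("brain", n))
  expect_equal(hm$r, hm2$r, tolerance = 1e-12)
})

test_that("epiallele heatmap applies the abundance floor and recovers coupling signs", {
  k <- 2L
  n <- 6L
  sil <- seq(0.2, 0.7, length.out = n)          # abundance of the silenced profile
  counts <- cbind(`00` = round(1000 * (1 - sil)), `11` = round(1000 * sil),
                  `01` = rep(1L, n), `10` = rep(0L, n))
  rownames(counts) <- paste0("s", 1:n)
  tbl <- epiallele_table(counts)
  expr <- 3 - 2 * sil  # expression falls as the silenced profile accumulates
  hm <- epiallele_expression_heatmap(tbl, setNames(expr, rownames(counts)),
                                     tissue = rep("heart", n),
                                     min_mean_freq = 0.01)
  expect_lt(hm$r["11", "heart"], 0)
  expect_gt(hm$r["00", "heart"], 0)
  # "01" sits below the 1% floor and is excluded but listed; "10" is absent
  expect_true("01" %in% hm$excluded)
  expect_false("01" %in% hm$rows)
  expect_false("10" %in% hm$rows)
  # frequency proportional to expression gives r = 1
  prop <- cbind(`00` = seq(100L, 600L, 100L), `11` = seq(600L, 100L, -100L))
  rownames(prop) <- paste0("p", 1:6)
  tpl <- epiallele_table(prop)
  ex <- seq(100, 600, 100) / 700
  hmp <- epiallele_expression_heatmap(tpl, setNames(ex, rownames(prop)),
                                      tissue = rep("brain", 6))
  expect_equal(unname(hmp$r["00", "brain"]), 1, tolerance = 1e-10)
})
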