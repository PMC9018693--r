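test_that("count table counts retained reads over the full epiallele space", {
  sp <- tiny_spec(k = 2L)
  calls <- data.frame(sample_id = "s1", epiallele = c("00", "00", "11"),
                      stringsAsFactors = FALSE)
  tbl <- build_count_table(calls, sp)
  expect_equal(ncol(tbl$counts), 4)
  expect_equal(unname(tbl$counts["s1", c("00", "11")]), c(2L, 1L))
  expect_equal(sum(tbl$counts), 3)
  # k = 7 spans 128 columns
  tbl7 <- build_count_table(
    data.frame(sample_id = "s", epiallele = "0000000"), spec7())
  expect_equal(ncol(tbl7$counts), 128)
  # zero-read samples are dropped with a warning
  calls2 <- data.frame(sample_id = c("a", "b"),
                       epiallele = c("00", NA), stringsAsFactors = FALSE)
  expect_warning(tbl2 <- build_count_table(calls2, sp), "zero retained")
  expect_identical(rownames(tbl2$counts), "a")
})

test_that("empirical table frequencies converge to the mixture (binomial oracle)", {
  sp <- spec7()
  probs <- c("0000000" = 0.45, "1111111" = 0.25, "1010101" = 0.2,
             "0000001" = 0.1)
  n <- 1e4
  mols <- sample_molecules(sp, clean_mixture(probs, n, seed = 55))
  tbl <- build_count_table(data.frame(sample_id = "s", epiallele = mols), sp)
  freq <- tbl$counts["s", ] / n
  for (e in names(probs)) {
    se <- sqrt(probs[[e]] * (1 - probs[[e]]) / n)
    expect_lt(abs(freq[[e]] - probs[[e]]), 3 * se)
  }
})

test_that("rarefaction subsamples exactly to depth and preserves frequencies", {
  sp <- tiny_spec(k = 2L)
  one <- epiallele_table(matrix(100L, 1, 1, dimnames = list("s1", "00")))
  r1 <- rarefy(one, depth = 10, seed = 1)
  expect_equal(unname(r1$counts["s1", "00"]), 10L)
  # row sum equal to depth leaves the row unchanged
  fixed <- epiallele_table(matrix(c(7L, 3L), 1, 2,
                                  dimnames = list("s1", c("01", "10"))))
  r2 <- rarefy(fixed, depth = 10, seed = 1)
  expect_identical(r2$counts[, c("01", "10")], fixed$counts[, c("01", "10")])
  # hypergeometric oracle: mean count of "01" over 200 seeds
  big <- epiallele_table(matrix(c(5000L, 5000L), 1, 2,
                                dimnames = list("s1", c("01", "10"))))
  draws <- vapply(1:200, function(sd)
    rarefy(big, depth = 1000, seed = sd)$counts[1, "01"], numeric(1))
  expect_true(all(vapply(1:10, function(sd)
    sum(rarefy(big, depth = 1000, seed = sd)$counts), numeric(1)) == 1000))
  hyper_sd <- sqrt(1000 * 0.5 * 0.5 * (10000 - 1000) / (10000 - 1))
  se_mean <- hyper_sd / sqrt(200)
  expect_lt(abs(mean(draws) - 500), 3 * se_mean)
  # shallow samples are dropped and reported
  two <- epiallele_table(matrix(c(100L, 5L), 2, 1,
                                dimnames = list(c("deep", "shallow"), "00")))
  expect_message(r3 <- rarefy(two, depth = 50, seed = 1), "shallow")
  expect_identical(rownames(r3$counts), "deep")
  expect_error(rarefy(one, depth = 0), "positive")
})

test_that("class distribution aggregates by Hamming weight", {
  sp <- spec7()
  tbl <- build_count_table(
    data.frame(sample_id = "s", epiallele = rep("0000000", 10)), sp)
  cd <- class_distribution(tbl)
  expect_equal(ncol(cd), 8)  # classes 0-Meth .. 7-Meth
  expect_equal(unname(cd["s", "0"]), 1.0)
  # uniform over all 128 epialleles: class c gets choose(7, c) / 128
  uni <- epiallele_table(matrix(1L, 1, 128,
                                dimnames = list("u", all_epialleles(7))))
  cdu <- class_distribution(uni)
  expect_equal(unname(cdu["u", ]), choose(7, 0:7) / 128)
  expect_equal(rowSums(cdu), c(u = 1), tolerance = 1e-9)
})

test_that("mean methylation and per-CpG methylation satisfy the exact identity", {
  sp <- spec7()
  tbl <- build_count_table(
    data.frame(sample_id = "s", epiallele = rep("1111111", 5)), sp)
  expect_equal(unname(mean_methylation(tbl)), 1.0)
  # half "1000000", half "0000000": first CpG 50%, rest 0, mean 1/14
  mixd <- build_count_table(
    data.frame(sample_id = "s",
               epiallele = rep(c("1000000", "0000000"), each = 50)), sp)
  pc <- per_cpg_methylation(mixd, labels = sp$cpg_labels)
  expect_equal(unname(pc["s", "-118"]), 0.5)
  expect_equal(unname(pc["s", "131"]), 0)
  expect_equal(unname(mean_methylation(mixd)), 0.5 / 7)
  # identity holds to 1e-12 on 100 random tables
  for (sd in 1:100) {
    tb <- random_table(n_samples = 4L, k = 5L, depth = 300L, seed = sd)
    expect_equal(mean_methylation(tb),
                 setNames(rowMeans(per_cpg_methylation(tb)),
                          rownames(tb$counts)),
                 tolerance = 1e-12)
  }
})

test_that("mean methylation is invariant under rarefaction in expectation", {
  tb <- random_table(n_samples = 3L, k = 5L, depth = 2000L, seed = 99)
  mm0 <- mean_methylation(tb)
  sims <- vapply(1:200, function(sd)
    mean_methylation(rarefy(tb, depth = 500, seed = sd)), numeric(3))
  se <- apply(sims, 1, sd) / sqrt(200)
  expect_true(all(abs(rowMeans(sims) - mm0) < 3 * se + 1e-9))
})

test_that("Bernoulli mixtures yield binomial class distributions (chi-square GOF)", {
  sp <- spec7()
  p <- 0.3
  n <- 1e5
  mix <- clean_mixture(bernoulli_mixture(p, 7), n, seed = 61)
  mols <- sample_molecules(sp, mix)
  obs <- table(factor(epiallele_class(mols), levels = 0:7))
  gof <- chisq.test(as.integer(obs), p = dbinom(0:7, 7, p))
  expect_gt(gof$p.value, 0.001)
})

test_that("ordination separates structure and returns valid variance fractions", {
  # identical samples: pairwise distance zero, degenerate result flagged as zeros
  same <- epiallele_table(matrix(c(10L, 10L, 10L, 5L, 5L, 5L), 3, 2,
                                 dimnames = list(c("a", "b", "c"),
                                                 c("01", "10"))))
  ord0 <- ordinate(same)
  expect_true(all(ord0$coords == 0))
  expect_true(all(ord0$var_explained == 0))
  # three samples on a compositional line: axis 1 explains everything
  lin <- epiallele_table(matrix(c(0L, 50L, 100L, 100L, 50L, 0L), 3, 2,
                                dimnames = list(c("a", "b", "c"),
                                                c("01", "10"))))
  ordl <- ordinate(lin, metric = "euclidean")
  expect_gt(ordl$var_explained[1], 0.999)
  # variance fractions are non-increasing, within [0, 1], summing to <= 1
  tb <- random_table(n_samples = 8L, k = 4L, depth = 400L, seed = 3)
  for (mth in c("pcoa", "pca")) {
    o <- ordinate(tb, method = mth, n_axes = 4L)
    expect_true(all(diff(o$var_explained) <= 1e-9))
    expect_true(all(o$var_explained >= 0 & o$var_explained <= 1))
    expect_lte(sum(o$var_explained), 1 + 1e-9)
    # sign convention: the largest-magnitude coordinate is positive
    for (j in seq_len(ncol(o$coords)))
      expect_gte(o$coords[which.max(abs(o$coords[, j])), j], 0)
  }
  expect_error(ordinate(same[["counts"]]), "epiallele_table")
  two <- epiallele_table(matrix(c(1L, 2L), 2, 1,
                                dimnames = list(c("a", "b"), "00")))
  expect_error(ordinate(two), "3 samples")
})

test_that("groups with equal mean methylation but disjoint epialleles separate", {
  # Hamming weight 2 on both sides, disjoint support
  ga <- c("1100000", "0011000")
  gb <- c("0000110", "1000001")
  make_group <- function(eps, ids, seed) {
    withr::with_seed(seed, {
      counts <- t(rmultinom(length(ids), 500, prob = rep(0.5, 2)))
      colnames(counts) <- eps
      rownames(counts) <- ids
      counts
    })
  }
  ca <- make_group(ga, paste0("a", 1:5), 7)
  cb <- make_group(gb, paste0("b", 1:5), 8)
  full <- matrix(0L, 10, 128, dimnames = list(c(rownames(ca), rownames(cb)),
                                              all_epialleles(7)))
  full[rownames(ca), ga] <- ca
  full[rownames(cb), gb] <- cb
  tbl <- epiallele_table(full)
  expect_equal(unname(mean_methylation(tbl)), rep(2 / 7, 10))
  ord <- ordinate(tbl)
  xy <- ord$coords[, 1:2]
  cent_a <- colMeans(xy[1:5, ]); cent_b <- colMeans(xy[6:10, ])
  between <- sqrt(sum((cent_a - cent_b)^2))
  within <- max(c(as.matrix(dist(xy[1:5, ])), as.matrix(dist(xy[6:10, ]))))
  expect_gt(between, within)
})

test_that("bray-curtis distances form a metric on random tables", {
  tb <- random_table(n_samples = 6L, k = 3L, depth = 100L, seed = 12)
  d <- as.matrix(vegan::vegdist(tb$counts, "bray"))
  expect_equal(d, t(d), tolerance = 1e-12)
  expect_true(all(diag(d) == 0))
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (l in 1:n)
    expect_lte(d[i, j], d[i, l] + d[l, j] + 1e-12)
})

test_that("count tables round-trip through TSV and BIOM", {
  tb <- random_table(n_samples = 3L, k = 3L, depth = 50L, seed = 5)
  tsv <- tempfile(fileext = ".tsv"); biom <- tempfile(fileext = ".biom")
  write_count_table(tb, tsv, biom)
  back <- utils::read.delim(tsv, check.names = FALSE)
  obs <- tb$counts[, colSums(tb$counts) > 0, drop = FALSE]
  expect_equal(as.matrix(back[, -1]),
               matrix(obs, nrow(obs), dimnames = dimnames(obs)),
               ignore_attr = TRUE)
  b <- biomformat::read_biom(biom)
  bm <- as.matrix(biomformat::biom_data(b))
  expect_equal(unname(t(bm)[rownames(obs), colnames(obs)]), unname(obs))
})
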