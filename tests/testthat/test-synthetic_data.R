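test_that("make_amplicon_spec builds valid geometries and is deterministic", {
  cases <- list(list(k = 7L, len = 388L,
                     labels = c(-118L, -91L, -47L, -3L, 92L, 112L, 131L)),
                list(k = 8L, len = 403L,
                     labels = c(-227L, -180L, -113L, -71L, -51L, 22L, 89L,
                                160L)),
                list(k = 1L, len = 40L, labels = 0L))
  for (cs in cases) {
    sp <- make_amplicon_spec(cs$k, cs$len, cs$labels, seed = cs$k)
    chars <- strsplit(sp$reference_seq, "")[[1]]
    expect_equal(nchar(sp$reference_seq), cs$len)
    expect_length(sp$cpg_offsets, cs$k)
    expect_true(all(chars[sp$cpg_offsets] == "C"))
    expect_true(all(chars[sp$cpg_offsets + 1L] == "G"))
    expect_true(all(diff(sp$cpg_offsets) > 0))
    # CpG set is exactly the scored one: no other CG dinucleotide
    cg <- which(chars[-length(chars)] == "C" & chars[-1] == "G")
    expect_equal(cg, sp$cpg_offsets)
    # enough non-CpG Cs for conversion QC, disjoint and jointly covering
    expect_gte(length(sp$non_cpg_c_offsets), cs$k)
    expect_length(intersect(sp$non_cpg_c_offsets, sp$cpg_offsets), 0)
    expect_setequal(c(sp$non_cpg_c_offsets, sp$cpg_offsets),
                    which(chars == "C"))
  }
  expect_identical(make_amplicon_spec(5, 200, 1:5, seed = 3)$reference_seq,
                   make_amplicon_spec(5, 200, 1:5, seed = 3)$reference_seq)
  expect_error(make_amplicon_spec(8, 100, 1:8, seed = 1), "geometry")
  expect_error(make_amplicon_spec(3, 200, c(5L, 2L, 9L), seed = 1),
               "increasing")
})

test_that("sample_molecules reproduces mixture probabilities", {
  sp <- spec7()
  m1 <- sample_molecules(sp, clean_mixture(c("0000000" = 1), 100))
  expect_identical(m1, rep("0000000", 100))
  m2 <- sample_molecules(sp, clean_mixture(c("1111111" = 1), 5))
  expect_identical(m2, rep("1111111", 5))
  # binomial oracle: each frequency within 3 s.e. of 0.5 at n = 1e5
  n <- 1e5
  mix <- clean_mixture(c("1000000" = 0.5, "0000001" = 0.5), n, seed = 77)
  mols <- sample_molecules(sp, mix)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(mean(mols == "1000000") - 0.5), 3 * se)
  expect_lt(abs(mean(mols == "0000001") - 0.5), 3 * se)
  # chi-square GOF of ground truth against the mixture
  mix2 <- clean_mixture(c("0000000" = 0.4, "1111111" = 0.35,
                          "1010101" = 0.25), n, seed = 78)
  mols2 <- sample_molecules(sp, mix2)
  obs <- table(factor(mols2, levels = names(mix2$epiallele_probs)))
  gof <- chisq.test(obs, p = mix2$epiallele_probs)
  expect_gt(gof$p.value, 0.001)
})

test_that("bisulfite conversion follows the methylation state exactly when error-free", {
  sp <- spec7()
  mix <- clean_mixture(c("1111111" = 1), 1, seed = 5)
  full <- bisulfite_convert_and_read("1111111", sp, mix, read_len = 388)$seq
  chars <- strsplit(full, "")[[1]]
  expect_true(all(chars[sp$cpg_offsets] == "C"))
  expect_true(all(chars[sp$non_cpg_c_offsets] == "T"))
  full0 <- bisulfite_convert_and_read("0000000", sp, mix, read_len = 388)$seq
  chars0 <- strsplit(full0, "")[[1]]
  expect_true(all(chars0[c(sp$cpg_offsets, sp$non_cpg_c_offsets)] == "T"))
  # read pair geometry: 251-mers overlapping by >= 40
  pr <- bisulfite_convert_and_read("1111111", sp, mix)
  expect_equal(nchar(pr$fw), 251)
  expect_equal(nchar(pr$rv), 251)
  expect_gte(2 * 251 - 388, 40)
})

test_that("non-CpG C conversion fraction matches the binomial oracle", {
  sp <- spec7()
  n <- 1e4
  mix <- mixture_spec(c("0000000" = 1), n, conversion_rate = 0.99,
                      inappropriate_conversion_rate = 0, seq_error_rate = 0,
                      seed = 91)
  rd <- simulate_bisulfite_reads(sp, mix, read_len = 388)
  m <- matrix(unlist(lapply(as.character(rd$fw), charToRaw)), nrow = 388)
  frac_t <- mean(m[sp$non_cpg_c_offsets, ] == charToRaw("T"))
  n_trials <- length(sp$non_cpg_c_offsets) * n
  se <- sqrt(0.99 * 0.01 / n_trials)
  expect_lt(abs(frac_t - 0.99), 3 * se)
})

test_that("spike-in simulation hits the extremes and is deterministic", {
  s1 <- simulate_spikein(5, conversion_rate = 1, seed = 1)
  chars <- strsplit(s1$reference, "")[[1]]
  cpos <- which(chars == "C")
  for (r in as.character(s1$reads))
    expect_true(all(strsplit(r, "")[[1]][cpos] == "T"))
  s0 <- simulate_spikein(5, conversion_rate = 0, seed = 1)
  expect_identical(as.character(s0$reads), rep(s0$reference, 5),
                   ignore_attr = TRUE)
  expect_identical(as.character(simulate_spikein(20, 0.7, seed = 3)$reads),
                   as.character(simulate_spikein(20, 0.7, seed = 3)$reads))
})

test_that("simulated expression couples to methylation as specified", {
  meth <- setNames(seq(0.05, 0.45, length.out = 9), paste0("s", 1:9))
  # zero coupling, zero noise: all 2^-dCt equal
  e0 <- delta_ct_table(simulate_expression(meth, 0, 0, seed = 1))
  expect_equal(diff(range(e0$rel_expr)), 0)
  # negative coupling, zero noise: exact linear map, Pearson r = -1
  e1 <- delta_ct_table(simulate_expression(meth, -1.5, 0, seed = 1))
  r <- cor(meth, e1$rel_expr[match(names(meth), e1$sample_id)])
  expect_equal(r, -1)
  expect_error(simulate_expression(meth, -3, 0), "positive")
})

test_that("generators are bit-reproducible given the seed", {
  sp <- spec8()
  mix <- mixture_spec(bernoulli_mixture(0.25, 8), 500, seed = 13)
  r1 <- simulate_bisulfite_reads(sp, mix, "s")
  r2 <- simulate_bisulfite_reads(sp, mix, "s")
  expect_identical(as.character(r1$fw), as.character(r2$fw))
  expect_identical(as.character(r1$rv), as.character(r2$rv))
  expect_identical(r1$truth, r2$truth)
})

test_that("bernoulli_mixture enumerates the full epiallele space correctly", {
  pr <- bernoulli_mixture(c(0.5, 0.1, 0.9), 3)
  expect_length(pr, 8)
  expect_equal(sum(pr), 1)
  expect_equal(unname(pr["000"]), 0.5 * 0.9 * 0.1)
  expect_equal(unname(pr["111"]), 0.5 * 0.1 * 0.9)
  expect_equal(unname(pr["010"]), 0.5 * 0.1 * 0.1)
})
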