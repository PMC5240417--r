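test_that("median-of-ratios size factors match their definition", {
  m <- matrix(rep(c(10L, 20L, 40L), 4), 3, 4,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  expect_equal(unname(estimate_size_factors(m)), rep(1, 4))

  # doubling one column doubles its factor relative to the others
  m2 <- m
  m2[, 2] <- m2[, 2] * 2L
  sf <- estimate_size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1)

  set.seed(31)
  r <- matrix(rnbinom(300, mu = 50, size = 5) + 1L, 50, 6,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:6)))
  expect_equal(unname(estimate_size_factors(r)),
               unname(oracle_size_factors(r)), tolerance = 1e-12)

  z <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  expect_error(estimate_size_factors(z), "pseudo-reference")
})

test_that("dispersion estimates recover the truth and respect its floor", {
  set.seed(41)
  # Poisson data: estimates concentrate near zero
  mp <- matrix(rpois(10000 * 10, 100), 10000, 10,
               dimnames = list(NULL, paste0("s", 1:10)))
  norm <- normalize_counts(mp, rep(1, 10))
  a0 <- estimate_dispersion(norm, list(1:10))
  expect_lt(median(a0), 0.02)

  # NB data at alpha = 0.2 recovered within a factor
  mn <- matrix(rnbinom(4000 * 10, mu = 100, size = 5), 4000, 10,
               dimnames = list(NULL, paste0("s", 1:10)))
  a2 <- estimate_dispersion(normalize_counts(mn, rep(1, 10)), list(1:10))
  expect_gt(median(a2), 0.1)
  expect_lt(median(a2), 0.3)

  # constant genes: zero moment estimate, so zero with an all-constant prior
  mc <- matrix(7L, 20, 6, dimnames = list(NULL, paste0("s", 1:6)))
  ac <- estimate_dispersion(normalize_counts(mc, rep(1, 6)), list(1:3, 4:6))
  expect_true(all(ac == 0))

  expect_error(estimate_dispersion(normalize_counts(mc[, 1, drop = FALSE],
                                                    1), list(1)),
               ">= 2 replicates")
})

test_that("exact conditional test: trivial, Poisson-limit and symmetry cases", {
  # no evidence: identical groups
  expect_equal(nb_exact_test(c(10, 12), c(10, 12), c(1, 1), c(1, 1), 0.1), 1)
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), c(1, 1), c(1, 1), 0.1), 1)

  # Poisson limit equals the binomial conditional enumeration
  p <- nb_exact_test(c(10, 12), c(11, 9), c(1, 1), c(1, 1), 1e-12)
  expect_equal(p, oracle_binom_conditional(22, 20, 2, 2), tolerance = 1e-6)

  # swapping the groups leaves the two-sided p unchanged
  p1 <- nb_exact_test(c(3, 9), c(20, 14), c(1, 1), c(1, 1), 0.1)
  p2 <- nb_exact_test(c(20, 14), c(3, 9), c(1, 1), c(1, 1), 0.1)
  expect_equal(p1, p2, tolerance = 1e-12)

  expect_error(nb_exact_test(c(-1, 2), c(1, 1), c(1, 1), c(1, 1), 0.1),
               "non-negative")
  expect_error(nb_exact_test(c(1, 2), c(1, 1), c(1, 1), c(1, 1), -0.1),
               ">= 0")
})

test_that("exact test matches exhaustive NB convolution on small tables", {
  set.seed(51)
  for (alpha in c(0, 0.1, 0.5)) {
    for (rep in 1:20) {
      na <- sample(2:3, 1); nb <- sample(2:3, 1)
      ca <- sample(0:12, na, replace = TRUE)
      cb <- sample(0:12, nb, replace = TRUE)
      p_impl <- nb_exact_test(ca, cb, rep(1, na), rep(1, nb), alpha)
      p_orac <- oracle_nb_exact(ca, cb, rep(1, na), rep(1, nb), alpha)
      expect_equal(p_impl, p_orac, tolerance = 1e-10)
    }
  }
})

test_that("Wald p-values are near-uniform under the null at moderate means", {
  set.seed(61)
  n <- 5000
  m <- matrix(rnbinom(n * 8, mu = 80, size = 10), n, 8,
              dimnames = list(sprintf("g%04d", 1:n), paste0("s", 1:8)))
  norm <- normalize_counts(m, rep(1, 8))
  res <- test_de(norm, 0.1, paste0("s", 1:4), paste0("s", 5:8),
                 max_total = 0)   # skip enumeration, Wald is the subject
  ks <- suppressWarnings(ks.test(res$p_wald, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("test_de obeys two-sided label-swap symmetry and the DEG rule", {
  set.seed(71)
  n <- 150
  mu <- 2^runif(n, 4, 9)
  fc <- ifelse(runif(n) < 0.3, 2^sample(c(-2, 2), n, replace = TRUE), 1)
  m <- cbind(matrix(rnbinom(n * 3, mu = mu, size = 20), n, 3),
             matrix(rnbinom(n * 3, mu = mu * fc, size = 20), n, 3))
  dimnames(m) <- list(sprintf("g%03d", 1:n), paste0("s", 1:6))
  norm <- normalize_counts(m, rep(1, 6))
  ab <- test_de(norm, 0.05, paste0("s", 1:3), paste0("s", 4:6))
  ba <- test_de(norm, 0.05, paste0("s", 4:6), paste0("s", 1:3))
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-12)
  expect_equal(ab$p_exact, ba$p_exact, tolerance = 1e-9)
  expect_equal(ab$p_wald, ba$p_wald, tolerance = 1e-9)
  # consensus rule: DEG iff both adjusted p-values pass and |lfc| > 1
  expect_identical(ab$is_deg,
                   ab$padj_exact < 0.001 & ab$padj_wald < 0.001 &
                     abs(ab$log2fc) > 1)
  expect_true(any(ab$is_deg))
  # identical groups stay null
  same <- test_de(norm, 0.05, paste0("s", 1:3), paste0("s", 1:3))
  expect_true(all(same$log2fc == 0))
  expect_true(all(same$p_exact == 1))
})

test_that("fixed-null (MPV) testing uses the Wald form with extra variance", {
  set.seed(81)
  n <- 60
  mu <- rep(100, n)
  m <- matrix(rnbinom(n * 3, mu = mu, size = 20), n, 3,
              dimnames = list(sprintf("g%02d", 1:n), paste0("s", 1:3)))
  norm <- normalize_counts(m, rep(1, 3))
  res <- test_de(norm, 0.05, NULL, paste0("s", 1:3),
                 null_mean = rep(100, n), null_mean_var = rep(10, n))
  expect_true(all(is.na(res$p_exact)))
  expect_true(all(res$p_wald >= 0 & res$p_wald <= 1))
  # inflating the null variance can only weaken the evidence
  res2 <- test_de(norm, 0.05, NULL, paste0("s", 1:3),
                  null_mean = rep(100, n), null_mean_var = rep(1000, n))
  expect_true(all(res2$p_wald >= res$p_wald - 1e-12))
})

test_that("BH adjustment matches hand computation and stats::p.adjust", {
  expect_equal(adjust_bh(0.01), 0.01)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(91)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    got <- adjust_bh(p)
    expect_equal(got, oracle_bh(p), tolerance = 1e-14)
    expect_equal(got, p.adjust(p, method = "BH"), tolerance = 1e-14)
    expect_true(all(got >= p - 1e-15))
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(adjust_bh(c(0.2, NA, 0.01)),
               c(0.2, NA, 0.02))
})

test_that("deg_summary reports directions, dedup and complementarity", {
  mk <- function(tissue, n_hi, n_lo, offset = 0) {
    n <- n_hi + n_lo
    data.frame(tissue = tissue,
               group_id = sprintf("G%04d", offset + seq_len(n)),
               is_deg = TRUE,
               direction = rep(c("higher", "lower"), c(n_hi, n_lo)),
               stringsAsFactors = FALSE)
  }
  res <- rbind(mk("leaf", 672, 314), mk("corolla", 100, 50, offset = 500))
  s <- deg_summary(res)
  leaf <- s[s$tissue == "leaf", ]
  expect_equal(leaf$pct_higher, 68.15)
  expect_equal(leaf$pct_lower, 31.85)
  # overall row deduplicates by group id (overlap of 486 groups here)
  ov <- s[s$tissue == "Overall", ]
  expect_identical(ov$n_higher + ov$n_lower,
                   length(unique(res$group_id)))
  # empty rows are NA, populated rows complement to 100
  empty <- deg_summary(data.frame(tissue = "leaf", group_id = "g",
                                  is_deg = FALSE, direction = "none"))
  expect_true(is.na(empty$pct_higher[1]))
  set.seed(99)
  for (i in 1:5) {
    r <- mk("leaf", sample(500, 1), sample(500, 1))
    ss <- deg_summary(r)
    expect_lt(abs(ss$pct_higher[1] + ss$pct_lower[1] - 100), 0.011)
  }
})
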