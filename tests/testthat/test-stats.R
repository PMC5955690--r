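# Inferential layer: paired t, BH-FDR, binned contrasts, GG epsilon,
# repeated-measures ANOVA, Wilcoxon signed rank, correlations.

test_that("paired t handles fixtures and degenerate inputs", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1.2, 1.8, 3.4, 3.9, 5.4)
  r <- paired_t(x, y)
  d <- x - y
  t_hand <- mean(d) / (stats::sd(d) / sqrt(5))
  p_hand <- 2 * stats::pt(-abs(t_hand), 4)
  expect_equal(r$t, t_hand, tolerance = 1e-6)
  expect_equal(r$p, p_hand, tolerance = 1e-6)
  expect_equal(r$df, 4)
  # identical vectors: no difference, not an error
  r0 <- paired_t(x, x)
  expect_equal(r0$t, 0); expect_equal(r0$p, 1); expect_false(r0$degenerate)
  # constant nonzero differences: flagged degenerate
  rd <- paired_t(x + 1, x)
  expect_true(rd$degenerate)
  expect_true(is.na(rd$p))
})

test_that("BH step-up rejects exactly the prescribed set", {
  r <- fdr_bh(rep(0.001, 9), q = 0.05)
  expect_true(all(r$reject))
  r2 <- fdr_bh(c(0.01, 0.02, 0.5), q = 0.05)
  expect_identical(r2$reject, c(TRUE, TRUE, FALSE))
  # direct step-up enumeration oracle on random p-values
  set.seed(30)
  p <- runif(40)^2
  r3 <- fdr_bh(p, q = 0.05)
  o <- order(p)
  ps <- p[o]
  kmax <- suppressWarnings(max(which(ps <= 0.05 * seq_along(ps) / length(ps))))
  oracle <- rep(FALSE, 40)
  if (is.finite(kmax)) oracle[o[seq_len(kmax)]] <- TRUE
  expect_identical(r3$reject, oracle)
  # monotone in q
  r01 <- fdr_bh(p, q = 0.01)
  expect_true(all(!r01$reject | r3$reject))
  expect_error(fdr_bh(numeric(0)), "empty")
})

test_that("binned contrasts compose from per-bin paired t-tests", {
  set.seed(31)
  times <- seq(0, 1.2 - 0.004, by = 0.004)
  n <- 10
  a <- matrix(rnorm(n * length(times)), n)
  b <- matrix(rnorm(n * length(times)), n)
  bc <- binned_contrast(a, b, times, bin_edges = seq(0.2, 1.1, 0.1))
  expect_equal(nrow(bc), 9)
  # per-bin equality with standalone paired_t
  for (k in c(1, 5, 9)) {
    sel <- times >= bc$t_start[k] & times < bc$t_end[k]
    pt <- paired_t(rowMeans(a[, sel]), rowMeans(b[, sel]))
    expect_equal(bc$t[k], pt$t, tolerance = 1e-12)
    expect_equal(bc$p[k], pt$p, tolerance = 1e-12)
  }
  # identical conditions -> nothing significant
  bc0 <- binned_contrast(a, a + rnorm(length(a), sd = 1e-6), times)
  expect_false(any(bc0$significant, na.rm = TRUE))
})

test_that("Greenhouse-Geisser epsilon matches Box's formula", {
  expect_equal(gg_epsilon(matrix(rnorm(20), 10, 2)), 1)
  # fixture: direct eigenvalue evaluation of Box's formula
  set.seed(32)
  y <- matrix(rnorm(15 * 4), 15, 4) %*% diag(c(1, 1.5, 2, 4))
  S <- stats::cov(y)
  k <- 4
  C <- qr.Q(qr(stats::contr.helmert(k)))   # orthonormal contrasts
  lam <- eigen(t(C) %*% S %*% C, symmetric = TRUE)$values
  eps_oracle <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  expect_equal(gg_epsilon(y), eps_oracle, tolerance = 1e-10)
  expect_gte(gg_epsilon(y), 1 / 3)
  # compound symmetry: epsilon near 1 for large n
  set.seed(33)
  subj <- rnorm(400)
  y2 <- sapply(1:4, function(j) subj + rnorm(400))
  expect_equal(gg_epsilon(y2), 1, tolerance = 0.02)
})

test_that("repeated-measures ANOVA agrees with aov() on both factors", {
  set.seed(34)
  n <- 12; ka <- 3; kb <- 2
  y <- matrix(rnorm(n * ka * kb), n)
  y <- y + rnorm(n)                      # subject effect
  y[, 1:2] <- y[, 1:2] + 1               # A effect (cells: B fastest)
  res <- rm_anova(y, k_a = ka, k_b = kb, factor_names = c("A", "B"))
  df <- data.frame(
    y = as.vector(t(y)),
    subj = factor(rep(seq_len(n), each = ka * kb)),
    A = factor(rep(rep(seq_len(ka), each = kb), n)),
    B = factor(rep(seq_len(kb), ka * n))
  )
  aa <- summary(stats::aov(y ~ A * B + Error(subj / (A * B)), data = df))
  f_aov <- c(
    aa[["Error: subj:A"]][[1]]["A", "F value"],
    aa[["Error: subj:B"]][[1]]["B", "F value"],
    aa[["Error: subj:A:B"]][[1]]["A:B", "F value"]
  )
  expect_equal(res$F, unname(f_aov), tolerance = 1e-8)
  expect_equal(res$df1, c(2, 1, 2))
  expect_equal(res$df2, c(22, 11, 22))
  expect_true(all(res$epsilon >= 0.5 & res$epsilon <= 1))
})

test_that("two-level ANOVA reduces to the squared paired t", {
  set.seed(35)
  a <- rnorm(14); b <- rnorm(14) + 0.6
  res <- rm_anova(cbind(a, b), k_a = 2, factor_names = "Condition")
  pt <- paired_t(a, b)
  expect_equal(res$F, pt$t^2, tolerance = 1e-10)
  expect_equal(res$p, pt$p, tolerance = 1e-10)
  expect_equal(res$epsilon, 1)
  # all cells equal -> F = 0
  res0 <- rm_anova(matrix(3, 8, 2), k_a = 2)
  expect_equal(res0$F, 0)
})

test_that("Wilcoxon signed rank matches exhaustive sign enumeration", {
  set.seed(36)
  x <- c(2.1, -0.4, 1.7, 3.0, -1.2, 0.8)
  y <- rep(0, 6)
  r <- wilcoxon_signed_rank(x, y)
  expect_true(r$exact)
  # enumeration over all 2^6 sign assignments of the ranked magnitudes
  rk <- rank(abs(x))
  Vobs <- sum(rk[x > 0])
  Vall <- sapply(0:(2^6 - 1), function(mask) {
    signs <- as.logical(bitwAnd(mask, 2^(0:5)))
    sum(rk[signs])
  })
  p_enum <- mean(abs(Vall - 10.5) >= abs(Vobs - 10.5))
  expect_equal(r$p, p_enum, tolerance = 1e-10)
  # exact and asymptotic paths agree closely by n = 15
  set.seed(37)
  x15 <- rnorm(15) + 0.8
  y15 <- rnorm(15)
  pe <- wilcoxon_signed_rank(x15, y15, exact_max = 15)$p
  pa <- wilcoxon_signed_rank(x15, y15, exact_max = 0)$p
  expect_equal(pe, pa, tolerance = 0.01)
  expect_error(wilcoxon_signed_rank(x, x), "zero")
})

test_that("PLV contrasts compose from per-connection Wilcoxon tests", {
  set.seed(38)
  n <- 14; el <- paste0("E", 1:6)
  a <- matrix(runif(n * 6, 0.2, 0.8), n, 6, dimnames = list(NULL, el))
  b <- a + matrix(rnorm(n * 6, sd = 0.02), n, 6)
  res <- plv_contrast(a, b, exclude = "E1")
  expect_equal(res$electrode, el[-1])
  w <- wilcoxon_signed_rank(a[, "E3"], b[, "E3"])
  expect_equal(res$p[res$electrode == "E3"], w$p, tolerance = 1e-12)
  # identical conditions -> no significance
  res0 <- plv_contrast(a, a + 1e-9 * matrix(rnorm(n * 6), n, 6))
  expect_false(any(res0$significant, na.rm = TRUE))
})

test_that("power-RT correlation matches the closed formula", {
  set.seed(39)
  x <- rnorm(21); y <- 0.3 * x + rnorm(21)
  r <- power_rt_correlation(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$r, r_hand, tolerance = 1e-12)
  expect_equal(power_rt_correlation(x, x)$r, 1, tolerance = 1e-12)
  expect_error(power_rt_correlation(rep(1, 5), rnorm(5)), "variance")
})

test_that("the null correlation test keeps its nominal type-I rate", {
  set.seed(40)
  hits <- mean(replicate(400, power_rt_correlation(rnorm(21), rnorm(21))$p < 0.05))
  expect_lt(abs(hits - 0.05), 0.03)
})
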