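# Inferential layer: binned paired t-tests with Benjamini-Hochberg FDR,
# repeated-measures ANOVA with Greenhouse-Geisser correction, Wilcoxon
# signed-rank contrasts for PLV, and power-RT correlation.

#' Paired t-test
#'
#' Classical paired t on the differences, two-sided. Zero variance of the
#' differences yields a degenerate flag rather than an infinite statistic.
#'
#' @param x,y paired per-subject values.
#' @return list with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) < .Machine$double.eps^0.5 * max(1, abs(mean(d)))) {
    if (all(abs(d) < .Machine$double.eps^0.5)) {
      # identical pairs: no evidence of a difference
      return(list(t = 0, p = 1, df = length(d) - 1,
                  mean_diff = 0, degenerate = FALSE))
    }
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_diff = mean(d), degenerate = FALSE)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up procedure: with ordered p-values p(1) <= ... <= p(m), reject all
#' hypotheses up to the largest i with p(i) <= q i / m. Returns the
#' rejection mask and BH-adjusted p-values.
#'
#' @param pvals p-values in \[0, 1\] (NAs tolerated, never rejected).
#' @param q FDR level.
#' @return list with `reject` (logical), `p_adjusted`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (!length(pvals)) stop("empty p-value vector")
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(pvals, method = "BH")
  reject <- !is.na(adj) & adj <= q
  list(reject = reject, p_adjusted = adj)
}

#' Binned paired contrast with FDR correction
#'
#' Averages each subject's condition time course within consecutive time
#' bins, runs a paired t-test per bin, and corrects across the bins of this
#' contrast family with BH-FDR.
#'
#' @param tc_a,tc_b subjects x time matrices (same time axis) for the two
#'   conditions.
#' @param times time axis in seconds.
#' @param bin_edges bin boundaries in seconds (default 100-ms bins spanning
#'   0.2-1.1 s after the cue).
#' @param q FDR level.
#' @param contrast label stored in the result.
#' @return a `data.frame`: one row per bin with `t_start`, `t_end`,
#'   `mean_diff`, `t`, `df`, `p`, `p_adjusted`, `significant`.
#' @export
binned_contrast <- function(tc_a, tc_b, times,
                            bin_edges = seq(0.2, 1.1, by = 0.1),
                            q = 0.05, contrast = "A-B") {
  stopifnot(nrow(tc_a) == nrow(tc_b), nrow(tc_a) >= 2,
            ncol(tc_a) == length(times), ncol(tc_b) == length(times))
  n_bins <- length(bin_edges) - 1
  res <- data.frame(
    contrast = contrast,
    t_start = bin_edges[-length(bin_edges)], t_end = bin_edges[-1],
    mean_diff = NA_real_, t = NA_real_, df = NA_real_, p = NA_real_
  )
  for (b in seq_len(n_bins)) {
    sel <- which(times >= res$t_start[b] & times < res$t_end[b])
    if (!length(sel)) stop(sprintf("bin [%g, %g) contains no samples",
                                   res$t_start[b], res$t_end[b]))
    a <- rowMeans(tc_a[, sel, drop = FALSE])
    bb <- rowMeans(tc_b[, sel, drop = FALSE])
    pt <- paired_t(a, bb)
    res$mean_diff[b] <- pt$mean_diff
    res$t[b] <- pt$t; res$df[b] <- pt$df; res$p[b] <- pt$p
  }
  fdr <- fdr_bh(res$p, q)
  res$p_adjusted <- fdr$p_adjusted
  res$significant <- fdr$reject
  res
}

#' Greenhouse-Geisser epsilon
#'
#' Box's sphericity correction computed from the sample covariance of the
#' within-subject conditions: with `S` the covariance of the orthonormal
#' contrast variables (equivalently the double-centered condition
#' covariance), `epsilon = tr(S)^2 / (d * tr(S^2))` where `d = k - 1`.
#' Clipped to the admissible range \[1/(k-1), 1\]; two conditions are always
#' spherical (epsilon = 1).
#'
#' @param y subjects x conditions matrix.
#' @return epsilon.
#' @export
gg_epsilon <- function(y) {
  y <- as.matrix(y)
  k <- ncol(y)
  stopifnot(k >= 2, nrow(y) >= 2)
  if (k == 2) return(1)
  S <- stats::cov(y)
  # double centering
  Sd <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  num <- sum(diag(Sd))^2
  den <- (k - 1) * sum(Sd^2)
  if (den < .Machine$double.eps) {
    warning("rank-deficient condition covariance; returning the lower bound")
    return(1 / (k - 1))
  }
  min(1, max(1 / (k - 1), num / den))
}

# orthonormal polynomial-style contrast matrix (k x k-1)
#' @noRd
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  qr.Q(qr(C))
}

#' Repeated-measures ANOVA (one or two within-subject factors)
#'
#' Classical univariate within-subject F-tests for the main effects and
#' (for two factors) the interaction, each tested against its own
#' effect-by-subject error term. For effects with more than one numerator
#' df the Greenhouse-Geisser epsilon is estimated from the covariance of
#' the effect's orthonormal contrast variables and applied to the
#' probability; uncorrected degrees of freedom and corrected probabilities
#' are reported.
#'
#' @param y subjects x cells matrix; cells ordered with factor B varying
#'   fastest within factor A.
#' @param k_a,k_b numbers of levels of factors A and B (`k_b = 1` for a
#'   one-factor design).
#' @param factor_names labels for the factors.
#' @return a `data.frame` with one row per effect: `effect`, `F`, `df1`,
#'   `df2` (uncorrected), `epsilon`, `p` (GG-corrected), `p_uncorrected`.
#' @export
rm_anova <- function(y, k_a, k_b = 1, factor_names = c("A", "B")) {
  y <- as.matrix(y)
  n <- nrow(y)
  stopifnot(ncol(y) == k_a * k_b, n >= 2)
  if (anyNA(y)) stop("missing cells; repeated-measures ANOVA needs complete data")

  effects <- list()
  add_effect <- function(name, M) {
    # M: cells x d orthonormal contrast matrix for the effect
    z <- y %*% M                       # subjects x d contrast variables
    d <- ncol(M)
    ss_eff <- n * sum(colMeans(z)^2)
    zc <- sweep(z, 2, colMeans(z))
    ss_err <- sum(zc^2)
    df1 <- d
    df2 <- d * (n - 1)
    Fv <- if (ss_err < .Machine$double.eps) {
      if (ss_eff < .Machine$double.eps) 0 else Inf
    } else (ss_eff / df1) / (ss_err / df2)
    eps <- if (d == 1) 1 else {
      S <- stats::cov(z)
      num <- sum(diag(S))^2
      den <- d * sum(S^2)
      if (den < .Machine$double.eps) 1 / d else min(1, max(1 / d, num / den))
    }
    p_unc <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    p_gg <- stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
    effects[[name]] <<- data.frame(effect = name, F = Fv, df1 = df1, df2 = df2,
                                   epsilon = eps, p = p_gg,
                                   p_uncorrected = p_unc)
  }

  Ia <- orthonormal_contrasts(k_a)
  if (k_b == 1) {
    add_effect(factor_names[1], Ia)
  } else {
    Ib <- orthonormal_contrasts(k_b)
    one_a <- matrix(1 / sqrt(k_a), k_a, 1)
    one_b <- matrix(1 / sqrt(k_b), k_b, 1)
    # cells ordered with B fastest: cell index = (a-1)*k_b + b
    add_effect(factor_names[1], kronecker(Ia, one_b))
    add_effect(factor_names[2], kronecker(one_a, Ib))
    add_effect(paste(factor_names, collapse = ":"), kronecker(Ia, Ib))
  }
  out <- do.call(rbind, effects)
  rownames(out) <- NULL
  out
}

#' Wilcoxon signed-rank test
#'
#' Zero differences are dropped. Exact p by full sign enumeration for n <=
#' `exact_max` (no ties); otherwise the normal approximation with
#' continuity correction. The z statistic (continuity-corrected) is always
#' reported.
#'
#' @param x,y paired samples.
#' @param exact_max largest n for the exact path.
#' @return list with `V` (signed-rank statistic), `z`, `p`, `n` (non-zero
#'   pairs), `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 15) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- sign(V - mu) * 0.5
  z <- if (sig2 > 0) (V - mu - cc) / sqrt(sig2) else 0
  exact <- n <= exact_max && !any(duplicated(abs(d)))
  p <- if (exact) {
    stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
  } else {
    stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)$p.value
  }
  list(V = V, z = z, p = p, n = n, exact = exact)
}

#' PLV condition contrast across connections
#'
#' Wilcoxon signed-rank test per seed-to-electrode connection, corrected
#' across connections with BH-FDR.
#'
#' @param plv_a,plv_b subjects x electrodes matrices of PLV for the two
#'   conditions (same electrode order, equalized trial counts upstream).
#' @param q FDR level.
#' @param exclude electrodes to drop (e.g. the seed itself).
#' @return `data.frame`: `electrode`, `median_diff`, `z`, `p`, `p_adjusted`,
#'   `significant`.
#' @export
plv_contrast <- function(plv_a, plv_b, q = 0.05, exclude = NULL) {
  stopifnot(all(dim(plv_a) == dim(plv_b)))
  el <- colnames(plv_a) %||% as.character(seq_len(ncol(plv_a)))
  keep <- !(el %in% exclude)
  el <- el[keep]
  plv_a <- plv_a[, keep, drop = FALSE]
  plv_b <- plv_b[, keep, drop = FALSE]
  res <- data.frame(electrode = el, median_diff = NA_real_, z = NA_real_,
                    p = NA_real_)
  for (j in seq_along(el)) {
    w <- tryCatch(wilcoxon_signed_rank(plv_a[, j], plv_b[, j]),
                  error = function(e) NULL)
    res$median_diff[j] <- stats::median(plv_a[, j] - plv_b[, j])
    if (!is.null(w)) { res$z[j] <- w$z; res$p[j] <- w$p }
  }
  fdr <- fdr_bh(res$p, q)
  res$p_adjusted <- fdr$p_adjusted
  res$significant <- fdr$reject
  res
}

#' Correlation between power and reaction time across subjects
#'
#' @param beta per-subject power values.
#' @param rt per-subject mean reaction times.
#' @return list with `r`, `p`, `n`.
#' @export
power_rt_correlation <- function(beta, rt) {
  stopifnot(length(beta) == length(rt), length(beta) >= 3)
  if (stats::sd(beta) == 0 || stats::sd(rt) == 0)
    stop("zero variance; correlation undefined")
  ct <- stats::cor.test(beta, rt)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(beta))
}
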