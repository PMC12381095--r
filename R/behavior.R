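# Behavioural statistics battery: repeated-measures ANOVA with
# Greenhouse-Geisser correction, Friedman test with Kendall's W, paired
# t-tests with Cohen's d_av, Wilcoxon signed-rank with effect size r,
# Benjamini-Hochberg FDR, and the JZS Bayes factor for paired designs.

#' Participant-by-condition matrix from a behaviour table
#'
#' Aggregates a trial-level behaviour table into a complete
#' participant x condition matrix (e.g. proportion correct or mean RT).
#'
#' @param behavior Tibble with `participant` and a condition column.
#' @param value Column to aggregate (`"accuracy"` or `"rt"`).
#' @param condition Grouping column (default `"condition"`; use
#'   `"probing_count"` for the probing analysis).
#' @param fun Aggregation function (default `mean`).
#' @return Numeric matrix, rows = participants, columns = conditions.
#' @export
condition_matrix <- function(behavior, value = "accuracy",
                             condition = "condition", fun = mean) {
  wide <- behavior |>
    dplyr::group_by(.data$participant, .data[[condition]]) |>
    dplyr::summarise(v = fun(.data[[value]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = dplyr::all_of(condition),
                       values_from = "v")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$participant
  if (anyNA(m)) stop("condition matrix has missing cells", call. = FALSE)
  m
}

orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), `/`)
}

#' One-way repeated-measures ANOVA with sphericity diagnostics
#'
#' Classical subject x condition decomposition with partial eta squared,
#' Mauchly's test of sphericity, the Greenhouse-Geisser epsilon, and the
#' epsilon-corrected p-value.
#'
#' @param data Participant x condition numeric matrix (see
#'   [condition_matrix()]), at least 3 rows and 2 columns, no missing cells.
#' @return An `rm_anova` object; see [tidy()] / [glance()] methods.
#' @export
#' @examples
#' y <- matrix(rnorm(18), 6, 3)
#' rm_anova_gg(y)
rm_anova_gg <- function(data) {
  Y <- as.matrix(data)
  if (anyNA(Y)) stop("matrix must be complete", call. = FALSE)
  n <- nrow(Y)
  k <- ncol(Y)
  if (k < 2) stop("need at least 2 conditions", call. = FALSE)
  if (n < 3) stop("need at least 3 participants", call. = FALSE)
  grand <- mean(Y)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_cond <- n * sum((colMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df_cond <- k - 1
  df_err <- (n - 1) * (k - 1)
  ms_cond <- ss_cond / df_cond
  ms_err <- ss_err / df_err
  f <- if (ms_err == 0) {
    if (ms_cond == 0) 0 else Inf
  } else {
    ms_cond / ms_err
  }
  eta_p2 <- if (ss_cond + ss_err == 0) 0 else ss_cond / (ss_cond + ss_err)

  C <- orthonormal_contrasts(k)
  Sc <- t(C) %*% stats::cov(Y) %*% C
  ev <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  eps_gg <- if (sum(ev^2) == 0) 1 else sum(ev)^2 / ((k - 1) * sum(ev^2))
  eps_gg <- min(1, max(1 / (k - 1), eps_gg))

  # Mauchly's W and its chi-square approximation
  if (k > 2 && all(ev > 0)) {
    W <- prod(ev) / (mean(ev)^(k - 1))
    rho <- 1 - (2 * (k - 1)^2 + (k - 1) + 2) / (6 * (k - 1) * (n - 1))
    mauchly_chi2 <- -(n - 1) * rho * log(W)
    mauchly_df <- (k - 1) * k / 2 - 1
    mauchly_p <- pchisq(mauchly_chi2, df = mauchly_df, lower.tail = FALSE)
  } else {
    # sphericity is trivially satisfied with 2 conditions
    W <- 1; mauchly_chi2 <- 0; mauchly_df <- 0; mauchly_p <- 1
  }

  p_uncorr <- pf(f, df_cond, df_err, lower.tail = FALSE)
  p_corr <- pf(f, eps_gg * df_cond, eps_gg * df_err, lower.tail = FALSE)

  structure(
    list(F = f, df_num = df_cond, df_den = df_err,
         ss_cond = ss_cond, ss_err = ss_err, ss_subj = ss_subj,
         p_uncorrected = p_uncorr, p_corrected = p_corr,
         partial_eta_sq = eta_p2,
         mauchly_w = W, mauchly_chi2 = mauchly_chi2,
         mauchly_df = mauchly_df, mauchly_p = mauchly_p,
         epsilon_gg = eps_gg, n = n, k = k,
         conditions = colnames(Y)),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "rm-ANOVA: F(%g, %g) = %.2f, p = %.4g (GG-corrected p = %.4g, eps = %.3f), eta_p^2 = %.3f\n",
    x$df_num, x$df_den, x$F, x$p_uncorrected, x$p_corrected, x$epsilon_gg,
    x$partial_eta_sq))
  cat(sprintf("Mauchly: W = %.3f, chi2(%g) = %.2f, p = %.4g\n",
              x$mauchly_w, x$mauchly_df, x$mauchly_chi2, x$mauchly_p))
  invisible(x)
}

#' @export
tidy.rm_anova <- function(x, ...) {
  tibble(term = "condition", statistic = x$F, df = x$df_num,
         df_residual = x$df_den, p.value = x$p_uncorrected,
         p.value.gg = x$p_corrected, epsilon_gg = x$epsilon_gg,
         partial_eta_sq = x$partial_eta_sq)
}

#' @export
glance.rm_anova <- function(x, ...) {
  tibble(n = x$n, k = x$k, mauchly_w = x$mauchly_w,
         mauchly_chi2 = x$mauchly_chi2, mauchly_p = x$mauchly_p)
}

#' Friedman test with Kendall's W
#'
#' Within-participant mid-ranks, chi-square statistic with tie correction,
#' and Kendall's coefficient of concordance `W = chi2 / (n (k - 1))`.
#'
#' @inheritParams rm_anova_gg
#' @return A tibble: `chi2`, `df`, `p`, `kendall_w`, `n`, `k`.
#' @export
friedman_kendall_w <- function(data) {
  Y <- as.matrix(data)
  if (anyNA(Y)) stop("matrix must be complete", call. = FALSE)
  n <- nrow(Y)
  k <- ncol(Y)
  if (k < 2) stop("need at least 2 conditions", call. = FALSE)
  R <- t(apply(Y, 1, rank))
  rs <- colSums(R)
  chi2 <- 12 / (n * k * (k + 1)) * sum(rs^2) - 3 * n * (k + 1)
  # tie correction
  tie_sum <- sum(apply(Y, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  corr <- 1 - tie_sum / (n * (k^3 - k))
  chi2 <- if (corr > 0) chi2 / corr else 0
  w <- chi2 / (n * (k - 1))
  tibble(chi2 = chi2, df = k - 1,
         p = pchisq(chi2, df = k - 1, lower.tail = FALSE),
         kendall_w = w, n = n, k = k)
}

#' Paired t-test with Cohen's d_av
#'
#' Standard paired t with the averaged-SD effect size
#' `d_av = mean(x - y) / ((sd(x) + sd(y)) / 2)` and a 95% CI on the raw mean
#' difference. With zero-variance differences the convention is `t = 0`,
#' `p = 1` when the mean difference is 0 and `p = 0` otherwise.
#'
#' @param x,y Paired numeric vectors (length at least 3).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble: `t`, `df`, `p`, `d_av`, `ci_lower`, `ci_upper`,
#'   `mean_diff`.
#' @export
paired_t_dav <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  se <- s / sqrt(n)
  if (se == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
    ci <- c(m, m)
  } else {
    t <- m / se
    p <- 2 * pt(abs(t), df = n - 1, lower.tail = FALSE)
    ci <- m + c(-1, 1) * qt(1 - (1 - conf_level) / 2, df = n - 1) * se
  }
  sd_av <- (sd(x) + sd(y)) / 2
  d_av <- if (sd_av == 0) 0 else m / sd_av
  tibble(t = t, df = n - 1, p = p, d_av = d_av,
         ci_lower = ci[1], ci_upper = ci[2], mean_diff = m)
}

#' Wilcoxon signed-rank test with effect size r
#'
#' Mid-ranks of absolute differences (zero differences dropped), both
#' rank-sum conventions (`w_pos`, `w_neg`, and their minimum `w_min`), a
#' normal-approximation z with continuity and tie corrections, the effect
#' size `r = z / sqrt(n)`, and an exact p-value by full sign enumeration for
#' `n <= 12` non-zero pairs (normal approximation otherwise).
#'
#' @param x,y Paired numeric vectors.
#' @return A tibble: `w_pos`, `w_neg`, `w_min`, `z`, `p`, `r`, `n_used`,
#'   `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero", call. = FALSE)
  rks <- rank(abs(d))
  w_pos <- sum(rks[d > 0])
  w_neg <- sum(rks[d < 0])
  mu <- n * (n + 1) / 4
  ties <- table(rks)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  sigma <- sqrt(sigma2)
  z <- if (sigma == 0) 0 else {
    dev <- w_pos - mu
    (dev - 0.5 * sign(dev)) / sigma
  }
  exact <- n <= 12
  if (exact) {
    # full enumeration over all 2^n sign assignments of the observed ranks
    signs <- all_sign_matrix(n)
    w_all <- as.vector((signs > 0) %*% rks)
    p <- min(1, 2 * min(mean(w_all <= w_pos + 1e-9),
                        mean(w_all >= w_pos - 1e-9)))
  } else {
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }
  tibble(w_pos = w_pos, w_neg = w_neg, w_min = min(w_pos, w_neg),
         z = z, p = p, r = z / sqrt(n), n_used = n, exact = exact)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment (order-preserving, monotone,
#' capped at 1); a thin wrapper over [stats::p.adjust()].
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' JZS Bayes factor for a paired t-test
#'
#' Default-prior Bayes factor for the one-sample t-test on paired
#' differences: the marginal likelihood of the t statistic under a
#' `Cauchy(0, scale)` prior on the standardized effect size, over the
#' point-null likelihood, computed by adaptive numerical integration over
#' the effect size (non-central t likelihood).
#'
#' @param t Observed paired t statistic.
#' @param n Number of pairs (at least 2).
#' @param cauchy_scale Prior scale (default `sqrt(2) / 2`, the conventional
#'   medium prior).
#' @return `bf10` (evidence for the alternative; `bf01 = 1 / bf10`).
#' @export
#' @examples
#' jzs_bf_paired(t = 2.5, n = 30)
jzs_bf_paired <- function(t, n, cauchy_scale = sqrt(2) / 2) {
  stopifnot(n >= 2, cauchy_scale > 0)
  if (!is.finite(t)) stop("`t` must be finite", call. = FALSE)
  df <- n - 1
  integrand <- function(delta) {
    # dt() warns about precision at large non-centrality; its accuracy is
    # far beyond what the quadrature needs
    suppressWarnings(
      dt(t, df = df, ncp = delta * sqrt(n)) * dcauchy(delta, 0, cauchy_scale))
  }
  marg <- integrate(integrand, -Inf, Inf, rel.tol = 1e-9,
                    stop.on.error = FALSE)$value
  marg / dt(t, df = df)
}

#' Full pairwise battery over a condition matrix
#'
#' For every pair of conditions: paired t-test with Cohen's d_av and 95% CI,
#' Wilcoxon signed-rank with z and r, JZS Bayes factor, and
#' Benjamini-Hochberg adjusted p-values across the family (parametric and
#' non-parametric families adjusted separately). Lilliefors normality
#' screening per condition is reported alongside but never gates which tests
#' run; both parametric and non-parametric results are always produced.
#'
#' @inheritParams rm_anova_gg
#' @param cauchy_scale Prior scale for the Bayes factor.
#' @return A list with `pairwise` (tibble, one row per contrast) and
#'   `normality` (tibble of Lilliefors statistics per condition when
#'   `nortest` is available, otherwise `NULL`).
#' @export
pairwise_battery <- function(data, cauchy_scale = sqrt(2) / 2) {
  Y <- as.matrix(data)
  k <- ncol(Y)
  conds <- colnames(Y) %||% paste0("c", seq_len(k))
  pairs <- utils::combn(k, 2)
  rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    tt <- paired_t_dav(Y[, a], Y[, b])
    wx <- wilcoxon_signed_rank(Y[, a], Y[, b])
    tibble(
      contrast = paste(conds[a], "vs", conds[b]),
      t = tt$t, df = tt$df, p_raw = tt$p, d_av = tt$d_av,
      ci_lower = tt$ci_lower, ci_upper = tt$ci_upper,
      bf10 = jzs_bf_paired(tt$t, nrow(Y), cauchy_scale),
      w_pos = wx$w_pos, w_min = wx$w_min, z = wx$z,
      wilcoxon_p_raw = wx$p, r = wx$r
    )
  })
  rows$p_adj <- bh_fdr(rows$p_raw)
  rows$wilcoxon_p_adj <- bh_fdr(rows$wilcoxon_p_raw)
  normality <- NULL
  if (nrow(Y) >= 5 && requireNamespace("nortest", quietly = TRUE)) {
    normality <- purrr::map_dfr(seq_len(k), function(j) {
      lt <- nortest::lillie.test(Y[, j])
      tibble(condition = conds[j], statistic = unname(lt$statistic),
             p = lt$p.value)
    })
  }
  list(pairwise = dplyr::relocate(rows, "p_adj", .after = "p_raw"),
       normality = normality)
}

#' Omnibus + pairwise behavioural analysis of a behaviour table
#'
#' Convenience wrapper: builds the participant x condition matrix for the
#' chosen measure, runs the repeated-measures ANOVA with Greenhouse-Geisser
#' correction, the Friedman test with Kendall's W, and the pairwise battery.
#' Response-time analyses include all trials regardless of accuracy.
#'
#' @param behavior Behaviour table (see [simulate_behavior()]).
#' @param value `"accuracy"` or `"rt"`.
#' @param condition Grouping column (default `"condition"`).
#' @return A list: `matrix`, `anova` (`rm_anova`), `friedman` (tibble),
#'   `pairwise` (tibble), `normality`.
#' @export
behavior_battery <- function(behavior, value = "accuracy",
                             condition = "condition") {
  m <- condition_matrix(behavior, value = value, condition = condition)
  pw <- pairwise_battery(m)
  list(matrix = m, anova = rm_anova_gg(m), friedman = friedman_kendall_w(m),
       pairwise = pw$pairwise, normality = pw$normality)
}
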