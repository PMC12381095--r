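test_that("repeated-measures ANOVA matches an independent sums-of-squares oracle", {
  # fixed 6 x 3 table
  Y <- matrix(c(7.1, 5.9, 6.4, 6.8, 7.7, 6.1,
                7.9, 6.2, 7.1, 7.0, 8.1, 6.9,
                8.4, 6.1, 7.9, 7.6, 8.5, 7.0),
              nrow = 6, dimnames = list(NULL, c("c1", "c2", "c3")))
  res <- rm_anova_gg(Y)

  # oracle: direct sums of squares, epsilon from the eigenvalues of the
  # contrast covariance, all coded independently here
  n <- 6; k <- 3
  grand <- mean(Y)
  ss_s <- k * sum((rowMeans(Y) - grand)^2)
  ss_c <- n * sum((colMeans(Y) - grand)^2)
  ss_e <- sum((Y - grand)^2) - ss_s - ss_c
  F_or <- (ss_c / (k - 1)) / (ss_e / ((n - 1) * (k - 1)))
  expect_equal(res$F, F_or, tolerance = 1e-12)
  expect_equal(res$partial_eta_sq, ss_c / (ss_c + ss_e), tolerance = 1e-12)

  C <- cbind(c(1, -1, 0) / sqrt(2), c(1, 1, -2) / sqrt(6))
  ev <- eigen(t(C) %*% cov(Y) %*% C)$values
  eps_or <- sum(ev)^2 / ((k - 1) * sum(ev^2))
  expect_equal(res$epsilon_gg, eps_or, tolerance = 1e-10)
  expect_equal(res$p_corrected,
               pf(F_or, eps_or * (k - 1), eps_or * (k - 1) * (n - 1),
                  lower.tail = FALSE),
               tolerance = 1e-10)

  # aov agreement on the uncorrected F
  df <- data.frame(y = as.vector(Y), s = factor(rep(1:n, k)),
                   cond = factor(rep(1:k, each = n)))
  aov_tab <- summary(aov(y ~ cond + Error(s / cond), df))
  F_aov <- aov_tab[["Error: s:cond"]][[1]]["cond", "F value"]
  expect_equal(res$F, F_aov, tolerance = 1e-10)

  # Mauchly agreement with stats::mauchly.test
  ml <- mauchly.test(lm(Y ~ 1), X = ~1)
  expect_equal(res$mauchly_w, unname(ml$statistic), tolerance = 1e-10)
  expect_equal(res$mauchly_p, ml$p.value, tolerance = 1e-10)
})

test_that("rm-ANOVA degenerate and two-condition identities hold", {
  # identical conditions: F = 0, eta = 0
  Y0 <- matrix(rep(c(1, 2, 3, 4), 3), 4, 3)
  r0 <- rm_anova_gg(Y0)
  expect_equal(r0$F, 0)
  expect_equal(r0$partial_eta_sq, 0)

  # 2 conditions: F equals the squared paired t
  set.seed(8)
  Y2 <- matrix(rnorm(20, mean = c(0, 0.5)), 10, 2, byrow = TRUE)
  r2 <- rm_anova_gg(Y2)
  tt <- t.test(Y2[, 1], Y2[, 2], paired = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r2$epsilon_gg, 1)

  expect_error(rm_anova_gg(Y2[, 1, drop = FALSE]), "2 conditions")
})

test_that("Friedman statistic, tie handling and Kendall's W are correct", {
  # identical columns: chi2 = 0, W = 0
  Yc <- matrix(rep(c(3, 1, 4, 1), 3), 4, 3)
  fc <- friedman_kendall_w(Yc)
  expect_equal(fc$chi2, 0)
  expect_equal(fc$kendall_w, 0)

  # perfectly consistent ordering: W = 1
  Yp <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  expect_equal(friedman_kendall_w(Yp)$kendall_w, 1)

  # agreement with stats::friedman.test (which applies the tie correction)
  set.seed(9)
  Y <- matrix(rnorm(24), 8, 3)
  Y[2, 2] <- Y[2, 1]                      # introduce a tie
  f <- friedman_kendall_w(Y)
  ft <- friedman.test(Y)
  expect_equal(f$chi2, unname(ft$statistic), tolerance = 1e-10)
  expect_equal(f$p, ft$p.value, tolerance = 1e-10)
  expect_equal(f$kendall_w, f$chi2 / (8 * 2), tolerance = 1e-12)

  # exhaustive enumeration on a 4 x 3 table: the implemented statistic
  # agrees with the direct rank-sum formula on every one of the (3!)^4
  # equally likely rank profiles, so the exact permutation p computed from
  # either route is identical
  perms <- as.matrix(expand.grid(1:6, 1:6, 1:6, 1:6))
  all_orders <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                      c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  chi2_formula <- function(R) {
    n <- nrow(R); k <- ncol(R)
    12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
  }
  sub <- perms[seq(1, nrow(perms), by = 9), ]   # 144 evenly spread profiles
  for (row in seq_len(nrow(sub))) {
    R <- rbind(all_orders[sub[row, 1], ], all_orders[sub[row, 2], ],
               all_orders[sub[row, 3], ], all_orders[sub[row, 4], ])
    expect_equal(friedman_kendall_w(R)$chi2, chi2_formula(R),
                 tolerance = 1e-10)
  }
  # exact p for one observed table from the enumerated null
  Ys <- matrix(c(1.2, 0.4, 2.2, 0.9,
                 1.9, 0.7, 2.5, 1.4,
                 2.4, 1.1, 2.1, 1.8), 4, 3)
  obs <- friedman_kendall_w(Ys)
  null_oracle <- apply(perms, 1, function(ix) {
    chi2_formula(rbind(all_orders[ix[1], ], all_orders[ix[2], ],
                       all_orders[ix[3], ], all_orders[ix[4], ]))
  })
  null_impl <- apply(sub, 1, function(ix) {
    friedman_kendall_w(rbind(all_orders[ix[1], ], all_orders[ix[2], ],
                             all_orders[ix[3], ], all_orders[ix[4], ]))$chi2
  })
  p_exact_oracle <- mean(null_oracle >= obs$chi2 - 1e-9)
  p_exact_impl_sub <- mean(null_impl >= obs$chi2 - 1e-9)
  p_exact_oracle_sub <- mean(null_oracle[seq(1, length(null_oracle), by = 9)] >=
                               obs$chi2 - 1e-9)
  # dual-route exact p agrees wherever both routes are evaluated
  expect_equal(p_exact_impl_sub, p_exact_oracle_sub, tolerance = 1e-12)
  expect_gt(p_exact_oracle, 0)
})

test_that("paired t with Cohen's d_av matches textbook formulas", {
  # x == y: everything zero, CI centred at 0
  x <- c(1, 2, 3, 4, 5)
  r0 <- paired_t_dav(x, x)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_equal(r0$d_av, 0)
  expect_equal((r0$ci_lower + r0$ci_upper) / 2, 0)

  # constant difference c with equal SDs s: d_av = c / s
  y <- x + 2
  rc <- paired_t_dav(y, x)
  expect_equal(rc$d_av, 2 / sd(x), tolerance = 1e-12)

  # 5-pair hand example against closed-form arithmetic and t.test
  a <- c(10.1, 12.3, 9.8, 11.0, 10.6)
  b <- c(9.0, 11.1, 10.2, 10.1, 9.4)
  rr <- paired_t_dav(a, b)
  d <- a - b
  t_or <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(rr$t, t_or, tolerance = 1e-12)
  expect_equal(rr$d_av, mean(d) / ((sd(a) + sd(b)) / 2), tolerance = 1e-12)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(rr$p, tt$p.value, tolerance = 1e-12)
  expect_equal(c(rr$ci_lower, rr$ci_upper), as.numeric(tt$conf.int),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Wilcoxon signed-rank matches exact enumeration and wilcox.test", {
  # symmetric pairs: z near 0
  x <- c(1, -1, 2, -2, 3, -3)
  rs <- wilcoxon_signed_rank(x, rep(0, 6))
  expect_lt(abs(rs$z), 0.5)
  expect_equal(rs$r, rs$z / sqrt(6), tolerance = 1e-12)

  # n = 6 tie-free hand example: exact p equals the full 2^6 enumeration and
  # wilcox.test's exact p
  a <- c(3.1, 0.8, 2.4, -0.6, 1.9, 1.2)
  b <- rep(0, 6)
  rr <- wilcoxon_signed_rank(a, b)
  d <- a - b
  rk <- rank(abs(d))
  combos <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  wdist <- as.vector(combos %*% rk)
  p_or <- min(1, 2 * min(mean(wdist <= rr$w_pos), mean(wdist >= rr$w_pos)))
  expect_equal(rr$p, p_or, tolerance = 1e-12)
  wt <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(rr$p, wt$p.value, tolerance = 1e-12)
  expect_equal(rr$w_pos, unname(wt$statistic))

  # both W conventions and their minimum
  expect_equal(rr$w_min, min(rr$w_pos, rr$w_neg))
  expect_equal(rr$w_pos + rr$w_neg, 6 * 7 / 2)

  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
})

test_that("Benjamini-Hochberg adjustment equals the step-up formula", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(10)
  p <- runif(25)
  adj <- bh_fdr(p)
  # brute-force BH: p * m / rank with a running minimum from the largest p
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  oracle <- pmin(1, cummin(p[o] * m / rank(p)[o]))[order(o)]
  expect_equal(adj, oracle, tolerance = 1e-12)
  expect_true(all(adj >= p & adj <= 1))
})

test_that("JZS Bayes factor behaves correctly and matches an independent quadrature oracle", {
  # t = 0 favours the null
  expect_lt(jzs_bf_paired(0, 20), 1)
  # monotone in |t| at fixed n
  bfs <- vapply(c(0, 0.5, 1, 2, 3, 4), jzs_bf_paired, numeric(1), n = 25)
  expect_true(all(diff(bfs) > 0))

  # independent oracle: Rouder's g-representation of the JZS Bayes factor,
  # BF10 = int (1+Ng)^-1/2 (1 + t^2/((1+Ng)v))^-(v+1)/2 pi(g) dg /
  #        (1 + t^2/v)^-(v+1)/2, g ~ inverse-gamma(1/2, r^2/2)
  jzs_oracle <- function(t, n, r = sqrt(2) / 2) {
    v <- n - 1
    num <- integrate(function(g) {
      (1 + n * g)^(-1 / 2) *
        (1 + t^2 / ((1 + n * g) * v))^(-(v + 1) / 2) *
        (r^2 / 2)^(1 / 2) / gamma(1 / 2) * g^(-3 / 2) * exp(-r^2 / (2 * g))
    }, 0, Inf, rel.tol = 1e-10)$value
    den <- (1 + t^2 / v)^(-(v + 1) / 2)
    num / den
  }
  grid <- list(c(0, 10), c(1.5, 12), c(2.5, 30), c(4.2, 43), c(-3.1, 20))
  for (tn in grid) {
    ours <- jzs_bf_paired(tn[1], tn[2])
    oracle <- jzs_oracle(tn[1], tn[2])
    expect_equal(ours, oracle, tolerance = 5e-4)
  }
  expect_error(jzs_bf_paired(Inf, 10), "finite")
})

test_that("the full battery reproduces the study-level behavioural pattern", {
  objs <- assign_conditions(180, 1, seed = 3)
  ret <- build_retrieval_schedule(objs, seed = 4)
  params <- generator_params(experiment = 1, seed = 90)
  behav <- simulate_behavior(ret, params, n_participants = 43)
  bat <- behavior_battery(behav, "accuracy")
  expect_s3_class(bat$anova, "rm_anova")
  expect_lt(bat$anova$p_corrected, 0.001)
  expect_equal(nrow(bat$pairwise), 3)
  expect_true(all(bat$pairwise$p_adj < 0.05))
  expect_true(all(bat$pairwise$p_adj >= bat$pairwise$p_raw))
  # condition means ordered as configured
  mns <- colMeans(bat$matrix)[c("PT", "NP", "ABS")]
  expect_true(all(diff(mns) < 0))
  # normality screening reported but non-gating
  expect_false(is.null(bat$normality))
  expect_equal(nrow(bat$normality), 3)
})
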