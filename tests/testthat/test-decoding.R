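test_that("shrinkage LDA matches closed-form geometry and likelihood scoring", {
  set.seed(21)
  # two far-separated isotropic classes: boundary is the perpendicular
  # bisector of the means
  mu <- rbind(a = c(-5, 0), b = c(5, 0))
  X <- rbind(matrix(rnorm(100, -5, 1), 50, 2), matrix(rnorm(100, 5, 1), 50, 2))
  X[, 2] <- rnorm(100)
  y <- rep(c("a", "b"), each = 50)
  fit <- lda_fit(X, y, shrinkage = 0)
  expect_equal(lda_predict(fit, X), y)   # separable: 100% on training data
  expect_equal(lda_predict(fit, rbind(c(-0.5, 0), c(0.5, 0))), c("a", "b"))

  # agreement with MASS::lda on the same data
  skip_if_not_installed("MASS")
  mfit <- MASS::lda(X, grouping = y)
  expect_equal(lda_predict(fit, X),
               as.character(predict(mfit, X)$class))

  # score equivalence with the explicit Gaussian log-likelihood, 3 features
  set.seed(22)
  X3 <- matrix(rnorm(60), 20, 3)
  y3 <- rep(c("a", "b"), each = 10)
  f3 <- lda_fit(X3, y3, shrinkage = 0.2)
  sc <- retrocue:::lda_scores(f3, X3)
  S <- f3$pooled_covariance
  for (i in c(1, 7, 15)) {
    ll <- vapply(seq_len(2), function(k) {
      mvn_ll <- -0.5 * t(X3[i, ] - f3$class_means[k, ]) %*%
        solve(S) %*% (X3[i, ] - f3$class_means[k, ])
      as.numeric(mvn_ll) + log(f3$class_priors[k])
    }, numeric(1))
    # scores differ from log-likelihoods by a class-independent constant
    expect_equal(unname(diff(sc[i, ])), unname(diff(ll)), tolerance = 1e-9)
  }
})

test_that("LDA limits: naive discriminant at lambda 1, nearest-mean with one trial", {
  set.seed(23)
  X <- matrix(rnorm(40, sd = c(1, 10)), 20, 2, byrow = TRUE)
  X[11:20, 1] <- X[11:20, 1] + 3
  y <- rep(c("a", "b"), each = 10)
  f1 <- lda_fit(X, y, shrinkage = 1)
  # lambda = 1: off-diagonal covariance suppressed entirely
  expect_true(all(f1$pooled_covariance[upper.tri(f1$pooled_covariance)] == 0))

  # one trial per class, lambda 1: nearest-class-mean behaviour
  Xs <- rbind(c(0, 0), c(4, 4))
  fs <- lda_fit(Xs, c("a", "b"), shrinkage = 1)
  expect_error(lda_predict(fs, matrix(1, 1, 3)), "dimension")

  # exact tie breaks to the lowest class index
  Xt <- rbind(c(-1, 0), c(1, 0))
  ft <- lda_fit(Xt, c("a", "b"), shrinkage = 1)
  expect_equal(lda_predict(ft, matrix(c(0, 0), 1, 2)), "a")

  expect_error(lda_fit(X, rep("a", 20)), "2 classes")
})

test_that("balanced folds subsample to equal class counts per fold", {
  labels <- rep(c("w", "x", "y", "z"), each = 10)
  f <- build_balanced_folds(labels, 10, seed = 3)
  for (k in 1:10) {
    expect_equal(as.vector(table(labels[which(f == k)])), rep(1, 4))
  }
  # unbalanced counts: excess trials held out entirely
  labels2 <- c(rep("a", 12), rep("b", 10), rep("c", 10), rep("d", 10))
  f2 <- build_balanced_folds(labels2, 10, seed = 4)
  expect_equal(sum(is.na(f2[labels2 == "a"])), 2)
  expect_equal(sum(is.na(f2[labels2 == "b"])), 0)
  # determinism
  expect_identical(f2, build_balanced_folds(labels2, 10, seed = 4))
  expect_error(build_balanced_folds(rep(c("a", "b"), 3), 10, seed = 1),
               "at least")
})

test_that("super-trials average within class with k-fold variance reduction", {
  set.seed(31)
  X <- matrix(rnorm(200), 40, 5)
  y <- rep(c("a", "b"), each = 20)
  s1 <- make_super_trials(X, y, k = 1, seed = 1)
  expect_identical(s1$features, X)
  expect_identical(s1$labels, y)

  # k = all trials of a class -> the class mean
  sall <- make_super_trials(X, y, k = 20, seed = 2)
  expect_equal(nrow(sall$features), 2)
  ord <- order(sall$labels)
  expect_equal(sall$features[ord[1], ], colMeans(X[y == "a", ]))

  # variance-of-mean law: i.i.d. trials averaged in fours
  ratios <- vapply(1:100, function(s) {
    Z <- matrix(rnorm(400), 100, 4)
    sz <- make_super_trials(Z, rep("a", 100), k = 4, seed = s)
    mean(apply(sz$features, 2, var)) / mean(apply(Z, 2, var))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.25), 0.05)

  expect_error(make_super_trials(X, y, k = 50, seed = 1), "exceeds")
})

test_that("within-phase decoding separates noiseless patterns and stays at chance when shuffled", {
  objs <- tiny_objects(12)
  enc <- build_encoding_schedule(objs, seed = 3)
  cfg <- decoder_config(n_folds = 4, super_trial_size = 1, n_repeats = 1,
                        shrinkage = 1, seed = 5)

  # noiseless, distinct patterns: perfect accuracy inside the signal window
  p0 <- tiny_params(location_signal_amplitude = 5, noise_sd = 0)
  eps0 <- simulate_study("encoding", enc, p0, n_participants = 2)
  tc0 <- decode_within_phase(eps0, cfg)
  expect_equal(tc0$times, eps0[[1]]$times)
  expect_equal(tc0$chance_level, 0.25)
  inside <- tc0$times > 100 & tc0$times < 900
  expect_true(all(tc0$accuracy[, inside] == 1))

  # labels shuffled relative to the data: accuracy within 3 SE of 0.25
  p1 <- tiny_params(location_signal_amplitude = 5, noise_sd = 10, seed = 61)
  eps1 <- simulate_study("encoding", enc, p1, n_participants = 8)
  eps_shuf <- lapply(seq_along(eps1), function(i) {
    e <- eps1[[i]]
    set.seed(700 + i)
    e$metadata$location <- sample(e$metadata$location)
    e
  })
  tc1 <- decode_within_phase(eps_shuf,
                             decoder_config(n_folds = 4, super_trial_size = 1,
                                            n_repeats = 2, seed = 6))
  per_p <- rowMeans(tc1$accuracy)
  se <- sd(per_p) / sqrt(length(per_p))
  expect_lt(abs(mean(per_p) - 0.25), 3 * se + 0.01)
})

test_that("cross-phase decoding transfers exactly when formats are shared and not when orthogonal", {
  objs <- tiny_objects(12)
  enc <- build_encoding_schedule(objs, seed = 3)
  wm <- build_wm_schedule(objs, 1, seed = 7)
  cfg <- decoder_config(super_trial_size = 2, n_repeats = 2, seed = 8)

  run_rho <- function(rho, n_p = 5) {
    p <- tiny_params(location_signal_amplitude = 5, noise_sd = 8,
                     cross_phase_similarity = rho, seed = 71)
    ea <- simulate_study("encoding", enc, p, n_participants = n_p)
    eb <- simulate_study("wm", wm, p, n_participants = n_p)
    decode_cross_phase(ea, c(0, 500), eb, c(300, 800), cfg)
  }

  x1 <- run_rho(1)
  per1 <- rowMeans(x1$accuracy)
  se1 <- sd(per1) / sqrt(length(per1))
  expect_gt(mean(per1), 0.25 + 3 * se1)  # clearly above chance

  x0 <- run_rho(0)
  per_p <- rowMeans(x0$accuracy)
  se <- sd(per_p) / sqrt(length(per_p))
  expect_lt(abs(mean(per_p) - 0.25), 3 * se + 0.01)
  # transfer is monotone in the cross-phase similarity
  expect_gt(mean(per1), mean(per_p))

  # reciprocal symmetry: swapping the argument order leaves results unchanged
  p <- tiny_params(location_signal_amplitude = 5, noise_sd = 8,
                   cross_phase_similarity = 0.5, seed = 72)
  ea <- simulate_study("encoding", enc, p, n_participants = 2)
  eb <- simulate_study("wm", wm, p, n_participants = 2)
  f <- decode_cross_phase(ea, c(0, 500), eb, c(300, 800), cfg)
  b <- decode_cross_phase(eb, c(300, 800), ea, c(0, 500), cfg)
  expect_identical(f$accuracy, b$accuracy)

  expect_error(decode_cross_phase(ea, c(0, 500), eb[1], c(300, 800), cfg),
               "participants")
})

test_that("swap-with-chance cluster test matches exhaustive enumeration on a tiny problem", {
  set.seed(41)
  n <- 4
  Tn <- 3
  acc <- matrix(0.25 + rnorm(n * Tn, 0.1, 0.08), n, Tn)
  tc <- retrocue:::new_decoding_timecourse(
    acc, times = c(0, 20, 40), chance = 0.25, kind = "within",
    config = decoder_config())
  cfg <- cluster_config(n_permutations = 5000, sidedness = "one", seed = 2)
  res <- decoding_cluster_test(tc, cfg)
  expect_true(res$exhaustive)
  expect_length(res$null_max_sizes, 2^(n * Tn))

  # independent oracle: all 2^(n*T) swap patterns, one-sided t per column
  D <- acc - 0.25
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n * Tn)))
  oracle <- apply(signs, 1, function(s) {
    Dp <- D * matrix(s, n, Tn)
    p <- vapply(seq_len(Tn), function(j) {
      t.test(Dp[, j], alternative = "greater")$p.value
    }, numeric(1))
    oracle_max_cluster(p, 0.05, 2)
  })
  expect_equal(sort(res$null_max_sizes), sort(as.integer(oracle)))
})

test_that("decoding cluster test fires on extreme signals and not on exact chance", {
  # accuracy identical to chance everywhere: no clusters at all
  tc0 <- retrocue:::new_decoding_timecourse(
    matrix(0.25, 6, 30), times = seq(0, by = 20, length.out = 30),
    chance = 0.25, kind = "within", config = decoder_config())
  r0 <- decoding_cluster_test(tc0, cluster_config(n_permutations = 200,
                                                  sidedness = "one", seed = 1))
  expect_equal(nrow(r0$clusters[r0$clusters$significant, ]), 0)

  # perfect decoding across a 50-point window for 20 participants: one
  # significant cluster spanning the window
  set.seed(3)
  acc <- matrix(pmin(1, 0.99 + rnorm(20 * 50, 0, 0.002)), 20, 50)
  tc1 <- retrocue:::new_decoding_timecourse(
    acc, times = seq(0, by = 20, length.out = 50),
    chance = 0.25, kind = "within", config = decoder_config())
  r1 <- decoding_cluster_test(tc1, cluster_config(n_permutations = 500,
                                                  sidedness = "one", seed = 4))
  sig <- r1$clusters[r1$clusters$significant, , drop = FALSE]
  expect_equal(nrow(sig), 1)
  expect_equal(sig$length, 50)
})

test_that("cluster-test false-positive rate is controlled at the nominal level", {
  # directly simulated null accuracy matrices around chance
  set.seed(17)
  n_sims <- 120
  fired <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    acc <- matrix(0.25 + rnorm(10 * 25, 0, 0.05), 10, 25)
    tc <- retrocue:::new_decoding_timecourse(
      acc, times = seq(0, by = 20, length.out = 25),
      chance = 0.25, kind = "within", config = decoder_config())
    r <- decoding_cluster_test(tc, cluster_config(n_permutations = 250,
                                                  sidedness = "one",
                                                  seed = s))
    fired[s] <- any(r$clusters$significant)
  }
  expect_lte(mean(fired), 0.1)
})
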