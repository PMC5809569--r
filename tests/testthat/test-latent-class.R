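test_that("choice probabilities are softmax probabilities", {
  expect_equal(choice_probabilities(c(0, 0), matrix(0, 3, 2)),
               rep(1 / 3, 3))
  # utilities (ln 2, 0, 0) -> (0.5, 0.25, 0.25)
  X <- matrix(c(1, 0, 0), ncol = 1)
  expect_equal(choice_probabilities(log(2), X), c(0.5, 0.25, 0.25))
  # random 5-alternative instance vs a direct exp/normalize oracle
  set.seed(42)
  X5 <- matrix(rnorm(5 * 4), 5, 4)
  b <- rnorm(4)
  oracle <- exp(X5 %*% b) / sum(exp(X5 %*% b))
  expect_equal(choice_probabilities(b, X5), as.vector(oracle),
               tolerance = 1e-12)
})

test_that("mixture log-likelihood has its closed forms and degeneracies", {
  at <- toy_attributes()
  des <- generate_design(at, design_config(tasks_per_version = 18L,
                                           seed = 1L))
  obs <- data.frame(respondent_id = "A", version = 1L, position = 1:18,
                    chosen = 1L)
  ds <- choice_dataset(des, obs)
  P <- nrow(effects_columns(at))
  # zero coefficients: every alternative equally likely
  expect_equal(lc_loglik(ds, 1, matrix(0, P, 1)), 18 * log(1 / 3),
               tolerance = 1e-12)
  # C = 1 equals the plain conditional-logit likelihood
  set.seed(7)
  b <- rnorm(P, sd = 0.5)
  ix <- dcemix:::estimation_index(ds)
  single <- sum(dcemix:::resp_loglik(ix, b))
  expect_equal(lc_loglik(ds, 1, b), single, tolerance = 1e-10)
  # degenerate mixing weights (1, 0) collapse to class 1
  B <- cbind(b, rnorm(P))
  expect_equal(lc_loglik(ds, c(1, 0), B), single, tolerance = 1e-10)
  # label permutation leaves the likelihood unchanged
  B2 <- cbind(B[, 2], B[, 1])
  expect_equal(lc_loglik(ds, c(0.3, 0.7), B),
               lc_loglik(ds, c(0.7, 0.3), B2), tolerance = 1e-10)
})

test_that("one-class fits match the independent clogit oracle", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  ds <- toy_estimation_data(n = 60L, S = 1L, seed = 21L)
  fit <- fit_latent_class(ds, 1L, seed = 1L)
  ix <- dcemix:::estimation_index(ds)
  rows <- as.vector(vapply(ix$obs_task,
                           function(t) (t - 1L) * ix$n_alt + seq_len(ix$n_alt),
                           integer(ix$n_alt)))
  Xo <- ix$X[rows, ]
  chosen_alt <- ix$chosen_row - (ix$obs_task - 1L) * ix$n_alt
  y <- rep(0L, length(rows))
  y[(seq_len(ix$n_obs) - 1L) * ix$n_alt + chosen_alt] <- 1L
  sid <- rep(seq_len(ix$n_obs), each = ix$n_alt)
  cl <- survival::clogit(y ~ Xo + survival::strata(sid),
                         control = survival::coxph.control(eps = 1e-10,
                                                           iter.max = 50))
  expect_equal(unname(fit$coefficients[, 1]), unname(coef(cl)),
               tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(cl)), tolerance = 1e-8)
})

test_that("EM improves monotonically and recovers a separated mixture", {
  cfg <- toy_synth_config(n = 200L, S = 2L, sd = 1.2, seed = 31L)
  ds <- split_holdout(simulate_respondents(cfg)$dataset)$estimation
  fit <- fit_latent_class(ds, 2L, n_starts = 4L, seed = 9L)
  expect_true(all(diff(fit$trace) >= -1e-8))
  expect_true(fit$converged)
  expect_equal(sum(fit$shares), 1, tolerance = 1e-12)
  expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-9))
  expect_equal(fit$shares, sort(fit$shares, decreasing = TRUE))
  # z-scores are coefficient / SE wherever the SE is positive
  ok <- fit$se > 0
  expect_equal(fit$z[ok], (fit$coefficients / fit$se)[ok])
  # generating shares are 0.3 / 0.7
  m <- match_segments(fit$utilities, cfg$segment_utilities)
  est <- fit$shares
  est_aligned <- numeric(2)
  est_aligned[m$mapping] <- est
  expect_lt(abs(est_aligned[1] - 0.3), 0.12)
  expect_true(all(m$correlation > 0.9))
})

test_that("posterior assignment is the modal class with low-index ties", {
  sol <- structure(list(posterior = rbind(c(0.9, 0.1), c(0.5, 0.5),
                                          c(0.2, 0.8)),
                        resp_ids = c("a", "b", "c")),
                   class = "lc_solution")
  expect_equal(unname(posterior_assign(sol)), c(1L, 1L, 2L))
})

test_that("fit indices reproduce the published table arithmetic", {
  r1 <- compute_fit_indices(-7741.23, 1, 42, 563)
  expect_equal(r1$p, 42)
  expect_equal(r1$df, 521)
  expect_equal(r1$AIC, 15566.46, tolerance = 1e-6)
  expect_equal(r1$AIC3, 15608.46, tolerance = 1e-6)
  expect_equal(r1$BIC, 15748.46, tolerance = 5e-7)
  expect_equal(r1$CAIC, 15790.46, tolerance = 5e-7)
  r2 <- compute_fit_indices(-7606.56, 2, 42, 563)
  expect_equal(r2$p, 85)
  expect_equal(r2$df, 478)
  expect_equal(r2$AIC, 15383.12, tolerance = 1e-6)
  expect_equal(r2$AIC3, 15468.12, tolerance = 1e-6)
  expect_equal(r2$BIC, 15751.45, tolerance = 5e-7)
  # the parameter count p = C * 42 + (C - 1) for the study instrument
  expect_equal(vapply(1:5, function(C) compute_fit_indices(0, C, 42, 563)$p,
                      numeric(1)),
               c(42, 85, 128, 171, 214))
  # zero case
  z <- compute_fit_indices(0, 1, 0, 10)
  expect_true(all(unlist(z[c("AIC", "AIC3", "BIC", "CAIC")]) == 0))
})

test_that("entropy separation spans its 0..1 range", {
  expect_equal(entropy_r2(matrix(0.5, 4, 2)), 0)
  expect_equal(entropy_r2(rbind(c(1, 0), c(0, 1), c(1, 0))), 1)
  expect_equal(entropy_r2(matrix(1, 5, 1)), 1)  # defined as 1 for C = 1
  # hand-computed oracle: per-cell -h log h summed
  H <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  cells <- -c(0.9 * log(0.9), 0.1 * log(0.1), 0.2 * log(0.2),
              0.8 * log(0.8))
  expect_equal(entropy_r2(H), 1 - sum(cells) / (2 * log(2)),
               tolerance = 1e-12)
})

test_that("the bootstrap likelihood-difference machinery is coherent", {
  # arithmetic of the observed statistic from published log-likelihoods
  expect_equal(-2 * (-7741.23 - (-7606.56)), 269.34, tolerance = 1e-10)
  # identical fits give statistic 0 and p = 1 in the null identity sense
  ds <- toy_estimation_data(n = 40L, S = 1L, seed = 17L, tasks = 8L,
                            n_versions = 2L)
  lrt <- bootstrap_lrt(ds, 1L, 2L, n_boot = 3L, seed = 4L,
                       n_starts = 2L, n_starts_boot = 1L, max_iter = 300L)
  expect_gte(lrt$statistic, -1e-6)
  expect_length(lrt$boot_stats, 3L)
  expect_gte(lrt$p_value, 0)
  expect_lte(lrt$p_value, 1)
  expect_error(bootstrap_lrt(ds, 2L, 1L, n_boot = 3L), "exceed")
})

test_that("a fitted solution survives the JSON round trip", {
  cfg <- toy_synth_config(n = 60L, S = 2L, seed = 71L, tasks = 8L)
  ds <- split_holdout(simulate_respondents(cfg)$dataset)$estimation
  fit <- fit_latent_class(ds, 2L, n_starts = 2L, seed = 3L)
  path <- withr::local_tempfile(fileext = ".json")
  write_solution(fit, path)
  back <- read_solution(path)
  for (f in c("C", "shares", "loglik", "coefficients", "se", "utilities",
              "posterior", "resp_ids", "vcov")) {
    expect_equal(back[[f]], fit[[f]], ignore_attr = TRUE, tolerance = 1e-12)
  }
  # post-estimation works identically off the reloaded solution
  expect_equal(importance_scores(back), importance_scores(fit))
  expect_equal(individual_partworths(back), individual_partworths(fit))
  # quadratic forms amplify last-digit serialization noise by the
  # covariance condition number; parity to ~1e-3 is the honest bound
  expect_equal(wald_tests(back), wald_tests(fit), tolerance = 1e-3)
})

test_that("Wald statistics behave at their null and alternative poles", {
  cfg <- toy_synth_config(n = 150L, S = 2L, sd = 1.2, seed = 23L)
  ds <- split_holdout(simulate_respondents(cfg)$dataset)$estimation
  fit <- fit_latent_class(ds, 2L, n_starts = 3L, seed = 2L)
  w <- wald_tests(fit)
  jz <- w[w$test == "joint_zero", ]
  expect_equal(nrow(jz), 6L * 2L)
  expect_true(all(jz$df == 3L))
  expect_true(all(jz$statistic > 0, na.rm = TRUE))
  expect_true(all(jz$p_value >= 0 & jz$p_value <= 1, na.rm = TRUE))
  eq <- w[w$test == "class_equality", ]
  expect_equal(nrow(eq), 6L)
  expect_true(all(eq$df == 3L))
  # forcing identical class coefficients zeroes the equality statistic
  fit2 <- fit
  fit2$coefficients[, 2] <- fit2$coefficients[, 1]
  w2 <- wald_tests(fit2)
  expect_equal(w2$statistic[w2$test == "class_equality"], rep(0, 6L),
               tolerance = 1e-12)
})
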