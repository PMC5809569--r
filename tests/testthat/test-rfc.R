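toy_share_setup <- function(n = 30L, seed = 12L) {
  at <- toy_attributes()
  U <- toy_utilities(at, S = 2, seed = seed)
  set.seed(seed)
  mix <- runif(n)
  W <- t(vapply(mix, function(m) m * U[, 1] + (1 - m) * U[, 2],
                numeric(nrow(U))))
  list(attributes = at, W = W,
       profiles = list(p1 = list(attr1 = 1L, attr2 = 2L),
                       p2 = list(attr1 = 3L, attr3 = 1L),
                       p3 = list(attr2 = 4L, attr4 = 2L)))
}

test_that("zero-noise shares equal deterministic first choice with tie split", {
  s <- toy_share_setup()
  cfg <- rfc_config(attribute_error_scale = 0, product_error_scale = 0,
                    seed = 1L)
  res <- rfc_shares(s$profiles, s$W, s$attributes, cfg)
  tot <- res[res$group == "total", ]
  # brute-force argmax oracle
  Minc <- dcemix:::profile_incidence(s$profiles, s$attributes)
  base <- s$W %*% Minc
  credit <- t(apply(base, 1, function(u) {
    w <- as.numeric(u >= max(u) - 1e-12)
    w / sum(w)
  }))
  expect_equal(tot$share, unname(100 * colMeans(credit)), tolerance = 1e-12)
  expect_equal(sum(tot$share), 100, tolerance = 1e-9)
  expect_equal(tot$se, rep(0, 3))
})

test_that("product-only Gumbel noise converges to the logit closed form", {
  s <- toy_share_setup(n = 25L)
  cfg <- rfc_config(iterations = 200000L, attribute_error_scale = 0,
                    product_error_scale = 1, seed = 2L)
  res <- rfc_shares(s$profiles, s$W, s$attributes, cfg)
  tot <- res[res$group == "total", ]
  Minc <- dcemix:::profile_incidence(s$profiles, s$attributes)
  base <- s$W %*% Minc
  logit <- 100 * colMeans(t(apply(base, 1,
                                  function(u) exp(u) / sum(exp(u)))))
  expect_true(all(abs(tot$share - logit) <= 3 * pmax(tot$se, 1e-3)))
})

test_that("identical profiles split evenly under any error scales", {
  s <- toy_share_setup(n = 10L)
  twins <- list(a = s$profiles$p1, b = s$profiles$p1)
  for (cfg in list(rfc_config(iterations = 40000L, seed = 5L),
                   rfc_config(iterations = 40000L,
                              attribute_error_scale = 0.5,
                              product_error_scale = 0.5, seed = 5L),
                   rfc_config(attribute_error_scale = 0,
                              product_error_scale = 0, seed = 5L))) {
    res <- rfc_shares(twins, s$W, s$attributes, cfg)
    tot <- res[res$group == "total", ]
    expect_lt(max(abs(tot$share - 50)), 1.5)
  }
})

test_that("shares are seed-deterministic and conserved within groups", {
  s <- toy_share_setup()
  cls <- rep(1:2, length.out = nrow(s$W))
  cfg <- rfc_config(iterations = 20000L, seed = 33L)
  r1 <- rfc_shares(s$profiles, s$W, s$attributes, cfg, class = cls)
  r2 <- rfc_shares(s$profiles, s$W, s$attributes, cfg, class = cls)
  expect_identical(r1, r2)
  for (g in unique(r1$group)) {
    expect_equal(sum(r1$share[r1$group == g]), 100, tolerance = 1e-6)
  }
  expect_setequal(unique(r1$group), c("total", "class1", "class2"))
})

test_that("a no-op sweep reproduces the scenario share exactly", {
  s <- toy_share_setup()
  cfg <- rfc_config(iterations = 10000L, seed = 8L)
  base <- rfc_shares(s$profiles, s$W, s$attributes, cfg)
  sw <- sensitivity_sweep(s$profiles, "p1", "attr1",
                          c(s$profiles$p1$attr1), s$W, s$attributes, cfg)
  expect_equal(sw$share, base$share)
  expect_equal(sw$se, base$se)
})

test_that("sweeping a monotone attribute moves the target share monotonically", {
  at <- toy_attributes()
  # utilities strictly increasing in attr1 levels for every respondent
  U <- toy_utilities(at, S = 1, seed = 2)
  U[1:4, 1] <- c(-1.5, -0.5, 0.5, 1.5)
  W <- rbind(t(U[, 1]), t(U[, 1]) * 0.8, t(U[, 1]) * 1.2)
  profiles <- list(tgt = list(attr1 = 1L, attr2 = 1L),
                   alt = list(attr3 = 2L, attr4 = 2L))
  cfg <- rfc_config(iterations = 60000L, product_error_scale = 1,
                    attribute_error_scale = 0, seed = 3L)
  sw <- sensitivity_sweep(profiles, "tgt", "attr1", 1:4, W, at, cfg)
  tgt <- sw[sw$profile == "tgt" & sw$group == "total", ]
  expect_equal(tgt$swept_level, 1:4)
  expect_true(all(diff(tgt$share) > 0))
})

test_that("hold-out share prediction normalizes and hits the degenerate pole", {
  sim <- simulate_respondents(toy_synth_config(n = 30L, seed = 14L))
  at <- sim$dataset$attributes
  hd <- sim$design[sim$design$is_holdout & sim$design$version == 1L, ]
  U <- toy_utilities(at, S = 2)
  W <- individual_partworths(structure(
    list(posterior = matrix(rep(c(0.7, 0.3), each = 30L), 30L),
         utilities = U, resp_ids = sprintf("R%02d", 1:30)),
    class = "lc_solution"))
  pred <- predict_holdout_shares(W, hd, at, rfc_config(iterations = 20000L,
                                                       seed = 6L))
  for (pos in unique(pred$position)) {
    expect_equal(sum(pred$share[pred$position == pos]), 100,
                 tolerance = 1e-6)
  }
  # single respondent, zero noise: all mass on the max-utility alternative
  one <- predict_holdout_shares(W[1, , drop = FALSE], hd, at,
                                rfc_config(attribute_error_scale = 0,
                                           product_error_scale = 0))
  for (pos in unique(one$position)) {
    expect_equal(sort(one$share[one$position == pos]), c(0, 0, 100))
  }
})

test_that("mean absolute error matches its arithmetic definition", {
  m <- mean_absolute_error(c(50, 30, 20), c(40, 40, 20))
  expect_equal(m$overall, 20 / 3, tolerance = 1e-12)
  expect_equal(mean_absolute_error(c(10, 90), c(10, 90))$overall, 0)
  # random paired tables vs an element-wise oracle
  set.seed(4)
  pred <- data.frame(position = rep(1:2, each = 3), alternative = rep(1:3, 2),
                     share = as.vector(prop.table(matrix(runif(6), 3), 2)) * 100)
  obs <- pred
  obs$share <- as.vector(prop.table(matrix(runif(6), 3), 2)) * 100
  m2 <- mean_absolute_error(pred, obs)
  oracle <- mean(c(mean(abs(pred$share[1:3] - obs$share[1:3])),
                   mean(abs(pred$share[4:6] - obs$share[4:6]))))
  expect_equal(m2$overall, oracle, tolerance = 1e-12)
  expect_error(mean_absolute_error(pred, obs[-1, ]), "match")
})
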