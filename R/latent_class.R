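# Latent-class conditional logit estimation.
#
# The model: respondent i belongs to unobserved class c with probability
# pi_c; conditional on class, the probability of choosing alternative j in
# task t is the softmax of x_tj' beta_c over the task's alternatives, with
# x the effects-coded attribute levels. Mixing is at the respondent level:
# one class governs all of a respondent's tasks, so
#   LL = sum_i log sum_c pi_c prod_t P(y_it | beta_c).
# Estimation is multi-start EM; the M-step for each class is a
# posterior-weighted Newton conditional logit.

#' Choice probabilities of a conditional logit task
#'
#' @param beta coefficient vector on the effects-coded scale.
#' @param X effects-coded matrix of one task, one row per alternative.
#' @return Probability per alternative (softmax of `X %*% beta`).
#' @examples
#' choice_probabilities(c(0, 0), diag(2))  # (0.5, 0.5)
#' @export
choice_probabilities <- function(beta, X) {
  eta <- as.vector(X %*% beta)
  eta <- eta - max(eta)
  e <- exp(eta)
  e / sum(e)
}

# log choice probabilities (and probabilities) for all indexed task rows
task_logprobs <- function(ix, beta) {
  cpp_task_logprobs(ix$rowptr, ix$colidx, ix$val, ix$taskptr, beta)
}

# per-respondent log-likelihood under a single coefficient vector
resp_loglik <- function(ix, beta) {
  lp <- task_logprobs(ix, beta)$logp
  rowsum(lp[ix$chosen_row], ix$obs_resp, reorder = TRUE)[, 1L]
}

# scatter per-observation weights onto chosen design-matrix rows
chosen_row_weights <- function(ix, w_obs) {
  wc <- numeric(nrow(ix$X))
  agg <- rowsum(w_obs, ix$chosen_row)
  wc[as.integer(rownames(agg))] <- agg[, 1L]
  wc
}

# Weighted conditional-logit Newton fit. w_obs weights each observation
# (all of a respondent's tasks share its posterior weight in the M-step).
# Returns beta, the weighted log-likelihood, gradient and (negative)
# Hessian at the optimum.
clogit_newton <- function(ix, w_obs, beta0 = NULL, ridge = 0,
                          tol = 1e-10, max_iter = 50L) {
  P <- ix$P
  beta <- beta0 %||% numeric(P)
  W_task <- numeric(ix$n_tasks)
  agg <- rowsum(w_obs, ix$obs_task)
  W_task[as.integer(rownames(agg))] <- agg[, 1L]
  wc <- chosen_row_weights(ix, w_obs)
  ev <- cpp_clogit_eval(ix$rowptr, ix$colidx, ix$val, P, ix$taskptr,
                        W_task, wc, beta, ridge, TRUE)
  ll <- ev$ll
  iter <- 0L
  repeat {
    iter <- iter + 1L
    A <- ev$neg_hessian
    delta <- tryCatch(solve(A, ev$grad),
                      error = function(e) solve(A + diag(1e-8, P), ev$grad))
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- cpp_clogit_ll(ix$rowptr, ix$colidx, ix$val, ix$taskptr,
                              wc, cand, ridge)
      if (ll_new >= ll - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    moved <- ll_new - ll
    beta <- cand
    ll <- ll_new
    if (iter >= max_iter) break
    ev <- cpp_clogit_eval(ix$rowptr, ix$colidx, ix$val, P, ix$taskptr,
                          W_task, wc, beta, ridge, TRUE)
    if (max(abs(ev$grad)) < tol || abs(moved) < 1e-12) break
  }
  if (iter >= max_iter) {  # loop exited before refreshing ev at beta
    ev <- cpp_clogit_eval(ix$rowptr, ix$colidx, ix$val, P, ix$taskptr,
                          W_task, wc, beta, ridge, TRUE)
  }
  list(beta = beta, loglik = ll, grad = ev$grad,
       neg_hessian = ev$neg_hessian, iter = iter)
}

# mixture log-likelihood pieces from per-class respondent log-likelihoods
mixture_ll <- function(LLmat, shares) {
  lw <- sweep(LLmat, 2L, log(shares), "+")
  m <- do.call(pmax, as.data.frame(lw))
  li <- m + log(rowSums(exp(lw - m)))
  H <- exp(lw - li)
  list(loglik = sum(li), posterior = H, resp_ll = li)
}

#' Log-likelihood of a latent-class conditional logit model
#'
#' Mixing is at the respondent level: one latent class governs all of a
#' respondent's tasks.
#'
#' @param dataset a `choice_data` object (estimation tasks only).
#' @param shares class shares (positive, summing to 1).
#' @param coefficients P x C matrix of effects-coded coefficients (or a
#'   vector when C = 1).
#' @return The log-likelihood (scalar).
#' @export
lc_loglik <- function(dataset, shares, coefficients) {
  coefficients <- as.matrix(coefficients)
  C <- length(shares)
  stopifnot(ncol(coefficients) == C, abs(sum(shares) - 1) < 1e-8)
  ix <- estimation_index(dataset)
  LLmat <- vapply(seq_len(C),
                  function(c) resp_loglik(ix, coefficients[, c]),
                  numeric(ix$n_resp))
  LLmat <- matrix(LLmat, nrow = ix$n_resp)
  if (C == 1L) return(sum(LLmat[, 1L]))
  keep <- shares > 0
  mixture_ll(LLmat[, keep, drop = FALSE], shares[keep])$loglik
}

# one EM run from a given posterior initialization
em_run <- function(ix, C, H0, tol = 1e-8, max_iter = 2000L, ridge = 0) {
  H <- H0
  betas <- matrix(0, nrow = ix$P, ncol = C)
  LLmat <- matrix(0, nrow = ix$n_resp, ncol = C)
  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    shares <- pmax(colMeans(H), 1e-12)
    shares <- shares / sum(shares)
    for (c in seq_len(C)) {
      w_obs <- H[ix$obs_resp, c]
      fit <- clogit_newton(ix, w_obs, beta0 = betas[, c], ridge = ridge,
                           max_iter = if (iter <= 2L) 50L else 10L)
      betas[, c] <- fit$beta
      LLmat[, c] <- resp_loglik(ix, fit$beta)
    }
    mix <- mixture_ll(LLmat, shares)
    H <- mix$posterior
    ll <- mix$loglik
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) <= tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- ll
  }
  list(shares = shares, betas = betas, posterior = H, LLmat = LLmat,
       loglik = ll, trace = trace, iterations = iter,
       converged = converged)
}

#' Fit a latent-class conditional logit model by multi-start EM
#'
#' Runs `n_starts` EM chains from independent random posterior
#' initializations (rows drawn from a flat Dirichlet) and keeps the chain
#' with the best final log-likelihood (ties broken toward the lower start
#' index). Each M-step refits every class's coefficients by
#' posterior-weighted Newton conditional logit with step-halving; the EM
#' log-likelihood sequence is non-decreasing. Standard errors come from
#' the inverse observed information of the full mixture log-likelihood at
#' convergence (coefficients and share logits jointly). Classes are
#' reported in decreasing share order.
#'
#' @param dataset a `choice_data` object with hold-outs removed (see
#'   [split_holdout()]).
#' @param C number of latent classes (>= 1).
#' @param n_starts number of random EM starts.
#' @param seed integer seed; start s draws from a stream derived from
#'   `(seed, s)`.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param ridge optional ridge-style stabilizing penalty on coefficients
#'   (default 0 = pure maximum likelihood; the reported log-likelihood is
#'   always the unpenalized one).
#' @return An `lc_solution` with class shares, per-class coefficients,
#'   standard errors and z-scores, expanded zero-centered level utilities
#'   (with delta-method standard errors), the posterior matrix, the final
#'   log-likelihood and the EM trace of the winning start.
#' @export
fit_latent_class <- function(dataset, C, n_starts = 10L, seed = 1L,
                             tol = 1e-8, max_iter = 2000L, ridge = 0) {
  stopifnot(C >= 1L)
  ix <- estimation_index(dataset)
  if (C > ix$n_resp) stopf("C = %d exceeds the %d respondents", C, ix$n_resp)

  best <- NULL
  best_start <- NA_integer_
  for (s in seq_len(n_starts)) {
    H0 <- with_seed(derive_seed(seed, s), {
      if (C == 1L) {
        matrix(1, nrow = ix$n_resp, ncol = 1L)
      } else {
        G <- matrix(stats::rgamma(ix$n_resp * C, shape = 1),
                    nrow = ix$n_resp)
        G / rowSums(G)
      }
    })
    run <- em_run(ix, C, H0, tol = tol, max_iter = max_iter, ridge = ridge)
    if (is.null(best) || run$loglik > best$loglik + 1e-9) {
      best <- run
      best_start <- s
    }
    if (C == 1L) break  # deterministic: further starts are identical
  }

  ord <- order(best$shares, decreasing = TRUE)
  shares <- best$shares[ord]
  betas <- best$betas[, ord, drop = FALSE]
  H <- best$posterior[, ord, drop = FALSE]

  inf <- mixture_information(ix, shares, betas, H)
  se <- matrix(sqrt(pmax(diag(inf$vcov_beta), 0)), nrow = ix$P, ncol = C)
  z <- betas / ifelse(se > 0, se, NA_real_)

  util <- expanded_solution(ix$attributes, betas, inf$vcov_beta)

  structure(list(
    C = C, shares = shares, coefficients = betas, se = se, z = z,
    utilities = util$utilities, utility_se = util$se, utility_z = util$z,
    loglik = best$loglik, posterior = H, resp_ids = ix$resp_ids,
    n_respondents = ix$n_resp, P = ix$P,
    column_map = ix$column_map, attributes = ix$attributes,
    vcov = inf$vcov_beta, n_starts = n_starts, best_start = best_start,
    seed = seed, iterations = best$iterations, trace = best$trace,
    converged = best$converged, ridge = ridge
  ), class = "lc_solution")
}

#' @export
print.lc_solution <- function(x, ...) {
  cat(sprintf(
    "Latent-class conditional logit: C = %d, N = %d, LL = %.2f%s\n",
    x$C, x$n_respondents, x$loglik,
    if (x$converged) "" else " (not converged)"
  ))
  cat("Class shares:", paste(sprintf("%.3f", x$shares), collapse = ", "),
      "\n")
  invisible(x)
}

# Observed information of the mixture log-likelihood at the fitted
# parameters, over theta = (beta_1, ..., beta_C, alpha) with shares
# parameterized as a softmax of alpha (alpha_C = 0). Built from analytic
# per-respondent scores and per-class conditional-logit Hessians.
mixture_information <- function(ix, shares, betas, H) {
  C <- length(shares)
  P <- ix$P
  n <- ix$n_resp
  X <- ix$X
  Xc <- X[ix$chosen_row, , drop = FALSE]

  G <- vector("list", C)      # per-respondent score of class c (n x P)
  Hc <- vector("list", C)     # posterior-weighted clogit Hessian (P x P)
  for (c in seq_len(C)) {
    lp <- task_logprobs(ix, betas[, c])
    Xbar <- rowsum(X * lp$p, ix$row_task, reorder = TRUE)  # n_tasks x P
    sc <- Xc - Xbar[ix$obs_task, , drop = FALSE]
    G[[c]] <- rowsum(sc, ix$obs_resp, reorder = TRUE)
    w_obs <- H[ix$obs_resp, c]
    W_task <- numeric(ix$n_tasks)
    agg <- rowsum(w_obs, ix$obs_task)
    W_task[as.integer(rownames(agg))] <- agg[, 1L]
    A1 <- crossprod(X, X * (W_task[ix$row_task] * lp$p))
    A2 <- crossprod(Xbar, Xbar * W_task)
    Hc[[c]] <- -(A1 - A2)
  }

  npar <- C * P + (C - 1L)
  Hfull <- matrix(0, npar, npar)
  bidx <- function(c) (c - 1L) * P + seq_len(P)
  for (c in seq_len(C)) {
    for (d in seq_len(C)) {
      blk <- if (c == d) {
        w <- H[, c] * (1 - H[, c])
        Hc[[c]] + crossprod(G[[c]] * sqrt(w))
      } else {
        -crossprod(G[[c]] * H[, c], G[[d]] * H[, d])
      }
      Hfull[bidx(c), bidx(d)] <- blk
    }
  }
  if (C > 1L) {
    aidx <- C * P + seq_len(C - 1L)
    for (c in seq_len(C)) {
      for (d in seq_len(C - 1L)) {
        w <- H[, c] * ((c == d) - H[, d])
        Hfull[bidx(c), aidx[d]] <- colSums(G[[c]] * w)
        Hfull[aidx[d], bidx(c)] <- Hfull[bidx(c), aidx[d]]
      }
    }
    for (d in seq_len(C - 1L)) {
      for (e in seq_len(C - 1L)) {
        Hfull[aidx[d], aidx[e]] <-
          sum(H[, d] * ((d == e) - H[, e])) -
          n * shares[d] * ((d == e) - shares[e])
      }
    }
  }

  V <- tryCatch(solve(-Hfull),
                error = function(e) {
                  MASS_ginv(-Hfull)
                })
  list(vcov = V, vcov_beta = V[seq_len(C * P), seq_len(C * P),
                               drop = FALSE])
}

# Moore-Penrose fallback for a singular information matrix
MASS_ginv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# expanded zero-centered utilities with delta-method SEs per class
expanded_solution <- function(attributes, betas, vcov_beta) {
  emap <- expanded_columns(attributes)
  cmap <- effects_columns(attributes)
  C <- ncol(betas)
  P <- nrow(betas)
  nE <- nrow(emap)
  U <- SE <- matrix(NA_real_, nrow = nE, ncol = C,
                    dimnames = list(emap$name, paste0("class", seq_len(C))))
  for (c in seq_len(C)) {
    V <- vcov_beta[(c - 1L) * P + seq_len(P), (c - 1L) * P + seq_len(P),
                   drop = FALSE]
    for (a in unique(emap$attribute_id)) {
      cols <- cmap$column[cmap$attribute_id == a]
      rows <- which(emap$attribute_id == a)
      b <- betas[cols, c]
      U[rows, c] <- c(b, -sum(b))
      v <- diag(V)[cols]
      SE[rows, c] <- sqrt(pmax(c(v, sum(V[cols, cols])), 0))
    }
  }
  list(utilities = U, se = SE, z = U / ifelse(SE > 0, SE, NA_real_))
}

#' Assign respondents to their modal posterior class
#'
#' @param solution an `lc_solution`.
#' @return Integer class label per respondent (named by respondent id);
#'   ties go to the lower class index.
#' @export
posterior_assign <- function(solution) {
  lab <- max.col(solution$posterior, ties.method = "first")
  stats::setNames(lab, solution$resp_ids)
}

#' Information criteria for a latent-class solution
#'
#' Parameter count is `p = C * P + (C - 1)` (per-class coefficients plus
#' free shares) and `N` is the number of respondents, so
#' `df = N - p`, `AIC = -2 LL + 2 p`, `AIC3 = -2 LL + 3 p`,
#' `BIC = -2 LL + p log N`, `CAIC = -2 LL + p (log N + 1)`.
#'
#' @param LL maximized log-likelihood.
#' @param C number of classes.
#' @param P coefficients per class (effects-coded columns).
#' @param N number of respondents.
#' @return One-row data frame: `C`, `p`, `df`, `LL`, `AIC`, `AIC3`,
#'   `BIC`, `CAIC`.
#' @export
compute_fit_indices <- function(LL, C, P, N) {
  p <- C * P + (C - 1)
  data.frame(
    C = C, p = p, df = N - p, LL = LL,
    AIC = -2 * LL + 2 * p,
    AIC3 = -2 * LL + 3 * p,
    BIC = -2 * LL + p * log(N),
    CAIC = -2 * LL + p * (log(N) + 1)
  )
}

#' Entropy-based class separation
#'
#' `1 - sum_i sum_c (-h_ic log h_ic) / (N log C)`: 0 when assignment is
#' uninformative (uniform posteriors), 1 when every posterior is
#' degenerate. Defined as 1 for a one-class model.
#'
#' @param posterior N x C matrix of posterior membership probabilities
#'   (rows sum to 1).
#' @return Scalar in `[0, 1]`.
#' @export
entropy_r2 <- function(posterior) {
  posterior <- as.matrix(posterior)
  C <- ncol(posterior)
  if (C == 1L) return(1)
  h <- posterior
  ent <- -sum(ifelse(h > 0, h * log(h), 0))
  1 - ent / (nrow(h) * log(C))
}

#' Model-selection table over candidate class counts
#'
#' Fits the model for each class count and assembles the fit-index table
#' (parameters, df, LL, AIC, AIC3, BIC, CAIC, entropy separation).
#'
#' @param dataset a `choice_data` object (hold-outs removed).
#' @param classes integer vector of class counts to fit.
#' @param ... passed to [fit_latent_class()].
#' @return List with `table` (one row per class count) and `fits` (the
#'   `lc_solution` objects).
#' @export
select_classes <- function(dataset, classes = 1:5, ...) {
  fits <- lapply(classes, function(C) fit_latent_class(dataset, C, ...))
  tab <- do.call(rbind, lapply(fits, function(f) {
    row <- compute_fit_indices(f$loglik, f$C, f$P, f$n_respondents)
    row$entropy_r2 <- entropy_r2(f$posterior)
    row
  }))
  list(table = tab, fits = fits)
}

# simulate a parametric-bootstrap dataset from a fitted solution,
# reusing the observed design and respondent-version structure
simulate_from_fit <- function(dataset, shares, betas, seed) {
  ix <- estimation_index(dataset)
  C <- length(shares)
  obs <- dataset$observations
  stopifnot(ix$const_nalt)
  n_alt <- ix$n_alt
  with_seed(seed, {
    cls <- sample.int(C, ix$n_resp, replace = TRUE, prob = shares)
    # per class: cumulative within-task probabilities, tasks in columns
    cum <- lapply(seq_len(C), function(c) {
      Pm <- matrix(task_logprobs(ix, betas[, c])$p, nrow = n_alt)
      apply(Pm, 2L, cumsum)
    })
    u <- stats::runif(ix$n_obs)
    chosen <- integer(ix$n_obs)
    for (c in seq_len(C)) {
      sel <- which(cls[ix$obs_resp] == c)
      if (!length(sel)) next
      cm <- cum[[c]][, ix$obs_task[sel], drop = FALSE]
      chosen[sel] <- 1L + colSums(cm < rep(u[sel], each = n_alt))
    }
    chosen <- pmin(chosen, n_alt)
    new_obs <- obs
    new_obs$chosen <- chosen
    choice_dataset(dataset$design, new_obs, dataset$attributes)
  })
}

#' Bootstrap likelihood-difference test for the number of classes
#'
#' Compares a `C0`-class against a `C1`-class model. The observed
#' statistic is `-2 (LL_C0 - LL_C1)` from fits on the data; its null
#' distribution is built by simulating parametric-bootstrap datasets from
#' the fitted `C0` model (same design, same respondents) and refitting
#' both class counts on each. The p-value is the proportion of bootstrap
#' statistics at least as large as the observed one.
#'
#' @param dataset a `choice_data` object (hold-outs removed).
#' @param C0,C1 class counts, `C1 > C0`.
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @param n_starts EM starts for the data fits.
#' @param n_starts_boot EM starts for each bootstrap refit (fewer, for
#'   tractability).
#' @param ... passed to [fit_latent_class()].
#' @return List with `statistic`, `boot_stats`, `p_value`, and the two
#'   data fits.
#' @export
bootstrap_lrt <- function(dataset, C0, C1, n_boot = 99L, seed = 1L,
                          n_starts = 10L, n_starts_boot = 3L, ...) {
  if (C1 <= C0) stopf("C1 must exceed C0")
  if (n_boot < 1L) stopf("n_boot must be >= 1")
  fit0 <- fit_latent_class(dataset, C0, n_starts = n_starts, seed = seed,
                           ...)
  fit1 <- fit_latent_class(dataset, C1, n_starts = n_starts, seed = seed,
                           ...)
  obs_stat <- -2 * (fit0$loglik - fit1$loglik)
  boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    bs <- derive_seed(seed, 1000L + b)
    bdat <- simulate_from_fit(dataset, fit0$shares, fit0$coefficients, bs)
    b0 <- fit_latent_class(bdat, C0, n_starts = n_starts_boot, seed = bs,
                           ...)
    b1 <- fit_latent_class(bdat, C1, n_starts = n_starts_boot, seed = bs,
                           ...)
    boot[b] <- -2 * (b0$loglik - b1$loglik)
  }
  list(statistic = obs_stat, boot_stats = boot,
       p_value = mean(boot >= obs_stat), n_boot = n_boot,
       fit0 = fit0, fit1 = fit1)
}

#' Wald tests per attribute
#'
#' For every attribute, two chi-square statistics: a joint-zero test per
#' class (are the attribute's K - 1 coefficients all zero; df = K - 1)
#' and a cross-class equality test (are the attribute's coefficients
#' identical in every class; df = (C - 1)(K - 1)). Both are quadratic
#' forms in the fitted covariance; an attribute whose covariance block is
#' singular is reported as `NA`.
#'
#' @param solution an `lc_solution`.
#' @return Data frame, one row per attribute x test (joint-zero rows per
#'   class, one equality row when C > 1): `attribute`, `test`, `class`,
#'   `statistic`, `df`, `p_value`.
#' @export
wald_tests <- function(solution) {
  cmap <- solution$column_map
  C <- solution$C
  P <- solution$P
  V <- solution$vcov
  out <- list()
  quad <- function(b, Vb, df) {
    st <- tryCatch(drop(t(b) %*% solve(Vb, b)), error = function(e) NA_real_)
    data.frame(statistic = st, df = df,
               p_value = if (is.na(st)) NA_real_ else
                 stats::pchisq(st, df, lower.tail = FALSE))
  }
  for (a in unique(cmap$attribute_id)) {
    cols <- cmap$column[cmap$attribute_id == a]
    k1 <- length(cols)
    nm <- cmap$attribute[cmap$attribute_id == a][1]
    for (c in seq_len(C)) {
      gidx <- (c - 1L) * P + cols
      q <- quad(solution$coefficients[cols, c],
                V[gidx, gidx, drop = FALSE], k1)
      out[[length(out) + 1L]] <- cbind(
        data.frame(attribute = nm, test = "joint_zero", class = c), q)
    }
    if (C > 1L) {
      d <- numeric(0)
      Rows <- list()
      for (c in 2:C) {
        d <- c(d, solution$coefficients[cols, 1L] -
                 solution$coefficients[cols, c])
        R <- matrix(0, nrow = k1, ncol = C * P)
        R[, cols] <- diag(k1)
        R[, (c - 1L) * P + cols] <- -diag(k1)
        Rows[[c - 1L]] <- R
      }
      R <- do.call(rbind, Rows)
      q <- quad(d, R %*% V %*% t(R), (C - 1L) * k1)
      out[[length(out) + 1L]] <- cbind(
        data.frame(attribute = nm, test = "class_equality",
                   class = NA_integer_), q)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
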