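# Preference-share simulation: deterministic first choice and randomized
# first choice (RFC). RFC perturbs each respondent's level utilities with
# Gumbel attribute-level error (shared across profiles showing the same
# level) and each profile total with Gumbel product-level error, credits
# the maximum-utility profile, and repeats over many iterations; with
# product-only error shares converge to logit (softmax) shares, with no
# error to deterministic first choice.

#' Randomized first choice configuration
#'
#' @param iterations total simulated choice iterations, spread evenly
#'   over respondents and batches (the realized count is rounded up to a
#'   multiple of `n_batches` per respondent).
#' @param attribute_error_scale Gumbel scale of the error added to each
#'   attribute-level utility (shared by profiles showing that level).
#' @param product_error_scale Gumbel scale of the error added to each
#'   profile's total utility.
#' @param seed integer seed; identical inputs and seed give identical
#'   shares.
#' @param n_batches batches used for the Monte Carlo standard error.
#' @return An `rfc_config` list.
#' @export
rfc_config <- function(iterations = 200000L, attribute_error_scale = 1,
                       product_error_scale = 0, seed = 1L,
                       n_batches = 20L) {
  if (iterations < 1L) stopf("iterations must be >= 1")
  if (attribute_error_scale < 0 || product_error_scale < 0) {
    stopf("error scales must be >= 0")
  }
  structure(list(iterations = as.integer(iterations),
                 attribute_error_scale = attribute_error_scale,
                 product_error_scale = product_error_scale,
                 seed = as.integer(seed),
                 n_batches = as.integer(n_batches)),
            class = "rfc_config")
}

# resolve one profile (named attribute -> level index or label) into
# expanded-utility column indices
resolve_profile <- function(profile, attributes) {
  emap <- expanded_columns(attributes)
  nm <- attribute_names(attributes)
  K <- n_levels(attributes)
  idx <- integer(0)
  for (an in names(profile)) {
    a <- match(an, nm)
    if (is.na(a)) stopf("profile references unknown attribute '%s'", an)
    lv <- profile[[an]]
    if (is.character(lv)) {
      l <- match(lv, attributes[[a]]$levels)
      if (is.na(l)) stopf("unknown level '%s' of attribute '%s'", lv, an)
    } else {
      l <- as.integer(lv)
      if (is.na(l) || l < 1L || l > K[a]) {
        stopf("level %s out of range for attribute '%s'", lv, an)
      }
    }
    idx <- c(idx, which(emap$attribute_id == a & emap$level == l))
  }
  idx
}

# profiles -> expanded-column incidence matrix (sum(K) x J)
profile_incidence <- function(profiles, attributes) {
  emap <- expanded_columns(attributes)
  J <- length(profiles)
  M <- matrix(0, nrow = nrow(emap), ncol = J,
              dimnames = list(emap$name, names(profiles)))
  for (j in seq_len(J)) M[resolve_profile(profiles[[j]], attributes), j] <- 1
  M
}

#' Read a scenario file
#'
#' A scenario is a named list of profiles; each profile maps attribute
#' names to a level (1-based index or level label). Attributes a profile
#' leaves out contribute zero utility (partial profile). On disk it is a
#' JSON object `{profile_name: {attribute: level, ...}, ...}`.
#'
#' @param path file path.
#' @return Named list of profiles.
#' @export
read_scenario <- function(path) {
  sc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(sc) < 2L) stopf("a scenario needs at least 2 profiles")
  sc
}

# group labels: "total" plus one group per class label when given
share_groups <- function(n, class) {
  if (is.null(class)) {
    list(total = seq_len(n))
  } else {
    stopifnot(length(class) == n)
    g <- split(seq_len(n), class)
    names(g) <- paste0("class", names(g))
    c(list(total = seq_len(n)), g)
  }
}

#' Simulate preference shares for a scenario
#'
#' Runs first-choice or randomized first choice simulation over the
#' respondents' individual part-worth utilities. Per iteration and
#' respondent, every expanded level utility is perturbed with independent
#' Gumbel(0, `attribute_error_scale`) noise (profiles showing the same
#' level share the draw), profile totals get Gumbel(0,
#' `product_error_scale`) noise, and the maximum-utility profile is
#' credited. With both scales zero the simulation is the deterministic
#' first-choice count, ties split equally. Unspecified attributes of a
#' partial profile contribute zero utility.
#'
#' @param profiles named list of profiles (attribute -> level index or
#'   label); at least 2.
#' @param partworths N x `sum(K)` matrix of individual expanded utilities
#'   ([individual_partworths()]), or a single respondent's vector.
#' @param attributes a [dce_attributes] dictionary.
#' @param config an [rfc_config].
#' @param class optional class label per respondent; adds per-class
#'   share groups to the output.
#' @return A `share_result` data frame: `profile`, `group`, `share`
#'   (percent; sums to 100 within each group) and `se` (Monte Carlo
#'   standard error from batching; 0 for the deterministic case).
#' @export
rfc_shares <- function(profiles, partworths, attributes, config = rfc_config(),
                       class = NULL) {
  if (length(profiles) < 2L) stopf("a scenario needs at least 2 profiles")
  if (is.null(dim(partworths))) partworths <- matrix(partworths, nrow = 1L)
  W <- as.matrix(partworths)
  Minc <- profile_incidence(profiles, attributes)
  if (nrow(Minc) != ncol(W)) {
    stopf("partworths have %d columns; expected %d expanded utilities",
          ncol(W), nrow(Minc))
  }
  N <- nrow(W)
  J <- ncol(Minc)
  base <- W %*% Minc                      # N x J deterministic utilities
  groups <- share_groups(N, class)
  pnames <- names(profiles) %||% paste0("profile", seq_len(J))

  a_s <- config$attribute_error_scale
  p_s <- config$product_error_scale
  if (a_s == 0 && p_s == 0) {
    mx <- apply(base, 1L, max)
    credit <- (base >= mx - 1e-12)
    credit <- credit / rowSums(credit)    # equal split among ties
    res <- lapply(names(groups), function(g) {
      sh <- 100 * colSums(credit[groups[[g]], , drop = FALSE]) /
        length(groups[[g]])
      data.frame(profile = pnames, group = g, share = sh, se = 0)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    class(out) <- c("share_result", "data.frame")
    return(out)
  }

  nb <- config$n_batches
  reps_b <- max(1L, as.integer(ceiling(config$iterations / (N * nb))))
  nE <- nrow(Minc)
  batch_share <- array(0, dim = c(nb, J, length(groups)))
  with_seed(config$seed, {
    for (b in seq_len(nb)) {
      counts <- matrix(0, nrow = J, ncol = length(groups))
      for (r in seq_len(reps_b)) {
        tot <- base
        if (a_s > 0) {
          E <- matrix(rgumbel(N * nE, a_s), nrow = N)
          tot <- tot + E %*% Minc
        }
        if (p_s > 0) {
          tot <- tot + matrix(rgumbel(N * J, p_s), nrow = N)
        }
        win <- max.col(tot, ties.method = "random")
        for (gi in seq_along(groups)) {
          counts[, gi] <- counts[, gi] +
            tabulate(win[groups[[gi]]], nbins = J)
        }
      }
      for (gi in seq_along(groups)) {
        batch_share[b, , gi] <-
          100 * counts[, gi] / (reps_b * length(groups[[gi]]))
      }
    }
  })
  res <- lapply(seq_along(groups), function(gi) {
    sh <- apply(batch_share[, , gi, drop = FALSE], 2L, mean)
    se <- apply(batch_share[, , gi, drop = FALSE], 2L, stats::sd) / sqrt(nb)
    data.frame(profile = pnames, group = names(groups)[gi],
               share = as.vector(sh), se = as.vector(se))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("share_result", "data.frame")
  out
}

#' Sensitivity sweep over one attribute of one profile
#'
#' Re-simulates the scenario once per swept level, changing only the
#' target profile's level of the swept attribute. All sweep points reuse
#' the same seed (common random numbers), so a sweep to the profile's
#' current level reproduces its share exactly.
#'
#' @param profiles named list of profiles.
#' @param target name (or index) of the profile being varied.
#' @param attribute attribute name to sweep.
#' @param levels level indices (or labels) to sweep over.
#' @param partworths,attributes,config,class as in [rfc_shares()].
#' @return A `share_result` data frame with an extra `swept_level`
#'   column.
#' @export
sensitivity_sweep <- function(profiles, target, attribute, levels,
                              partworths, attributes,
                              config = rfc_config(), class = NULL) {
  j <- if (is.character(target)) match(target, names(profiles)) else
    as.integer(target)
  if (is.na(j) || j < 1L || j > length(profiles)) {
    stopf("unknown target profile")
  }
  out <- list()
  for (lv in levels) {
    prof <- profiles
    prof[[j]][[attribute]] <- lv
    sh <- rfc_shares(prof, partworths, attributes, config, class)
    sh$swept_level <- lv
    out[[length(out) + 1L]] <- sh
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("share_result", "data.frame")
  res
}

#' Predict hold-out task shares from individual utilities
#'
#' Treats each hold-out task as a scenario whose profiles are the task's
#' alternatives (partial profiles over the shown attributes) and
#' simulates the share choosing each alternative.
#'
#' @param partworths N x `sum(K)` individual utility matrix.
#' @param holdout_design `dce_design` rows of the hold-out tasks (one
#'   version's worth; content is identical across versions).
#' @param attributes a [dce_attributes] dictionary.
#' @param config an [rfc_config].
#' @param class optional class labels, as in [rfc_shares()].
#' @return Data frame: `position`, `alternative`, `group`, `share`
#'   (percent, summing to 100 per task and group), `se`.
#' @export
predict_holdout_shares <- function(partworths, holdout_design, attributes,
                                   config = rfc_config(), class = NULL) {
  hd <- holdout_design
  nm <- attribute_names(attributes)
  keys <- unique(hd$position)
  out <- list()
  for (pos in keys) {
    rows <- hd[hd$position == pos, , drop = FALSE]
    rows <- rows[!duplicated(rows$alternative), , drop = FALSE]
    rows <- rows[order(rows$alternative), , drop = FALSE]
    profs <- lapply(seq_len(nrow(rows)), function(r) {
      lv <- lapply(nm, function(a) rows[[a]][r])
      names(lv) <- nm
      lv[!vapply(lv, is.na, logical(1))]
    })
    names(profs) <- paste0("alt", rows$alternative)
    sh <- rfc_shares(profs, partworths, attributes, config, class)
    sh$position <- pos
    sh$alternative <- rows$alternative[match(sh$profile, names(profs))]
    out[[length(out) + 1L]] <- sh[, c("position", "alternative", "group",
                                      "share", "se")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Observed choice shares per task
#'
#' The percentage of respondents choosing each alternative of each task —
#' the empirical counterpart of [predict_holdout_shares()].
#'
#' @param dataset a `choice_data` object (typically the hold-out part of
#'   [split_holdout()]).
#' @return Data frame: `position`, `alternative`, `share` (percent).
#' @export
observed_choice_shares <- function(dataset) {
  obs <- dataset$observations
  des <- dataset$design
  out <- list()
  for (pos in sort(unique(obs$position))) {
    sel <- obs[obs$position == pos, ]
    alts <- sort(unique(des$alternative[des$position == pos]))
    cnt <- vapply(alts, function(a) sum(sel$chosen == a), numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      position = pos, alternative = alts,
      share = 100 * cnt / nrow(sel))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean absolute error of predicted vs observed shares
#'
#' Per task, the mean over alternatives of the absolute difference
#' between predicted and observed percentages; overall, the mean over
#' tasks.
#'
#' @param predicted,observed either numeric vectors of matched
#'   percentages (treated as one task) or data frames with `position`,
#'   `alternative` and `share` columns (the `"total"` group is used if a
#'   `group` column is present).
#' @return List with `per_task` (data frame `position`, `mae`) and
#'   `overall`.
#' @export
mean_absolute_error <- function(predicted, observed) {
  if (is.numeric(predicted) && is.numeric(observed)) {
    if (length(predicted) != length(observed)) {
      stopf("predicted and observed lengths differ")
    }
    m <- mean(abs(predicted - observed))
    return(list(per_task = data.frame(position = 1L, mae = m),
                overall = m))
  }
  p <- as.data.frame(predicted)
  if ("group" %in% names(p)) p <- p[p$group == "total", ]
  o <- as.data.frame(observed)
  if ("group" %in% names(o)) o <- o[o$group == "total", ]
  key_p <- paste(p$position, p$alternative)
  key_o <- paste(o$position, o$alternative)
  if (!setequal(key_p, key_o) || anyDuplicated(key_p) ||
      anyDuplicated(key_o)) {
    stopf("predicted and observed alternative sets do not match")
  }
  o <- o[match(key_p, key_o), ]
  d <- abs(p$share - o$share)
  per_task <- stats::aggregate(d, by = list(position = p$position), mean)
  names(per_task)[2] <- "mae"
  list(per_task = per_task, overall = mean(per_task$mae))
}
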