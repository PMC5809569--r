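#' Expand effects-coded coefficients to zero-centered level utilities
#'
#' On the effects-coded scale an attribute with K levels carries K - 1
#' coefficients; the omitted level's utility is minus their sum, so each
#' attribute's K level utilities sum to zero.
#'
#' @param coefficients vector of length `sum(K - 1)` (one class), or a
#'   P x C matrix.
#' @param attributes a [dce_attributes] dictionary.
#' @return Matrix of expanded utilities, `sum(K)` rows (named by the
#'   [expanded_columns()] layout) by one column per class.
#' @examples
#' attrs <- dce_attributes("a", list(as.character(1:4)))
#' expand_utilities(c(-0.97, -0.02, 0.12), attrs)  # last level = 0.87
#' @export
expand_utilities <- function(coefficients, attributes) {
  B <- as.matrix(coefficients)
  cmap <- effects_columns(attributes)
  emap <- expanded_columns(attributes)
  if (nrow(B) != nrow(cmap)) {
    stopf("expected %d coefficients, got %d", nrow(cmap), nrow(B))
  }
  U <- matrix(NA_real_, nrow = nrow(emap), ncol = ncol(B),
              dimnames = list(emap$name, colnames(B)))
  for (a in unique(emap$attribute_id)) {
    cols <- cmap$column[cmap$attribute_id == a]
    rows <- which(emap$attribute_id == a)
    b <- B[cols, , drop = FALSE]
    U[rows, ] <- rbind(b, -colSums(b))
  }
  U
}

# inverse: first K-1 expanded utilities per attribute are the coefficients
contract_utilities <- function(utilities, attributes) {
  U <- as.matrix(utilities)
  emap <- expanded_columns(attributes)
  keep <- unlist(lapply(split(seq_len(nrow(emap)), emap$attribute_id),
                        function(r) r[-length(r)]), use.names = FALSE)
  U[sort(keep), , drop = FALSE]
}

#' Attribute importance scores
#'
#' Within a class, an attribute's importance is its utility range (max
#' minus min over its zero-centered level utilities) as a percentage of
#' the sum of all attributes' ranges. Importances within a class sum to
#' 100; ranks are assigned by descending importance before any rounding,
#' ties going to the earlier-listed attribute.
#'
#' @param utilities expanded utility matrix (`sum(K)` x C) as returned by
#'   [expand_utilities()], or an `lc_solution`.
#' @param attributes a [dce_attributes] dictionary (ignored when
#'   `utilities` is an `lc_solution`).
#' @return An `importance_table` data frame: `attribute`, `class`,
#'   `range`, `importance` (percent), `rank`.
#' @export
importance_scores <- function(utilities, attributes = NULL) {
  if (inherits(utilities, "lc_solution")) {
    attributes <- utilities$attributes
    utilities <- utilities$utilities
  }
  stopifnot(inherits(attributes, "dce_attributes"))
  U <- as.matrix(utilities)
  emap <- expanded_columns(attributes)
  nm <- attribute_names(attributes)
  C <- ncol(U)
  out <- list()
  for (c in seq_len(C)) {
    rng <- vapply(seq_along(nm), function(a) {
      u <- U[emap$attribute_id == a, c]
      max(u) - min(u)
    }, numeric(1))
    tot <- sum(rng)
    if (tot <= 0) stopf("all attribute ranges are zero in class %d", c)
    imp <- 100 * rng / tot
    rk <- integer(length(imp))
    rk[order(-imp, seq_along(imp))] <- seq_along(imp)
    out[[c]] <- data.frame(attribute = nm, class = c, range = rng,
                           importance = imp, rank = rk,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("importance_table", "data.frame")
  res
}

#' Posterior-weighted individual part-worth utilities
#'
#' Each respondent's utilities are the posterior-probability-weighted
#' mixture of the class utilities, `u_i = sum_c h_ic u_c`, on the
#' expanded zero-centered scale — the standard latent-class individual
#' estimate. Per-attribute zero sums are preserved (a weighted average of
#' zero-sum vectors is zero-sum).
#'
#' @param solution an `lc_solution`.
#' @return N x `sum(K)` matrix of individual level utilities, rows named
#'   by respondent id.
#' @export
individual_partworths <- function(solution) {
  stopifnot(inherits(solution, "lc_solution"))
  M <- solution$posterior %*% t(solution$utilities)
  rownames(M) <- solution$resp_ids
  M
}
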