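#' Write or read a fitted solution as JSON
#'
#' Serializes an `lc_solution` — shares, coefficients, standard errors,
#' z-scores, expanded utilities, log-likelihood, posterior matrix,
#' covariance and the attribute dictionary — to a structured JSON text
#' file, so a fit can be archived and reloaded for post-estimation
#' (importance scores, individual part-worths, Wald tests, share
#' simulation) without refitting.
#'
#' @param solution an `lc_solution`.
#' @param path file path.
#' @return `write_solution` returns `path` invisibly; `read_solution`
#'   returns an `lc_solution`.
#' @export
write_solution <- function(solution, path) {
  stopifnot(inherits(solution, "lc_solution"))
  at <- solution$attributes
  obj <- list(
    C = solution$C, shares = solution$shares,
    loglik = solution$loglik, converged = solution$converged,
    n_starts = solution$n_starts, best_start = solution$best_start,
    seed = solution$seed, iterations = solution$iterations,
    ridge = solution$ridge, n_respondents = solution$n_respondents,
    P = solution$P,
    attributes = lapply(at, function(a) list(name = a$name,
                                             levels = a$levels)),
    coefficients = solution$coefficients, se = solution$se,
    z = solution$z, utilities = solution$utilities,
    utility_se = solution$utility_se, utility_z = solution$utility_z,
    resp_ids = solution$resp_ids, posterior = solution$posterior,
    vcov = solution$vcov, trace = solution$trace
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_solution
#' @export
read_solution <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  at <- dce_attributes(vapply(obj$attributes$name, identity, ""),
                       obj$attributes$levels)
  emap <- expanded_columns(at)
  cmap <- effects_columns(at)
  fixm <- function(m, rn) {
    m <- matrix(as.numeric(m), nrow = length(rn))
    rownames(m) <- rn
    m
  }
  sol <- list(
    C = obj$C, shares = as.numeric(obj$shares),
    coefficients = fixm(obj$coefficients, cmap$name),
    se = fixm(obj$se, cmap$name), z = fixm(obj$z, cmap$name),
    utilities = fixm(obj$utilities, emap$name),
    utility_se = fixm(obj$utility_se, emap$name),
    utility_z = fixm(obj$utility_z, emap$name),
    loglik = obj$loglik,
    posterior = matrix(as.numeric(obj$posterior),
                       nrow = length(obj$resp_ids)),
    resp_ids = obj$resp_ids, n_respondents = obj$n_respondents,
    P = obj$P, column_map = cmap, attributes = at,
    vcov = matrix(as.numeric(obj$vcov), nrow = obj$C * obj$P),
    n_starts = obj$n_starts, best_start = obj$best_start,
    seed = obj$seed, iterations = obj$iterations,
    trace = as.numeric(obj$trace), converged = obj$converged,
    ridge = obj$ridge
  )
  structure(sol, class = "lc_solution")
}
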