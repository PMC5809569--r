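#' Define the attribute dictionary of a choice experiment
#'
#' An attribute dictionary lists the design dimensions of the experiment
#' (e.g. supervisor support, training group size) and the discrete levels
#' each can take. All design, coding, estimation and simulation functions
#' take the dictionary as their reference for level validity and for the
#' effects-coding column layout.
#'
#' @param names character vector of attribute names (unique, non-empty).
#' @param levels list of character vectors, one per attribute, giving the
#'   ordered level labels. Each attribute needs at least two unique levels.
#' @return An object of class `dce_attributes`: a list with one element per
#'   attribute, each holding `attribute_id`, `name` and `levels`.
#' @examples
#' attrs <- dce_attributes(
#'   c("supervisor_support", "group_size"),
#'   list(c("none", "33%", "67%", "100%"),
#'        c("alone", "10", "50", "100"))
#' )
#' n_levels(attrs)
#' @export
dce_attributes <- function(names, levels) {
  if (!is.character(names) || anyDuplicated(names) || any(!nzchar(names))) {
    stopf("attribute names must be unique non-empty strings")
  }
  if (!is.list(levels) || length(levels) != length(names)) {
    stopf("`levels` must be a list with one entry per attribute")
  }
  out <- vector("list", length(names))
  for (a in seq_along(names)) {
    lv <- as.character(levels[[a]])
    if (length(lv) < 2L || anyDuplicated(lv)) {
      stopf("attribute '%s': needs >= 2 unique levels", names[a])
    }
    out[[a]] <- list(attribute_id = a, name = names[a], levels = lv)
  }
  structure(out, class = "dce_attributes")
}

#' @export
print.dce_attributes <- function(x, ...) {
  cat(sprintf("Attribute dictionary: %d attributes\n", length(x)))
  for (a in x) {
    cat(sprintf("  [%d] %s (%d levels): %s\n", a$attribute_id, a$name,
                length(a$levels), paste(a$levels, collapse = " | ")))
  }
  invisible(x)
}

#' Number of levels per attribute
#'
#' @param attributes a [dce_attributes] dictionary.
#' @return Named integer vector of level counts.
#' @export
n_levels <- function(attributes) {
  stopifnot(inherits(attributes, "dce_attributes"))
  vapply(attributes, function(a) length(a$levels), integer(1),
         USE.NAMES = FALSE) |>
    stats::setNames(attribute_names(attributes))
}

attribute_names <- function(attributes) {
  vapply(attributes, `[[`, character(1), "name")
}

#' Effects-coding column layout
#'
#' Each attribute with K levels owns K - 1 columns in the effects-coded
#' design matrix (the last listed level is the omitted reference, coded -1
#' on all of the attribute's columns). The layout maps estimation
#' coefficients back to (attribute, level) pairs.
#'
#' @param attributes a [dce_attributes] dictionary.
#' @return Data frame with one row per column: `column`, `attribute_id`,
#'   `attribute`, `level` (1-based level index) and `name`.
#' @export
effects_columns <- function(attributes) {
  stopifnot(inherits(attributes, "dce_attributes"))
  K <- n_levels(attributes)
  att <- rep(seq_along(K), K - 1L)
  lev <- unlist(lapply(K, function(k) seq_len(k - 1L)), use.names = FALSE)
  nm <- attribute_names(attributes)
  data.frame(
    column = seq_along(att),
    attribute_id = att,
    attribute = nm[att],
    level = lev,
    name = paste0(nm[att], ".", lev),
    stringsAsFactors = FALSE
  )
}

# layout of the expanded (zero-centered, all-K-levels) utility scale
expanded_columns <- function(attributes) {
  K <- n_levels(attributes)
  att <- rep(seq_along(K), K)
  lev <- unlist(lapply(K, seq_len), use.names = FALSE)
  nm <- attribute_names(attributes)
  data.frame(
    column = seq_along(att),
    attribute_id = att,
    attribute = nm[att],
    level = lev,
    name = paste0(nm[att], ".", lev),
    stringsAsFactors = FALSE
  )
}

#' Read or write an attribute dictionary as JSON
#'
#' The on-disk format is a JSON array of `{name, levels}` objects.
#'
#' @param path file path.
#' @return `read_attributes` returns a [dce_attributes] object;
#'   `write_attributes` returns `path` invisibly.
#' @export
read_attributes <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!length(raw)) stopf("attribute file '%s' is empty", path)
  dce_attributes(
    vapply(raw, function(a) as.character(a$name %||% ""), character(1)),
    lapply(raw, function(a) unlist(a$levels, use.names = FALSE))
  )
}

#' @rdname read_attributes
#' @param attributes a [dce_attributes] dictionary.
#' @export
write_attributes <- function(attributes, path) {
  stopifnot(inherits(attributes, "dce_attributes"))
  out <- lapply(attributes, function(a) list(name = a$name, levels = a$levels))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
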