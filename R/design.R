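#' Configuration of a partial-profile choice design
#'
#' Describes the survey instrument: how many randomized versions to build,
#' how many experimental tasks each version holds, how many alternatives a
#' task presents, and how many of the attributes each task shows (the
#' partial-profile subset). Hold-out positions mark where fixed validation
#' tasks are spliced into the task sequence.
#'
#' @param n_versions number of randomized survey versions.
#' @param tasks_per_version experimental choice tasks per version.
#' @param alternatives_per_task alternatives shown in each task.
#' @param attributes_per_task attributes defining each task's alternatives.
#' @param holdout_positions 1-based positions of fixed hold-out tasks in
#'   the final task sequence (may be empty).
#' @param seed integer seed; each version draws from its own RNG stream
#'   derived from `(seed, version)`.
#' @return A `design_config` list.
#' @export
design_config <- function(n_versions = 1L, tasks_per_version = 18L,
                          alternatives_per_task = 3L,
                          attributes_per_task = 3L,
                          holdout_positions = integer(),
                          seed = 1L) {
  cfg <- list(
    n_versions = as.integer(n_versions),
    tasks_per_version = as.integer(tasks_per_version),
    alternatives_per_task = as.integer(alternatives_per_task),
    attributes_per_task = as.integer(attributes_per_task),
    holdout_positions = as.integer(holdout_positions),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_versions < 1L || tasks_per_version < 1L ||
        alternatives_per_task < 2L || attributes_per_task < 1L) {
      stopf("design_config: counts must be positive (>= 2 alternatives)")
    }
    if (anyDuplicated(holdout_positions)) {
      stopf("design_config: duplicate holdout positions")
    }
    n_slots <- tasks_per_version + length(holdout_positions)
    if (length(holdout_positions) &&
        (min(holdout_positions) < 1L || max(holdout_positions) > n_slots)) {
      stopf("design_config: holdout positions outside 1..%d", n_slots)
    }
  })
  structure(cfg, class = "design_config")
}

validate_design_config <- function(attributes, config) {
  stopifnot(inherits(attributes, "dce_attributes"),
            inherits(config, "design_config"))
  K <- n_levels(attributes)
  if (config$attributes_per_task > length(attributes)) {
    stopf("attributes_per_task (%d) exceeds the %d available attributes",
          config$attributes_per_task, length(attributes))
  }
  if (config$alternatives_per_task > min(K)) {
    stopf(paste0("alternatives_per_task (%d) exceeds the smallest level ",
                 "count (%d); no-overlap assignment is impossible"),
          config$alternatives_per_task, min(K))
  }
  invisible(TRUE)
}

# empty long-format design skeleton
design_frame <- function(attributes, n_rows) {
  nm <- attribute_names(attributes)
  base <- data.frame(
    version = integer(n_rows), position = integer(n_rows),
    is_holdout = logical(n_rows), alternative = integer(n_rows)
  )
  for (a in nm) base[[a]] <- rep(NA_integer_, n_rows)
  base
}

as_dce_design <- function(df, attributes) {
  structure(df, class = c("dce_design", "data.frame"),
            attributes = attributes)
}

design_attributes <- function(design) {
  at <- attr(design, "attributes")
  if (is.null(at)) stopf("design lacks its attribute dictionary")
  at
}

#' Generate a randomized partial-profile choice design
#'
#' Builds `n_versions` independent survey versions. Within a version, each
#' task shows `attributes_per_task` attributes chosen by a least-shown-first
#' rule (so attribute display counts differ by at most one per version) and
#' assigns each shown attribute `alternatives_per_task` pairwise-distinct
#' levels, preferring the least-shown levels and randomizing their order
#' across alternatives. The no-overlap rule — within a task, a shown
#' attribute takes a different level in every alternative — holds by
#' construction. Each version draws from its own RNG stream derived from
#' `(seed, version)`, so the design is reproducible version by version.
#'
#' @param attributes a [dce_attributes] dictionary.
#' @param config a [design_config].
#' @return A `dce_design`: a long data frame with one row per
#'   (version, position, alternative); columns `version`, `position`,
#'   `is_holdout`, `alternative`, then one integer column per attribute
#'   holding the 1-based level index shown, or `NA` when the attribute is
#'   not part of the task.
#' @examples
#' attrs <- dce_attributes(paste0("a", 1:5), rep(list(as.character(1:4)), 5))
#' des <- generate_design(attrs, design_config(n_versions = 2, seed = 7))
#' head(des)
#' @export
generate_design <- function(attributes, config) {
  validate_design_config(attributes, config)
  n_attr <- length(attributes)
  K <- n_levels(attributes)
  n_alt <- config$alternatives_per_task
  n_task <- config$tasks_per_version
  rows_per_version <- n_task * n_alt
  out <- design_frame(attributes, config$n_versions * rows_per_version)
  nm <- attribute_names(attributes)

  for (v in seq_len(config$n_versions)) {
    vrows <- (v - 1L) * rows_per_version + seq_len(rows_per_version)
    grid <- with_seed(derive_seed(config$seed, v), {
      attr_count <- integer(n_attr)
      level_count <- lapply(K, function(k) integer(k))
      g <- matrix(NA_integer_, nrow = rows_per_version, ncol = n_attr)
      for (task in seq_len(n_task)) {
        # least-shown attributes first, random among ties
        ord <- order(attr_count, stats::runif(n_attr))
        shown <- ord[seq_len(config$attributes_per_task)]
        attr_count[shown] <- attr_count[shown] + 1L
        trows <- (task - 1L) * n_alt + seq_len(n_alt)
        for (a in shown) {
          lord <- order(level_count[[a]], stats::runif(K[a]))
          levs <- sample(lord[seq_len(n_alt)])
          g[trows, a] <- levs
          level_count[[a]][levs] <- level_count[[a]][levs] + 1L
        }
      }
      g
    })
    out$version[vrows] <- v
    out$position[vrows] <- rep(seq_len(n_task), each = n_alt)
    out$alternative[vrows] <- rep(seq_len(n_alt), n_task)
    for (a in seq_len(n_attr)) out[[nm[a]]][vrows] <- grid[, a]
  }
  as_dce_design(out, attributes)
}

#' Generate fixed hold-out tasks
#'
#' Hold-out tasks are built once, from their own seed, and shown
#' identically to every respondent; they are excluded from the balance
#' targets of the experimental design.
#'
#' @param attributes a [dce_attributes] dictionary.
#' @param n_tasks number of hold-out tasks.
#' @param config a [design_config] (for alternatives/attributes per task).
#' @param seed dedicated integer seed.
#' @return A `dce_design` with `n_tasks` tasks (version 0, `is_holdout`
#'   set), positions 1..n_tasks to be remapped by [attach_holdouts()].
#' @export
generate_holdout_tasks <- function(attributes, n_tasks, config, seed) {
  hcfg <- design_config(
    n_versions = 1L, tasks_per_version = n_tasks,
    alternatives_per_task = config$alternatives_per_task,
    attributes_per_task = config$attributes_per_task,
    seed = seed
  )
  h <- generate_design(attributes, hcfg)
  h$version <- 0L
  h$is_holdout <- TRUE
  h
}

#' Splice hold-out tasks into every version of a design
#'
#' Inserts the given hold-out tasks at fixed 1-based positions of each
#' version's task sequence, renumbering positions so experimental tasks
#' keep their relative order. The hold-out content is identical across
#' versions.
#'
#' @param design experimental `dce_design` (no hold-outs).
#' @param holdouts `dce_design` holding the hold-out tasks (one version).
#' @param positions 1-based positions for the hold-outs in the combined
#'   sequence; `length(positions)` must equal the number of hold-out tasks.
#' @return A `dce_design` in which every version has
#'   `tasks_per_version + length(positions)` tasks, with `is_holdout` set
#'   at exactly `positions`.
#' @export
attach_holdouts <- function(design, holdouts, positions) {
  attributes <- design_attributes(design)
  positions <- as.integer(positions)
  if (anyDuplicated(positions)) stopf("duplicate holdout positions")
  h_pos <- sort(unique(holdouts$position))
  if (length(h_pos) != length(positions)) {
    stopf("%d holdout task(s) but %d position(s)",
          length(h_pos), length(positions))
  }
  if (!length(positions)) return(design)

  exp_pos <- sort(unique(design$position))
  n_slots <- length(exp_pos) + length(positions)
  if (min(positions) < 1L || max(positions) > n_slots) {
    stopf("holdout positions must lie in 1..%d", n_slots)
  }
  slot_is_holdout <- seq_len(n_slots) %in% positions
  exp_slots <- which(!slot_is_holdout)

  versions <- sort(unique(design$version))
  pieces <- vector("list", length(versions))
  nm <- attribute_names(attributes)
  keep <- c("version", "position", "is_holdout", "alternative", nm)
  for (i in seq_along(versions)) {
    v <- versions[i]
    vd <- design[design$version == v, keep, drop = FALSE]
    vd$position <- exp_slots[match(vd$position, exp_pos)]
    hd <- holdouts[, keep, drop = FALSE]
    hd$version <- v
    hd$position <- positions[match(hd$position, h_pos)]
    hd$is_holdout <- TRUE
    piece <- rbind(vd, hd)
    pieces[[i]] <- piece[order(piece$position, piece$alternative), ,
                         drop = FALSE]
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  as_dce_design(out, attributes)
}

#' Tally level exposure and attribute co-occurrence in a design
#'
#' @param design a `dce_design`.
#' @return A list with `level_counts` (attribute x level matrix of level
#'   appearances, zero rows kept for attributes never shown),
#'   `task_counts` (tasks showing each attribute) and `cooccurrence`
#'   (attribute x attribute matrix of tasks showing both).
#' @export
design_balance_report <- function(design) {
  attributes <- design_attributes(design)
  if (!nrow(design)) stopf("empty design")
  nm <- attribute_names(attributes)
  K <- n_levels(attributes)
  level_counts <- matrix(0L, nrow = length(nm), ncol = max(K),
                         dimnames = list(nm, paste0("level", seq_len(max(K)))))
  task_key <- paste(design$version, design$position)
  task_counts <- stats::setNames(integer(length(nm)), nm)
  shown <- matrix(FALSE, nrow = length(unique(task_key)), ncol = length(nm))
  task_idx <- match(task_key, unique(task_key))
  for (a in seq_along(nm)) {
    lv <- design[[nm[a]]]
    tab <- tabulate(lv[!is.na(lv)], nbins = max(K))
    level_counts[a, ] <- tab
    shown[, a] <- as.logical(
      rowsum(as.integer(!is.na(lv)), task_idx, reorder = TRUE)
    )
    task_counts[a] <- sum(shown[, a])
  }
  cooc <- crossprod(shown)
  dimnames(cooc) <- list(nm, nm)
  list(level_counts = level_counts, task_counts = task_counts,
       cooccurrence = cooc)
}

#' Read or write a design as delimited text
#'
#' One CSV row per (version, position, alternative): `version`, `position`,
#' `is_holdout`, `alternative`, then one column per attribute with the
#' 1-based level index, empty when the attribute is not shown.
#'
#' @param design a `dce_design`.
#' @param path file path.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_design
#' @param attributes a [dce_attributes] dictionary.
#' @export
read_design <- function(path, attributes) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- attribute_names(attributes)
  need <- c("version", "position", "is_holdout", "alternative", nm)
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("design file missing columns: %s",
                          paste(miss, collapse = ", "))
  df$is_holdout <- as.logical(df$is_holdout)
  K <- n_levels(attributes)
  for (a in seq_along(nm)) {
    lv <- suppressWarnings(as.integer(df[[nm[a]]]))
    bad <- which(!is.na(lv) & (lv < 1L | lv > K[a]))
    if (length(bad)) stopf("design file row %d: level %d invalid for '%s'",
                           bad[1], lv[bad[1]], nm[a])
    df[[nm[a]]] <- lv
  }
  as_dce_design(df[, need], attributes)
}
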