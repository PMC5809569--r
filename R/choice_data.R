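#' Effects-code design rows
#'
#' Effects (deviation) coding gives an attribute with K levels K - 1
#' columns: level l < K is the indicator of its own column, the last
#' listed level is coded -1 on all K - 1 columns, and an attribute not
#' shown in a partial-profile task contributes zeros. Coefficients on this
#' scale are the first K - 1 zero-centered level utilities; the omitted
#' level's utility is minus their sum.
#'
#' @param rows design-format rows (as in [generate_design()] output): one
#'   row per alternative with one integer level column per attribute.
#' @param attributes a [dce_attributes] dictionary.
#' @return Numeric matrix with `nrow(rows)` rows and `sum(K - 1)` columns,
#'   entries in \{-1, 0, 1\}, with the [effects_columns()] layout.
#' @examples
#' attrs <- dce_attributes("a", list(as.character(1:4)))
#' rows <- data.frame(a = c(1L, 4L))
#' effects_code(rows, attrs)  # (1,0,0) and (-1,-1,-1)
#' @export
effects_code <- function(rows, attributes) {
  stopifnot(inherits(attributes, "dce_attributes"))
  cmap <- effects_columns(attributes)
  K <- n_levels(attributes)
  nm <- attribute_names(attributes)
  X <- matrix(0, nrow = nrow(rows), ncol = nrow(cmap),
              dimnames = list(NULL, cmap$name))
  for (a in seq_along(nm)) {
    if (!nm[a] %in% names(rows)) stopf("missing attribute column '%s'", nm[a])
    lv <- rows[[nm[a]]]
    bad <- which(!is.na(lv) & (lv < 1L | lv > K[a]))
    if (length(bad)) {
      stopf("row %d: level %d is not valid for attribute '%s' (K = %d)",
            bad[1], lv[bad[1]], nm[a], K[a])
    }
    cols <- which(cmap$attribute_id == a)
    for (l in seq_len(K[a] - 1L)) {
      X[which(!is.na(lv) & lv == l), cols[l]] <- 1
    }
    ref <- which(!is.na(lv) & lv == K[a])
    if (length(ref)) X[ref, cols] <- -1
  }
  X
}

#' Assemble a choice dataset
#'
#' Couples a design with one observed choice per respondent-task.
#'
#' @param design a `dce_design` covering every task referenced.
#' @param observations data frame with columns `respondent_id`, `version`,
#'   `position`, `chosen` (1-based chosen alternative).
#' @param attributes optional [dce_attributes]; defaults to the design's.
#' @return A `choice_data` object: list of `attributes`, `design`,
#'   `observations`.
#' @export
choice_dataset <- function(design, observations, attributes = NULL) {
  attributes <- attributes %||% design_attributes(design)
  need <- c("respondent_id", "version", "position", "chosen")
  miss <- setdiff(need, names(observations))
  if (length(miss)) stopf("observations missing columns: %s",
                          paste(miss, collapse = ", "))
  observations <- observations[, need]
  observations$respondent_id <- as.character(observations$respondent_id)

  task_key <- unique(paste(design$version, design$position))
  obs_key <- paste(observations$version, observations$position)
  unknown <- which(!obs_key %in% task_key)
  if (length(unknown)) {
    stopf("observation %d references unknown task (version %s, position %s)",
          unknown[1], observations$version[unknown[1]],
          observations$position[unknown[1]])
  }
  full_key <- paste(observations$respondent_id, obs_key)
  if (anyDuplicated(full_key)) {
    d <- full_key[duplicated(full_key)][1]
    stopf("duplicate observation for respondent-task '%s'", d)
  }
  vers <- tapply(observations$version, observations$respondent_id,
                 function(v) length(unique(v)))
  if (any(vers > 1L)) {
    stopf("respondent '%s' references more than one survey version",
          names(vers)[which(vers > 1L)[1]])
  }
  n_alt <- tapply(design$alternative, paste(design$version, design$position),
                  max)
  bad <- which(observations$chosen < 1L |
                 observations$chosen > n_alt[obs_key])
  if (length(bad)) {
    stopf("observation %d: chosen alternative %d out of range", bad[1],
          observations$chosen[bad[1]])
  }
  structure(list(attributes = attributes, design = design,
                 observations = observations),
            class = "choice_data")
}

#' @export
print.choice_data <- function(x, ...) {
  cat(sprintf(
    "Choice dataset: %d respondents, %d observations, %d tasks (%d holdout)\n",
    length(unique(x$observations$respondent_id)), nrow(x$observations),
    length(unique(paste(x$design$version, x$design$position))),
    length(unique(paste(x$design$version,
                        x$design$position)[x$design$is_holdout]))
  ))
  invisible(x)
}

#' Number of respondents in a choice dataset
#' @param dataset a `choice_data` object.
#' @export
n_respondents <- function(dataset) {
  length(unique(dataset$observations$respondent_id))
}

#' Write a choice dataset to delimited text
#'
#' One CSV row per (respondent, task, alternative): `respondent_id`,
#' `version`, `position`, `is_holdout`, `alternative`, `chosen` (0/1),
#' then one column per attribute with the shown level (1-based index, or
#' label when `labels = TRUE`); empty when the attribute is not shown.
#'
#' @param dataset a `choice_data` object.
#' @param path file path.
#' @param labels write level labels instead of indices.
#' @export
write_choices <- function(dataset, path, labels = FALSE) {
  at <- dataset$attributes
  nm <- attribute_names(at)
  des <- dataset$design
  obs <- dataset$observations
  des_key <- paste(des$version, des$position)
  obs_key <- paste(obs$version, obs$position)
  by_task <- split(seq_len(nrow(des)), des_key)
  idx <- by_task[obs_key]
  reps <- lengths(idx)
  drow <- unlist(idx, use.names = FALSE)
  out <- data.frame(
    respondent_id = rep(obs$respondent_id, reps),
    version = des$version[drow],
    position = des$position[drow],
    is_holdout = des$is_holdout[drow],
    alternative = des$alternative[drow],
    chosen = as.integer(des$alternative[drow] ==
                          rep(obs$chosen, reps)),
    stringsAsFactors = FALSE
  )
  for (a in seq_along(nm)) {
    lv <- des[[nm[a]]][drow]
    out[[nm[a]]] <- if (labels) at[[a]]$levels[lv] else lv
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# decode one attribute column that may hold indices or labels
decode_levels <- function(x, levels, column, mode) {
  filled <- !is.na(x) & nzchar(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  if (!any(filled)) return(list(levels = out, mode = mode))
  ch <- trimws(as.character(x[filled]))
  as_int <- suppressWarnings(as.integer(ch))
  this_mode <- if (all(!is.na(as_int))) "index" else "label"
  if (any(!is.na(as_int)) && this_mode == "label") {
    # a column mixing numerals with text labels is ambiguous
    if (!all(ch[!is.na(as_int)] %in% levels)) {
      stopf("column '%s' mixes numeric indices with text labels", column)
    }
  }
  if (!is.na(mode) && mode != this_mode) {
    stopf("file mixes level indices and labels across columns ('%s')",
          column)
  }
  if (this_mode == "index") {
    bad <- which(as_int < 1L | as_int > length(levels))
    if (length(bad)) {
      stopf("column '%s': level index %d out of range", column, as_int[bad[1]])
    }
    out[filled] <- as_int
  } else {
    m <- match(ch, levels)
    if (anyNA(m)) {
      stopf("column '%s': unknown level label '%s'", column,
            ch[which(is.na(m))[1]])
    }
    out[filled] <- m
  }
  list(levels = out, mode = this_mode)
}

#' Read a choice dataset from delimited text
#'
#' Reads the long format written by [write_choices()]. Levels may be given
#' as 1-based indices or as text labels, but not a mixture within one
#' file. Each (respondent, version, position) group must contain exactly
#' one `chosen = 1` row; violations are reported with the offending task.
#'
#' @param path file path.
#' @param attributes a [dce_attributes] dictionary.
#' @return A `choice_data` object.
#' @export
read_choices <- function(path, attributes) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  nm <- attribute_names(attributes)
  need <- c("respondent_id", "version", "position", "is_holdout",
            "alternative", "chosen", nm)
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("choice file missing columns: %s",
                          paste(miss, collapse = ", "))
  to_int <- function(col) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stopf("line %d: column '%s' is not an integer", bad[1] + 1L, col)
    }
    v
  }
  df$version <- to_int("version")
  df$position <- to_int("position")
  df$alternative <- to_int("alternative")
  df$chosen <- to_int("chosen")
  if (any(!df$chosen %in% c(0L, 1L))) {
    stopf("line %d: 'chosen' must be 0 or 1",
          which(!df$chosen %in% c(0L, 1L))[1] + 1L)
  }
  hl <- trimws(toupper(df$is_holdout))
  df$is_holdout <- hl %in% c("TRUE", "T", "1")

  mode <- NA_character_
  for (a in seq_along(nm)) {
    dec <- decode_levels(df[[nm[a]]], attributes[[a]]$levels, nm[a], mode)
    df[[nm[a]]] <- dec$levels
    if (!is.na(dec$mode)) mode <- dec$mode
  }

  # exactly one chosen row per respondent-task
  grp <- paste(df$respondent_id, df$version, df$position)
  nch <- rowsum(df$chosen, grp, reorder = FALSE)
  off <- which(nch[, 1] != 1L)
  if (length(off)) {
    stopf("task '%s' has %d chosen alternatives (expected 1)",
          rownames(nch)[off[1]], nch[off[1], 1])
  }

  # reconstruct the design from unique tasks; content must be consistent
  task_cols <- c("version", "position", "is_holdout", "alternative", nm)
  des <- unique(df[, task_cols])
  ka <- paste(des$version, des$position, des$alternative)
  if (anyDuplicated(ka)) {
    stopf("task (version %s, position %s) appears with conflicting content",
          des$version[duplicated(ka)][1], des$position[duplicated(ka)][1])
  }
  des <- des[order(des$version, des$position, des$alternative), ]
  rownames(des) <- NULL
  design <- as_dce_design(des, attributes)

  ch <- df[df$chosen == 1L,
           c("respondent_id", "version", "position", "alternative")]
  names(ch)[4] <- "chosen"
  ch <- ch[order(ch$respondent_id, ch$version, ch$position), ]
  rownames(ch) <- NULL
  choice_dataset(design, ch, attributes)
}

#' Split a dataset into estimation and hold-out parts
#'
#' Responses to tasks flagged `is_holdout` are removed from the data
#' before estimation and kept aside for predictive validation.
#'
#' @param dataset a `choice_data` object.
#' @return List of two `choice_data` objects, `estimation` and `holdout`;
#'   together they partition the input observations exactly.
#' @export
split_holdout <- function(dataset) {
  des <- dataset$design
  key <- paste(des$version, des$position)
  hold_keys <- unique(key[des$is_holdout])
  obs_key <- paste(dataset$observations$version,
                   dataset$observations$position)
  in_hold <- obs_key %in% hold_keys
  mk <- function(obs, rows) {
    d <- as_dce_design(des[rows, , drop = FALSE], dataset$attributes)
    structure(list(attributes = dataset$attributes, design = d,
                   observations = obs),
              class = "choice_data")
  }
  list(
    estimation = mk(dataset$observations[!in_hold, , drop = FALSE],
                    !des$is_holdout),
    holdout = mk(dataset$observations[in_hold, , drop = FALSE],
                 des$is_holdout)
  )
}

# --- estimation indexing -------------------------------------------------
# Precomputes the effects-coded matrix over the tasks respondents actually
# answered, plus integer maps from observations to matrix rows. All
# estimation and simulation hot paths work off this structure.
estimation_index <- function(dataset) {
  at <- dataset$attributes
  des <- dataset$design
  obs <- dataset$observations
  if (!nrow(obs)) stopf("dataset has no observations")

  des_key <- paste(des$version, des$position)
  obs_key <- paste(obs$version, obs$position)
  used <- unique(obs_key)
  keep <- des_key %in% used
  d <- des[keep, , drop = FALSE]
  dk <- des_key[keep]
  ord <- order(match(dk, used), d$alternative)
  d <- d[ord, , drop = FALSE]
  dk <- dk[ord]

  row_task <- match(dk, used)
  n_tasks <- length(used)
  task_sizes <- tabulate(row_task, nbins = n_tasks)
  task_start <- c(0L, cumsum(task_sizes))[seq_len(n_tasks)]
  X <- effects_code(d, at)

  resp_ids <- unique(obs$respondent_id)
  obs_resp <- match(obs$respondent_id, resp_ids)
  obs_task <- match(obs_key, used)
  # chosen alternative -> row of X; within each task block alternatives
  # are sorted ascending and must be exactly 1..n_alt
  stopifnot(all(d$alternative ==
                  unlist(lapply(task_sizes, seq_len), use.names = FALSE)))
  chosen_row <- task_start[obs_task] + obs$chosen

  # CSR view of X for the compiled conditional-logit kernels
  nz <- which(X != 0, arr.ind = TRUE)
  o <- order(nz[, 1L], nz[, 2L])
  ri <- nz[o, 1L]
  rowptr <- c(0L, cumsum(tabulate(ri, nbins = nrow(X))))
  colidx <- nz[o, 2L] - 1L
  val <- X[cbind(ri, nz[o, 2L])]

  list(
    X = X, P = ncol(X), column_map = effects_columns(at),
    row_task = row_task, n_tasks = n_tasks, task_sizes = task_sizes,
    taskptr = c(0L, cumsum(task_sizes)),
    rowptr = as.integer(rowptr), colidx = as.integer(colidx), val = val,
    const_nalt = length(unique(task_sizes)) == 1L,
    n_alt = task_sizes[1],
    obs_resp = obs_resp, obs_task = obs_task, chosen_row = chosen_row,
    n_resp = length(resp_ids), resp_ids = resp_ids, n_obs = nrow(obs),
    attributes = at
  )
}
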