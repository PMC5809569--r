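test_that("effects coding follows the deviation-coding conventions", {
  at <- dce_attributes("a", list(paste0("x", 1:4)))
  X <- effects_code(data.frame(a = c(1L, 2L, 3L, 4L, NA)), at)
  expect_equal(unname(X[1, ]), c(1, 0, 0))
  expect_equal(unname(X[2, ]), c(0, 1, 0))
  expect_equal(unname(X[3, ]), c(0, 0, 1))
  expect_equal(unname(X[4, ]), c(-1, -1, -1))
  expect_equal(unname(X[5, ]), c(0, 0, 0))      # attribute not shown
  # zero-sum: one row per level sums to the zero vector
  expect_equal(unname(colSums(X[1:4, ])), c(0, 0, 0))
  expect_error(effects_code(data.frame(a = 5L), at), "not valid")
})

test_that("partial-profile rows are nonzero only in shown attributes,
           cell for cell", {
  at <- study_presets()$attributes
  nm <- vapply(at, `[[`, "", "name")
  des <- generate_design(at, design_config(tasks_per_version = 6L, seed = 13L))
  X <- effects_code(des, at)
  cmap <- effects_columns(at)
  # independent per-cell recoding oracle
  for (r in seq_len(nrow(des))) {
    for (j in seq_len(ncol(X))) {
      lv <- des[[cmap$attribute[j]]][r]
      expected <- if (is.na(lv)) 0
      else if (lv == 4L) -1
      else if (lv == cmap$level[j]) 1
      else 0
      expect_identical(unname(X[r, j]), expected)
    }
  }
  # exactly 3 shown attributes -> nonzeros confined to their 9 columns
  shown <- !is.na(des[1, nm])
  live <- cmap$attribute %in% nm[shown]
  expect_true(all(X[1, !live] == 0))
})

test_that("choice data survive a write/read round trip", {
  sim <- simulate_respondents(toy_synth_config(n = 5L, seed = 3L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_choices(sim$dataset, path)
  back <- read_choices(path, sim$dataset$attributes)
  expect_equal(back$observations[order(back$observations$respondent_id,
                                       back$observations$position), ],
               sim$dataset$observations[order(
                 sim$dataset$observations$respondent_id,
                 sim$dataset$observations$position), ],
               ignore_attr = TRUE)
  # label-mode writing reads back identically too
  write_choices(sim$dataset, path, labels = TRUE)
  back2 <- read_choices(path, sim$dataset$attributes)
  expect_equal(back2$observations, back$observations, ignore_attr = TRUE)
})

test_that("malformed choice files are rejected with their location", {
  at <- dce_attributes(c("a", "b"), list(paste0("a", 1:3), paste0("b", 1:3)))
  hdr <- "respondent_id,version,position,is_holdout,alternative,chosen,a,b"
  ok <- c("R1,1,1,FALSE,1,1,1,2", "R1,1,1,FALSE,2,0,2,1")
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c(hdr, sub(",0,2,1", ",1,2,1", ok[2]), ok[1]), path)
  expect_error(read_choices(path, at), "2 chosen")

  writeLines(c(hdr, ok[1], "R1,1,1,FALSE,2,0,b2,b1"), path)
  expect_error(read_choices(path, at), "mixes")

  writeLines(c(hdr, ok[1], "R1,1,1,FALSE,2,0,2,9"), path)
  expect_error(read_choices(path, at), "out of range")

  writeLines(c(hdr, ok[1], "R1,1,x,FALSE,2,0,2,1"), path)
  expect_error(read_choices(path, at), "line 3")
})

test_that("dataset validation catches duplicate and cross-version records", {
  sim <- simulate_respondents(toy_synth_config(n = 4L, seed = 6L))
  ds <- sim$dataset
  dup <- rbind(ds$observations, ds$observations[1, ])
  expect_error(choice_dataset(ds$design, dup, ds$attributes), "duplicate")
  two <- ds$observations
  # move one record of the first respondent to a different (valid) version
  two$version[1] <- two$version[1] %% 5L + 1L
  expect_error(choice_dataset(ds$design, two, ds$attributes),
               "version|unknown task")
})

test_that("hold-out split partitions the study layout 18 + 2", {
  sim <- simulate_respondents(
    study_config(seed = 5L, n_respondents = 40L, n_versions = 10L))
  parts <- split_holdout(sim$dataset)
  per_resp <- table(parts$estimation$observations$respondent_id)
  expect_true(all(per_resp == 18L))
  per_resp_h <- table(parts$holdout$observations$respondent_id)
  expect_true(all(per_resp_h == 2L))
  # the two partitions reconstruct the input exactly
  both <- rbind(parts$estimation$observations, parts$holdout$observations)
  key <- function(o) sort(paste(o$respondent_id, o$position, o$chosen))
  expect_identical(key(both), key(sim$dataset$observations))
  # no hold-outs at all -> empty second partition
  nohold <- toy_synth_config(n = 5L, holdouts = integer())
  parts2 <- split_holdout(simulate_respondents(nohold)$dataset)
  expect_equal(nrow(parts2$holdout$observations), 0L)
})

test_that("study-sized files parse with the expected row arithmetic", {
  sim <- simulate_respondents(
    study_config(seed = 2L, n_respondents = 563L, n_versions = 25L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_choices(sim$dataset, path)
  raw <- utils::read.csv(path)
  expect_equal(nrow(raw), 563L * 20L * 3L)   # 33,780 alternative rows
  back <- read_choices(path, sim$dataset$attributes)
  expect_equal(nrow(back$observations), 563L * 20L)
  expect_equal(n_respondents(back), 563L)
})
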