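test_that("generated tasks satisfy the no-overlap rule on the study layout", {
  at <- study_presets()$attributes
  cfg <- design_config(n_versions = 1L, tasks_per_version = 18L,
                       alternatives_per_task = 3L, attributes_per_task = 3L,
                       seed = 7L)
  des <- generate_design(at, cfg)
  nm <- vapply(at, `[[`, "", "name")
  expect_equal(length(unique(des$position)), 18L)
  for (pos in unique(des$position)) {
    rows <- des[des$position == pos, nm]
    shown <- names(rows)[colSums(!is.na(rows)) > 0]
    expect_length(shown, 3L)
    for (a in shown) {
      lv <- rows[[a]]
      expect_false(anyNA(lv))
      expect_length(unique(lv), 3L)  # pairwise-distinct levels
    }
    # unshown attributes are fully absent from the task
    expect_true(all(colSums(!is.na(rows)) %in% c(0L, 3L)))
  }
})

test_that("two binary attributes admit only the permutation assignments", {
  at <- dce_attributes(c("a", "b"), list(c("a1", "a2"), c("b1", "b2")))
  for (s in 1:10) {
    cfg <- design_config(n_versions = 1L, tasks_per_version = 1L,
                         alternatives_per_task = 2L,
                         attributes_per_task = 2L, seed = s)
    des <- generate_design(at, cfg)
    for (col in c("a", "b")) expect_setequal(des[[col]], 1:2)
  }
})

test_that("impossible configurations are rejected", {
  at <- dce_attributes(c("a", "b"), list(c("a1", "a2"), c("b1", "b2")))
  expect_error(generate_design(at, design_config(alternatives_per_task = 3L,
                                                 attributes_per_task = 2L)),
               "no-overlap")
  expect_error(generate_design(at, design_config(alternatives_per_task = 2L,
                                                 attributes_per_task = 3L)),
               "exceeds")
})

test_that("designs are reproducible from the seed, version by version", {
  at <- toy_attributes()
  cfg <- design_config(n_versions = 4L, tasks_per_version = 10L, seed = 11L)
  d1 <- generate_design(at, cfg)
  d2 <- generate_design(at, cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  # a version's content does not depend on how many other versions exist
  d3 <- generate_design(at, design_config(n_versions = 2L,
                                          tasks_per_version = 10L,
                                          seed = 11L))
  expect_identical(as.data.frame(d1[d1$version <= 2L, ]),
                   as.data.frame(d3))
})

test_that("attribute and level exposure is balanced, by independent tally", {
  at <- study_presets()$attributes
  nm <- vapply(at, `[[`, "", "name")
  cfg <- design_config(n_versions = 100L, tasks_per_version = 18L, seed = 3L)
  des <- generate_design(at, cfg)
  # per version, attribute show-counts differ by at most one
  for (v in c(1L, 37L, 100L)) {
    dv <- des[des$version == v, nm]
    shows <- colSums(!is.na(dv)) / 3L
    expect_lte(max(shows) - min(shows), 1L)
    expect_equal(sum(shows), 18L * 3L)
  }
  # across versions, per-level exposure is near uniform (brute-force tally)
  for (a in nm[c(1L, 8L, 14L)]) {
    tab <- table(factor(des[[a]], levels = 1:4))
    expect_equal(sum(tab), sum(!is.na(des[[a]])))
    expect_lt(max(tab) - min(tab), 0.1 * mean(tab) + 4)
  }
})

test_that("hold-out tasks are spliced at fixed positions, identically", {
  at <- toy_attributes()
  cfg <- design_config(n_versions = 3L, tasks_per_version = 18L, seed = 2L)
  des <- generate_design(at, cfg)
  hold <- generate_holdout_tasks(at, 2L, cfg, seed = 99L)
  full <- attach_holdouts(des, hold, c(6L, 14L))
  nm <- vapply(at, `[[`, "", "name")
  for (v in 1:3) {
    fv <- full[full$version == v, ]
    expect_equal(sort(unique(fv$position)), 1:20)
    expect_setequal(unique(fv$position[fv$is_holdout]), c(6L, 14L))
  }
  # identical hold-out content across versions
  h1 <- full[full$is_holdout & full$version == 1L, c("position",
                                                     "alternative", nm)]
  for (v in 2:3) {
    hv <- full[full$is_holdout & full$version == v, c("position",
                                                      "alternative", nm)]
    expect_equal(unname(as.list(h1)), unname(as.list(hv)))
  }
  # relative order of experimental tasks preserved
  v1 <- full[full$version == 1L & !full$is_holdout & full$alternative == 1L, ]
  o1 <- des[des$version == 1L & des$alternative == 1L, nm]
  expect_equal(unname(as.list(v1[order(v1$position), nm])),
               unname(as.list(o1)))
})

test_that("hold-out splicing validates its inputs", {
  at <- toy_attributes()
  cfg <- design_config(n_versions = 1L, tasks_per_version = 18L, seed = 2L)
  des <- generate_design(at, cfg)
  hold <- generate_holdout_tasks(at, 2L, cfg, seed = 99L)
  expect_error(attach_holdouts(des, hold, c(6L, 25L)), "1\\.\\.20")
  expect_error(attach_holdouts(des, hold, c(6L, 6L)), "duplicate")
  expect_error(attach_holdouts(des, hold, 6L), "position")
  expect_identical(attach_holdouts(des, hold[0, ], integer()), des)
})

test_that("balance report counts match a brute-force re-tally", {
  at <- dce_attributes(c("a", "b", "c"),
                       list(paste0("a", 1:4), paste0("b", 1:4),
                            paste0("c", 1:4)))
  # single handmade task showing only attribute a with levels 1..3
  des <- data.frame(version = 1L, position = 1L, is_holdout = FALSE,
                    alternative = 1:3, a = 1:3, b = NA_integer_,
                    c = NA_integer_)
  des <- dcemix:::as_dce_design(des, at)
  rep1 <- design_balance_report(des)
  expect_equal(unname(rep1$level_counts["a", ]), c(1L, 1L, 1L, 0L))
  expect_equal(unname(rep1$level_counts["b", ]), rep(0L, 4))  # zero row kept
  expect_equal(unname(rep1$task_counts), c(1L, 0L, 0L))

  cfg <- design_config(n_versions = 6L, tasks_per_version = 8L, seed = 4L)
  des2 <- generate_design(at, cfg)
  rep2 <- design_balance_report(des2)
  for (nm in c("a", "b", "c")) {
    expect_equal(sum(rep2$level_counts[nm, ]),
                 rep2$task_counts[[nm]] * 3L)   # appearances x alternatives
    expect_equal(unname(rep2$level_counts[nm, ]),
                 unname(c(table(factor(des2[[nm]], levels = 1:4)))))
  }
})

test_that("a design survives a CSV round trip", {
  at <- toy_attributes()
  cfg <- design_config(n_versions = 2L, tasks_per_version = 6L,
                       holdout_positions = c(3L), seed = 9L)
  des <- generate_design(at, design_config(n_versions = 2L,
                                           tasks_per_version = 6L, seed = 9L))
  hold <- generate_holdout_tasks(at, 1L, cfg, seed = 10L)
  full <- attach_holdouts(des, hold, 3L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(full, path)
  back <- read_design(path, at)
  expect_equal(as.data.frame(back), as.data.frame(full))
})
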