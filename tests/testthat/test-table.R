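test_that("single-key sorting orders ascending with ties by record id", {
  df <- data.frame(record_id = 1:4, p1 = c(3, 1, 2, 1), m1 = 0)
  tab <- result_table(df, "p1", "m1")
  sorted <- multi_sort(tab, "p1")
  expect_identical(sorted$ordering, c(2L, 4L, 3L, 1L))
  # sorting on a constant column changes nothing (stability)
  sorted2 <- multi_sort(tab, "m1")
  expect_identical(sorted2$ordering, 1:4)
})

test_that("nested sorting reorders only within earlier bins", {
  # the nested step pattern: sort p2 then p1
  df <- data.frame(record_id = 1:4,
                   p2 = c("B", "A", "B", "A"), p1 = c(2, 2, 1, 1),
                   m1 = 0, stringsAsFactors = FALSE)
  tab <- result_table(df, c("p2", "p1"), "m1")
  tab <- multi_sort(tab, "p2")
  tab <- multi_sort(tab, "p1")
  got <- tab$records[tab$ordering, c("p2", "p1")]
  expect_identical(got$p2, c("A", "A", "B", "B"))
  expect_identical(got$p1, c(1, 2, 1, 2))
  expect_identical(tab$sort_keys, c("p2", "p1"))
})

test_that("sort errors: unknown or repeated key", {
  tab <- make_random_table(10)
  expect_error(multi_sort(tab, "nope"), "unknown column")
  expect_error(multi_sort(multi_sort(tab, "p1"), "p1"), "already")
})

test_that("multi_sort matches the lexicographic oracle on random tables", {
  for (seed in 1:25) {
    tab <- make_random_table(sample(5:120, 1), seed = seed)
    keys <- sample(c(tab$param_columns, tab$measure_columns),
                   sample(1:3, 1))
    for (k in keys) tab <- multi_sort(tab, k)
    expect_identical(tab$ordering, oracle_lex_sort(tab$records, keys),
                     info = paste("seed", seed))
    # bins of the first key are contiguous and internally ordered by later keys
    v <- tab$records[[keys[1]]][tab$ordering]
    expect_true(all(diff(order(v)) > 0) || !is.unsorted(v))
  }
})

test_that("smart sort picks the parameter with highest mean |Pearson r|", {
  # one measure is an exact linear function of p2: p2 must win
  set.seed(3)
  g <- expand_param_grid(list(parameter_spec("p1", 0, 1, 5),
                              parameter_spec("p2", 0, 1, 5)))
  df <- data.frame(record_id = seq_len(nrow(g)), g,
                   m1 = 2 * g$p2,
                   m2 = stats::rnorm(nrow(g), sd = 0.1))
  tab <- result_table(df, c("p1", "p2"), c("m1", "m2"))
  res <- smart_sort(tab)
  expect_identical(res$parameter, "p2")
  expect_identical(res$table$sort_keys, "p2")
  v <- res$table$records$p2[res$table$ordering]
  expect_false(is.unsorted(v))
})

test_that("smart sort degenerate cases follow the conventions", {
  df <- data.frame(record_id = 1:6, p1 = c(1, 2, 3, 4, 5, 6),
                   m1 = c(1, 1, 1, 1, 1, 1))
  tab <- result_table(df, "p1", "m1")
  # constant measures: all scores 0, leftmost (single) parameter chosen
  expect_identical(smart_sort(tab)$parameter, "p1")

  df2 <- data.frame(record_id = 1:6, p1 = 1, p2 = c(1, 1, 2, 2, 3, 3),
                    m1 = c(1, 1, 1, 1, 1, 1))
  tab2 <- result_table(df2, c("p1", "p2"), "m1")
  expect_identical(smart_sort(tab2)$parameter, "p1")  # tie -> leftmost

  one <- result_table(data.frame(record_id = 1L, p1 = 1, m1 = 1), "p1", "m1")
  expect_error(smart_sort(one), "at least 2")
})

test_that("smart sort matches the independent correlation oracle", {
  for (seed in 1:25) {
    tab <- make_random_table(sample(5:120, 1), n_params = 3, seed = 100 + seed)
    expect_identical(smart_sort(tab)$parameter, oracle_smart_choice(tab),
                     info = paste("seed", seed))
  }
})

test_that("variance weighting is available as the alternative aggregate", {
  set.seed(9)
  df <- data.frame(record_id = 1:20, p1 = stats::runif(20),
                   p2 = stats::runif(20))
  df$m_small <- df$p1 * 0.001 + stats::rnorm(20, sd = 1e-5)  # tiny variance
  df$m_big <- df$p2 * 100 + stats::rnorm(20, sd = 1)         # dominates
  tab <- result_table(df, c("p1", "p2"), c("m_small", "m_big"))
  expect_identical(smart_sort(tab, weighting = "variance")$parameter, "p2")
})

test_that("context selection returns the maximal run under the cursor", {
  df <- data.frame(record_id = 1:6, p1 = c(1, 1, 2, 2, 2, 3), m1 = 6:1)
  tab <- result_table(df, "p1", "m1")
  expect_identical(context_selection(tab, 4L, "p1"), 3:5)
  expect_identical(context_selection(tab, 1L, "p1"), 1:2)  # run at the top
  expect_identical(context_selection(tab, 6L, "p1"), 6L)   # singleton
  # distinct from both neighbours -> singleton
  expect_identical(context_selection(tab, 3L, "m1"), 3L)
  expect_error(context_selection(tab, 7L, "p1"), "invalid")
  tab2 <- filter_interval(tab, "p1", 2, 3)
  expect_error(context_selection(tab2, 1L, "p1"), "hidden")
})

test_that("context selection matches the maximal-run oracle and is contiguous", {
  for (seed in 1:25) {
    tab <- make_random_table(sample(5:120, 1), seed = 200 + seed)
    tab <- multi_sort(tab, sample(tab$param_columns, 1))
    col <- sample(c(tab$param_columns, tab$measure_columns), 1)
    disp <- tab$ordering[tab$visible[tab$ordering]]
    pos <- sample(seq_along(disp), 1)
    got <- context_selection(tab, disp[pos], col)
    vals <- tab$records[[col]][disp]
    expect_identical(got, disp[oracle_context_run(vals, pos)])
    # endpoints' neighbours differ in the cursor column
    run <- match(got, disp)
    if (min(run) > 1)
      expect_false(vals[min(run) - 1] == vals[pos])
    if (max(run) < length(disp))
      expect_false(vals[max(run) + 1] == vals[pos])
  }
})

test_that("interval filters are inclusive and compose by intersection", {
  df <- data.frame(record_id = 1:5, p1 = c(0, 0.25, 0.5, 0.75, 1),
                   m1 = c(5, 4, 3, 2, 1))
  tab <- result_table(df, "p1", "m1")
  full <- filter_interval(tab, "p1", 0, 1)
  expect_identical(full$visible, rep(TRUE, 5))  # spanning filter is a no-op
  f1 <- filter_interval(tab, "p1", 0.25, 0.75)
  expect_identical(which(f1$visible), 2:4)
  f2 <- filter_interval(f1, "m1", 3, 5)
  expect_identical(which(f2$visible), 2:3)  # intersection of both filters
  expect_error(filter_interval(tab, "p1", 1, 0), "<=")
  expect_identical(which(reset_filters(f2)$visible), 1:5)
})

test_that("selection is pruned to the visible set by filtering", {
  tab <- make_random_table(20, seed = 5)
  tab <- select_rows(tab, c(3L, 7L, 11L))
  med <- stats::median(tab$records$p1)
  tab2 <- filter_interval(tab, "p1", med, max(tab$records$p1))
  expect_true(all(tab2$visible[tab2$selection]))
  expect_true(all(tab2$selection %in% c(3L, 7L, 11L)))
})

test_that("filter and sort commute", {
  for (seed in 1:10) {
    tab <- make_random_table(60, seed = 300 + seed)
    a <- multi_sort(filter_interval(tab, "p1", 0.25, 0.75), "m1")
    b <- filter_interval(multi_sort(tab, "m1"), "p1", 0.25, 0.75)
    expect_identical(visible_records(a), visible_records(b))
  }
})

test_that("domain coverage reports the occupied parts of each domain", {
  df <- data.frame(record_id = 1:5, p1 = c(0, 0.25, 0.5, 0.75, 1),
                   m1 = c(1, 1, 1, 1, 1))
  tab <- result_table(df, "p1", "m1")
  cov_all <- domain_coverage(tab, 1:5, n_bins = 4)
  expect_equal(cov_all$p1, data.frame(lo = 0, hi = 1))  # full domain
  # constant column: single degenerate strip
  expect_equal(cov_all$m1, data.frame(lo = 1, hi = 1))

  cov_one <- domain_coverage(tab, 3L, n_bins = 4)
  expect_equal(nrow(cov_one$p1), 1L)
  expect_lte(cov_one$p1$hi - cov_one$p1$lo, 0.25 + 1e-12)  # one bin wide
  expect_true(cov_one$p1$lo <= 0.5 && cov_one$p1$hi >= 0.5)

  cov_none <- domain_coverage(tab, integer(), n_bins = 4)
  expect_identical(nrow(cov_none$p1), 0L)
  empty <- result_table(data.frame(record_id = integer(), p1 = numeric(),
                                   m1 = numeric()), "p1", "m1")
  expect_error(domain_coverage(empty, integer()), "empty")
})

test_that("table state round-trips through JSON", {
  d <- withr::local_tempdir()
  man <- make_deconv_sweep(d, n_samples = 3L, shape = c(16, 16))
  tab <- result_table(man)
  tab <- multi_sort(tab, "p2")
  tab <- filter_interval(tab, "p1", -0.5, 0)
  tab <- select_rows(tab, context_selection(tab, 2L, "p2"))
  sp <- file.path(d, "state.json")
  write_table_state(tab, sp)
  back <- read_table_state(man, sp)
  expect_identical(back$ordering, tab$ordering)
  expect_identical(back$visible, tab$visible)
  expect_identical(back$sort_keys, tab$sort_keys)
  expect_identical(back$selection, tab$selection)
})
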