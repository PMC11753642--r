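# Binary MFO wrapper: binarization, fitness, selection, exhaustive oracle.

test_that("binarization thresholds at 0.5 and repairs empty masks by argmax", {
  expect_equal(binarize_position(c(0.9, 0.9)), c(TRUE, TRUE))
  expect_equal(binarize_position(c(0.6, 0.4, 0.5)), c(TRUE, FALSE, FALSE))
  expect_equal(binarize_position(c(0.1, 0.3, 0.2)), c(FALSE, TRUE, FALSE))
  # argmax tie goes to the lowest index
  expect_equal(binarize_position(c(0.3, 0.3)), c(TRUE, FALSE))
  expect_error(binarize_position(c(0.2, NA)), "non-finite")
})

test_that("selection fitness is the weighted error + size-penalty combination", {
  df <- separable_table(n_per_class = 10, d_noise = 3)
  spec <- fitness_spec(alpha = 0.99, cv_folds = 5, seed = 1)
  d <- 4
  mask_all <- rep(TRUE, d)
  mask_sep <- names(df)[-match("label", names(df))] == "sep"
  f_all <- selection_fitness(mask_all, df, spec = spec)
  f_sep <- selection_fitness(mask_sep, df, spec = spec)
  # the separating feature alone classifies perfectly: fitness is only the
  # size penalty
  expect_equal(f_sep, 0.01 * 1 / 4)
  # fitness = alpha*err + (1-alpha)*ratio is recomputable for any mask
  sel <- select_features(df, config = mfo_config(8, 10, seed = 2),
                         spec = spec)
  expect_equal(sel$fitness,
               0.99 * sel$cv_error + 0.01 * sel$n_selected / d)
  # monotone in cv_error for fixed mask size: all-features fitness cannot
  # beat the perfect separator plus its smaller penalty
  expect_gte(f_all, f_sep)
  expect_error(selection_fitness(rep(FALSE, d), df, spec = spec),
               "no feature")
})

test_that("fitness rejects fold assignments that lose a class", {
  df <- separable_table(n_per_class = 3, d_noise = 2)
  expect_error(selection_fitness(rep(TRUE, 3), df,
                                 spec = fitness_spec(cv_folds = 5, seed = 1)),
               "class is absent")
})

test_that("a perfectly separating feature is selected", {
  df <- separable_table(n_per_class = 15, d_noise = 5)
  sel <- select_features(df, config = mfo_config(15, 25, seed = 7),
                         spec = fitness_spec(seed = 7))
  expect_true(sel$mask[["sep"]])
  expect_gte(sel$n_selected, 1)
})

test_that("exhaustive oracle enumerates the global minimum and dominates MFO", {
  sf <- synthetic_features(n_per_class = 15, k_classes = 2, d_informative = 2,
                           d_noise = 4, separation = 3, seed = 11)
  spec <- fitness_spec(seed = 11)
  oracle <- exhaustive_selection(sf$features, spec = spec)
  expect_gte(oracle$n_selected, 1)
  # oracle fitness is a true lower bound for any mask, including MFO's
  sel <- select_features(sf$features,
                         config = mfo_config(12, 20, seed = 3), spec = spec)
  expect_lte(oracle$fitness, sel$fitness)
  # spot-check the minimum against direct evaluation of a few masks
  d <- ncol(sf$features) - 1
  for (mask in list(c(TRUE, rep(FALSE, d - 1)), rep(TRUE, d))) {
    expect_lte(oracle$fitness, selection_fitness(mask, sf$features,
                                                 spec = spec))
  }
  expect_error(
    exhaustive_selection(synthetic_features(n_per_class = 5, k_classes = 2,
                                            d_informative = 2,
                                            d_noise = 14,
                                            seed = 1)$features),
    "refused")
})

test_that("oracle picks the enumerated minimum on a tiny table", {
  # d = 1 has a single candidate mask
  df1 <- tibble::tibble(f = c(0, 0, 1, 1, 0, 1),
                        label = c("a", "a", "b", "b", "a", "b"))
  o1 <- exhaustive_selection(df1, spec = fitness_spec(cv_folds = 2, seed = 1))
  expect_equal(unname(o1$mask), TRUE)
})

test_that("selection is deterministic under a fixed seed", {
  sf <- synthetic_features(n_per_class = 10, k_classes = 2, d_informative = 2,
                           d_noise = 6, separation = 2, seed = 5)
  run <- function() select_features(sf$features,
                                    config = mfo_config(10, 12, seed = 21),
                                    spec = fitness_spec(seed = 21))
  s1 <- run()
  s2 <- run()
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$trace, s2$trace)
  expect_gte(s1$n_selected, 1) # mask validity
})

test_that("selection result methods and JSON serialization round-trip", {
  df <- separable_table(n_per_class = 10, d_noise = 3)
  sel <- select_features(df, config = mfo_config(6, 8, seed = 1))
  td <- tidy(sel)
  expect_named(td, c("feature", "selected"))
  expect_equal(sum(td$selected), sel$n_selected)
  expect_equal(glance(sel)$cv_error, sel$cv_error)
  expect_s3_class(autoplot(sel), "ggplot")
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_json(sel, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(sort(js$selected_indices), which(unname(sel$mask)))
  expect_equal(js$fitness, sel$fitness)
})
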