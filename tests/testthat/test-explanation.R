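test_that("a constant model attributes nothing anywhere", {
  fit <- hand_model(list(list(var = -1L, thr = 0, left = -1L, right = -1L,
                              value = 0.7, n = 4L)))
  bg <- data.frame(x1 = rnorm(6), x2 = rnorm(6), x3 = rnorm(6))
  tg <- data.frame(x1 = rnorm(3), x2 = rnorm(3), x3 = rnorm(3))
  for (meth in c("sampling", "exact_subsets", "tree_path")) {
    ex <- shap_values(fit, bg, tg, method = meth, n_samples = 30, seed = 1)
    expect_equal(ex$base_value, 0.7)
    expect_true(all(abs(ex$phi) < 1e-12), info = meth)
  }
})

test_that("single-split stump matches the exhaustive Shapley oracle", {
  # f(x) = 1[x1 > 0.5], two-point background straddling the cut
  fit <- hand_model(list(stump(0L, 0.5, 0, 1)))
  bg <- data.frame(x1 = c(0, 1), x2 = c(5, -5), x3 = c(1, 2))
  tg <- data.frame(x1 = c(1, 0, 0.2), x2 = c(0, 1, 3), x3 = c(0, 0, 9))
  f_or <- function(row) as.numeric(row[1] > 0.5)
  for (meth in c("exact_subsets", "tree_path")) {
    ex <- shap_values(fit, bg, tg, method = meth)
    for (i in 1:3) {
      want <- oracle_shap(f_or, as.numeric(tg[i, ]), as.matrix(bg))
      expect_equal(unname(ex$phi[i, ]), want, tolerance = 1e-9,
                   info = paste(meth, i))
    }
  }
  # sampling agrees within Monte-Carlo tolerance
  exs <- shap_values(fit, bg, tg, method = "sampling", n_samples = 2000,
                     seed = 2)
  for (i in 1:3)
    expect_equal(unname(exs$phi[i, ]),
                 oracle_shap(f_or, as.numeric(tg[i, ]), as.matrix(bg)),
                 tolerance = 0.02)
})

test_that("depth-2 tree and 2-tree forest match the oracle", {
  # depth-2 tree: split x1 then x2
  deep <- list(var = c(0L, 1L, -1L, -1L, -1L),
               thr = c(0.5, 0.5, 0, 0, 0),
               left = c(1L, 2L, -1L, -1L, -1L),
               right = c(4L, 3L, -1L, -1L, -1L),
               value = c(0, 0, 0.2, 0.9, 0.6),
               n = c(4L, 2L, 1L, 1L, 2L))
  fit <- hand_model(list(deep))
  set.seed(3)
  bg <- data.frame(x1 = rnorm(5), x2 = rnorm(5), x3 = rnorm(5))
  tg <- data.frame(x1 = c(0.2, 0.8), x2 = c(0.9, 0.1), x3 = c(0, 1))
  f_or <- function(row) {
    if (row[1] <= 0.5) { if (row[2] <= 0.5) 0.2 else 0.9 } else 0.6
  }
  for (meth in c("exact_subsets", "tree_path")) {
    ex <- shap_values(fit, bg, tg, method = meth)
    for (i in 1:2)
      expect_equal(unname(ex$phi[i, ]),
                   oracle_shap(f_or, as.numeric(tg[i, ]), as.matrix(bg)),
                   tolerance = 1e-9, info = meth)
  }

  # 2-tree forest: vote fraction of two stumps
  fit2 <- hand_model(list(stump(0L, 0.5, 0, 1), stump(1L, 0.5, 1, 0)),
                     family = "random_forest")
  f_or2 <- function(row)
    (as.numeric(row[1] > 0.5) + as.numeric(row[2] <= 0.5)) / 2
  for (meth in c("exact_subsets", "tree_path")) {
    ex <- shap_values(fit2, bg, tg, method = meth)
    for (i in 1:2)
      expect_equal(unname(ex$phi[i, ]),
                   oracle_shap(f_or2, as.numeric(tg[i, ]), as.matrix(bg)),
                   tolerance = 1e-9, info = meth)
  }
})

test_that("additivity holds on every explained observation of a real fit", {
  tab <- imbalanced_table(n_maj = 40, n_min = 20, seed = 13)
  bg <- tab[sample(nrow(tab), 20), ]
  tg <- tab[1:12, ]
  for (fam in c("decision_tree", "random_forest", "gradient_boosting")) {
    fit <- train(model_spec(fam, n_trees = 10, seed = 2), tab)
    ex <- shap_values(fit, bg, tg, method = "sampling", n_samples = 40,
                      seed = 3)
    gap <- abs(ex$base_value + rowSums(ex$phi) - ex$model_output)
    expect_lt(max(gap), 1e-6)
    # determinism under seed
    ex2 <- shap_values(fit, bg, tg, method = "sampling", n_samples = 40,
                       seed = 3)
    expect_identical(ex$phi, ex2$phi)
  }
  # tree_path refuses the non-additive boosting link
  gb <- train(model_spec("gradient_boosting", n_trees = 5, seed = 1), tab)
  expect_error(shap_values(gb, bg, tg, method = "tree_path"),
               "tree_path")
})

test_that("exact enumeration refuses too many features", {
  set.seed(4)
  tab <- as.data.frame(matrix(rnorm(20 * 13), 20))
  names(tab) <- paste0("f", 1:13)
  tab$class_label <- rep(c(0, 1), 10)
  fit <- train(model_spec("decision_tree"), tab)
  expect_error(shap_values(fit, tab, tab[1, ], method = "exact_subsets"),
               "12 features")
})

test_that("global importance ranks by mean |phi| with dummy features last", {
  fit <- hand_model(list(stump(0L, 0.5, 0, 1)))
  bg <- data.frame(x1 = c(0, 1, 0, 1), x2 = rnorm(4), x3 = rnorm(4))
  tg <- data.frame(x1 = c(1, 1, 0), x2 = rnorm(3), x3 = rnorm(3))
  ex <- shap_values(fit, bg, tg, method = "tree_path")
  gi <- global_importance(ex)
  expect_equal(gi$feature[1], "x1")
  expect_equal(gi$rank, 1:3)
  # unused features have exactly zero importance, ties broken alphabetically
  expect_equal(gi$mean_abs_phi[2:3], c(0, 0))
  expect_equal(gi$feature[2:3], c("x2", "x3"))
  # duplicating the observation list changes nothing
  ex2 <- ex
  ex2$phi <- rbind(ex$phi, ex$phi)
  ex2$model_output <- c(ex$model_output, ex$model_output)
  expect_equal(global_importance(ex2)$mean_abs_phi, gi$mean_abs_phi)

  ex0 <- ex
  ex0$phi <- ex$phi[0, , drop = FALSE]
  expect_error(global_importance(ex0), "no attributions")
})

test_that("force decomposition partitions pushes and sums to the net", {
  fit <- hand_model(list(stump(0L, 0.5, 0, 1)))
  bg <- data.frame(x1 = c(0, 1), x2 = c(1, -1), x3 = c(0, 0))
  tg <- data.frame(x1 = 1, x2 = 0, x3 = 0)
  ex <- shap_values(fit, bg, tg, method = "exact_subsets")
  at <- attribution(ex, 1)
  fd <- force_decomposition(at)
  expect_equal(sum(fd$positive$phi) + sum(fd$negative$phi), fd$net,
               tolerance = 1e-12)
  expect_equal(fd$net, at$model_output - at$base_value)
  expect_true(all(diff(abs(fd$positive$phi)) <= 0))

  # all-zero attribution gives empty push lists
  at0 <- at
  at0$phi[] <- 0
  fd0 <- force_decomposition(at0)
  expect_equal(nrow(fd0$positive), 0L)
  expect_equal(nrow(fd0$negative), 0L)
})
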