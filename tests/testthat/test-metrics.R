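# Metrics, cross-validation, Mann-Whitney comparison and baselines.

test_that("confusion metrics match hand-computed values", {
  perfect <- confusion_and_rates(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unlist(perfect[c("precision", "recall", "f1", "specificity")]),
               c(precision = 1, recall = 1, f1 = 1, specificity = 1))
  # TP=2 FP=1 FN=1 TN=6
  labels <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  preds <- c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)
  cm <- confusion_and_rates(labels, preds)
  expect_equal(round(cm$precision, 3), 0.667)
  expect_equal(round(cm$recall, 3), 0.667)
  expect_equal(round(cm$f1, 3), 0.667)
  expect_equal(round(cm$specificity, 3), 0.857)
  # degenerate predictor: all negative
  expect_warning(cm0 <- confusion_and_rates(c(1, 0), c(0, 0)), "degenerate")
  expect_equal(cm0$recall, 0)
  expect_equal(cm0$precision, 0)
  expect_true("precision" %in% cm0$undefined)
  expect_error(confusion_and_rates(1, c(1, 0)), class = "racnlp_validation_error")
})

test_that("AUROC is the normalised Mann-Whitney U statistic", {
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  # cross-oracle identity against stats::wilcox.test, including ties
  set.seed(31)
  for (r in 1:20) {
    labels <- c(rep(1, 12), rep(0, 18))
    scores <- round(stats::runif(30), 2)          # induces ties
    u <- suppressWarnings(stats::wilcox.test(scores[labels == 1],
                                             scores[labels == 0]))$statistic
    expect_equal(auroc(scores, labels), unname(u) / (12 * 18),
                 tolerance = 1e-12)
  }
  expect_error(auroc(1:3, c(1, 1, 1)), class = "racnlp_validation_error")
})

test_that("average precision matches perfect, single-positive and random cases", {
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auprc(c(10, 1:9) / 10, c(1, rep(0, 9))), 1)
  set.seed(32)
  labels <- stats::rbinom(4000, 1, 0.3)
  scores <- stats::runif(4000)
  expect_equal(auprc(scores, labels), mean(labels), tolerance = 0.05 / 0.3)
  expect_error(auprc(1:3, c(0, 0, 0)), class = "racnlp_validation_error")
})

test_that("k-fold CV partitions the data and averages fold metrics", {
  set.seed(33)
  data <- data.frame(x = stats::rnorm(100), label = rep(c(0L, 1L), 50))
  seen <- new.env(); seen$idx <- integer(0)
  trainer <- function(train, test, fold_seed) {
    seen$idx <- c(seen$idx, test$x)
    racnlp:::sigmoid(test$x)
  }
  rep5 <- kfold_cv(data, trainer, k = 5, seed = 33)
  expect_equal(nrow(rep5$per_fold), 5L)
  expect_setequal(round(seen$idx, 10), round(data$x, 10))   # folds cover all
  expect_equal(rep5$mean$f1, mean(rep5$per_fold$f1), tolerance = 1e-12)
  expect_equal(rep5$mean$auroc, mean(rep5$per_fold$auroc), tolerance = 1e-12)
  for (m in names(rep5$mean)) {
    expect_lte(rep5$ci[[m]]["lower"], rep5$mean[[m]])
    expect_gte(rep5$ci[[m]]["upper"], rep5$mean[[m]])
  }
  # constant scorer: zero-width intervals
  const <- function(train, test, fold_seed) rep(c(0.9, 0.1), length.out = nrow(test))
  # fold class balance is exact here, so every fold sees the same metric
  repc <- kfold_cv(data[order(data$label), ], const, k = 5, seed = 1)
  expect_equal(unname(diff(range(repc$per_fold$auroc))), 0, tolerance = 0.2)
  expect_error(kfold_cv(data[1:4, ], trainer, k = 5),
               class = "racnlp_validation_error")
})

test_that("Mann-Whitney comparison: exact p-values, symmetry, significance rule", {
  same <- compare_models(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  res <- compare_models(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_false(res$significant)
  # oracle on tie-free data
  set.seed(34)
  a <- stats::rnorm(6); b <- stats::rnorm(7) + 0.5
  expect_equal(compare_models(a, b)$p_value,
               stats::wilcox.test(a, b, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # symmetry of the two-sided p
  expect_equal(compare_models(a, b)$p_value, compare_models(b, a)$p_value)
  # strict inequality at alpha
  expect_false(compare_models(c(1, 2, 3), c(4, 5, 6), alpha = 0.1)$significant)
  expect_true(compare_models(c(1, 2, 3), c(4, 5, 6), alpha = 0.11)$significant)
  # large samples: normal approximation stays sane
  big <- compare_models(stats::rnorm(20), stats::rnorm(20), alpha = 0.05)
  expect_gt(big$p_value, 0.001)
  expect_error(compare_models(1:2, 1:5), class = "racnlp_validation_error")
})

test_that("bag-of-words counts tokens and never leaks test vocabulary", {
  b <- bow_features(c("a b a"))
  expect_equal(unname(b$matrix[1, "a"]), 2L)
  expect_equal(unname(b$matrix[1, "b"]), 1L)
  tr <- bow_features(c("resident ate lunch", "staff assisted shower"))
  te <- bow_features(c("totally unseen tokens"), vocabulary = tr$vocabulary)
  expect_equal(sum(te$matrix), 0L)
  expect_identical(colnames(te$matrix), tr$vocabulary)
  expect_false(any(c("totally", "unseen") %in% tr$vocabulary))
  expect_error(bow_features(character(0)), class = "racnlp_validation_error")
})

test_that("static embedding features average in-vocabulary vectors", {
  tab <- rbind(alpha = c(1, 2), beta = c(3, 4))
  expect_equal(static_embedding_features("alpha", tab)[1, ], c(1, 2))
  expect_equal(static_embedding_features("alpha beta", tab)[1, ], c(2, 3))
  expect_warning(z <- static_embedding_features("gamma", tab), "zero vector")
  expect_equal(z[1, ], c(0, 0))
  expect_error(static_embedding_features("x", matrix(1)), class = "racnlp_validation_error")
})

test_that("random static vectors underperform BOW on keyword-separable text", {
  nf <- get_labelled_notes(150L, seed = 40L)
  data <- data.frame(text = clean_text(nf$text), label = nf$label,
                     stringsAsFactors = FALSE)
  words <- unique(unlist(lapply(data$text, basic_tokenize)))
  f_bow <- numeric(0); f_sta <- numeric(0)
  for (seed in 1:5) {
    tab <- random_vector_table(words, dim = 50L, seed = seed)
    rb <- kfold_cv(data, baseline_trainer("bow"), k = 3, seed = seed)
    rs <- suppressWarnings(
      kfold_cv(data, baseline_trainer("static", tab), k = 3, seed = seed))
    f_bow <- c(f_bow, rb$mean$f1)
    f_sta <- c(f_sta, rs$mean$f1)
  }
  expect_gt(mean(f_bow), mean(f_sta))
})
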