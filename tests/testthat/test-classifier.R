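test_that("80/20 split sends the remainder to training and is reproducible", {
  s <- make_split(1964, seed = 2)
  expect_length(s$train, 1572)
  expect_length(s$validation, 392)
  expect_length(intersect(s$train, s$validation), 0)
  expect_setequal(c(s$train, s$validation), 1:1964)
  s10 <- make_split(10, seed = 2)
  expect_length(s10$train, 8)
  expect_identical(make_split(1964, seed = 2), s)
  expect_false(identical(make_split(1964, seed = 3), s))
})

test_that("group-wise splitting keeps whole groups on one side", {
  groups <- rep(1:10, each = 20)
  s <- make_split(200, seed = 5, groups = groups)
  expect_length(intersect(unique(groups[s$train]),
                          unique(groups[s$validation])), 0)
})

test_that("classifier metrics follow the confusion-matrix definitions", {
  ## TP=83 FN=17 TN=95 FP=5
  actual <- rep(c("distress", "cry"), c(100, 100))
  predicted <- c(rep("distress", 83), rep("cry", 17),
                 rep("cry", 95), rep("distress", 5))
  r <- evaluate_classifier(predicted, actual)
  expect_equal(r$sensitivity, 0.83)
  expect_equal(r$specificity, 0.95)
  expect_equal(r$accuracy, (83 + 95) / 200)
  expect_equal(r$accuracy, (r$tp + r$tn) / r$n)
  ## perfect predictions
  perf <- evaluate_classifier(actual, actual)
  expect_equal(c(perf$accuracy, perf$sensitivity, perf$specificity), c(1, 1, 1))
  ## all-positive predictor on a balanced set
  allpos <- evaluate_classifier(rep("distress", 200), actual)
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$accuracy, 0.5)
})

test_that("random forest separates linearly separable MFCC features", {
  n <- 60
  f <- with_seed(110, rbind(matrix(stats::rnorm(n * 26), n, 26),
                            matrix(stats::rnorm(n * 26, mean = 4), n, 26)))
  colnames(f) <- paste0("mfcc", 1:26)
  y <- rep(c("cry", "distress"), each = n)
  split <- make_split(2 * n, seed = 6)
  rf <- train_rf(f, y, split = split, seed = 6)
  pred <- predict(rf, f[split$validation, ])
  expect_gte(evaluate_classifier(pred, y[split$validation])$accuracy, 0.95)
  expect_error(train_rf(f, rep("cry", 2 * n), split = split, seed = 6),
               "two classes")
})

test_that("single-class training sets are refused", {
  f <- matrix(stats::rnorm(40 * 26), 40, 26)
  y <- rep(c("cry", "distress"), each = 20)
  bad_split <- list(train = 1:20, validation = 21:40)  # train is one class
  expect_error(train_rf(f, y, split = bad_split), "single-class")
  imgs <- lapply(1:40, function(i) matrix(stats::rnorm(64), 8, 8))
  expect_error(train_cnn(imgs, y, split = bad_split), "single-class")
})
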