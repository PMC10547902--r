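test_that("convolution, batch-norm and dense gradients match finite differences", {
  set.seed(1)
  H <- 8; W <- 8
  imgs <- lapply(1:6, function(i) matrix(stats::rnorm(H * W), H, W))
  y <- c(1, 2, 1, 2, 1, 2)
  layers <- cryscope:::cnn_init(H, W, c(2L, 2L), 4L, seed = 3)
  X <- cryscope:::cnn_stack(imgs)
  fw <- cryscope:::cnn_forward(layers, X, 6, train = TRUE)
  sm <- cryscope:::softmax_ce(fw$out, y)
  gr <- cryscope:::cnn_backward(layers, fw$cache, sm$dY, 6)
  lossfn <- function(ls) cryscope:::softmax_ce(
    cryscope:::cnn_forward(ls, X, 6, train = TRUE)$out, y)$loss
  eps <- 1e-5
  ## conv weight (offset 5 = centre tap)
  l2 <- layers; l2[[1]]$W[[5]][1, 1] <- l2[[1]]$W[[5]][1, 1] + eps
  expect_equal((lossfn(l2) - sm$loss) / eps, gr[[1]]$W[[5]][1, 1],
               tolerance = 1e-3)
  ## batch-norm gain
  l3 <- layers; l3[[2]]$gamma[1] <- l3[[2]]$gamma[1] + eps
  expect_equal((lossfn(l3) - sm$loss) / eps, gr[[2]]$gamma[1], tolerance = 1e-3)
  ## dense weights (both layers)
  for (li in c(10L, 12L)) {
    l4 <- layers; l4[[li]]$W[2, 1] <- l4[[li]]$W[2, 1] + eps
    expect_equal((lossfn(l4) - sm$loss) / eps, gr[[li]]$W[2, 1],
                 tolerance = 1e-3)
  }
})

test_that("the network learns a simple separable image problem", {
  mk_img <- function(cls, seed) with_seed(seed, {
    img <- matrix(stats::rnorm(16 * 16, sd = 0.3), 16, 16)
    if (cls == 2) img[5:12, 5:12] <- img[5:12, 5:12] + 2
    img
  })
  imgs <- c(lapply(1:30, function(i) mk_img(1, i)),
            lapply(1:30, function(i) mk_img(2, 100 + i)))
  y <- rep(c("cry", "distress"), each = 30)
  split <- make_split(60, seed = 8)
  mod <- train_cnn(imgs, y, split = split, seed = 8, epochs = 6,
                   filters = c(4L, 8L), dense = 8L, batch = 16L)
  pred <- predict(mod, imgs[split$validation])
  acc <- evaluate_classifier(pred, y[split$validation])$accuracy
  expect_gte(acc, 0.9)
  ## probabilities are proper
  p <- predict(mod, imgs[split$validation], type = "prob")
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
})

test_that("forward inference is deterministic for a fixed model", {
  imgs <- lapply(1:4, function(i) with_seed(i, matrix(stats::rnorm(64), 8, 8)))
  y <- c("a", "a", "b", "b")
  mod <- train_cnn(imgs, y, split = list(train = 1:4, validation = 1:4),
                   seed = 3, epochs = 1, filters = c(2L, 2L), dense = 4L,
                   batch = 2L)
  p1 <- predict(mod, imgs, type = "prob")
  p2 <- predict(mod, imgs, type = "prob")
  expect_identical(p1, p2)
})
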