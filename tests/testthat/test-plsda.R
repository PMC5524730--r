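# PLSDA: closed-form first direction, score orthogonality, separable and
# null behaviour, and the tie convention.

test_that("a separable one-descriptor problem is learned exactly", {
  d <- separableDescriptors(n = 20)
  m <- fitPlsda(d$X, d$y, nLv = 1L)
  pr <- predict(m, d$X)
  expect_equal(as.character(pr$class), as.character(d$y))
})

test_that("the first weight vector is the normalized X'y direction", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 30; p <- 6
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("D", 1:p)))
    y <- factor(sample(c("sweet", "non-sweet"), n, replace = TRUE),
                levels = c("sweet", "non-sweet"))
    if (nlevels(droplevels(y)) < 2) next
    m <- fitPlsda(X, y, nLv = 1L)
    Z <- applyScaler(m@scaler, X)
    yd <- as.numeric(y == "sweet")
    w0 <- crossprod(Z, yd - mean(yd))
    w0 <- w0 / sqrt(sum(w0^2))
    expect_lt(min(sum((m@weights[, 1] - w0)^2),
                  sum((m@weights[, 1] + w0)^2)), 1e-16)
  }
})

test_that("training scores are mutually orthogonal up to 5 latent variables", {
  set.seed(32)
  X <- matrix(rnorm(40 * 8), 40, 8, dimnames = list(NULL, paste0("D", 1:8)))
  y <- factor(rep(c("sweet", "non-sweet"), 20))
  for (a in 1:5) {
    m <- fitPlsda(X, y, nLv = a)
    G <- crossprod(m@scores)
    expect_lt(max(abs(G - diag(diag(G), a))), 1e-8 * max(diag(G)))
  }
})

test_that("permuted labels give chance-level cross-validation", {
  set.seed(33)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("D", 1:5)))
  ners <- vapply(1:20, function(i) {
    y <- factor(sample(rep(c("sweet", "non-sweet"), 30)),
                levels = c("sweet", "non-sweet"))
    pred <- venetianBlindCv(X, y, plsdaSpec(1L), G = 5L)
    nonErrorRate(classMetrics(y, pred, context = "cv"))
  }, numeric(1))
  expect_lt(abs(mean(ners) - 0.5), 0.08)
})

test_that("a sample at the training centroid is a tie under balanced coding", {
  d <- separableDescriptors(n = 20)
  m <- fitPlsda(d$X, d$y, nLv = 1L)
  centroid <- matrix(colMeans(d$X), 1, dimnames = list("c", colnames(d$X)))
  pr <- predict(m, centroid)
  # predicted responses equal the class priors (0.5 each) -> not assigned
  expect_equal(unname(as.matrix(pr[, m@classes])[1, ]), c(0.5, 0.5))
  expect_true(is.na(pr$class))
})

test_that("predictions are invariant to shifting a raw descriptor", {
  d <- shiftedDescriptors(n = 40, seed = 8)
  m1 <- fitPlsda(d$X, d$y, nLv = 2L)
  X2 <- d$X; X2[, 1] <- X2[, 1] + 100
  m2 <- fitPlsda(X2, d$y, nLv = 2L)
  q <- d$X[1:5, , drop = FALSE]; q2 <- X2[1:5, , drop = FALSE]
  expect_equal(predict(m1, q)$class, predict(m2, q2)$class)
})

test_that("rank-deficient requests fail loudly", {
  X <- cbind(a = rnorm(10), b = rnorm(10))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  y <- factor(rep(c("sweet", "non-sweet"), 5))
  expect_error(fitPlsda(X, y, nLv = 3L), "rank")
  expect_error(fitPlsda(X[1:4, ], y[1:4], nLv = 3L), "few samples")
})
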