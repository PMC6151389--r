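# independent analytic gradient via the reference backprop step: with
# momentum 0, delta_w = -eta * dE/dw, so grad = (old - new) / eta
analyticGradients <- function(model, x, target) {
  cfg <- trainingConfig(eta = 1, alpha = 0)
  upd <- annBackpropStep(model, x, target, cfg)
  list(W1 = model@W1 - upd@W1, b1 = model@b1 - upd@b1,
       W2 = model@W2 - upd@W2, b2 = model@b2 - upd@b2)
}

numericGradients <- function(model, x, target, h = 1e-5) {
  X <- matrix(x, 1); Y <- matrix(target, 1)
  fdSlot <- function(slot) {
    g <- methods::slot(model, slot) * 0
    for (i in seq_along(g)) {
      mp <- model; mm <- model
      sp <- methods::slot(mp, slot); sp[i] <- sp[i] + h
      methods::slot(mp, slot) <- sp
      sm <- methods::slot(mm, slot); sm[i] <- sm[i] - h
      methods::slot(mm, slot) <- sm
      g[i] <- (annLoss(mp, X, Y) - annLoss(mm, X, Y)) / (2 * h)
    }
    g
  }
  list(W1 = fdSlot("W1"), b1 = fdSlot("b1"), W2 = fdSlot("W2"),
       b2 = fdSlot("b2"))
}

maxRelErr <- function(a, b) {
  max(vapply(names(a), function(nm)
    max(abs(a[[nm]] - b[[nm]]) / pmax(abs(a[[nm]]), 1e-3)), numeric(1)))
}

test_that("initialization is seed-deterministic with bounded weights", {
  m1 <- annInit(400, 32, 379, seed = 7)
  m2 <- annInit(400, 32, 379, seed = 7)
  expect_identical(m1@W1, m2@W1)
  expect_identical(m1@W2, m2@W2)
  expect_equal(dim(m1@W1), c(32L, 400L))
  expect_equal(dim(m1@W2), c(379L, 32L))
  expect_lte(max(abs(m1@W1)), 1 / sqrt(400))
  expect_lte(max(abs(m1@W2)), 1 / sqrt(32))
  expect_equal(m1@b1, numeric(32))
  expect_error(annInit(0, 4, 2), "positive")
})

test_that("forward pass matches hand arithmetic and stays in (0,1)", {
  m <- annInit(3, 4, 2, seed = 1)
  m@W1 <- m@W1 * 0; m@W2 <- m@W2 * 0
  expect_equal(annForward(m, c(0.3, -1, 2)), c(0.5, 0.5))

  # hand-built 2-2-1 net with unit weights: y = sigmoid(2 * sigmoid(0))
  m221 <- annInit(2, 2, 1, seed = 1)
  m221@W1 <- matrix(1, 2, 2); m221@W2 <- matrix(1, 1, 2)
  m221@vW1 <- m221@W1 * 0; m221@vW2 <- m221@W2 * 0
  expect_equal(annForward(m221, c(0, 0)), 1 / (1 + exp(-1)),
               tolerance = 1e-12)

  set.seed(5)
  m2 <- annInit(10, 6, 4, seed = 2)
  for (i in 1:50) {
    y <- annForward(m2, rnorm(10, sd = 5))
    expect_true(all(y > 0 & y < 1))
  }
  expect_error(annForward(m2, rnorm(9)), "input size")
})

test_that("a zero learning rate leaves the model unchanged", {
  m <- annInit(4, 3, 2, seed = 3)
  cfg <- trainingConfig(eta = 1e-300, alpha = 0)  # eta must be > 0
  upd <- annBackpropStep(m, rnorm(4), c(1, 0), cfg)
  expect_equal(upd@W1, m@W1, tolerance = 1e-250)
  expect_error(trainingConfig(eta = 0), "eta")
})

test_that("backprop gradients match central finite differences", {
  set.seed(11)
  m <- annInit(3, 4, 2, seed = 11)
  x <- rnorm(3); target <- c(1, 0)
  ga <- analyticGradients(m, x, target)
  gn <- numericGradients(m, x, target)
  expect_lt(maxRelErr(ga, gn), 1e-5)
})

test_that("one sigma-rule step on the 2-2-1 net matches full hand arithmetic", {
  m <- annInit(2, 2, 1, seed = 1)
  m@W1 <- matrix(c(0.5, -0.3, 0.2, 0.1), 2, 2)
  m@b1 <- c(0.1, -0.2)
  m@W2 <- matrix(c(0.4, -0.6), 1, 2)
  m@b2 <- 0.05
  m@vW1 <- m@W1 * 0; m@vW2 <- m@W2 * 0
  x <- c(1, -2); target <- 1; eta <- 0.1
  # forward by hand
  a1 <- m@W1 %*% x + m@b1
  h <- 1 / (1 + exp(-a1))
  y <- 1 / (1 + exp(-(m@W2 %*% h + m@b2)))
  # output delta for E = 1/2 (y - t)^2 through the sigmoid
  dOut <- (y - target) * y * (1 - y)
  dHid <- as.numeric(t(m@W2) %*% dOut) * as.numeric(h) * (1 - as.numeric(h))
  expW2 <- m@W2 - eta * dOut %*% t(h)
  expb2 <- m@b2 - eta * as.numeric(dOut)
  expW1 <- m@W1 - eta * dHid %*% t(x)
  expb1 <- m@b1 - eta * dHid
  upd <- annBackpropStep(m, x, target, trainingConfig(eta = eta, alpha = 0))
  expect_equal(upd@W2, expW2, tolerance = 1e-14)
  expect_equal(upd@b2, as.numeric(expb2), tolerance = 1e-14)
  expect_equal(upd@W1, expW1, tolerance = 1e-14)
  expect_equal(upd@b1, expb1, tolerance = 1e-14)
})

test_that("momentum accumulates the previous delta", {
  m <- annInit(2, 2, 1, seed = 4)
  cfg <- trainingConfig(eta = 0.1, alpha = 0.5)
  x <- c(1, 1); tgt <- 1
  m1 <- annBackpropStep(m, x, tgt, cfg)
  m2 <- annBackpropStep(m1, x, tgt, cfg)
  # second step's delta includes alpha * first delta
  d1 <- m1@W1 - m@W1
  cfg0 <- trainingConfig(eta = 0.1, alpha = 0)
  pure <- annBackpropStep(m1, x, tgt, cfg0)
  expect_equal(m2@W1 - m1@W1, (pure@W1 - m1@W1) + 0.5 * d1,
               tolerance = 1e-12)
})

test_that("the C++ training epoch equals a sequence of reference R steps", {
  set.seed(21)
  n <- 7
  X <- matrix(rnorm(n * 5), n, 5)
  Y <- matrix(rbinom(n * 3, 1, 0.4), n, 3)
  cfg <- trainingConfig(eta = 0.1, alpha = 0.5, epochs = 2,
                        shuffleSeed = 77)
  m0 <- annInit(5, 4, 3, seed = 9)
  trained <- annTrain(m0, X, Y, cfg)
  # replicate the shuffles the trainer drew
  set.seed(77)
  orders <- replicate(2, sample.int(n))
  ref <- m0
  for (ep in 1:2) for (i in orders[, ep])
    ref <- annBackpropStep(ref, X[i, ], Y[i, ], cfg)
  expect_equal(trained@W1, ref@W1, tolerance = 1e-12)
  expect_equal(trained@W2, ref@W2, tolerance = 1e-12)
  expect_equal(trained@b1, ref@b1, tolerance = 1e-12)
  expect_equal(trained@b2, ref@b2, tolerance = 1e-12)
})

test_that("training honors epochs = 0, learns AND, and is seed-deterministic", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  Y <- matrix(c(0, 0, 0, 1), 4, 1)
  m0 <- annInit(2, 3, 1, seed = 5)

  same <- annTrain(m0, X, Y, trainingConfig(epochs = 0))
  expect_identical(same@W1, m0@W1)

  cfg <- trainingConfig(eta = 0.5, alpha = 0.5, epochs = 2000,
                        shuffleSeed = 5)
  trained <- annTrain(m0, X, Y, cfg)
  trace <- trained@config$lastRun$trace
  expect_lt(trace[length(trace)], 0.05)

  again <- annTrain(m0, X, Y, cfg)
  expect_identical(trained@W1, again@W1)
  expect_identical(trained@config$lastRun$trace,
                   again@config$lastRun$trace)
})

test_that("masked outputs contribute no gradient", {
  m <- annInit(3, 3, 2, seed = 6)
  x <- c(1, 0, -1)
  cfg <- trainingConfig(eta = 0.2, alpha = 0)
  masked <- annBackpropStep(m, x, c(1, 0), cfg, mask = c(1, 0))
  # output 2 weights move only through... nothing: its delta is zeroed
  expect_equal(masked@W2[2, ], m@W2[2, ])
  expect_equal(masked@b2[2], m@b2[2])
  expect_false(isTRUE(all.equal(masked@W2[1, ], m@W2[1, ])))
})

test_that("early stopping returns the best monitored epoch", {
  set.seed(30)
  X <- matrix(rnorm(40 * 6), 40, 6)
  Y <- matrix(rbinom(40 * 2, 1, 0.5), 40, 2)
  cfg <- trainingConfig(epochs = 200, patience = 10, shuffleSeed = 3)
  m <- annInit(6, 4, 2, seed = 3)
  fit <- annTrain(m, X[1:30, ], Y[1:30, ], cfg,
                  Xval = X[31:40, ], Yval = Y[31:40, ])
  run <- fit@config$lastRun
  expect_lte(run$epochsRun, 200)
  expect_lte(run$bestEpoch, run$epochsRun)
  expect_equal(run$valTrace[run$bestEpoch], min(run$valTrace))
  # returned weights reproduce the best monitoring loss
  expect_equal(annLoss(fit, X[31:40, ], Y[31:40, ]), min(run$valTrace),
               tolerance = 1e-10)
})

test_that("model JSON serialization round-trips bit-stably", {
  m <- annInit(6, 4, 3, seed = 8, kinases = c("a", "b", "c"))
  X <- matrix(rnorm(30), 5, 6)
  m@normalizer <- fitNormalizer(X)
  tf <- tempfile(fileext = ".json")
  writeAnnModel(m, tf)
  back <- readAnnModel(tf)
  expect_identical(back@W1, m@W1)
  expect_identical(back@W2, m@W2)
  expect_identical(back@b1, m@b1)
  expect_identical(back@kinases, m@kinases)
  expect_identical(back@normalizer@center, m@normalizer@center)
  x <- rnorm(6)
  expect_identical(annForward(back, x), annForward(m, x))
})

test_that("profile prediction is deterministic and invariant to rigid motion", {
  mols <- makeFixtureMolecules(10, seed = 40)
  X <- featurizeSet(mols)
  Y <- matrix(rbinom(10 * 3, 1, 0.4), 10, 3,
              dimnames = list(rownames(X), c("k1", "k2", "k3")))
  nrm <- fitNormalizer(X)
  m <- annInit(400, 8, 3, seed = 2, kinases = colnames(Y))
  m <- annTrain(m, applyNormalizer(nrm, X), Y,
                trainingConfig(epochs = 20, shuffleSeed = 2))
  m@normalizer <- nrm
  P1 <- predictProfile(m, mols)
  expect_true(all(P1 > 0 & P1 < 1))
  expect_identical(P1, predictProfile(m, mols))
  set.seed(61)
  rot <- lapply(mols, function(mm) applyCoords(mm,
                                               rigidTransform(molCoords(mm))))
  P2 <- predictProfile(m, rot)
  expect_lt(max(abs(P1 - P2)), 1e-9)
  badCfg <- descriptorConfig(data.frame(kind = "scalar1d", property = "",
                                        k = 0L, delta = 0, b = 0))
  expect_error(predictProfile(m, mols, badCfg), "expects")
})
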