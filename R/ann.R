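# Multi-task feed-forward network: initialization, forward pass, online
# back-propagation with momentum, training loop and serialization.

#' Training configuration for the network
#'
#' Defaults follow the classic online ("simple") back-propagation recipe:
#' learning rate `eta = 0.1`, momentum `alpha = 0.5`, sum-of-squares loss
#' on the sigmoid outputs, per-example updates in a freshly shuffled order
#' each epoch, at most 500 epochs with early stopping on a monitoring-set
#' loss (patience 50). Cross-entropy loss is available via `loss = "xent"`.
#'
#' @param eta learning rate (> 0).
#' @param alpha momentum coefficient in `[0, 1)`.
#' @param epochs maximum training epochs (>= 0).
#' @param patience early-stopping patience in epochs (used only when a
#'   monitoring set is supplied to [annTrain()]).
#' @param shuffleSeed seed for the per-epoch example shuffles.
#' @param loss `"sse"` or `"xent"`.
#' @return a list with class-checked fields, suitable for [annTrain()].
#' @export
trainingConfig <- function(eta = 0.1, alpha = 0.5, epochs = 500,
                           patience = 50, shuffleSeed = 1, loss = "sse") {
  stopifnot(eta > 0, alpha >= 0, alpha < 1, epochs >= 0,
            loss %in% c("sse", "xent"))
  list(eta = eta, alpha = alpha, epochs = as.integer(epochs),
       patience = as.integer(patience),
       shuffleSeed = as.integer(shuffleSeed), loss = loss)
}

#' Initialize a network model
#'
#' Weights are drawn uniformly from `[-1/sqrt(fan_in), +1/sqrt(fan_in)]`,
#' biases start at zero and momentum velocities at zero; the draw is fully
#' determined by the seed.
#'
#' @param nIn,nHidden,nOut layer sizes (the canonical architecture is
#'   400 -> 32 -> one output per kinase).
#' @param seed RNG seed for the weight draw.
#' @param kinases optional output ids.
#' @return an [AnnModel-class].
#' @export
annInit <- function(nIn, nHidden = 32, nOut = 1, seed = 1,
                    kinases = character()) {
  if (nIn < 1 || nHidden < 1 || nOut < 1)
    stop("layer sizes must be positive")
  set.seed(seed)
  r1 <- 1 / sqrt(nIn)
  r2 <- 1 / sqrt(nHidden)
  W1 <- matrix(stats::runif(nHidden * nIn, -r1, r1), nHidden, nIn)
  W2 <- matrix(stats::runif(nOut * nHidden, -r2, r2), nOut, nHidden)
  methods::new("AnnModel",
    W1 = W1, b1 = numeric(nHidden), W2 = W2, b2 = numeric(nOut),
    vW1 = W1 * 0, vb1 = numeric(nHidden), vW2 = W2 * 0,
    vb2 = numeric(nOut),
    normalizer = NULL, kinases = as.character(kinases),
    seed = as.integer(seed), config = list())
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass
#'
#' `h = sigmoid(W1 x + b1)`, `y = sigmoid(W2 h + b2)`; outputs are strictly
#' inside (0, 1).
#'
#' @param model an [AnnModel-class].
#' @param x normalized feature vector of length `ncol(W1)`.
#' @return numeric vector of per-output scores, named by kinase ids when
#'   the model carries them.
#' @export
annForward <- function(model, x) {
  if (length(x) != ncol(model@W1))
    stop("input length ", length(x), " does not match network input size ",
         ncol(model@W1))
  h <- .sigmoid(model@W1 %*% x + model@b1)
  y <- as.numeric(.sigmoid(model@W2 %*% h + model@b2))
  if (length(model@kinases)) names(y) <- model@kinases
  y
}

# full-matrix forward pass (rows = examples)
.annForwardMatrix <- function(model, X) {
  H <- .sigmoid(tcrossprod(X, model@W1) +
                  matrix(model@b1, nrow(X), length(model@b1), byrow = TRUE))
  P <- .sigmoid(tcrossprod(H, model@W2) +
                  matrix(model@b2, nrow(X), length(model@b2), byrow = TRUE))
  if (length(model@kinases)) colnames(P) <- model@kinases
  P
}

#' One online back-propagation step (reference implementation)
#'
#' Applies `delta_w(t) = -eta dE/dw + alpha delta_w(t-1)` for a single
#' presented example, with `E = 1/2 sum (y - target)^2` for the default
#' sum-of-squares loss (or the sigmoid cross-entropy when
#' `config$loss == "xent"`). The previous weight deltas are retained in
#' the model's velocity slots. An optional 0/1 `mask` zeroes the gradient
#' of unobserved outputs.
#'
#' @param model an [AnnModel-class]; @param x input vector;
#' @param target 0/1 target vector of length `nOut`;
#' @param config a [trainingConfig()];
#' @param mask optional 0/1 vector, 1 = output observed.
#' @return the updated model.
#' @export
annBackpropStep <- function(model, x, target, config = trainingConfig(),
                            mask = NULL) {
  stopifnot(length(x) == ncol(model@W1),
            length(target) == nrow(model@W2))
  h <- as.numeric(.sigmoid(model@W1 %*% x + model@b1))
  y <- as.numeric(.sigmoid(model@W2 %*% h + model@b2))
  dOut <- y - target
  if (config$loss == "sse") dOut <- dOut * y * (1 - y)
  if (!is.null(mask)) dOut <- dOut * mask
  dHid <- as.numeric(crossprod(model@W2, dOut)) * h * (1 - h)
  model@vW2 <- -config$eta * tcrossprod(dOut, h) + config$alpha * model@vW2
  model@vb2 <- -config$eta * dOut + config$alpha * model@vb2
  model@vW1 <- -config$eta * tcrossprod(dHid, x) + config$alpha * model@vW1
  model@vb1 <- -config$eta * dHid + config$alpha * model@vb1
  model@W2 <- model@W2 + model@vW2
  model@b2 <- model@b2 + model@vb2
  model@W1 <- model@W1 + model@vW1
  model@b1 <- model@b1 + model@vb1
  model
}

#' Loss of a model on a dataset
#'
#' @param model an [AnnModel-class]; @param X inputs; @param Y 0/1 targets;
#' @param loss `"sse"` or `"xent"`; @param mask optional 0/1 matrix.
#' @return total loss over all rows and outputs.
#' @export
annLoss <- function(model, X, Y, loss = "sse", mask = NULL) {
  P <- .annForwardMatrix(model, X)
  if (loss == "xent") {
    L <- -(Y * log(P + 1e-12) + (1 - Y) * log(1 - P + 1e-12))
  } else {
    E <- P - Y
    L <- 0.5 * E * E
  }
  if (!is.null(mask)) L <- L * mask
  sum(L)
}

#' Train the network by online back-propagation with momentum
#'
#' Runs per-example updates in a freshly shuffled order each epoch
#' (seeded by `config$shuffleSeed`), recording the full-batch training
#' loss per epoch. When a monitoring set (`Xval`, `Yval`) is given, the
#' epoch with the lowest monitoring loss is kept and training stops after
#' `config$patience` epochs without improvement. Fully deterministic given
#' (model, data, config).
#'
#' @param model an initialized [AnnModel-class].
#' @param X normalized feature matrix (rows = compounds).
#' @param Y 0/1 label matrix, rows aligned with `X`.
#' @param config a [trainingConfig()].
#' @param Xval,Yval optional monitoring set for early stopping.
#' @param mask optional 0/1 matrix masking unobserved labels.
#' @return the trained model; the per-epoch loss traces and the selected
#'   epoch are stored in `model@config$lastRun`.
#' @export
annTrain <- function(model, X, Y, config = trainingConfig(),
                     Xval = NULL, Yval = NULL, mask = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), ncol(X) == ncol(model@W1),
            ncol(Y) == nrow(model@W2))
  if (config$epochs < 0) stop("epochs must be >= 0")
  if (config$epochs == 0 || nrow(X) == 0) {
    model@config <- c(model@config[setdiff(names(model@config), "lastRun")],
                      list(lastRun = list(trace = numeric(),
                                          valTrace = numeric(),
                                          bestEpoch = 0L, epochsRun = 0L,
                                          config = config)))
    return(model)
  }
  set.seed(config$shuffleSeed)
  orders <- t(vapply(seq_len(config$epochs),
                     function(e) sample.int(nrow(X)),
                     integer(nrow(X))))
  storage.mode(orders) <- "integer"
  emptyM <- matrix(0, 0, 0)
  res <- .annTrainCpp(model@W1, model@b1, model@W2, model@b2,
                      model@vW1, model@vb1, model@vW2, model@vb2,
                      X, Y,
                      if (is.null(mask)) emptyM else as.matrix(mask),
                      orders, config$eta, config$alpha,
                      identical(config$loss, "xent"),
                      if (is.null(Xval)) emptyM else as.matrix(Xval),
                      if (is.null(Yval)) emptyM else as.matrix(Yval),
                      config$patience)
  model@W1 <- res$W1; model@b1 <- as.numeric(res$b1)
  model@W2 <- res$W2; model@b2 <- as.numeric(res$b2)
  model@vW1 <- res$vW1; model@vb1 <- as.numeric(res$vb1)
  model@vW2 <- res$vW2; model@vb2 <- as.numeric(res$vb2)
  model@config <- c(model@config[setdiff(names(model@config), "lastRun")],
                    list(lastRun = list(trace = as.numeric(res$trace),
                                        valTrace = as.numeric(res$valTrace),
                                        bestEpoch = res$bestEpoch,
                                        epochsRun = res$epochsRun,
                                        config = config)))
  model
}

#' Predict a kinase activity profile for molecules
#'
#' Featurizes the molecules with the model's descriptor layout, applies
#' the stored input normalizer and runs the forward pass, giving one score
#' in (0, 1) per kinase output.
#'
#' @param model a trained [AnnModel-class] carrying a normalizer.
#' @param mols a [Molecule-class] or list of molecules.
#' @param config the [DescriptorConfig-class] used at training time.
#' @return numeric matrix, compounds x kinases.
#' @export
predictProfile <- function(model, mols, config = defaultDescriptorConfig()) {
  if (methods::is(mols, "Molecule")) mols <- list(mols)
  X <- featurizeSet(mols, config)
  if (ncol(X) != ncol(model@W1))
    stop("descriptor layout produces ", ncol(X),
         " features but the model expects ", ncol(model@W1))
  if (is.null(model@normalizer))
    stop("model carries no input normalizer; train it first")
  Z <- applyNormalizer(model@normalizer, X)
  P <- .annForwardMatrix(model, Z)
  rownames(P) <- rownames(X)
  P
}

#' Serialize a model to versioned JSON
#'
#' Writes shapes, weights, momentum state, normalizer, kinase ids, seed
#' and the training-config snapshot at full double precision, so that
#' [readAnnModel()] reloads a bit-identical model.
#'
#' @param model an [AnnModel-class]; @param path output JSON file.
#' @export
writeAnnModel <- function(model, path) {
  nrm <- model@normalizer
  doc <- list(
    format = "KinomeQSAR-ann", version = 1L,
    dims = list(nIn = ncol(model@W1), nHidden = nrow(model@W1),
                nOut = nrow(model@W2)),
    W1 = model@W1, b1 = model@b1, W2 = model@W2, b2 = model@b2,
    vW1 = model@vW1, vb1 = model@vb1, vW2 = model@vW2, vb2 = model@vb2,
    normalizer = if (!is.null(nrm))
      list(center = nrm@center, scale = nrm@scale,
           constant = nrm@constant),
    kinases = model@kinases, seed = model@seed,
    config = model@config[setdiff(names(model@config), "lastRun")]
  )
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                           null = "null", matrix = "rowmajor")
  writeLines(json, path)
  invisible(path)
}

#' @rdname writeAnnModel
#' @return [readAnnModel()] returns the reloaded [AnnModel-class].
#' @export
readAnnModel <- function(path) {
  doc <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyMatrix = TRUE)
  if (!identical(doc$format, "KinomeQSAR-ann"))
    stop(path, " is not a KinomeQSAR ANN model file")
  nrm <- NULL
  if (!is.null(doc$normalizer))
    nrm <- methods::new("Normalizer",
                        center = as.numeric(doc$normalizer$center),
                        scale = as.numeric(doc$normalizer$scale),
                        constant = as.logical(doc$normalizer$constant))
  asMat <- function(x, nr, nc) {
    if (is.matrix(x)) x else matrix(x, nr, nc)
  }
  nh <- doc$dims[["nHidden"]]; ni <- doc$dims[["nIn"]]
  no <- doc$dims[["nOut"]]
  methods::new("AnnModel",
    W1 = asMat(doc$W1, nh, ni),
    b1 = as.numeric(doc$b1),
    W2 = asMat(doc$W2, no, nh),
    b2 = as.numeric(doc$b2),
    vW1 = asMat(doc$vW1, nh, ni),
    vb1 = as.numeric(doc$vb1),
    vW2 = asMat(doc$vW2, no, nh),
    vb2 = as.numeric(doc$vb2),
    normalizer = nrm,
    kinases = as.character(doc$kinases %||% character()),
    seed = as.integer(doc$seed),
    config = as.list(doc$config %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
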