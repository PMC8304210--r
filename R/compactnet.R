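# The compact squeeze-and-excitation classifier: configuration, exact
# parameter / multiply-accumulate accounting, construction, and inference.

#' Create a classifier configuration
#'
#' Defaults give the canonical compact architecture: conv blocks with 64, 128,
#' 256, 256 channels (strides 1, 1, 2, 1), SE channel attention with ratio 16
#' and a softmax gate, dropout 0.5 after each fully-connected layer, FC widths
#' 512 then 6, input 224 x 224 x 3. With that configuration the feature map
#' sequence is 112, 56, 14, 7 (spatial) and the model has 7,396,886 trainable
#' parameters.
#'
#' @param blockChannels integer vector of conv output channels.
#' @param blockStrides integer vector of conv strides (1 or 2).
#' @param useSE include the channel-attention module.
#' @param seRatio SE bottleneck compression ratio.
#' @param gate SE gate nonlinearity, \code{"softmax"} (default) or
#'   \code{"sigmoid"}.
#' @param useDropout apply dropout after the FC layers during training.
#' @param dropoutRate dropout probability.
#' @param fc0Width width of the first FC layer.
#' @param nClasses number of classes.
#' @param inputSize square input spatial size.
#' @return A \linkS4class{CompactNetConfig}.
#' @examples
#' cfg <- compactNetConfig()
#' featureMapSizes(cfg)
#' @export
compactNetConfig <- function(blockChannels = c(64L, 128L, 256L, 256L),
                             blockStrides = c(1L, 1L, 2L, 1L),
                             useSE = TRUE, seRatio = 16L,
                             gate = c("softmax", "sigmoid"),
                             useDropout = TRUE, dropoutRate = 0.5,
                             fc0Width = 512L, nClasses = 6L,
                             inputSize = 224L) {
  gate <- match.arg(gate)
  new("CompactNetConfig",
      blockChannels = as.integer(blockChannels),
      blockStrides = as.integer(blockStrides),
      useSE = useSE, seRatio = as.integer(seRatio), gate = gate,
      useDropout = useDropout, dropoutRate = dropoutRate,
      fc0Width = as.integer(fc0Width), nClasses = as.integer(nClasses),
      inputSize = as.integer(inputSize))
}

#' Ablation variants of the compact classifier
#'
#' \code{"noSE"} removes the channel-attention module, \code{"noDropout"}
#' disables dropout, \code{"twoBlock"} / \code{"threeBlock"} keep only the
#' first 2 / 3 conv blocks (channels and strides are the canonical prefix;
#' the first FC width is re-derived from the resulting feature-map geometry
#' at build time).
#'
#' @param variant one of \code{"canonical"}, \code{"noSE"},
#'   \code{"noDropout"}, \code{"twoBlock"}, \code{"threeBlock"}.
#' @param ... further arguments passed to \code{\link{compactNetConfig}}.
#' @return A \linkS4class{CompactNetConfig}.
#' @examples
#' ablationConfig("noSE")
#' @export
ablationConfig <- function(variant = c("canonical", "noSE", "noDropout",
                                       "twoBlock", "threeBlock"), ...) {
  variant <- match.arg(variant)
  switch(variant,
    canonical = compactNetConfig(...),
    noSE = compactNetConfig(useSE = FALSE, ...),
    noDropout = compactNetConfig(useDropout = FALSE, ...),
    twoBlock = compactNetConfig(blockChannels = c(64L, 128L),
                                blockStrides = c(1L, 1L), ...),
    threeBlock = compactNetConfig(blockChannels = c(64L, 128L, 256L),
                                  blockStrides = c(1L, 1L, 2L), ...))
}

# side length after each block: conv (3x3, pad 1, given stride) then
# max pool (3x3, stride 2, pad 1)
featureMapSideLengths <- function(inputSize, strides) {
  s <- inputSize
  out <- integer(length(strides))
  for (i in seq_along(strides)) {
    s <- (s + 2L - 3L) %/% strides[i] + 1L   # conv
    convSide <- s
    s <- (s - 1L) %/% 2L + 1L                # pool
    out[i] <- s
    attr(out, "conv") <- c(attr(out, "conv"), convSide)
  }
  out
}

#' Feature-map geometry of a configuration
#'
#' @param config a \linkS4class{CompactNetConfig}.
#' @return data.frame with one row per block: channels, conv output side,
#'   pooled output side.
#' @examples
#' featureMapSizes(compactNetConfig())
#' @export
featureMapSizes <- function(config) {
  sides <- featureMapSideLengths(config@inputSize, config@blockStrides)
  data.frame(block = seq_along(config@blockChannels),
             channels = config@blockChannels,
             convSide = attr(sides, "conv"),
             poolSide = as.integer(sides))
}

.flatDim <- function(config) {
  sides <- featureMapSideLengths(config@inputSize, config@blockStrides)
  n <- length(sides)
  config@blockChannels[n] * sides[n]^2
}

#' Exact parameter and multiply-accumulate accounting
#'
#' Closed-form, per-layer accounting of trainable parameters and MACs for a
#' configuration. Convolutions carry biases and the channel-normalization
#' scale/shift pair (2 parameters per output channel). Conv MACs are
#' k^2 * Cin * Cout * Hout * Wout at each conv's own output resolution; FC
#' MACs are in * out; the SE bottleneck contributes 2 * C * (C / ratio). An
#' additional total including elementwise work (normalization, ReLU, pooling
#' comparisons, SE pooling/scaling) is reported because published FLOP figures
#' often fold those in.
#'
#' @param config a \linkS4class{CompactNetConfig}.
#' @return List with \code{nParameters}, \code{macCount},
#'   \code{macCountElementwise} and a per-layer data.frame \code{perLayer}
#'   (columns layer, params, macs).
#' @examples
#' acct <- modelAccount(compactNetConfig())
#' acct$nParameters
#' @export
modelAccount <- function(config) {
  stopifnot(is(config, "CompactNetConfig"))
  sides <- featureMapSideLengths(config@inputSize, config@blockStrides)
  convSides <- attr(sides, "conv")
  cin <- 3L
  layers <- list()
  elementwise <- 0
  for (i in seq_along(config@blockChannels)) {
    cout <- config@blockChannels[i]
    convElems <- as.numeric(cout) * convSides[i]^2
    poolElems <- as.numeric(cout) * sides[i]^2
    layers[[length(layers) + 1L]] <- data.frame(
      layer = sprintf("block%d_conv", i - 1L),
      params = 9 * cin * cout + cout + 2 * cout,
      macs = 9 * as.numeric(cin) * cout * convSides[i]^2)
    # scale+shift (2/elem), ReLU (1/elem), 3x3 pool comparisons (9/out elem)
    elementwise <- elementwise + 3 * convElems + 9 * poolElems
    cin <- cout
  }
  nBlocks <- length(config@blockChannels)
  cFinal <- config@blockChannels[nBlocks]
  hwFinal <- as.numeric(sides[nBlocks])^2
  if (config@useSE) {
    cr <- cFinal %/% config@seRatio
    layers[[length(layers) + 1L]] <- data.frame(
      layer = "se",
      params = cFinal * cr + cr + cr * cFinal + cFinal,
      macs = 2 * as.numeric(cFinal) * cr)
    elementwise <- elementwise + 2 * cFinal * hwFinal  # pool + rescale
  }
  flat <- .flatDim(config)
  layers[[length(layers) + 1L]] <- data.frame(
    layer = "fc0", params = as.numeric(flat) * config@fc0Width + config@fc0Width,
    macs = as.numeric(flat) * config@fc0Width)
  layers[[length(layers) + 1L]] <- data.frame(
    layer = "fc1",
    params = as.numeric(config@fc0Width) * config@nClasses + config@nClasses,
    macs = as.numeric(config@fc0Width) * config@nClasses)
  elementwise <- elementwise + config@fc0Width
  perLayer <- do.call(rbind, layers)
  list(nParameters = sum(perLayer$params),
       macCount = sum(perLayer$macs),
       macCountElementwise = sum(perLayer$macs) + elementwise,
       perLayer = perLayer)
}

#' Total trainable parameter count
#'
#' @param config a \linkS4class{CompactNetConfig}.
#' @return Integer-valued numeric scalar.
#' @examples
#' countParameters(compactNetConfig())  # 7396886
#' @export
countParameters <- function(config) modelAccount(config)$nParameters

#' Total multiply-accumulate count for one input
#'
#' @param config a \linkS4class{CompactNetConfig}.
#' @param includeElementwise also count normalization/ReLU/pool/SE elementwise
#'   operations (default FALSE: pure MACs).
#' @return Numeric scalar.
#' @examples
#' countMacs(compactNetConfig())
#' @export
countMacs <- function(config, includeElementwise = FALSE) {
  acct <- modelAccount(config)
  if (includeElementwise) acct$macCountElementwise else acct$macCount
}

.configToNative <- function(config) {
  list(block_channels = config@blockChannels,
       block_strides = config@blockStrides,
       use_se = config@useSE, se_ratio = config@seRatio,
       gate = config@gate, use_dropout = config@useDropout,
       dropout_rate = config@dropoutRate, fc0_width = config@fc0Width,
       n_classes = config@nClasses, input_size = config@inputSize)
}

# Kaiming-normal initial parameter list for a configuration
.initParams <- function(config, seed) {
  if (!is.null(seed)) set.seed(seed)
  params <- list()
  cin <- 3L
  for (i in seq_along(config@blockChannels)) {
    cout <- config@blockChannels[i]
    p <- sprintf("block%d_", i - 1L)
    fanin <- 9L * cin
    params[[paste0(p, "conv_w")]] <-
      array(rnorm(fanin * cout, sd = sqrt(2 / fanin)), c(3, 3, cin, cout))
    params[[paste0(p, "conv_b")]] <- numeric(cout)
    params[[paste0(p, "bn_gamma")]] <- rep(1, cout)
    params[[paste0(p, "bn_beta")]] <- numeric(cout)
    cin <- cout
  }
  if (config@useSE) {
    cFinal <- cin
    cr <- cFinal %/% config@seRatio
    params$se_w1 <- matrix(rnorm(cr * cFinal, sd = sqrt(2 / cFinal)),
                           cr, cFinal)
    params$se_b1 <- numeric(cr)
    params$se_w2 <- matrix(rnorm(cFinal * cr, sd = sqrt(2 / cr)), cFinal, cr)
    params$se_b2 <- numeric(cFinal)
  }
  flat <- .flatDim(config)
  params$fc0_w <- matrix(rnorm(config@fc0Width * flat, sd = sqrt(2 / flat)),
                         config@fc0Width, flat)
  params$fc0_b <- numeric(config@fc0Width)
  params$fc1_w <- matrix(rnorm(config@nClasses * config@fc0Width,
                               sd = sqrt(2 / config@fc0Width)),
                         config@nClasses, config@fc0Width)
  params$fc1_b <- numeric(config@nClasses)
  params
}

#' Build a compact classifier
#'
#' Instantiates the native network for a configuration. Weights are
#' Kaiming-normal initialized (deterministically when \code{seed} is given)
#' unless an explicit parameter list is supplied (e.g. from
#' \code{\link{getParams}} of a trained model).
#'
#' @param config a \linkS4class{CompactNetConfig}.
#' @param seed integer seed for weight initialization (default 1).
#' @param params optional parameter list replacing random initialization.
#' @param inputNorm list with \code{mean} and \code{sd} 3-vectors applied to
#'   [0,1]-scaled input channels (default mean 0.5, sd 0.25; training
#'   overwrites these with training-set statistics).
#' @return A \linkS4class{CompactNet}.
#' @examples
#' net <- buildModel(ablationConfig("twoBlock", inputSize = 32L), seed = 1)
#' numParameters(net)
#' @export
buildModel <- function(config, seed = 1L, params = NULL, inputNorm = NULL) {
  validObject(config)
  state <- new.env(parent = emptyenv())
  state$ptr <- .cn_create(.configToNative(config))
  if (is.null(params)) params <- .initParams(config, seed)
  .cn_set_params(state$ptr, params)
  state$params <- params
  if (is.null(inputNorm))
    inputNorm <- list(mean = rep(0.5, 3), sd = rep(0.25, 3))
  .cn_set_input_norm(state$ptr, inputNorm$mean, inputNorm$sd)
  state$inputNorm <- inputNorm
  new("CompactNet", config = config, state = state)
}

# external pointers do not survive serialization; rebuild lazily
.modelPtr <- function(model) {
  st <- model@state
  if (is.null(st$ptr) || .ptr_is_nil(st$ptr)) {
    st$ptr <- .cn_create(.configToNative(model@config))
    .cn_set_params(st$ptr, st$params)
    .cn_set_input_norm(st$ptr, st$inputNorm$mean, st$inputNorm$sd)
  }
  st$ptr
}

#' Trainable parameters of a built model
#'
#' @param model a \linkS4class{CompactNet}.
#' @return Named list of weight arrays/vectors (a checkpointable state).
#' @export
getParams <- function(model) .cn_get_params(.modelPtr(model))

#' Replace the parameters of a built model
#'
#' @param model a \linkS4class{CompactNet}.
#' @param params parameter list of matching shapes.
#' @return The model, invisibly.
#' @export
setParams <- function(model, params) {
  .cn_set_params(.modelPtr(model), params)
  model@state$params <- params
  invisible(model)
}

#' Number of trainable scalars of a built model (by tensor enumeration)
#'
#' Independent of the closed-form \code{\link{countParameters}}: enumerates
#' the instantiated network's trainable tensors and sums their lengths.
#'
#' @param model a \linkS4class{CompactNet}.
#' @return Numeric scalar.
#' @export
numParameters <- function(model) {
  sum(vapply(getParams(model), length, numeric(1)))
}

# crops -> integer pixel array (h, w, 3, n)
.cropsToArray <- function(crops) {
  if (is.array(crops) && length(dim(crops)) == 4L) return(crops)
  if (is.array(crops) && length(dim(crops)) == 3L)
    return(array(crops, c(dim(crops), 1L)))
  if (is(crops, "CellCrop")) crops <- list(crops)
  stopifnot(is.list(crops), length(crops) > 0L)
  d <- dim(pixels(crops[[1]]))
  out <- array(0L, c(d, length(crops)))
  for (i in seq_along(crops)) out[, , , i] <- pixels(crops[[i]])
  out
}

.makeDataset <- function(x) {
  d <- dim(x)
  .cn_dataset_create(as.integer(x), d[4], d[1], d[2])
}

#' Class probabilities for a batch of crops
#'
#' Deterministic evaluation-mode forward pass: dropout is inactive and
#' repeated calls on identical input are bitwise identical. Rows are softmax
#' probabilities over the six classes.
#'
#' @param model a \linkS4class{CompactNet}.
#' @param crops list of \linkS4class{CellCrop}, or an integer array
#'   h x w x 3 x n (values 0-255) matching the model's input size.
#' @param evalMode must be TRUE; training-mode (stochastic) inference is not
#'   supported.
#' @return Numeric matrix n x nClasses; rows sum to 1.
#' @export
predictProbs <- function(model, crops, evalMode = TRUE) {
  if (!isTRUE(evalMode))
    stop("training-mode prediction is not supported; use evalMode = TRUE")
  x <- .cropsToArray(crops)
  d <- dim(x)
  if (d[1] != model@config@inputSize || d[2] != model@config@inputSize)
    stop(sprintf("crops are %d x %d but the model expects %d x %d",
                 d[1], d[2], model@config@inputSize, model@config@inputSize))
  ds <- .makeDataset(x)
  p <- .cn_predict(.modelPtr(model), ds, seq_len(d[4]))
  colnames(p) <- if (model@config@nClasses == 6L) LEUKOCYTE_CLASSES else NULL
  p
}

#' Predicted class labels for a batch of crops
#'
#' @inheritParams predictProbs
#' @return Factor of class labels (argmax of \code{\link{predictProbs}}).
#' @export
predictClasses <- function(model, crops) {
  p <- predictProbs(model, crops)
  cls <- if (is.null(colnames(p))) as.character(seq_len(ncol(p))) else
    colnames(p)
  factor(cls[max.col(p, ties.method = "first")], levels = cls)
}

#' Squeeze-and-excitation forward pass (reference implementation)
#'
#' Channel attention on a C-channel feature map: per-channel global average
#' pooling, a two-layer bottleneck gate, and channel-wise rescaling. With the
#' softmax gate the channel weights are a probability vector.
#'
#' @param features C x L matrix (channels x spatial positions) or an
#'   H x W x C array.
#' @param W1 (C/r) x C matrix; \code{b1} its bias.
#' @param W2 C x (C/r) matrix; \code{b2} its bias.
#' @param b1,b2 numeric bias vectors.
#' @param gate \code{"softmax"} (default) or \code{"sigmoid"}.
#' @return Reweighted features of the same shape, with the channel weights
#'   attached as attribute \code{"weights"}.
#' @examples
#' f <- matrix(c(1, 0), 2, 8)  # two channels with means 1 and 0
#' w <- attr(seForward(f, diag(2), 0, diag(2), 0), "weights")
#' round(w, 4)
#' @export
seForward <- function(features, W1, b1 = 0, W2, b2 = 0,
                      gate = c("softmax", "sigmoid")) {
  gate <- match.arg(gate)
  asArray <- is.array(features) && length(dim(features)) == 3L
  f <- if (asArray) {
    d <- dim(features)
    t(matrix(features, d[1] * d[2], d[3]))
  } else as.matrix(features)
  s <- rowMeans(f)
  z1 <- pmax(W1 %*% s + b1, 0)
  u <- as.vector(W2 %*% z1 + b2)
  w <- if (gate == "softmax") {
    e <- exp(u - max(u)); e / sum(e)
  } else 1 / (1 + exp(-u))
  out <- f * w
  if (asArray) out <- array(t(out), dim(features))
  attr(out, "weights") <- as.vector(w)
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full configuration, the parameter list and the
#' input normalization constants, so \code{loadModel} reconstructs an
#' identical network.
#'
#' @param model a \linkS4class{CompactNet}.
#' @param path file path (RDS).
#' @return \code{saveModel}: the path, invisibly. \code{loadModel}: a
#'   \linkS4class{CompactNet}.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(config = model@config, params = getParams(model),
               inputNorm = model@state$inputNorm), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  ck <- readRDS(path)
  buildModel(ck$config, params = ck$params, inputNorm = ck$inputNorm)
}

#' Export a model account as JSON
#'
#' @param config a \linkS4class{CompactNetConfig}.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
writeModelAccount <- function(config, path) {
  acct <- modelAccount(config)
  jsonlite::write_json(
    list(n_parameters = acct$nParameters, mac_count = acct$macCount,
         mac_count_with_elementwise = acct$macCountElementwise,
         per_layer = acct$perLayer),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
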