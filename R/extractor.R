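#' Convolutional feature extractor contract
#'
#' A feature extractor is a deterministic map from a 227 x 227 3-channel
#' image to named activation vectors, one per exposed layer (rectifier and
#' dropout layers are never exposed). The production choice in the emulated
#' study is an ImageNet-pretrained AlexNet-variant; because the analysis
#' depends only on the pipeline mechanics and not on any particular
#' pretrained weights, this package ships a fixed-seed random-weight
#' AlexNet-style stack ([random_conv_extractor()]) that satisfies the same
#' contract and runs without downloads. Any object with elements
#' `layer_names` (character), `layer_dims` (named integer) and
#' `forward(pixels_227x227x3, layers)` returning a named list of numeric
#' vectors can be used wherever an extractor is expected.
#'
#' @name feature_extractor
NULL

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Random-weight AlexNet-style feature extractor
#'
#' Builds a scaled-down AlexNet-like convolutional stack with fixed-seed
#' He-initialized Gaussian weights. Exposed layers are the five
#' convolutional layers (pre-rectifier), the max-pooling layers and two
#' fully connected layers; rectifier outputs are used internally between
#' layers but never exposed as features. Identical seeds give identical
#' weights, so the extractor is deterministic.
#'
#' @param seed Integer seed for the weights.
#' @param widths Integer vector of the five convolutional widths
#'   (filters per layer).
#' @param fc_dims Integer vector of the two fully connected widths.
#' @return A `feature_extractor` object.
#' @export
random_conv_extractor <- function(seed = 42L,
                                  widths = c(12L, 24L, 32L, 32L, 24L),
                                  fc_dims = c(512L, 256L)) {
  stopifnot(length(widths) == 5L, length(fc_dims) == 2L)
  conv_spec <- list(
    conv1 = list(k = 11L, stride = 4L, pad = 0L, cout = widths[1]),
    conv2 = list(k = 5L, stride = 1L, pad = 2L, cout = widths[2]),
    conv3 = list(k = 3L, stride = 1L, pad = 1L, cout = widths[3]),
    conv4 = list(k = 3L, stride = 1L, pad = 1L, cout = widths[4]),
    conv5 = list(k = 3L, stride = 1L, pad = 1L, cout = widths[5])
  )
  pool_after <- c(conv1 = TRUE, conv2 = TRUE, conv3 = FALSE,
                  conv4 = FALSE, conv5 = TRUE)
  weights <- with_seed(seed, {
    w <- list()
    # spatial sizes through the stack, starting at 227
    size <- 227L
    cin <- 3L
    for (nm in names(conv_spec)) {
      sp <- conv_spec[[nm]]
      fan_in <- sp$k * sp$k * cin
      w[[nm]] <- list(
        W = matrix(rnorm(fan_in * sp$cout, 0, sqrt(2 / fan_in)),
                   fan_in, sp$cout),
        b = rep(0, sp$cout)
      )
      size <- (size + 2L * sp$pad - sp$k) %/% sp$stride + 1L
      if (pool_after[[nm]]) size <- (size - 3L) %/% 2L + 1L
      cin <- sp$cout
    }
    flat <- size * size * cin
    for (j in seq_along(fc_dims)) {
      nm <- paste0("fc", 5L + j)
      w[[nm]] <- list(
        W = matrix(rnorm(flat * fc_dims[j], 0, sqrt(2 / flat)),
                   fc_dims[j], flat),
        b = rep(0, fc_dims[j])
      )
      flat <- fc_dims[j]
    }
    w
  })

  # trace shapes once to publish layer dims
  dims <- integer(0)
  size <- 227L
  cin <- 3L
  for (nm in names(conv_spec)) {
    sp <- conv_spec[[nm]]
    size <- (size + 2L * sp$pad - sp$k) %/% sp$stride + 1L
    dims[[nm]] <- size * size * sp$cout
    if (pool_after[[nm]]) {
      size <- (size - 3L) %/% 2L + 1L
      dims[[paste0("pool", substring(nm, 5L))]] <- size * size * sp$cout
    }
    cin <- sp$cout
  }
  dims[["fc6"]] <- fc_dims[1]
  dims[["fc7"]] <- fc_dims[2]
  # publish in forward order
  order_names <- c("conv1", "pool1", "conv2", "pool2", "conv3", "conv4",
                   "conv5", "pool5", "fc6", "fc7")
  dims <- dims[order_names]

  structure(
    list(
      kind = "random_conv",
      seed = as.integer(seed),
      layer_names = order_names,
      layer_dims = dims,
      conv_spec = conv_spec,
      pool_after = pool_after,
      weights = weights
    ),
    class = "feature_extractor"
  )
}

# Dispatch to the extractor's forward pass; custom extractors supply a
# `forward(pixels, layers)` element.
extractor_forward <- function(extractor, pixels, layers = NULL) {
  if (identical(extractor$kind, "random_conv")) {
    forward_random_conv(extractor, pixels, layers)
  } else if (is.function(extractor$forward)) {
    extractor$forward(pixels, layers)
  } else {
    stopf("extractor does not provide a forward pass")
  }
}

forward_random_conv <- function(ext, pixels, layers = NULL) {
  if (is.null(layers)) layers <- ext$layer_names
  unknown <- setdiff(layers, ext$layer_names)
  if (length(unknown)) stopf("unknown layer(s): %s",
                             paste(unknown, collapse = ", "))
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))  # replicate gray
  }
  if (!identical(dim(pixels)[1:2], c(227L, 227L))) {
    stopf("extractor input must be 227 x 227")
  }
  # last layer we actually need, in forward order
  last <- max(match(layers, ext$layer_names))
  acts <- list()
  x <- pixels
  for (nm in names(ext$conv_spec)) {
    sp <- ext$conv_spec[[nm]]
    w <- ext$weights[[nm]]
    pre <- .conv2d_forward(x, w$W, w$b, sp$k, sp$k, sp$stride, sp$pad)
    acts[[nm]] <- as.vector(pre)
    x <- relu(pre)
    if (ext$pool_after[[nm]]) {
      x <- .maxpool_forward(x, 3L, 2L)
      acts[[paste0("pool", substring(nm, 5L))]] <- as.vector(x)
    }
    if (match(nm, ext$layer_names) >= last &&
        all(layers %in% names(acts))) break
  }
  if (!all(layers %in% names(acts))) {
    v <- as.vector(x)
    for (nm in c("fc6", "fc7")) {
      w <- ext$weights[[nm]]
      pre <- as.vector(w$W %*% v + w$b)
      acts[[nm]] <- pre
      v <- relu(pre)
      if (all(layers %in% names(acts))) break
    }
  }
  acts[layers]
}

#' Extract one layer's activations for an image
#'
#' @param image An `augmented_image` (or bare 227 x 227 matrix; grayscale is
#'   replicated to 3 channels).
#' @param extractor A [feature_extractor].
#' @param layer Layer name; must be one of `extractor$layer_names`.
#' @return Numeric activation vector of length
#'   `extractor$layer_dims[[layer]]`.
#' @export
extract_features <- function(image, extractor, layer = "conv5") {
  px <- if (inherits(image, "augmented_image")) image$pixels else image
  if (!layer %in% extractor$layer_names) {
    stopf("unknown layer '%s'", layer)
  }
  extractor_forward(extractor, px, layer)[[layer]]
}
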