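#' Convolutional Block Attention Module (CBAM)
#'
#' CBAM refines a feature map `F` (a `C x H x W` array) by two sequential
#' multiplicative attentions: a channel attention `Mc` (one weight per
#' channel, from a shared two-layer MLP over global average- and max-pooled
#' channel descriptors) followed by a spatial attention `Ms` (one weight per
#' position, from a 7x7 convolution over the channel-wise average- and
#' max-pooled planes). Both attentions pass through a sigmoid, so every
#' weight lies strictly in (0, 1) and the output magnitude never exceeds the
#' input magnitude elementwise. Shapes are preserved.
#'
#' @name cbam-module
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))

check_feature_map <- function(f) {
  if (!is.array(f) || length(dim(f)) != 3L || !all(is.finite(f))) {
    stop("feature map must be a finite C x H x W array", call. = FALSE)
  }
  if (any(dim(f) < 1L)) stop("feature map dimensions must be >= 1", call. = FALSE)
  invisible(dim(f))
}

#' Channel-attention parameters
#'
#' The shared MLP maps `C -> C/r -> C` with a ReLU in between and no bias
#' terms. `r` must divide `C`.
#'
#' @param w0 Matrix `(C/r) x C`, first MLP layer.
#' @param w1 Matrix `C x (C/r)`, second MLP layer.
#' @param r Reduction ratio.
#' @return A list of class `"cbam_channel_params"`.
#' @export
channel_params <- function(w0, w1, r) {
  w0 <- as.matrix(w0); w1 <- as.matrix(w1)
  C <- ncol(w0)
  if (r < 1L || C %% r != 0L) stop("r must be a positive divisor of C", call. = FALSE)
  if (nrow(w0) != C %/% r || nrow(w1) != C || ncol(w1) != C %/% r) {
    stop("MLP weight shapes inconsistent with C and r", call. = FALSE)
  }
  structure(list(w0 = w0, w1 = w1, r = as.integer(r)),
            class = "cbam_channel_params")
}

#' Spatial-attention parameters
#'
#' @param kernel A `2 x 7 x 7` array: 7x7 convolution weights over the
#'   stacked pooled planes (2 input channels, 1 output channel).
#' @param bias Scalar bias.
#' @param pool_order Order in which the pooled planes are stacked along the
#'   channel axis before convolution; default average first, then max.
#' @return A list of class `"cbam_spatial_params"`.
#' @export
spatial_params <- function(kernel, bias = 0, pool_order = c("avg", "max")) {
  kernel <- as.array(kernel)
  if (!identical(dim(kernel), c(2L, 7L, 7L))) {
    stop("spatial kernel must be a 2 x 7 x 7 array", call. = FALSE)
  }
  pool_order <- match.arg(pool_order, c("avg", "max"), several.ok = TRUE)
  if (length(pool_order) != 2L || anyDuplicated(pool_order)) {
    stop("pool_order must be a permutation of c(\"avg\", \"max\")", call. = FALSE)
  }
  structure(list(kernel = kernel, bias = bias, pool_order = pool_order),
            class = "cbam_spatial_params")
}

#' Deterministic CBAM parameter initialization
#'
#' Draws all weights i.i.d. uniform on \[-0.1, 0.1\] under the given seed, so
#' untrained attention modules are reproducible and non-degenerate.
#'
#' @param C Channel count of the feature maps the module will see.
#' @param r Reduction ratio (default 16; must divide `C`).
#' @param seed Integer seed.
#' @return A list with elements `channel` and `spatial`.
#' @export
init_cbam_params <- function(C, r = 16L, seed = 0L) {
  if (C %% r != 0L) stop("r must divide C", call. = FALSE)
  withr::with_seed(seed, {
    w0 <- matrix(stats::runif(C %/% r * C, -0.1, 0.1), nrow = C %/% r)
    w1 <- matrix(stats::runif(C * (C %/% r), -0.1, 0.1), nrow = C)
    k <- array(stats::runif(2 * 7 * 7, -0.1, 0.1), dim = c(2L, 7L, 7L))
    b <- stats::runif(1, -0.1, 0.1)
  })
  list(channel = channel_params(w0, w1, r), spatial = spatial_params(k, b))
}

#' Channel attention
#'
#' `Mc = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))` where both poolings are
#' global over the `H x W` positions of each channel and the MLP weights are
#' shared between the two branches.
#'
#' @param f A `C x H x W` feature map.
#' @param p [channel_params()].
#' @return Numeric vector of length `C` with values strictly in (0, 1)
#'   (the `C x 1 x 1` attention map).
#' @export
channel_attention <- function(f, p) {
  d <- check_feature_map(f)
  if (d[1L] != ncol(p$w0)) stop("channel count does not match MLP weights", call. = FALSE)
  flat <- matrix(f, nrow = d[1L])   # C x (H*W)
  avg <- rowMeans(flat)
  mx <- apply(flat, 1L, max)
  mlp <- function(v) as.numeric(p$w1 %*% pmax(p$w0 %*% v, 0))
  sigmoid(mlp(avg) + mlp(mx))
}

#' Spatial attention
#'
#' Channel-wise average- and max-pooling produce two `H x W` planes, stacked
#' along a channel axis (order per the parameters), convolved with a 7x7
#' kernel at stride 1 with zero padding 3 (so `H x W` is preserved), plus a
#' scalar bias, then passed through a sigmoid.
#'
#' @param f A `C x H x W` feature map.
#' @param p [spatial_params()].
#' @return An `H x W` matrix with values strictly in (0, 1)
#'   (the `1 x H x W` attention map).
#' @export
spatial_attention <- function(f, p) {
  d <- check_feature_map(f)
  H <- d[2L]; W <- d[3L]
  planes <- list(
    avg = apply(f, c(2L, 3L), mean),
    max = apply(f, c(2L, 3L), max)
  )
  stacked <- planes[p$pool_order]
  out <- matrix(p$bias, nrow = H, ncol = W)
  # zero-padded 7x7 convolution, accumulated shift by shift
  for (ci in 1:2) {
    plane <- stacked[[ci]]
    for (u in -3:3) {
      r_lo <- max(1L, 1L - u); r_hi <- min(H, H - u)  # rows with a valid source
      if (r_hi < r_lo) next
      rs <- r_lo:r_hi
      for (v in -3:3) {
        w <- p$kernel[ci, u + 4L, v + 4L]
        if (w == 0) next
        c_lo <- max(1L, 1L - v); c_hi <- min(W, W - v)
        if (c_hi < c_lo) next
        cs <- c_lo:c_hi
        out[rs, cs] <- out[rs, cs] + w * plane[rs + u, cs + v]
      }
    }
  }
  sigmoid(out)
}

#' Apply CBAM to a feature map
#'
#' `F' = Mc (x) F` (broadcast over positions), then `F'' = Ms (x) F'`
#' (broadcast over channels).
#'
#' @param f A `C x H x W` feature map.
#' @param cp [channel_params()].
#' @param sp [spatial_params()].
#' @return A `C x H x W` array of the same shape as `f`.
#' @export
cbam <- function(f, cp, sp) {
  d <- check_feature_map(f)
  mc <- channel_attention(f, cp)
  f1 <- f * mc                     # Mc recycles along the first (channel) axis
  ms <- spatial_attention(f1, sp)
  ms_b <- aperm(array(ms, dim = c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  f1 * ms_b
}

#' Four-stream CBAM
#'
#' Applies an independent CBAM to each of four feature-map streams, as when
#' attention modules are inserted at four points of a detection neck. Order
#' is preserved.
#'
#' @param streams List of exactly four `C x H x W` arrays (shapes may differ
#'   between streams).
#' @param params List of exactly four `list(channel =, spatial =)` parameter
#'   pairs, as from [init_cbam_params()].
#' @return A list of four refined feature maps.
#' @export
apply_4cbam <- function(streams, params) {
  if (!is.list(streams) || length(streams) != 4L) {
    stop("exactly four feature-map streams are required", call. = FALSE)
  }
  if (!is.list(params) || length(params) != 4L) {
    stop("exactly four parameter pairs are required", call. = FALSE)
  }
  lapply(1:4, function(i) cbam(streams[[i]], params[[i]]$channel, params[[i]]$spatial))
}

#' Serialize CBAM parameters to JSON
#'
#' A portable named-array container: shapes plus flat value vectors.
#'
#' @param params A `list(channel =, spatial =)` pair.
#' @param path Output file path.
#' @export
write_cbam_params <- function(params, path) {
  obj <- list(
    w0 = list(dim = dim(params$channel$w0), values = as.numeric(params$channel$w0)),
    w1 = list(dim = dim(params$channel$w1), values = as.numeric(params$channel$w1)),
    r = params$channel$r,
    kernel = list(dim = dim(params$spatial$kernel),
                  values = as.numeric(params$spatial$kernel)),
    bias = params$spatial$bias,
    pool_order = params$spatial$pool_order
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cbam_params
#' @export
read_cbam_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    channel = channel_params(
      array(obj$w0$values, dim = obj$w0$dim),
      array(obj$w1$values, dim = obj$w1$dim), obj$r),
    spatial = spatial_params(
      array(obj$kernel$values, dim = obj$kernel$dim), obj$bias, obj$pool_order)
  )
}
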