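# Forward and backward passes. Feature maps are H x W x C arrays; the
# convolution, pooling and upsampling primitives live in compiled code.
# Each forward pass returns the prediction plus the cache needed for the
# matching backward pass (layer inputs, pre-activations, pooling argmaxes).

act_fwd <- function(z, act) {
  switch(act,
    relu = z * (z > 0),
    lrelu = z * (z > 0) + LRELU_ALPHA * z * (z <= 0),
    none = z)
}

act_grad <- function(da, z, act) {
  switch(act,
    relu = da * (z > 0),
    lrelu = da * ((z > 0) + LRELU_ALPHA * (z <= 0)),
    none = da)
}

as_cube <- function(x) {
  if (is.matrix(x)) array(x, c(nrow(x), ncol(x), 1L)) else x
}

concat_ch <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3]))
  out[, , seq_len(d[3])] <- a
  out[, , d[3] + seq_len(dim(b)[3])] <- b
  out
}

# ---- W5: global-residual chain --------------------------------------------

w5_forward <- function(model, x, with_cache = FALSE) {
  h <- as_cube(x)
  n <- length(model$layers)
  cache <- if (with_cache) vector("list", n)
  for (l in seq_len(n)) {
    ly <- model$layers[[l]]
    z <- conv2d_fwd(h, ly$w, ly$b, ly$K)
    if (with_cache) cache[[l]] <- list(inp = h, z = z)
    h <- act_fwd(z, ly$act)
  }
  list(y = x + h[, , 1L], cache = cache)
}

w5_backward <- function(model, cache, dy) {
  n <- length(model$layers)
  dh <- as_cube(dy)
  grads <- vector("list", n)
  for (l in rev(seq_len(n))) {
    ly <- model$layers[[l]]
    dz <- act_grad(dh, cache[[l]]$z, ly$act)
    g <- conv2d_bwd(cache[[l]]$inp, ly$w, dz, ly$K)
    grads[[l]] <- list(w = g$dw, b = as.numeric(g$db))
    dh <- g$dx
  }
  grads
}

# ---- DN: per-layer residual accumulator -----------------------------------

dn_forward <- function(model, x, with_cache = FALSE) {
  h <- as_cube(x)
  acc <- x
  n <- length(model$layers)
  Fch <- model$spec$n_filters_F
  cache <- if (with_cache) vector("list", n)
  for (l in seq_len(n)) {
    ly <- model$layers[[l]]
    z <- conv2d_fwd(h, ly$w, ly$b, ly$K)
    if (with_cache) cache[[l]] <- list(inp = h, z = z)
    acc <- acc + z[, , Fch + 1L]                 # linear residual channel
    if (l < n) h <- act_fwd(z[, , seq_len(Fch), drop = FALSE], ly$act)
  }
  list(y = acc, cache = cache)
}

dn_backward <- function(model, cache, dy) {
  n <- length(model$layers)
  Fch <- model$spec$n_filters_F
  grads <- vector("list", n)
  dfeat <- NULL
  for (l in rev(seq_len(n))) {
    ly <- model$layers[[l]]
    z <- cache[[l]]$z
    dz <- array(0, dim(z))
    dz[, , Fch + 1L] <- dy                       # every residual sees dy
    if (l < n) {
      zf <- z[, , seq_len(Fch), drop = FALSE]
      dz[, , seq_len(Fch)] <- act_grad(dfeat, zf, ly$act)
    }
    g <- conv2d_bwd(cache[[l]]$inp, ly$w, dz, ly$K)
    grads[[l]] <- list(w = g$dw, b = as.numeric(g$db))
    dfeat <- g$dx
  }
  grads
}

# ---- N2N: U-Net-style encoder/decoder -------------------------------------

n2n_conv <- function(model, name, h, cache, with_cache) {
  ly <- model$layers[[model$layer_index[[name]]]]
  z <- conv2d_fwd(h, ly$w, ly$b, ly$K)
  if (with_cache) cache[[name]] <- list(inp = h, z = z)
  list(a = act_fwd(z, ly$act), cache = cache)
}

n2n_forward <- function(model, x, with_cache = FALSE) {
  if (is.null(model$layer_index)) {
    model$layer_index <- setNames(seq_along(model$layers),
                                  vapply(model$layers, `[[`, "", "name"))
  }
  cache <- list()
  xc <- as_cube(x)
  if (any(dim(xc)[1:2] %% 32L != 0L)) {
    abort("N2N input dimensions must be divisible by 32 (use denoise() for automatic padding)",
          class = "carsdenoise_data_error")
  }
  cv <- function(name, h) {
    r <- n2n_conv(model, name, h, cache, with_cache)
    cache <<- r$cache
    r$a
  }
  pool <- function(name, h) {
    p <- maxpool2_fwd(h)
    if (with_cache) cache[[paste0(name, "_idx")]] <<- p$idx
    p$y
  }
  a0 <- cv("enc0", xc)
  a1 <- cv("enc1", a0);  p1 <- pool("p1", a1)
  a2 <- cv("enc2", p1);  p2 <- pool("p2", a2)
  a3 <- cv("enc3", p2);  p3 <- pool("p3", a3)
  a4 <- cv("enc4", p3);  p4 <- pool("p4", a4)
  a5 <- cv("enc5", p4);  p5 <- pool("p5", a5)
  a6 <- cv("enc6", p5)
  d5 <- cv("dec5b", cv("dec5a", concat_ch(upsample2_fwd(a6), p4)))
  d4 <- cv("dec4b", cv("dec4a", concat_ch(upsample2_fwd(d5), p3)))
  d3 <- cv("dec3b", cv("dec3a", concat_ch(upsample2_fwd(d4), p2)))
  d2 <- cv("dec2b", cv("dec2a", concat_ch(upsample2_fwd(d3), p1)))
  y <- cv("dec1c", cv("dec1b", cv("dec1a", concat_ch(upsample2_fwd(d2), xc))))
  list(y = y[, , 1L], cache = cache, layer_index = model$layer_index)
}

n2n_backward <- function(model, cache, dy, layer_index) {
  model$layer_index <- layer_index
  grads <- vector("list", length(model$layers))
  cvb <- function(name, da) {
    idx <- layer_index[[name]]
    ly <- model$layers[[idx]]
    dz <- act_grad(da, cache[[name]]$z, ly$act)
    g <- conv2d_bwd(cache[[name]]$inp, ly$w, dz, ly$K)
    grads[[idx]] <<- list(w = g$dw, b = as.numeric(g$db))
    g$dx
  }
  split_ch <- function(d, n_first) {
    list(a = d[, , seq_len(n_first), drop = FALSE],
         b = d[, , -seq_len(n_first), drop = FALSE])
  }
  F <- model$spec$n_filters_F
  dd <- cvb("dec1a", cvb("dec1b", cvb("dec1c", as_cube(dy))))
  sp <- split_ch(dd, 2L * F)                    # (up(d2), input)
  dd2 <- upsample2_bwd(sp$a)
  dd <- cvb("dec2a", cvb("dec2b", dd2))
  sp <- split_ch(dd, 2L * F)                    # (up(d3), p1)
  dp1 <- sp$b
  dd <- cvb("dec3a", cvb("dec3b", upsample2_bwd(sp$a)))
  sp <- split_ch(dd, 2L * F)                    # (up(d4), p2)
  dp2 <- sp$b
  dd <- cvb("dec4a", cvb("dec4b", upsample2_bwd(sp$a)))
  sp <- split_ch(dd, 2L * F)                    # (up(d5), p3)
  dp3 <- sp$b
  dd <- cvb("dec5a", cvb("dec5b", upsample2_bwd(sp$a)))
  sp <- split_ch(dd, F)                         # (up(a6), p4)
  dp4 <- sp$b
  da6 <- upsample2_bwd(sp$a)
  dp5 <- cvb("enc6", da6)
  da5 <- maxpool2_bwd(dp5, cache$p5_idx)
  dp4 <- dp4 + cvb("enc5", da5)
  da4 <- maxpool2_bwd(dp4, cache$p4_idx)
  dp3 <- dp3 + cvb("enc4", da4)
  da3 <- maxpool2_bwd(dp3, cache$p3_idx)
  dp2 <- dp2 + cvb("enc3", da3)
  da2 <- maxpool2_bwd(dp2, cache$p2_idx)
  dp1 <- dp1 + cvb("enc2", da2)
  da1 <- maxpool2_bwd(dp1, cache$p1_idx)
  da0 <- cvb("enc1", da1)
  cvb("enc0", da0)
  grads
}

net_forward <- function(model, x, with_cache = FALSE) {
  switch(model$spec$family,
    W5 = w5_forward(model, x, with_cache),
    DN = dn_forward(model, x, with_cache),
    N2N = n2n_forward(model, x, with_cache))
}

net_backward <- function(model, fwd, dy) {
  switch(model$spec$family,
    W5 = w5_backward(model, fwd$cache, dy),
    DN = dn_backward(model, fwd$cache, dy),
    N2N = n2n_backward(model, fwd$cache, dy, fwd$layer_index))
}

pad_to_multiple <- function(img, m) {
  H <- nrow(img); W <- ncol(img)
  Hp <- ceiling(H / m) * m
  Wp <- ceiling(W / m) * m
  if (Hp == H && Wp == W) return(list(img = img, H = H, W = W))
  ri <- c(seq_len(H), rev(seq_len(H))[seq_len(Hp - H)])   # reflect
  ci <- c(seq_len(W), rev(seq_len(W))[seq_len(Wp - W)])
  list(img = img[ri, ci, drop = FALSE], H = H, W = W)
}

#' Denoise an image
#'
#' Applies the model's stored input normalisation, runs the forward pass
#' (reflect-padding N2N inputs to a multiple of 32 and cropping back), and
#' rescales the output.
#'
#' @param model A built (ideally trained) `denoiser` or a
#'   `denoiser_ensemble`.
#' @param image A finite numeric matrix.
#' @return A denoised matrix of the same shape.
#' @export
denoise <- function(model, image) {
  UseMethod("denoise")
}

#' @export
denoise.denoiser <- function(model, image) {
  if (!is.matrix(image) || !all(is.finite(image))) {
    abort("`image` must be a finite numeric matrix",
          class = "carsdenoise_data_error")
  }
  s <- model$norm$scale %||% 1
  x <- image / s
  if (model$spec$family == "N2N") {
    p <- pad_to_multiple(x, 32L)
    y <- net_forward(model, p$img)$y[seq_len(p$H), seq_len(p$W), drop = FALSE]
  } else {
    y <- net_forward(model, x)$y
  }
  y * s
}
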