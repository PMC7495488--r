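# Denoiser architectures. All three families map an H x W single-channel
# image to an H x W image and are built from the (F, K, L) hyperparameter
# triple: F filters per convolution, K x K kernels, L convolution layers.
#
#   W5  — a shallow chain of convolutions with one global residual skip:
#         output = input + conv_chain(input). L counts the interior layers
#         between the 1->F head and the F->1 tail (so L = 8 means 10
#         convolutions in total).
#   DN  — a chain like W5, but every layer additionally emits one linear
#         single-channel projection that is summed into a running output
#         accumulator initialised with the input (a per-layer residual).
#         L counts all convolution layers.
#   N2N — a U-Net-style encoder-decoder with 5 max-pooling stages, skip
#         concatenations, nearest-neighbour upsampling and leaky ReLU
#         (alpha = 0.1). The encoder uses F filters, the decoder 2F,
#         except the last three layers (64, 32, 1). K = 3 and L = 18 are
#         fixed. Inputs must be divisible by 32 (training) or are
#         reflect-padded and cropped back (inference).

LRELU_ALPHA <- 0.1

#' Specify a denoiser architecture
#'
#' @param family `"W5"`, `"DN"` or `"N2N"`.
#' @param n_filters_F Filters per convolution layer (encoder filters for
#'   N2N).
#' @param kernel_K Odd kernel size. Fixed to 3 for N2N.
#' @param n_layers_L Number of convolution layers (see family conventions
#'   above). Fixed to 18 for N2N.
#' @return An object of class `arch_spec`.
#' @export
#' @examples
#' arch_spec("W5", 16, 3, 8)     # the selected shallow-residual model
#' arch_spec("DN", 32, 5, 10)    # the selected per-layer-residual model
#' arch_spec("N2N", 48)          # the selected U-Net-style model
arch_spec <- function(family = c("W5", "DN", "N2N"), n_filters_F = 16,
                      kernel_K = 3L, n_layers_L = NULL) {
  family <- match.arg(family)
  if (family == "N2N") {
    if (!is.null(n_layers_L) && n_layers_L != 18L) {
      abort("N2N has a fixed 18-convolution topology",
            class = "carsdenoise_config_error")
    }
    if (kernel_K != 3L) {
      abort("N2N uses 3x3 kernels only", class = "carsdenoise_config_error")
    }
    n_layers_L <- 18L
  }
  n_layers_L <- n_layers_L %||% switch(family, W5 = 8L, DN = 10L)
  check_scalar_number(n_filters_F, "n_filters_F", lower = 1)
  check_scalar_number(kernel_K, "kernel_K", lower = 1)
  check_scalar_number(n_layers_L, "n_layers_L", lower = 1)
  if (kernel_K %% 2 == 0) {
    abort("`kernel_K` must be odd", class = "carsdenoise_config_error")
  }
  structure(list(family = family, n_filters_F = as.integer(n_filters_F),
                 kernel_K = as.integer(kernel_K),
                 n_layers_L = as.integer(n_layers_L)), class = "arch_spec")
}

he_uniform <- function(fan_in, n_out) {
  lim <- sqrt(6 / fan_in)
  matrix(runif(n_out * fan_in, -lim, lim), n_out, fan_in)
}

new_conv <- function(in_ch, out_ch, K, act, name) {
  list(w = he_uniform(K * K * in_ch, out_ch), b = numeric(out_ch),
       K = as.integer(K), act = act, in_ch = in_ch, out_ch = out_ch,
       name = name)
}

w5_channel_plan <- function(F, L, convention) {
  n_total <- if (convention == "interior") L + 2L else L
  if (n_total < 2L) {
    abort("W5 needs at least a head and a tail convolution",
          class = "carsdenoise_config_error")
  }
  list(n_total = n_total,
       in_ch = c(1L, rep(F, n_total - 1L)),
       out_ch = c(rep(F, n_total - 1L), 1L))
}

n2n_layer_table <- function(F) {
  # name, in_ch, out_ch, act; the 18-convolution schedule with 2
  # convolutions per resolution level and the fixed 64/32/1 tail.
  tibble::tribble(
    ~name,    ~in_ch,      ~out_ch,  ~act,
    "enc0",   1L,          F,        "lrelu",
    "enc1",   F,           F,        "lrelu",
    "enc2",   F,           F,        "lrelu",
    "enc3",   F,           F,        "lrelu",
    "enc4",   F,           F,        "lrelu",
    "enc5",   F,           F,        "lrelu",
    "enc6",   F,           F,        "lrelu",
    "dec5a",  2L * F,      2L * F,   "lrelu",
    "dec5b",  2L * F,      2L * F,   "lrelu",
    "dec4a",  3L * F,      2L * F,   "lrelu",
    "dec4b",  2L * F,      2L * F,   "lrelu",
    "dec3a",  3L * F,      2L * F,   "lrelu",
    "dec3b",  2L * F,      2L * F,   "lrelu",
    "dec2a",  3L * F,      2L * F,   "lrelu",
    "dec2b",  2L * F,      2L * F,   "lrelu",
    "dec1a",  2L * F + 1L, 64L,      "lrelu",
    "dec1b",  64L,         32L,      "lrelu",
    "dec1c",  32L,         1L,       "none"
  )
}

#' Build a denoiser from an architecture specification
#'
#' Initialises weights (He-uniform, seeded) for the requested family.
#'
#' @param spec An [arch_spec()].
#' @param seed Integer seed for weight initialisation.
#' @param convention Layer-count convention for `n_layers_L`: `"auto"`
#'   (interior count for W5, total count for DN), `"interior"` or
#'   `"total"`. N2N ignores it.
#' @return An object of class `denoiser`.
#' @export
build_denoiser <- function(spec, seed = 1L,
                           convention = c("auto", "interior", "total")) {
  if (!inherits(spec, "arch_spec")) {
    abort("`spec` must be an `arch_spec`", class = "carsdenoise_config_error")
  }
  convention <- match.arg(convention)
  F <- spec$n_filters_F; K <- spec$kernel_K; L <- spec$n_layers_L
  layers <- with_seed_(seed, switch(spec$family,
    W5 = {
      conv <- if (convention == "auto") "interior" else convention
      plan <- w5_channel_plan(F, L, conv)
      ls <- lapply(seq_len(plan$n_total), function(i) {
        act <- if (i == plan$n_total) "none" else "relu"
        new_conv(plan$in_ch[i], plan$out_ch[i], K, act, paste0("conv", i))
      })
      # zero-init the residual branch output: the untrained net is the
      # identity map, the natural starting point for a residual denoiser
      ls[[plan$n_total]]$w[] <- 0
      ls
    },
    DN = {
      conv <- if (convention == "auto") "total" else convention
      n_total <- if (conv == "interior") L + 2L else L
      lapply(seq_len(n_total), function(i) {
        in_ch <- if (i == 1L) 1L else F
        ly <- new_conv(in_ch, F + 1L, K, "relu", paste0("conv", i))
        ly$w[F + 1L, ] <- 0          # zero-init every residual projection
        ly
      })
    },
    N2N = {
      tab <- n2n_layer_table(F)
      purrr::pmap(tab, function(name, in_ch, out_ch, act) {
        new_conv(in_ch, out_ch, 3L, act, name)
      })
    }
  ))
  structure(list(spec = spec, layers = layers,
                 norm = list(scale = NULL), seed = as.integer(seed)),
            class = "denoiser")
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (weights plus biases). For a 4-member
#' ensemble the count is exactly four times a single member's.
#'
#' @param model A `denoiser` or `denoiser_ensemble`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  UseMethod("count_parameters")
}

#' @export
count_parameters.denoiser <- function(model) {
  sum(vapply(model$layers, function(l) length(l$w) + length(l$b), double(1)))
}

#' @export
count_parameters.denoiser_ensemble <- function(model) {
  sum(vapply(model$members, count_parameters, double(1)))
}

#' Per-layer architecture summary
#'
#' @param object A `denoiser`.
#' @param ... Unused.
#' @return A tibble with one row per convolution layer: name, input/output
#'   channels, kernel, activation and parameter count.
#' @export
summary.denoiser <- function(object, ...) {
  purrr::map_dfr(object$layers, function(l) {
    tibble::tibble(layer = l$name, in_ch = l$in_ch, out_ch = l$out_ch,
                   kernel = l$K, activation = l$act,
                   parameters = length(l$w) + length(l$b))
  })
}

#' @export
print.denoiser <- function(x, ...) {
  cat(sprintf("<denoiser %s (F=%d, K=%d, L=%d): %d convolutions, %s parameters%s>\n",
              x$spec$family, x$spec$n_filters_F, x$spec$kernel_K,
              x$spec$n_layers_L, length(x$layers),
              format(count_parameters(x), big.mark = ","),
              if (is.null(x$norm$scale)) ", untrained" else ""))
  invisible(x)
}

#' Default grid-search hyperparameter space
#'
#' The per-family (F, K, L) grids used for model selection: DN crosses
#' F in (64, 32, 16, 8), K in (7, 5, 3), L in (25, 20, 15, 10); W5 crosses
#' F in (128, 64, 32, 16, 8), K in (7, 5, 3), L in (10, 8, 6, 5, 4); N2N
#' varies only F in (128, 96, 64, 48, 32).
#'
#' @param family `"W5"`, `"DN"` or `"N2N"`.
#' @return A tibble of `family`, `n_filters_F`, `kernel_K`, `n_layers_L`
#'   rows in canonical F, K, L order.
#' @export
grid_space <- function(family = c("W5", "DN", "N2N")) {
  family <- match.arg(family)
  g <- switch(family,
    DN = tidyr::expand_grid(n_filters_F = c(64L, 32L, 16L, 8L),
                            kernel_K = c(7L, 5L, 3L),
                            n_layers_L = c(25L, 20L, 15L, 10L)),
    W5 = tidyr::expand_grid(n_filters_F = c(128L, 64L, 32L, 16L, 8L),
                            kernel_K = c(7L, 5L, 3L),
                            n_layers_L = c(10L, 8L, 6L, 5L, 4L)),
    N2N = tidyr::expand_grid(n_filters_F = c(128L, 96L, 64L, 48L, 32L),
                             kernel_K = 3L, n_layers_L = 18L)
  )
  dplyr::mutate(g, family = family, .before = 1)
}
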