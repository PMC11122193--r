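#' @name model_spec
#' @title Declarative CNN architecture specs with analytic parameter counts
#'
#' @description
#' The classifier used to benchmark GC features is a small CNN: three
#' blocks of \[convolution (32 filters, ReLU, same padding, bias) +
#' average pooling (stride = pool size, valid)\], then flatten, two dense
#' layers of 512 units, a dropout of 0.1, and a softmax output. Rather
#' than depending on a deep-learning framework, the architecture is
#' represented declaratively and its trainable-parameter count is derived
#' analytically by shape propagation: convolutions contribute
#' kh*kw*c_in*filters + filters, dense layers in*units + units, and
#' pooling/flatten/dropout contribute nothing.
NULL

layer <- function(kind, ...) c(list(kind = kind), list(...))

#' Build the 2-D CNN spec for GC-feature input
#'
#' Input plane (2, n_nodes_total, 1): the radius row and the center row of
#' all patches concatenated. Convolutions use a (1 x 3) kernel, pools
#' (1 x 2), so only the width shrinks (three halvings). The resulting
#' parameter count depends only on the total node count M*N of the source
#' image, not on the patch size.
#'
#' @param n_nodes_total Total nodes per image (P * N = M * N pixels);
#'   must be at least 8 so three pool halvings are possible.
#' @param n_classes Number of output classes.
#' @return A `model_spec`.
#' @examples
#' count_parameters(build_gcfe_2d_spec(784, 47))  # 3504879
#' @export
build_gcfe_2d_spec <- function(n_nodes_total, n_classes) {
  if (n_nodes_total < 8L) {
    stop("n_nodes_total must be >= 8 to allow three pool halvings",
         call. = FALSE)
  }
  new_model_spec(
    input = c(2L, as.integer(n_nodes_total), 1L),
    conv_kernel = c(1L, 3L), pool_kernel = c(1L, 2L),
    n_classes = n_classes
  )
}

#' Build the 2-D CNN spec for stacked standard-Laplacian input
#'
#' The P per-patch N x N Laplacians are stacked vertically into a
#' (P*N, N, 1) plane; convolutions use (3 x 3) kernels and pools (2 x 2)
#' with floor division on odd dimensions.
#'
#' @param p_patches Number of patches P.
#' @param n_nodes Nodes per patch N (= patch_size^2).
#' @param n_classes Number of output classes.
#' @return A `model_spec`.
#' @examples
#' count_parameters(build_laplacian_2d_spec(4, 196, 47))  # 38841263
#' @export
build_laplacian_2d_spec <- function(p_patches, n_nodes, n_classes) {
  new_model_spec(
    input = c(as.integer(p_patches * n_nodes), as.integer(n_nodes), 1L),
    conv_kernel = c(3L, 3L), pool_kernel = c(2L, 2L),
    n_classes = n_classes
  )
}

new_model_spec <- function(input, conv_kernel, pool_kernel, n_classes) {
  layers <- list()
  for (b in 1:3) {
    layers <- c(layers, list(
      layer("conv", kernel = conv_kernel, filters = 32L,
            padding = "same", stride = 1L, activation = "relu"),
      layer("avgpool", kernel = pool_kernel, padding = "valid",
            stride = pool_kernel)
    ))
  }
  layers <- c(layers, list(
    layer("flatten"),
    layer("dense", units = 512L, activation = "relu"),
    layer("dense", units = 512L, activation = "relu"),
    layer("dropout", rate = 0.1),
    layer("output", units = as.integer(n_classes), activation = "softmax")
  ))
  spec <- structure(
    list(input = input, layers = layers, n_classes = as.integer(n_classes)),
    class = "model_spec"
  )
  propagate_shapes(spec)  # errors early if a pooled dim collapses
  spec
}

#' Propagate tensor shapes through a model spec
#'
#' Same-padded convolutions preserve spatial dimensions and set channels
#' to the filter count; valid average pooling with stride equal to its
#' kernel maps each pooled dimension d to floor(d / k); flatten collapses
#' to h*w*c.
#'
#' @param spec A `model_spec`.
#' @return A list with one output shape per layer (spatial dims or flat
#'   width), plus per-layer parameter counts in attribute `"params"`.
#' @export
propagate_shapes <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  shape <- spec$input  # (h, w, c)
  shapes <- vector("list", length(spec$layers))
  params <- numeric(length(spec$layers))
  for (li in seq_along(spec$layers)) {
    ly <- spec$layers[[li]]
    if (ly$kind == "conv") {
      params[li] <- prod(ly$kernel) * shape[3L] * ly$filters + ly$filters
      shape[3L] <- ly$filters
    } else if (ly$kind == "avgpool") {
      shape[1:2] <- shape[1:2] %/% ly$kernel
      if (any(shape[1:2] < 1L)) {
        stop(sprintf("pooled dimension collapsed to zero at layer %d", li),
             call. = FALSE)
      }
    } else if (ly$kind == "flatten") {
      shape <- prod(shape)
    } else if (ly$kind %in% c("dense", "output")) {
      params[li] <- shape[1L] * ly$units + ly$units
      shape <- ly$units
    }  # dropout: shape and params unchanged
    shapes[[li]] <- shape
  }
  structure(shapes, params = params)
}

#' Count trainable parameters of a model spec
#'
#' Exact integer sum over layers: conv layers contribute
#' kh*kw*c_in*filters + filters, dense/output layers in*units + units,
#' pooling/flatten/dropout zero.
#'
#' @param spec A `model_spec`.
#' @return Exact integer-valued count (as a double, since counts exceed
#'   .Machine$integer.max for large inputs).
#' @export
count_parameters <- function(spec) {
  sum(attr(propagate_shapes(spec), "params"))
}

#' @export
print.model_spec <- function(x, ...) {
  shapes <- propagate_shapes(x)
  params <- attr(shapes, "params")
  cat(sprintf("CNN spec: input (%s), %d classes\n",
              paste(x$input, collapse = ", "), x$n_classes))
  for (li in seq_along(x$layers)) {
    ly <- x$layers[[li]]
    desc <- switch(ly$kind,
      conv = sprintf("conv %dx%d x%d same", ly$kernel[1L], ly$kernel[2L],
                     ly$filters),
      avgpool = sprintf("avgpool %dx%d", ly$kernel[1L], ly$kernel[2L]),
      flatten = "flatten",
      dense = sprintf("dense %d", ly$units),
      dropout = sprintf("dropout %.1f", ly$rate),
      output = sprintf("output %d softmax", ly$units)
    )
    cat(sprintf("  %-22s -> (%s)  params %s\n", desc,
                paste(shapes[[li]], collapse = ", "),
                format(params[li], big.mark = ",", scientific = FALSE)))
  }
  cat(sprintf("Total trainable parameters: %s (%.6f x 10^6)\n",
              format(sum(params), big.mark = ",", scientific = FALSE),
              sum(params) / 1e6))
  invisible(x)
}

#' Deterministic train/validation/test split indices
#'
#' Sizes are floor(n * ratio) for all but the last split, which takes the
#' remainder; the 70/15/15 convention on 1000 samples gives 700/150/150.
#'
#' @param n Number of samples.
#' @param ratios Split proportions summing to 1.
#' @param seed Optional seed for the permutation; `NULL` leaves the order
#'   sequential.
#' @return A list of index vectors, one per ratio.
#' @export
split_indices <- function(n, ratios = c(0.7, 0.15, 0.15), seed = NULL) {
  stopifnot(abs(sum(ratios) - 1) < 1e-8, n >= length(ratios))
  idx <- seq_len(n)
  if (!is.null(seed)) {
    idx <- withr::with_seed(seed, sample(idx))
  }
  sizes <- floor(n * ratios)
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  split(idx, rep(seq_along(sizes), times = sizes))
}

#' Train and evaluate a CNN spec on extracted features
#'
#' Training the classifier requires a deep-learning backend (keras or
#' torch); the feature-extraction core of this package deliberately does
#' not depend on one. When no backend is installed this function raises a
#' classed capability error rather than silently degrading.
#'
#' @param spec A `model_spec`.
#' @param features Feature array laid out per [gcfe_layout_1d()] /
#'   [gcfe_layout_2d()], samples in the first dimension.
#' @param labels Integer class labels.
#' @param epochs Training epochs (default 10).
#' @param split Train/validation/test proportions (default 70/15/15).
#' @param seed Seed for the split permutation.
#' @return A list with accuracy, F1, recall and precision on the test
#'   split (when a backend is available).
#' @export
train_and_evaluate <- function(spec, features, labels, epochs = 10L,
                               split = c(0.7, 0.15, 0.15), seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  backend <- c("keras", "torch")
  available <- backend[vapply(backend, requireNamespace, logical(1),
                              quietly = TRUE)]
  if (length(available) == 0L) {
    stop(structure(
      class = c("gcfe_capability_error", "error", "condition"),
      list(message = paste(
        "no deep-learning backend available: training requires the",
        "'keras' or 'torch' package; feature extraction and parameter",
        "counting work without one"
      ), call = sys.call())
    ))
  }
  stop("backend training harness not implemented for: ",
       paste(available, collapse = ", "), call. = FALSE)
}
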