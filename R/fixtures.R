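#' Generate a deterministic synthetic test image
#'
#' Byte-reproducible 8-bit images for exercising every pipeline stage
#' without external data: `constant` (all pixels `value`), `checkerboard`
#' (alternating `value`/`value2`, top-left = `value`), `gradient` (left-to-
#' right linear ramp from `value` to `value2`), and `random` (seeded
#' uniform integers in \[`value`, `value2`\]).
#'
#' @param kind One of `"constant"`, `"checkerboard"`, `"gradient"`,
#'   `"random"`.
#' @param height,width Image dimensions (rows, columns).
#' @param value,value2 Intensity parameters in \[0, 255\]; defaults 0 and
#'   255 except `constant`, which uses `value = 128`.
#' @param seed Seed for `kind = "random"` (default 1).
#' @return An integer-valued height x width matrix of 0-255 intensities.
#' @examples
#' synth_image("checkerboard", 2, 2)           # [[0,255],[255,0]]
#' identical(synth_image("random", 8, 8, seed = 7),
#'           synth_image("random", 8, 8, seed = 7))
#' @export
synth_image <- function(kind = c("constant", "checkerboard", "gradient",
                                 "random"),
                        height, width, value = NULL, value2 = 255L,
                        seed = 1L) {
  kind <- match.arg(kind)
  height <- as.integer(height)
  width <- as.integer(width)
  stopifnot(height >= 1L, width >= 1L)
  if (is.null(value)) value <- if (kind == "constant") 128L else 0L
  switch(kind,
    constant = matrix(as.integer(value), height, width),
    checkerboard = {
      parity <- outer(seq_len(height), seq_len(width), "+") %% 2L
      matrix(ifelse(parity == 0L, as.integer(value), as.integer(value2)),
             height, width)
    },
    gradient = {
      ramp <- if (width == 1L) value else
        round(seq(value, value2, length.out = width))
      matrix(rep(as.integer(ramp), each = height), height, width)
    },
    random = withr::with_seed(as.integer(seed), {
      matrix(sample(seq.int(value, value2), height * width, replace = TRUE),
             height, width)
    })
  )
}

#' The 4 x 4 walkthrough sample image
#'
#' A fixed, seeded synthetic 4 x 4 image used in the documentation to walk
#' through the pipeline at a size small enough to inspect by hand. (It is a
#' stand-in: the published flowchart's pixel values are not printed, so
#' only structurally forced facts are asserted about it — with patch size
#' 2 and the pairwise graph, every GC center is 3 and every radius is at
#' most 3.)
#'
#' @return A 4 x 4 integer matrix of 0-255 intensities.
#' @export
fig_sample_4x4 <- function() {
  synth_image("random", 4L, 4L, seed = 42L)
}
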