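#' Nimble image-sharpening filter
#'
#' Sharpens an image by amplifying the difference between each pixel and the
#' mean of its four axial neighbours:
#' \deqn{S(m,n) = \alpha I(m,n) + (1-\alpha)\,\frac{I(m,n+1)+I(m,n-1)+I(m+1,n)+I(m-1,n)}{4}}
#' With \eqn{\alpha = 2} (the default) this adds the negative discrete
#' Laplacian response to the image, boosting edges while leaving flat
#' regions untouched. The filter coefficients sum to one, so the operator
#' is affine-equivariant and constant images are fixed points.
#'
#' @param image numeric matrix (grayscale) or height x width x 3 array with
#'   intensities in `[0, 255]`. Both dimensions must be at least 3 so every
#'   interior pixel has four neighbours. Colour images are filtered per
#'   channel.
#' @param alpha sharpening strength, a scalar `>= 1`. `alpha = 1` is the
#'   identity; larger values sharpen more. Default 2.
#' @param boundary how to supply the missing neighbours at the image border:
#'   `"replicate"` (nearest edge pixel, default), `"reflect"` (mirror
#'   without repeating the edge), or `"zero"`.
#' @param clip clip the result back into `[0, 255]`? Default `TRUE`; set
#'   `FALSE` to inspect the raw filter response (used e.g. when testing
#'   affine equivariance).
#'
#' @return An array of the same shape as `image`.
#' @examples
#' img <- matrix(6, 3, 3); img[2, 2] <- 10
#' nimble_sharpen(img, alpha = 2)[2, 2]  # 2*10 - 6 = 14
#' @export
nimble_sharpen <- function(image, alpha = 2,
                           boundary = c("replicate", "reflect", "zero"),
                           clip = TRUE) {
  boundary <- match.arg(boundary)
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha)) {
    abort("`alpha` must be a single finite number.", class = "braincdnet_parameter_error")
  }
  if (alpha < 1) {
    abort("`alpha` must be >= 1 (1 is the identity limit).",
          class = "braincdnet_parameter_error")
  }
  check_raw_image(image, min_side = 3)

  if (is.matrix(image)) {
    out <- nimble_channel(image, alpha, boundary)
  } else {
    out <- image
    for (ch in seq_len(dim(image)[3])) {
      out[, , ch] <- nimble_channel(image[, , ch], alpha, boundary)
    }
  }
  if (clip) out <- pmin(pmax(out, 0), 255)
  out
}

# Filter one channel. Neighbour access is vectorised by padding the matrix
# by one pixel on each side according to the boundary policy.
nimble_channel <- function(x, alpha, boundary) {
  h <- nrow(x)
  w <- ncol(x)
  p <- matrix(0, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- x
  idx <- switch(boundary,
    replicate = list(top = 1L, bottom = h, left = 1L, right = w),
    reflect   = list(top = 2L, bottom = h - 1L, left = 2L, right = w - 1L),
    zero      = NULL
  )
  if (!is.null(idx)) {
    p[1L, 2:(w + 1L)]      <- x[idx$top, ]
    p[h + 2L, 2:(w + 1L)]  <- x[idx$bottom, ]
    p[2:(h + 1L), 1L]      <- x[, idx$left]
    p[2:(h + 1L), w + 2L]  <- x[, idx$right]
  }
  rows <- 2:(h + 1L)
  cols <- 2:(w + 1L)
  avg4 <- (p[rows - 1L, cols] + p[rows + 1L, cols] +
           p[rows, cols - 1L] + p[rows, cols + 1L]) / 4
  alpha * x + (1 - alpha) * avg4
}

# Shared RawImage validation.
check_raw_image <- function(image, min_side = 1L) {
  if (!is.numeric(image) || !(is.matrix(image) || (is.array(image) && length(dim(image)) == 3))) {
    abort("`image` must be a numeric matrix or a height x width x channels array.",
          class = "braincdnet_dimension_error")
  }
  d <- dim(image)
  if (length(d) == 3 && !d[3] %in% c(1L, 3L)) {
    abort("`image` must have 1 or 3 channels.", class = "braincdnet_dimension_error")
  }
  if (d[1] < min_side || d[2] < min_side) {
    abort(sprintf("`image` must be at least %d x %d.", min_side, min_side),
          class = "braincdnet_dimension_error")
  }
  if (anyNA(image) || !all(is.finite(image))) {
    abort("`image` must contain only finite values.", class = "braincdnet_dimension_error")
  }
  if (min(image) < 0 || max(image) > 255) {
    abort("`image` intensities must lie in [0, 255].", class = "braincdnet_dimension_error")
  }
  invisible(image)
}
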