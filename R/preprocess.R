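#' Resize an image to a square network input
#'
#' Bilinear resize (via \pkg{EBImage}) to `side` x `side`, replicating a
#' single grayscale channel to three so the output always matches the
#' network's three-channel input contract.
#'
#' @param image numeric matrix or height x width x \{1,3\} array in `[0, 255]`.
#' @param side output edge length in pixels (default 224).
#' @return A `side` x `side` x 3 array in `[0, 255]`.
#' @export
resize_image <- function(image, side = 224L) {
  if (!is.numeric(side) || length(side) != 1 || side < 1) {
    abort("`side` must be a positive integer.", class = "braincdnet_parameter_error")
  }
  side <- as.integer(side)
  check_raw_image(image, min_side = 1L)
  chans <- if (is.matrix(image)) list(image) else
    lapply(seq_len(dim(image)[3]), function(ch) image[, , ch])
  resized <- lapply(chans, function(ch) {
    if (nrow(ch) == side && ncol(ch) == side) return(ch)
    r <- EBImage::resize(ch, w = side, h = side, filter = "bilinear")
    matrix(pmin(pmax(as.numeric(r), 0), 255), side, side)
  })
  if (length(resized) == 1L) resized <- resized[c(1L, 1L, 1L)]
  array(unlist(resized, use.names = FALSE), dim = c(side, side, 3L))
}

#' Prepare a raw image for the network
#'
#' The full preprocessing path: bilinear resize to `side` x `side` x 3,
#' optional Nimble sharpening (the ablation arm disables it), then scaling
#' to `[0, 1]`. Sharpening is applied after resizing so the filter acts at
#' the network's resolution and the result does not depend on the source
#' resolution.
#'
#' @inheritParams nimble_sharpen
#' @inheritParams resize_image
#' @param sharpen apply the Nimble filter? `FALSE` reproduces the
#'   no-sharpening ablation arm.
#' @return A `side` x `side` x 3 array of values in `[0, 1]`.
#' @seealso [nimble_sharpen()], [resize_image()]
#' @export
prepare_image <- function(image, alpha = 2, sharpen = TRUE,
                          boundary = "replicate", side = 224L) {
  out <- resize_image(image, side = side)
  if (isTRUE(sharpen)) out <- nimble_sharpen(out, alpha = alpha, boundary = boundary)
  out / 255
}

#' Read an image file as a raw intensity array
#'
#' Decodes PNG/JPEG/TIFF via \pkg{EBImage} and rescales to `[0, 255]`.
#' Images with an alpha channel keep only the first three channels.
#'
#' @param path file path.
#' @return numeric matrix (grayscale) or height x width x 3 array.
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  x <- EBImage::imageData(img)
  # EBImage stores x (width) first; transpose to height x width
  if (length(dim(x)) == 2) {
    x <- t(x)
  } else {
    x <- x[, , seq_len(min(dim(x)[3], 3L)), drop = FALSE]
    x <- aperm(x, c(2L, 1L, 3L))
    if (dim(x)[3] == 2L) x <- x[, , 1L]  # gray + alpha
  }
  x * 255
}

#' List a directory-per-class image dataset
#'
#' Expects `root/<class_name>/*.{png,jpg,jpeg,tif}`; class names are the
#' sorted subdirectory names and labels are 0-based integers in that order.
#'
#' @param root dataset root directory.
#' @return A tibble with columns `path`, `class`, `label`.
#' @export
list_image_dataset <- function(root) {
  if (!dir.exists(root)) {
    abort(sprintf("dataset root '%s' does not exist.", root),
          class = "braincdnet_input_error")
  }
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) < 2) {
    abort("dataset root must contain at least two class subdirectories.",
          class = "braincdnet_input_error")
  }
  purrr::map_dfr(seq_along(classes), function(i) {
    files <- sort(list.files(file.path(root, classes[i]),
                             pattern = "\\.(png|jpe?g|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    tibble(path = files, class = classes[i], label = i - 1L)
  })
}

#' Load a directory-per-class dataset into memory
#'
#' @inheritParams list_image_dataset
#' @return A labeled dataset: list with `images` (list of raw arrays),
#'   `labels` (0-based integers) and `class_names`.
#' @export
load_image_dataset <- function(root) {
  manifest <- list_image_dataset(root)
  structure(
    list(images = purrr::map(manifest$path, read_image),
         labels = manifest$label,
         class_names = sort(unique(manifest$class))),
    class = "labeled_dataset"
  )
}

#' Preprocess every image of a labeled dataset into a network-input batch
#'
#' @param dataset a labeled dataset (from [generate_dataset()] or
#'   [load_image_dataset()]).
#' @inheritParams prepare_image
#' @return list with `x` (a `side` x `side` x 3 x n array in `[0, 1]`),
#'   `y` (0-based labels) and `class_names`.
#' @export
prepare_dataset <- function(dataset, alpha = 2, sharpen = TRUE,
                            boundary = "replicate", side = 224L) {
  n <- length(dataset$images)
  x <- array(0, dim = c(side, side, 3L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- prepare_image(dataset$images[[i]], alpha = alpha,
                                sharpen = sharpen, boundary = boundary,
                                side = side)
  }
  list(x = x, y = as.integer(dataset$labels), class_names = dataset$class_names)
}
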