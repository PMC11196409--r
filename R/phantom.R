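#' Specification of the synthetic MRI phantom generator
#'
#' Phantoms are statistical stand-ins for axial brain MRI slices: a dark
#' background, a bright ellipse (the "brain") and, for pathological
#' classes, a uniform bright disc (the "lesion") at a random position
#' inside the ellipse, plus additive Gaussian noise. Class identity is
#' carried by the lesion's added intensity, so class separability is
#' controlled exactly and the full training pipeline can be exercised
#' without patient data.
#'
#' @param n_per_class images per class (>= 1).
#' @param n_classes 2 (healthy vs. pathological; class 0 has no lesion) or
#'   3 (three pathological classes with distinct lesion intensities).
#' @param image_side edge length in pixels; default 224 so phantoms match
#'   the network input without resizing.
#' @param lesion_intensity per-class added lesion intensity (intensity
#'   units on the `[0, 255]` scale). Defaults: `c(0, 80)` for two classes,
#'   `c(40, 80, 120)` for three. Intensities of distinct classes must
#'   differ by at least `3 * noise_sd`.
#' @param lesion_radius_range `(min, max)` lesion radius in pixels at
#'   `image_side = 224`; scaled proportionally for other sides.
#' @param noise_sd standard deviation of the additive Gaussian pixel noise.
#' @param seed integer seed; phantom `(class, index)` pairs map to
#'   independent substreams so generation is deterministic and
#'   order-independent.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_per_class, n_classes = 2L, image_side = 224L,
                         lesion_intensity = NULL,
                         lesion_radius_range = c(12, 30),
                         noise_sd = 5, seed = 1L) {
  if (!n_classes %in% c(2L, 3L)) {
    abort("`n_classes` must be 2 or 3.", class = "braincdnet_input_error")
  }
  if (n_per_class < 1) {
    abort("`n_per_class` must be >= 1.", class = "braincdnet_input_error")
  }
  if (is.null(lesion_intensity)) {
    lesion_intensity <- if (n_classes == 2L) c(0, 80) else c(40, 80, 120)
  }
  if (length(lesion_intensity) != n_classes) {
    abort("`lesion_intensity` needs one value per class.",
          class = "braincdnet_input_error")
  }
  sep <- min(stats::dist(lesion_intensity))
  if (noise_sd > 0 && sep < 3 * noise_sd) {
    abort("class lesion intensities must differ by at least 3 * noise_sd.",
          class = "braincdnet_input_error")
  }
  structure(
    list(n_per_class = as.integer(n_per_class),
         n_classes = as.integer(n_classes),
         image_side = as.integer(image_side),
         lesion_intensity = lesion_intensity,
         lesion_radius_range = lesion_radius_range * image_side / 224,
         noise_sd = noise_sd,
         seed = as.integer(seed),
         class_names = if (n_classes == 2L) c("healthy", "pathological")
                       else c("glioma", "meningioma", "pituitary")),
    class = "phantom_spec")
}

# independent, reproducible substream per (seed, class, draw)
phantom_substream_seed <- function(seed, class_id, draw_index) {
  (as.numeric(seed) * 7919 + class_id * 104729 + draw_index * 7561) %% 2147483647
}

#' Generate one phantom image
#'
#' @param class_id 0-based class index.
#' @param spec a [phantom_spec()].
#' @param draw_index 1-based index of the draw within the class; the same
#'   `(seed, class_id, draw_index)` triple always yields a bit-identical
#'   image.
#' @return numeric matrix `image_side` x `image_side` in `[0, 255]`.
#' @export
generate_phantom <- function(class_id, spec, draw_index = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (class_id < 0 || class_id >= spec$n_classes) {
    abort("`class_id` must lie in [0, n_classes).", class = "braincdnet_input_error")
  }
  s <- spec$image_side
  withr::with_seed(phantom_substream_seed(spec$seed, class_id, draw_index), {
    cx <- s / 2; cy <- s / 2
    ax <- s * runif(1, 0.36, 0.40)   # semi-axes with mild shape variation
    ay <- s * runif(1, 0.28, 0.32)
    xs <- matrix(seq_len(s), s, s)          # row coordinate
    ys <- matrix(seq_len(s), s, s, byrow = TRUE)
    inside <- ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2 <= 1
    img <- matrix(10, s, s)
    img[inside] <- 120
    amp <- spec$lesion_intensity[class_id + 1L]
    if (amp > 0) {
      r <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
      # lesion centre uniform inside the ellipse shrunk so the disc fits
      repeat {
        u <- runif(2, -1, 1)
        if (sum(u^2) <= 1) break
      }
      lx <- cx + u[1] * max(ax - r, 1)
      ly <- cy + u[2] * max(ay - r, 1)
      lesion <- (xs - lx)^2 + (ys - ly)^2 <= r^2
      img[lesion] <- img[lesion] + amp
    }
    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(s * s, 0, spec$noise_sd), s, s)
    }
    pmin(pmax(img, 0), 255)
  })
}

#' Generate a balanced labeled phantom dataset
#'
#' @param spec a [phantom_spec()].
#' @return A `labeled_dataset`: list with `images` (list of matrices),
#'   `labels` (0-based, `n_classes * n_per_class` long, balanced) and
#'   `class_names`. Reproducible from `spec$seed`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- expand.grid(draw = seq_len(spec$n_per_class),
                      class = seq_len(spec$n_classes) - 1L)
  images <- purrr::map2(grid$class, grid$draw,
                        function(cl, dr) generate_phantom(cl, spec, dr))
  structure(
    list(images = images, labels = as.integer(grid$class),
         class_names = spec$class_names),
    class = "labeled_dataset")
}

#' Write a labeled dataset as a directory-per-class PNG tree
#'
#' Produces the layout consumed by [load_image_dataset()] and the
#' preprocessing CLI: `root/<class_name>/<class>_<index>.png`.
#'
#' @param dataset a `labeled_dataset`.
#' @param root output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_image_dataset <- function(dataset, root) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  for (cl in unique(dataset$labels)) {
    dir.create(file.path(root, dataset$class_names[cl + 1L]),
               recursive = TRUE, showWarnings = FALSE)
  }
  counter <- integer(length(dataset$class_names))
  for (i in seq_along(dataset$images)) {
    cl <- dataset$labels[i]
    counter[cl + 1L] <- counter[cl + 1L] + 1L
    name <- dataset$class_names[cl + 1L]
    png::writePNG(dataset$images[[i]] / 255,
                  file.path(root, name,
                            sprintf("%s_%04d.png", name, counter[cl + 1L])))
  }
  invisible(root)
}
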