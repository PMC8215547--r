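# Dataset plumbing: IDX (MNIST-format) reading/writing and a synthetic
# digit generator so the whole pipeline is testable without downloads.

#' Read an IDX image/label pair
#'
#' Parses the MNIST IDX binary format (big-endian, magic 2051 for images and
#' 2049 for labels), normalizes pixel values to [0, 1] and checks that the
#' two files describe the same number of items.
#'
#' @param images_path,labels_path file paths
#' @return a `labeled_image_set`: list with `images` (n x rows x cols array
#'   in [0,1]), `labels` (integer vector, 0..9), `provenance` ("idx")
#' @export
read_idx <- function(images_path, labels_path) {
  con <- file(images_path, "rb"); on.exit(close(con), add = TRUE)
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 2051L))
    stop("bad magic number in image file (expected 2051)")
  n <- readBin(con, "integer", 1, size = 4, endian = "big")
  nr <- readBin(con, "integer", 1, size = 4, endian = "big")
  nc <- readBin(con, "integer", 1, size = 4, endian = "big")
  raw <- readBin(con, "integer", n * nr * nc, size = 1, signed = FALSE)
  if (length(raw) != n * nr * nc) stop("truncated image file")
  images <- aperm(array(raw / 255, c(nc, nr, n)), c(3, 2, 1))

  con2 <- file(labels_path, "rb"); on.exit(close(con2), add = TRUE)
  magic2 <- readBin(con2, "integer", 1, size = 4, endian = "big")
  if (!identical(magic2, 2049L))
    stop("bad magic number in label file (expected 2049)")
  n2 <- readBin(con2, "integer", 1, size = 4, endian = "big")
  labels <- readBin(con2, "integer", n2, size = 1, signed = FALSE)
  if (length(labels) != n2) stop("truncated label file")
  if (n2 != n) stop("image/label count mismatch")
  if (any(labels < 0 | labels > 9)) stop("labels outside 0..9")
  structure(list(images = images, labels = as.integer(labels),
                 provenance = "idx"), class = "labeled_image_set")
}

#' Write an IDX image/label pair
#'
#' @param set a `labeled_image_set`
#' @param images_path,labels_path output paths
#' @return invisibly, the image path
#' @export
write_idx <- function(set, images_path, labels_path) {
  d <- dim(set$images)
  con <- file(images_path, "wb")
  writeBin(c(2051L, d[1], d[2], d[3]), con, size = 4, endian = "big")
  px <- as.integer(round(aperm(set$images, c(3, 2, 1)) * 255))
  writeBin(as.raw(px), con)
  close(con)
  con <- file(labels_path, "wb")
  writeBin(c(2049L, d[1]), con, size = 4, endian = "big")
  writeBin(as.raw(set$labels), con)
  close(con)
  invisible(images_path)
}

#' @export
print.labeled_image_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("labeled image set (%s): %d images %dx%d, %d classes\n",
              x$provenance, d[1], d[2], d[3], length(unique(x$labels))))
  invisible(x)
}

# --- synthetic digit templates ---------------------------------------------

.ellipse_pts <- function(cx, cy, rx, ry, n = 24) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  cbind(cx + rx * cos(th), cy + ry * sin(th))
}

# each digit: list of polylines, columns (x, y) in a 28 x 28 frame
.digit_strokes <- function() {
  list(
    `0` = list(.ellipse_pts(14, 14, 5, 7.5)),
    `1` = list(cbind(c(11, 14, 14), c(8, 5, 23)),
               cbind(c(11, 17), c(23, 23))),
    `2` = list(cbind(c(9.5, 11, 14, 17, 18, 16, 10, 9, 9),
                     c(9, 6, 5, 6.5, 10, 14, 21, 23, 23)),
               cbind(c(9, 19), c(23, 23))),
    `3` = list(cbind(c(9.5, 13, 17, 16.5, 13), c(7.5, 5, 8, 12, 13.5)),
               cbind(c(13, 17.5, 18, 13.5, 9.5),
                     c(13.5, 16, 20, 23, 21.5))),
    `4` = list(cbind(c(16.5, 16.5), c(5, 23)),
               cbind(c(16.5, 9, 20), c(5, 17, 17))),
    `5` = list(cbind(c(18, 10.5, 10, 10.5), c(6, 6, 13, 13)),
               cbind(c(10.5, 15, 18, 16, 9.5),
                     c(13, 12.5, 16.5, 21.5, 21))),
    `6` = list(cbind(c(16.5, 13, 10.5, 10, 10.5), c(5.5, 8, 13, 17, 19.5)),
               .ellipse_pts(13.8, 18, 3.8, 4.6)),
    `7` = list(cbind(c(9.5, 19), c(6, 6)),
               cbind(c(19, 12.5), c(6, 23))),
    `8` = list(.ellipse_pts(14, 9.5, 4, 4),
               .ellipse_pts(14, 18.2, 4.7, 4.6)),
    `9` = list(.ellipse_pts(14, 10, 4, 4.4),
               cbind(c(18, 17.5, 15.5), c(10, 18, 23))))
}

# min distance from each pixel center to a polyline
.dist_to_polyline <- function(px, py, pts) {
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(pts) - 1)) {
    x1 <- pts[i, 1]; y1 <- pts[i, 2]; x2 <- pts[i + 1, 1]; y2 <- pts[i + 1, 2]
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(pmax(((px - x1) * dx + (py - y1) * dy) / L2, 0), 1)
    d <- pmin(d, sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2))
  }
  d
}

.render_template <- function(strokes, stroke_scale = 1, side = 28) {
  g <- expand.grid(x = seq_len(side), y = seq_len(side))
  d <- rep(Inf, nrow(g))
  for (pl in strokes) d <- pmin(d, .dist_to_polyline(g$x, g$y, pl))
  width <- 1.15 * stroke_scale
  img <- pmin(pmax((width - d) / 0.8 + 1, 0), 1)
  matrix(img, side, side, byrow = TRUE)   # row = y, col = x
}

.template_cache <- function(stroke_scale) {
  key <- paste0("templates|", stroke_scale)
  if (is.null(.lnn_cache[[key]]))
    .lnn_cache[[key]] <- lapply(.digit_strokes(), .render_template,
                                stroke_scale = stroke_scale)
  .lnn_cache[[key]]
}

#' Generate a synthetic digit dataset
#'
#' Renders ten fixed stroke templates (28 x 28 grayscale) with random
#' integer translation (+/- 2 px), stroke-intensity jitter and per-pixel
#' noise (both scaled by `noise_level`). Classes are balanced and the
#' generation is deterministic given `seed`. The templates are drawn so
#' that, after 2x2 average pooling and threshold tuning, mean active-pixel
#' counts in the 15-40 range are reachable.
#'
#' @param n number of images
#' @param seed RNG seed (`NULL` = use the current RNG state)
#' @param noise_level nuisance scale in [0, 1]; 0 gives noiseless templates
#'   on a 5 x 5 translation grid
#' @param stroke_scale multiplies the stroke width
#' @return a `labeled_image_set` with provenance "synthetic"
#' @export
generate_synthetic_digits <- function(n, seed = NULL, noise_level = 0.08,
                                      stroke_scale = 1) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  templates <- .template_cache(stroke_scale)
  labels <- rep(0:9, length.out = n)
  images <- array(0, c(n, 28, 28))
  for (i in seq_len(n)) {
    tpl <- templates[[labels[i] + 1]]
    dx <- sample(-2:2, 1); dy <- sample(-2:2, 1)
    img <- matrix(0, 28, 28)
    rs <- pmax(1, 1 + dy):pmin(28, 28 + dy)
    cs <- pmax(1, 1 + dx):pmin(28, 28 + dx)
    img[rs, cs] <- tpl[rs - dy, cs - dx]
    if (noise_level > 0) {
      img <- img * (1 + noise_level * runif(1, -0.5, 0.5))
      img <- img + matrix(rnorm(784, 0, 0.15 * noise_level), 28, 28)
      img <- pmin(pmax(img, 0), 1)
    }
    images[i, , ] <- img
  }
  structure(list(images = images, labels = as.integer(labels),
                 provenance = "synthetic"), class = "labeled_image_set")
}

#' Summary statistics of a labeled image set
#'
#' @param set a `labeled_image_set`
#' @param reference_threshold threshold at which active (ink) pixels are
#'   counted on the raw images
#' @return list with `n`, `class_counts` (named 0..9) and
#'   `mean_active_pixels`
#' @export
dataset_stats <- function(set, reference_threshold = 0.5) {
  counts <- table(factor(set$labels, levels = 0:9))
  active <- apply(set$images > reference_threshold, 1, sum)
  list(n = dim(set$images)[1], class_counts = counts,
       mean_active_pixels = mean(active))
}
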