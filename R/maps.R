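#' Class-wise average pupil-center position map
#'
#' Averages the binary mark masks of all subjects in one anxiety class and
#' eye side into a per-pixel frequency map: each pixel holds the fraction of
#' subjects with a mark there, so brighter areas are the more commonly
#' spotted pupil-center locations. The map's `centroid_offset` is the
#' frequency-weighted mean offset (x, y, px) of the map from the grid
#' center.
#'
#' @param masks non-empty list of `mark_mask` objects sharing grid geometry.
#' @param class_label,eye_side annotations carried into the result.
#' @return object of class `average_map`: list with `frequency` (matrix in
#'   \[0, 1\]), `grid`, `class_label`, `eye_side`, `n_subjects`,
#'   `centroid_offset`.
#' @export
average_class_map <- function(masks, class_label = NA_character_,
                              eye_side = NA_character_) {
  if (!length(masks)) stop("empty mask list")
  if (!all(vapply(masks, inherits, logical(1), "mark_mask")))
    stop("all inputs must be mark_mask objects")
  dims <- vapply(masks, function(m) dim(m$mask), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("masks have mixed geometries; rescale to a common grid first")
  freq <- Reduce(`+`, lapply(masks, function(m) m$mask * 1)) / length(masks)
  new_average_map(freq, masks[[1]]$grid, class_label, eye_side,
                  length(masks))
}

new_average_map <- function(freq, grid, class_label, eye_side, n_subjects) {
  structure(list(frequency = freq, grid = grid,
                 class_label = class_label, eye_side = eye_side,
                 n_subjects = n_subjects,
                 centroid_offset = map_centroid_offset(freq, grid)),
            class = "average_map")
}

# frequency-weighted mean (x, y) offset from the grid center
map_centroid_offset <- function(freq, grid) {
  tot <- sum(freq)
  if (tot == 0) return(c(x = 0, y = 0))
  nr <- nrow(freq); nc <- ncol(freq)
  cols <- matrix(rep(seq_len(nc), each = nr), nrow = nr)
  rows <- matrix(rep(seq_len(nr), times = nc), nrow = nr)
  c(x = sum(freq * cols) / tot - grid$center_px[1],
    y = sum(freq * rows) / tot - grid$center_px[2])
}

#' @export
print.average_map <- function(x, ...) {
  cat(sprintf(
    "average_map (%s, %s eye): n = %d, support %d px, centroid offset (%.1f, %.1f) px\n",
    x$class_label, x$eye_side, x$n_subjects, sum(x$frequency > 0),
    x$centroid_offset["x"], x$centroid_offset["y"]))
  invisible(x)
}

#' Support area of an average map
#' @param map an `average_map`.
#' @param threshold frequency above which a pixel counts as support.
#' @return pixel count with `frequency > threshold`.
#' @export
map_support_area <- function(map, threshold = 0) {
  stopifnot(inherits(map, "average_map"))
  sum(map$frequency > threshold)
}

#' PCA-denoised average position map
#'
#' Projects the flattened subject masks onto their top-`k` principal
#' components, reconstructs each subject from that low-rank basis, averages
#' the reconstructions and clips to \[0, 1\]. With `k = 0` this is the plain
#' mean image (the centering term); with full rank it equals
#' [average_class_map()] up to numerical error. The frequency-map estimator
#' is the primary output; the PCA path is an optional smoothing
#' interpretation.
#'
#' @param masks list of `mark_mask` (at least `k + 1`).
#' @param k number of principal components to retain (`0 <= k < n_subjects`).
#' @inheritParams average_class_map
#' @return an `average_map`.
#' @export
pca_denoise <- function(masks, k, class_label = NA_character_,
                        eye_side = NA_character_) {
  if (length(masks) < 2) stop("need at least 2 masks")
  if (k < 0 || k >= length(masks))
    stop("k must satisfy 0 <= k < number of masks")
  dims <- vapply(masks, function(m) dim(m$mask), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("masks have mixed geometries; rescale to a common grid first")
  X <- do.call(rbind, lapply(masks, function(m) as.vector(m$mask * 1)))
  n <- nrow(X)
  mu <- colMeans(X)
  if (k == 0) {
    recon_mean <- mu
  } else {
    # left singular vectors via the n x n Gram matrix (p is large)
    Xc <- sweep(X, 2, mu)
    U <- eigen(tcrossprod(Xc), symmetric = TRUE)$vectors[, seq_len(k),
                                                         drop = FALSE]
    # mean over subjects of the rank-k reconstructions U_k U_k' Xc
    w <- crossprod(U, rep(1 / n, n))           # k x 1
    recon_mean <- mu + as.vector(crossprod(Xc, U %*% w))
  }
  freq <- matrix(pmin(pmax(recon_mean, 0), 1),
                 nrow = dims[1, 1], ncol = dims[2, 1])
  new_average_map(freq, masks[[1]]$grid, class_label, eye_side,
                  length(masks))
}

#' Reconstruction error of a rank-k PCA model of a mask stack
#'
#' Mean squared error between the flattened masks and their rank-`k`
#' reconstructions; non-increasing in `k`.
#'
#' @inheritParams pca_denoise
#' @return scalar mean squared reconstruction error.
#' @export
pca_reconstruction_error <- function(masks, k) {
  if (k < 0 || k >= length(masks))
    stop("k must satisfy 0 <= k < number of masks")
  X <- do.call(rbind, lapply(masks, function(m) as.vector(m$mask * 1)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  lambda <- eigen(tcrossprod(Xc), symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  # squared residual norm = sum of discarded eigenvalues of the Gram matrix
  sum(lambda[seq_len(length(lambda)) > k]) / length(Xc)
}

#' Write / read an average map as a lossless PNG
#'
#' Frequencies in \[0, 1\] are quantized to 16 bits and stored losslessly:
#' the high byte in the red channel, the low byte in the green channel and
#' the 8-bit visual rendering in the blue channel, so small per-pixel
#' fractions survive the round trip while the file still previews sensibly.
#' `read_map_png` inverts the encoding.
#'
#' @param map an `average_map`.
#' @param path output path.
#' @return `write_map_png`: `path`, invisibly. `read_map_png`: the frequency
#'   matrix (16-bit precision).
#' @export
write_map_png <- function(map, path) {
  stopifnot(inherits(map, "average_map"))
  q <- round(map$frequency * 65535)
  img <- array(0, dim = c(nrow(q), ncol(q), 3))
  img[, , 1] <- (q %/% 256) / 255
  img[, , 2] <- (q %% 256) / 255
  img[, , 3] <- round(map$frequency * 255) / 255
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_map_png
#' @export
read_map_png <- function(path) {
  img <- png::readPNG(path)
  stopifnot(length(dim(img)) == 3, dim(img)[3] >= 3)
  (round(img[, , 1] * 255) * 256 + round(img[, , 2] * 255)) / 65535
}
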