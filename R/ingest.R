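#' Read a pupil-center plot image
#'
#' Decodes a PNG or TIFF raster into a height x width x 3 array of values in
#' \[0, 1\]. Grayscale images are replicated across channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return numeric array `[rows, cols, 3]` with values in \[0, 1\].
#' @export
read_plot_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format '", ext, "' (expected PNG or TIFF)")
  )
  if (is.na(dim(img)[3]) || length(dim(img)) == 2)
    img <- array(rep(img, 3), dim = c(dim(img)[1:2], 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] < 3)
    stop("image does not decode to a 3-channel raster")
  img
}

#' Mark-color specification
#'
#' The device marks each sampled pupil-center position with a small blue
#' square; the exact RGB of those marks is not published, so detection uses
#' a configurable band in hue/saturation/value space. The default band is
#' tuned to saturated blue and excludes the white background, the gray
#' crosshair and black axis/grid line pixels.
#'
#' @param hue_range hue interval in \[0, 1\] (pure blue = 2/3).
#' @param min_saturation,min_value lower bounds in \[0, 1\].
#' @return a list of class `color_spec`.
#' @export
mark_color_spec <- function(hue_range = c(0.5, 0.83),
                            min_saturation = 0.5,
                            min_value = 0.3) {
  stopifnot(length(hue_range) == 2, hue_range[1] < hue_range[2],
            all(hue_range >= 0 & hue_range <= 1),
            min_saturation >= 0, min_saturation <= 1,
            min_value >= 0, min_value <= 1)
  structure(list(hue_range = hue_range,
                 min_saturation = min_saturation,
                 min_value = min_value),
            class = "color_spec")
}

#' Detect pupil-center marks in a plot image
#'
#' Classifies every pixel against the mark color band and returns a binary
#' mask of mark pixels, restricted to the tracking square: any pixel
#' matching the mark color outside the square (axis labels, legends) is
#' discarded. An image with no mark pixels is a valid plot (perfect
#' fixation); it yields an empty mask with `empty = TRUE` and a warning.
#'
#' @param image a `[rows, cols, 3]` array in \[0, 1\] (see
#'   [read_plot_image()]), or a path to one.
#' @param grid a [tracking_grid()] locating the tracking square in the image.
#' @param color_spec a [mark_color_spec()].
#' @param source_id optional subject/eye identifier carried through outputs.
#' @return an object of class `mark_mask`: list with `mask` (logical matrix),
#'   `grid`, `source_id`, `empty` flag.
#' @export
detect_marks <- function(image, grid, color_spec = mark_color_spec(),
                         source_id = NA_character_) {
  if (is.character(image)) image <- read_plot_image(image)
  if (!(is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3))
    stop("`image` must decode to a 3-channel raster")
  stopifnot(inherits(grid, "tracking_grid"))
  nr <- dim(image)[1]; nc <- dim(image)[2]
  if (grid$center_px[1] < 1 || grid$center_px[1] > nc ||
      grid$center_px[2] < 1 || grid$center_px[2] > nr)
    stop("grid center lies outside the image bounds")

  rgb <- rbind(as.vector(image[, , 1]),
               as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hit <- hsv[1, ] >= color_spec$hue_range[1] &
         hsv[1, ] <= color_spec$hue_range[2] &
         hsv[2, ] >= color_spec$min_saturation &
         hsv[3, ] >= color_spec$min_value
  mask <- matrix(hit, nrow = nr, ncol = nc)

  # crop to the tracking square
  cols <- matrix(rep(seq_len(nc), each = nr), nrow = nr)
  rows <- matrix(rep(seq_len(nr), times = nc), nrow = nr)
  mask <- mask & in_grid(cols, rows, grid)

  empty <- !any(mask)
  if (empty) warning("no mark pixels detected: empty plot")
  new_mark_mask(mask, grid, source_id, empty)
}

new_mark_mask <- function(mask, grid, source_id = NA_character_,
                          empty = !any(mask)) {
  structure(list(mask = mask, grid = grid, source_id = source_id,
                 empty = empty),
            class = "mark_mask")
}

#' @export
print.mark_mask <- function(x, ...) {
  cat(sprintf("mark_mask [%d x %d]: %d mark pixels%s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              if (x$empty) " (empty plot)" else ""))
  invisible(x)
}

#' Write a mark mask to a lossless PNG
#' @param mask a `mark_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "mark_mask"))
  png::writePNG(mask$mask * 1, path)
  invisible(path)
}

#' Extract connected mark clusters from a mask
#'
#' Labels connected components of the mark mask (8-connectivity by default,
#' so diagonally touching squares read as one cluster) and measures each
#' cluster:
#' * `area_px` -- member pixel count;
#' * `perimeter_px` -- boundary-edge count, i.e. the number of pixel edges
#'   separating a mark pixel from background or image border (city-block
#'   contour; a single s x s square has perimeter exactly 4s);
#' * `centroid_x_px`, `centroid_y_px` -- unweighted mean of member pixel
#'   coordinates;
#' * `dist_px` -- Euclidean distance from the centroid to the grid center.
#'
#' Clusters partition the mask: every mark pixel belongs to exactly one
#' cluster, so cluster areas sum to the union area.
#'
#' @param mask a `mark_mask` from [detect_marks()].
#' @param connectivity 8 (default) or 4.
#' @return an object of class `cluster_set`: list with `clusters`
#'   (data.frame, one row per cluster), `grid`, `union_area`, `source_id`.
#' @export
extract_clusters <- function(mask, connectivity = 8) {
  stopifnot(inherits(mask, "mark_mask"), connectivity %in% c(4, 8))
  m <- mask$mask
  labels <- label_components(m, connectivity)
  fg <- which(m)
  empty_df <- data.frame(id = integer(), area_px = integer(),
                         perimeter_px = integer(),
                         centroid_x_px = numeric(), centroid_y_px = numeric(),
                         dist_px = numeric())
  if (length(fg) == 0)
    return(new_cluster_set(empty_df, mask$grid, 0L, mask$source_id))

  nr <- nrow(m)
  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  lab <- labels[fg]

  exposed <- exposed_edges(m)[fg]          # per-pixel count of exposed edges
  area <- as.vector(rowsum(rep(1L, length(fg)), lab))
  perim <- as.vector(rowsum(exposed, lab))
  cx <- as.vector(rowsum(as.numeric(cols), lab)) / area
  cy <- as.vector(rowsum(as.numeric(rows), lab)) / area
  ids <- sort(unique(lab))
  d <- sqrt((cx - mask$grid$center_px[1])^2 + (cy - mask$grid$center_px[2])^2)

  df <- data.frame(id = seq_along(ids), area_px = as.integer(area),
                   perimeter_px = as.integer(perim),
                   centroid_x_px = cx, centroid_y_px = cy, dist_px = d)
  new_cluster_set(df, mask$grid, sum(m), mask$source_id)
}

new_cluster_set <- function(clusters, grid, union_area,
                            source_id = NA_character_) {
  structure(list(clusters = clusters, grid = grid,
                 union_area = as.integer(union_area), source_id = source_id),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters, union area %d px\n",
              nrow(x$clusters), x$union_area))
  if (nrow(x$clusters)) print(utils::head(x$clusters, 10))
  invisible(x)
}

#' @rdname extract_clusters
#' @param x a `cluster_set`.
#' @return for `as.data.frame.cluster_set`: the per-cluster data.frame.
#' @export
as.data.frame.cluster_set <- function(x, ...) x$clusters

# Connected-component labels of a logical matrix. Foreground pixels become
# vertices; edges join pixels adjacent under the chosen connectivity.
label_components <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  fg <- which(m)
  labels <- matrix(0L, nr, nc)
  if (length(fg) == 0) return(labels)
  idx <- matrix(0L, nr, nc)
  idx[fg] <- seq_along(fg)

  offs <- list(c(1L, 0L), c(0L, 1L))            # down, right
  if (connectivity == 8)
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))  # down-right, down-left

  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r2 <- rows + o[1]; c2 <- cols + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- idx[cbind(r2[ok], c2[ok])]
    hit <- nb > 0L
    from <- c(from, idx[fg][ok][hit])
    to <- c(to, nb[hit])
  }
  g <- igraph::make_graph(edges = rbind(from, to), n = length(fg),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  labels[fg] <- as.integer(comp)
  labels
}

# Per-pixel count of exposed boundary edges (4-neighborhood edges facing
# background or the image border). Summing over a component gives its
# boundary-edge perimeter.
exposed_edges <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  up    <- pad[1:nr, 2:(nc + 1L)]
  down  <- pad[3:(nr + 2L), 2:(nc + 1L)]
  left  <- pad[2:(nr + 1L), 1:nc]
  right <- pad[2:(nr + 1L), 3:(nc + 2L)]
  (core & !up) + (core & !down) + (core & !left) + (core & !right)
}
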