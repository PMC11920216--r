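#' Synthetic cohort configuration
#'
#' Defines the class-conditional generative model for synthetic pupil-center
#' plots. Each subject dwells at a number of positions; dwell centers are
#' drawn from an isotropic Gaussian with a class-specific dispersion and a
#' mean offset (bias) emulating the nasal/upward decentration seen in real
#' plots, truncated so every rendered mark square fits inside the tracking
#' square. Dispersions must be ordered normal <= borderline <= case: the
#' area of decentration grows with anxiety severity.
#'
#' Defaults are chosen so that default cohorts land SA, SP and ACD in the
#' order-of-magnitude ranges reported for real cohorts (SA in the hundreds
#' to low thousands of px^2, SP around 100-250 px, ACD around 10-30 px at
#' the 100 px/mm reference scale).
#'
#' @param n_per_class subjects per anxiety class (normal, borderline, case).
#' @param dwell_count_range 2-column matrix (or list of length-2 vectors),
#'   one row per class: min/max number of dwell positions.
#' @param dispersion_px length-3 numeric: per-class standard deviation (px)
#'   of dwell-center scatter; must be non-decreasing.
#' @param bias_px 3 x 2 matrix: per-class mean offset (x, y) in px from the
#'   grid center, for a right eye; mirrored in x for left eyes.
#' @param mark_side_px side (px) of the rendered square marks.
#' @param margin_px white margin around the tracking square in rendered
#'   images.
#' @param seed integer random seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = 100,
                             dwell_count_range = rbind(normal = c(20, 40),
                                                       borderline = c(30, 60),
                                                       case = c(50, 100)),
                             dispersion_px = c(normal = 10, borderline = 18,
                                               case = 26),
                             bias_px = rbind(normal = c(6, -4),
                                             borderline = c(12, -8),
                                             case = c(18, -12)),
                             mark_side_px = 5,
                             margin_px = 10,
                             seed = 1L) {
  if (is.list(dwell_count_range))
    dwell_count_range <- do.call(rbind, dwell_count_range)
  stopifnot(n_per_class >= 0, nrow(dwell_count_range) == 3,
            length(dispersion_px) == 3, nrow(bias_px) == 3,
            mark_side_px >= 1, margin_px >= 0)
  if (is.unsorted(dispersion_px))
    stop("class dispersions must be ordered normal <= borderline <= case")
  grid <- default_grid(margin_px = margin_px)
  e <- grid_extent_px(grid)
  if (mark_side_px > 2 * e + 1)
    stop("mark squares cannot fit inside the tracking square")
  if (any(abs(bias_px) + 4 * dispersion_px > e))
    stop("dwell scatter does not fit inside the tracking square")
  structure(list(n_per_class = as.integer(n_per_class),
                 dwell_count_range = dwell_count_range,
                 dispersion_px = dispersion_px,
                 bias_px = bias_px,
                 mark_side_px = as.integer(mark_side_px),
                 margin_px = as.integer(margin_px),
                 grid = grid,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "synthetic_config: %d subjects/class, mark side %d px, seed %d\n",
    x$n_per_class, x$mark_side_px, x$seed))
  cat(sprintf("  dispersion px: %s; dwell counts: %s\n",
              paste(x$dispersion_px, collapse = "/"),
              paste(apply(x$dwell_count_range, 1, paste, collapse = "-"),
                    collapse = ", ")))
  invisible(x)
}

# HADS sub-score band per class
hads_band <- function(class) {
  switch(class, normal = c(0L, 7L), borderline = c(8L, 10L),
         case = c(11L, 21L))
}

# 7 items iid uniform on 0..3, rejected until the sub-score lands in the
# class band (every band has acceptance probability > 0.1).
sample_hads_items <- function(class) {
  band <- hads_band(class)
  repeat {
    items <- sample(0:3, 7, replace = TRUE)
    s <- sum(items)
    if (s >= band[1] && s <= band[2]) return(items)
  }
}

# class-conditional clinical covariates: cooperation VAS (1-10), heart rate
# at five time points (baseline, start, flap, ablation, end; beats/min) and
# photoablation breaks. Means and spreads follow the qualitative ordering of
# real cohorts (monotone in severity; ablation-time peak in the case group).
sample_covariates <- function(class) {
  ci <- match(class, anxiety_levels())
  vas_mu <- c(2.3, 4.1, 5.3)[ci]; vas_sd <- c(0.8, 0.4, 0.3)[ci]
  vas <- min(max(round(stats::rnorm(1, vas_mu, vas_sd)), 1), 10)
  hr_mu <- rbind(normal     = c(65.5, 67.0, 66.1, 68.5, 68.0),
                 borderline = c(65.4, 67.5, 67.3, 71.5, 70.0),
                 case       = c(69.8, 74.9, 75.5, 79.5, 79.9))[ci, ]
  hr_sd <- rbind(normal     = c(2.2, 2.3, 2.1, 2.0, 1.8),
                 borderline = c(1.6, 3.1, 1.4, 3.5, 2.2),
                 case       = c(3.2, 5.0, 3.6, 6.2, 4.6))[ci, ]
  hr <- stats::rnorm(5, hr_mu, hr_sd)
  names(hr) <- c("baseline", "start", "flap", "ablation", "end")
  n_breaks <- stats::rpois(1, c(0.2, 0.3, 0.9)[ci])
  breaks_s <- if (n_breaks > 0) sum(stats::rexp(n_breaks, rate = 1 / 3)) else 0
  list(vas = vas, hr = hr, n_breaks = n_breaks, breaks_duration_s = breaks_s)
}

#' Generate a synthetic cohort with analytic ground truth
#'
#' Draws `n_per_class` subjects per anxiety class. For each subject the
#' dwell centers are sampled from the class's truncated Gaussian, converted
#' to axis-aligned mark squares (top-left corner + side, integer pixel
#' coordinates), and the analytic plot parameters (SA, SP, ACD) are computed
#' from the square-union geometry by exact pixel enumeration
#' ([analytic_parameters()]) -- independent of any rendered image. HADS
#' items, cooperation VAS, heart rate and break covariates are drawn from
#' class-conditional distributions. Eye laterality alternates right/left
#' within each class, and the decentration bias is mirrored horizontally for
#' left eyes.
#'
#' Fully reproducible: the same config (including its seed) yields an
#' identical cohort.
#'
#' @param config a [synthetic_config()].
#' @return list of `ground_truth` objects, one per subject (attribute
#'   `config` carries the generating configuration).
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  cohort <- list()
  sid <- 0L
  for (ci in seq_along(anxiety_levels())) {
    cls <- anxiety_levels()[ci]
    for (j in seq_len(config$n_per_class)) {
      sid <- sid + 1L
      eye <- if (j %% 2 == 1) "right" else "left"
      cohort[[sid]] <- sample_subject(config, cls, eye, sid)
    }
  }
  attr(cohort, "config") <- config
  cohort
}

sample_subject <- function(config, class, eye, subject_id) {
  ci <- match(class, anxiety_levels())
  grid <- config$grid
  e <- grid_extent_px(grid)
  s <- config$mark_side_px
  rng <- config$dwell_count_range[ci, ]
  n_dwell <- sample(seq(rng[1], rng[2]), 1)
  bias <- config$bias_px[ci, ]
  if (eye == "left") bias[1] <- -bias[1]
  disp <- config$dispersion_px[ci]

  # square top-left corners, truncated-resampled to keep squares in-grid
  lo_x <- grid$center_px[1] - e; hi_x <- grid$center_px[1] + e - s + 1
  lo_y <- grid$center_px[2] - e; hi_y <- grid$center_px[2] + e - s + 1
  x0 <- integer(0); y0 <- integer(0)
  while (length(x0) < n_dwell) {
    need <- n_dwell - length(x0)
    cx <- round(grid$center_px[1] + bias[1] + stats::rnorm(need, 0, disp))
    cy <- round(grid$center_px[2] + bias[2] + stats::rnorm(need, 0, disp))
    nx <- cx - floor(s / 2); ny <- cy - floor(s / 2)
    ok <- nx >= lo_x & nx <= hi_x & ny >= lo_y & ny <= hi_y
    x0 <- c(x0, nx[ok]); y0 <- c(y0, ny[ok])
  }
  squares <- data.frame(x0 = as.integer(x0), y0 = as.integer(y0),
                        side = s)
  items <- sample_hads_items(class)
  cov <- sample_covariates(class)
  structure(list(subject_id = subject_id,
                 class = factor(class, levels = anxiety_levels()),
                 eye = eye,
                 squares = squares,
                 params = analytic_parameters(squares, grid),
                 hads_items = items,
                 hads_sub_score = sum(items),
                 vas = cov$vas, hr = cov$hr,
                 n_breaks = cov$n_breaks,
                 breaks_duration_s = cov$breaks_duration_s,
                 grid = grid),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground_truth #%d (%s, %s eye): %d squares, SA %g SP %g ACD %.2f, HADS %d\n",
    x$subject_id, as.character(x$class), x$eye, nrow(x$squares),
    x$params$sa, x$params$sp, x$params$acd, x$hads_sub_score))
  invisible(x)
}

#' Analytic plot parameters from square-union geometry
#'
#' Computes (SA, SP, ACD) directly from the mark squares' corner
#' coordinates, without rendering or detecting anything. Squares are first
#' grouped into clusters by rectangle-level 8-adjacency (two squares touch
#' if their pixel intervals are within one pixel in both axes, transitively
#' closed); each cluster's pixel union is then enumerated exactly to obtain
#' its area, boundary-edge perimeter and centroid. Serves as the ground-
#' truth oracle for the image pathway
#' (render -> detect -> extract -> compute).
#'
#' @param squares data.frame with integer columns `x0`, `y0` (top-left
#'   pixel) and `side`, or a `ground_truth` object.
#' @param grid a [tracking_grid()] (ignored when `squares` is a
#'   `ground_truth`, which carries its own grid).
#' @return a `plot_params` object.
#' @export
analytic_parameters <- function(squares, grid) {
  if (inherits(squares, "ground_truth")) {
    grid <- squares$grid
    squares <- squares$squares
  }
  stopifnot(is.data.frame(squares),
            all(c("x0", "y0", "side") %in% names(squares)))
  n <- nrow(squares)
  if (n == 0) return(new_plot_params(0, 0, 0, empty = TRUE))
  if (any(squares$side < 1)) stop("square sides must be >= 1")

  x0 <- squares$x0; y0 <- squares$y0; s <- squares$side
  x1 <- x0 + s - 1L; y1 <- y0 + s - 1L

  # rectangle-level 8-adjacency: intervals within 1 px on both axes
  adj_from <- integer(0); adj_to <- integer(0)
  if (n > 1) {
    pr <- utils::combn(n, 2)
    i <- pr[1, ]; j <- pr[2, ]
    touch <- (pmax(x0[i], x0[j]) - pmin(x1[i], x1[j]) <= 1L) &
             (pmax(y0[i], y0[j]) - pmin(y1[i], y1[j]) <= 1L)
    adj_from <- i[touch]; adj_to <- j[touch]
  }
  g <- igraph::make_graph(edges = rbind(adj_from, adj_to), n = n,
                          directed = FALSE)
  member <- igraph::components(g)$membership

  area <- perim <- cx <- cy <- numeric(max(member))
  for (k in seq_len(max(member))) {
    idx <- which(member == k)
    px <- unique(do.call(rbind, lapply(idx, function(q)
      cbind(x = rep(x0[q]:x1[q], each = s[q]), y = y0[q]:y1[q]))))
    area[k] <- nrow(px)
    cx[k] <- mean(px[, "x"]); cy[k] <- mean(px[, "y"])
    key <- paste(px[, "x"], px[, "y"])
    nb <- c(paste(px[, "x"] + 1L, px[, "y"]), paste(px[, "x"] - 1L, px[, "y"]),
            paste(px[, "x"], px[, "y"] + 1L), paste(px[, "x"], px[, "y"] - 1L))
    perim[k] <- sum(!(nb %in% key))
  }
  d <- sqrt((cx - grid$center_px[1])^2 + (cy - grid$center_px[2])^2)
  new_plot_params(sa = sum(area), sp = sum(perim),
                  acd = sum(area * d) / sum(area), empty = FALSE)
}

#' Rasterize mark squares into a mark mask
#'
#' Builds the binary mark mask a rendered plot of these squares would
#' produce, without going through image encoding/decoding. Useful for
#' average-map computation and as a fast mask source in simulations.
#'
#' @param squares data.frame (`x0`, `y0`, `side`) or `ground_truth`.
#' @param grid a [tracking_grid()].
#' @param source_id identifier carried through.
#' @return a `mark_mask`.
#' @export
rasterize_squares <- function(squares, grid,
                              source_id = NA_character_) {
  if (inherits(squares, "ground_truth")) {
    if (missing(source_id)) source_id <- as.character(squares$subject_id)
    grid <- squares$grid
    squares <- squares$squares
  }
  e <- grid_extent_px(grid)
  nr <- as.integer(grid$center_px[2] + e + (grid$center_px[2] - e - 1))
  nc <- as.integer(grid$center_px[1] + e + (grid$center_px[1] - e - 1))
  mask <- matrix(FALSE, nr, nc)
  if (nrow(squares) && any(squares$side < 1))
    stop("square sides must be >= 1")
  for (q in seq_len(nrow(squares))) {
    xs <- squares$x0[q]:(squares$x0[q] + squares$side[q] - 1L)
    ys <- squares$y0[q]:(squares$y0[q] + squares$side[q] - 1L)
    if (min(xs) < 1 || max(xs) > nc || min(ys) < 1 || max(ys) > nr)
      stop("square outside the image bounds")
    mask[ys, xs] <- TRUE
  }
  new_mark_mask(mask, grid, source_id)
}

#' Render a synthetic pupil-center plot
#'
#' Draws the subject's mark squares in the detector's default blue on a
#' white background, with a gray crosshair through the grid center (outside
#' the mark color band, so detection recovers exactly the mark pixels).
#' Rendering is the exact inverse of [detect_marks()]: the detected mask
#' equals the analytic union of the squares, bit-exactly.
#'
#' @param truth a `ground_truth` from [sample_cohort()], or a data.frame of
#'   squares.
#' @param grid a [tracking_grid()] (taken from `truth` when available).
#' @param path optional output PNG path; when given the image is written
#'   losslessly.
#' @return the image array `[rows, cols, 3]`, invisibly when `path` is set.
#' @export
render_plot <- function(truth, grid = NULL, path = NULL) {
  if (inherits(truth, "ground_truth")) {
    grid <- truth$grid
    squares <- truth$squares
  } else squares <- truth
  stopifnot(inherits(grid, "tracking_grid"))
  e <- grid_extent_px(grid)
  nr <- as.integer(grid$center_px[2] + e + (grid$center_px[2] - e - 1))
  nc <- as.integer(grid$center_px[1] + e + (grid$center_px[1] - e - 1))

  img <- array(1, dim = c(nr, nc, 3))                      # white
  cxi <- as.integer(round(grid$center_px[1]))
  cyi <- as.integer(round(grid$center_px[2]))
  xs <- (cxi - e):(cxi + e); ys <- (cyi - e):(cyi + e)
  img[cyi, xs, ] <- 0.5                                    # gray crosshair
  img[ys, cxi, ] <- 0.5

  if (nrow(squares)) {
    if (any(squares$x0 < grid$center_px[1] - e |
            squares$x0 + squares$side - 1 > grid$center_px[1] + e |
            squares$y0 < grid$center_px[2] - e |
            squares$y0 + squares$side - 1 > grid$center_px[2] + e))
      stop("mark square outside the tracking square")
    for (q in seq_len(nrow(squares))) {
      qx <- squares$x0[q]:(squares$x0[q] + squares$side[q] - 1L)
      qy <- squares$y0[q]:(squares$y0[q] + squares$side[q] - 1L)
      img[qy, qx, 1] <- 0; img[qy, qx, 2] <- 0; img[qy, qx, 3] <- 1
    }
  }
  if (!is.null(path)) {
    png::writePNG(img, path)
    return(invisible(img))
  }
  img
}

#' Measure a plot image end to end
#'
#' Convenience chain `detect_marks` -> `extract_clusters` ->
#' `compute_parameters`.
#'
#' @inheritParams detect_marks
#' @param connectivity passed to [extract_clusters()].
#' @return a `plot_params`.
#' @export
measure_plot <- function(image, grid, color_spec = mark_color_spec(),
                         connectivity = 8, source_id = NA_character_) {
  mask <- suppressWarnings(
    detect_marks(image, grid, color_spec, source_id))
  compute_parameters(extract_clusters(mask, connectivity))
}

#' Tabulate a synthetic cohort
#'
#' Flattens a cohort into one row per subject: identifiers, class, eye,
#' analytic SA/SP/ACD, HADS items and sub-score, VAS, heart rates, breaks.
#' Pipe through [score_subjects()] to append FIS columns.
#'
#' @param cohort list of `ground_truth` from [sample_cohort()].
#' @return data.frame with one row per subject.
#' @export
cohort_table <- function(cohort) {
  rows <- lapply(cohort, function(g) {
    out <- data.frame(subject_id = g$subject_id,
                      class = as.character(g$class),
                      eye = g$eye,
                      sa = g$params$sa, sp = g$params$sp, acd = g$params$acd,
                      hads_sub_score = g$hads_sub_score,
                      vas = g$vas,
                      n_breaks = g$n_breaks,
                      breaks_duration_s = g$breaks_duration_s)
    for (i in 1:7) out[[paste0("hads_", i)]] <- g$hads_items[i]
    for (tp in names(g$hr)) out[[paste0("hr_", tp)]] <- unname(g$hr[tp])
    out
  })
  df <- do.call(rbind, rows)
  df$class <- factor(df$class, levels = anxiety_levels())
  df$hads_class <- classify_hads(df$hads_sub_score)
  df
}
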