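#' FIS coefficients
#'
#' The Fixation Instability Score is a fixed linear combination of the three
#' plot morphometrics,
#' `FIS = 0.005 * SA + 0.027 * SP + 0.213 * ACD + 4.458`,
#' calibrated against the HADS anxiety sub-score. The coefficients are held
#' here as named configuration constants (overridable via
#' `options(fixstab.fis_coefficients = ...)`) so the score can be
#' recalibrated for a different device without code changes.
#'
#' @return named numeric vector with elements `sa`, `sp`, `acd`, `intercept`.
#' @export
fis_coefficients <- function() {
  getOption("fixstab.fis_coefficients",
            c(sa = 0.005, sp = 0.027, acd = 0.213, intercept = 4.458))
}

#' Compute plot morphometrics from a cluster set
#'
#' * `SA` (sum area): total mark area, the union of all (possibly
#'   overlapping) position marks -- the mask's mark pixel count.
#' * `SP` (sum perimeter): summed boundary length of all mark clusters.
#' * `ACD` (average centroid deviation): each cluster centroid's Euclidean
#'   distance to the tracking-area center, weighted by cluster area, then
#'   averaged: `sum(area_i * dist_i) / sum(area_i)`. Larger clusters weigh
#'   more. Defined as 0 for an empty plot.
#'
#' All three are in plot-pixel units at the grid's resolution.
#'
#' @param clusters a `cluster_set` from [extract_clusters()].
#' @return object of class `plot_params`: list with numeric `sa`, `sp`,
#'   `acd` and the `empty` flag.
#' @examples
#' g <- tracking_grid(c(50, 50), px_per_mm = 10)
#' truth <- list(squares = data.frame(x0 = 46, y0 = 46, side = 10))
#' m <- rasterize_squares(truth$squares, g)
#' compute_parameters(extract_clusters(m))  # SA 100, SP 40, ACD 0
#' @export
compute_parameters <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  cl <- clusters$clusters
  if (nrow(cl) == 0)
    return(new_plot_params(0, 0, 0, empty = TRUE))
  sa <- clusters$union_area
  sp <- sum(cl$perimeter_px)
  acd <- sum(cl$area_px * cl$dist_px) / sum(cl$area_px)
  new_plot_params(sa, sp, acd, empty = FALSE)
}

new_plot_params <- function(sa, sp, acd, empty = (sa == 0)) {
  if (any(!is.finite(c(sa, sp, acd))) || any(c(sa, sp, acd) < 0))
    stop("SA, SP and ACD must be finite and non-negative")
  structure(list(sa = as.numeric(sa), sp = as.numeric(sp),
                 acd = as.numeric(acd), empty = empty),
            class = "plot_params")
}

#' @rdname compute_parameters
#' @param sa,sp,acd non-negative scalars (direct construction, e.g. from a
#'   CSV of precomputed parameters).
#' @export
plot_params <- function(sa, sp, acd) new_plot_params(sa, sp, acd)

#' @export
print.plot_params <- function(x, ...) {
  cat(sprintf("plot_params: SA = %g px^2, SP = %g px, ACD = %g px%s\n",
              x$sa, x$sp, x$acd, if (x$empty) " (empty plot)" else ""))
  invisible(x)
}

#' Fixation Instability Score
#'
#' Evaluates the FIS linear formula on a plot's (SA, SP, ACD) triple and
#' assigns the 0-90 scale value and anxiety class. The raw score is clipped
#' and rounded (half-up) to an integer scale value in \[0, 90\]; the class
#' boundaries follow the published cutoffs: normal for raw FIS <= 12,
#' borderline for 12 < FIS <= 36, case for FIS > 36 (equivalently integer
#' bands 0-12 / 13-36 / 37-90).
#'
#' An empty plot (no marks at all) scores the formula intercept, 4.458,
#' which classifies as normal; the empty flag is carried through.
#'
#' @param params a `plot_params` (or anything with numeric `sa`, `sp`,
#'   `acd` fields).
#' @return object of class `fis_result`: list with `fis_raw`, `fis_scale`
#'   (integer in \[0, 90\]), `anxiety_class` (factor: normal / borderline /
#'   case), `empty`.
#' @examples
#' compute_fis(plot_params(490.5, 110, 12.08))
#' @export
compute_fis <- function(params) {
  v <- c(params$sa, params$sp, params$acd)
  if (any(!is.finite(v)) || any(v < 0))
    stop("SA, SP and ACD must be finite and non-negative")
  k <- fis_coefficients()
  raw <- k[["sa"]] * params$sa + k[["sp"]] * params$sp +
    k[["acd"]] * params$acd + k[["intercept"]]
  scale_val <- as.integer(min(max(floor(raw + 0.5), 0), 90))
  structure(list(fis_raw = raw,
                 fis_scale = scale_val,
                 anxiety_class = classify_fis(raw),
                 empty = isTRUE(params$empty)),
            class = "fis_result")
}

#' @export
print.fis_result <- function(x, ...) {
  cat(sprintf("FIS %.3f (scale %d/90): %s%s\n", x$fis_raw, x$fis_scale,
              as.character(x$anxiety_class),
              if (isTRUE(x$empty)) " [empty plot]" else ""))
  invisible(x)
}

#' Anxiety classes
#' @return character vector of the three ordered class labels.
#' @export
anxiety_levels <- function() c("normal", "borderline", "case")

#' Classify a raw FIS value on the 0-90 anxiety scale
#'
#' Bands: normal for FIS <= 12, borderline for 12 < FIS <= 36, case for
#' FIS > 36 -- consistent with the integer scale bands 0-12, 13-36, 37-90.
#'
#' @param fis_raw finite numeric vector of raw FIS values.
#' @return factor with levels normal, borderline, case.
#' @export
classify_fis <- function(fis_raw) {
  if (!is.numeric(fis_raw) || any(!is.finite(fis_raw)))
    stop("`fis_raw` must be finite numeric")
  cls <- ifelse(fis_raw <= 12, "normal",
                ifelse(fis_raw <= 36, "borderline", "case"))
  factor(cls, levels = anxiety_levels())
}

#' Score the HADS anxiety sub-scale
#'
#' The anxiety sub-scale of the Hospital Anxiety and Depression Scale has
#' seven items, each answered on a 0-3 ordinal scale, summed to a sub-score
#' in \[0, 21\]. Bands: <= 7 normal (no anxiety), 8-10 borderline (doubtful
#' anxiety), 11-21 case (definite anxiety).
#'
#' @param items integer vector of exactly 7 responses, each in `0:3`.
#' @return object of class `hads_response`: list with `items`, `sub_score`,
#'   `hads_class` (factor).
#' @examples
#' score_hads(c(1, 1, 1, 1, 1, 1, 2))  # sub-score 8, borderline
#' @export
score_hads <- function(items) {
  if (length(items) != 7)
    stop("HADS anxiety sub-scale requires exactly 7 items, got ",
         length(items))
  if (!is.numeric(items) || any(!is.finite(items)) ||
      any(items != as.integer(items)) || any(items < 0 | items > 3))
    stop("each HADS item must be an integer in 0..3")
  s <- as.integer(sum(items))
  structure(list(items = as.integer(items), sub_score = s,
                 hads_class = classify_hads(s)),
            class = "hads_response")
}

#' @rdname score_hads
#' @param sub_score integer vector of sub-scores in `0:21`.
#' @return for `classify_hads`: factor with levels normal/borderline/case.
#' @export
classify_hads <- function(sub_score) {
  if (any(sub_score < 0 | sub_score > 21))
    stop("HADS sub-score must lie in 0..21")
  cls <- ifelse(sub_score <= 7, "normal",
                ifelse(sub_score <= 10, "borderline", "case"))
  factor(cls, levels = anxiety_levels())
}

#' @export
print.hads_response <- function(x, ...) {
  cat(sprintf("HADS anxiety sub-score %d/21: %s\n", x$sub_score,
              as.character(x$hads_class)))
  invisible(x)
}

#' Score a table of subjects
#'
#' Convenience wrapper: takes a data.frame with columns `sa`, `sp`, `acd`
#' (and optionally `hads_1` ... `hads_7`) and appends `fis_raw`,
#' `fis_scale`, `anxiety_class`, and -- when HADS items are present --
#' `hads_sub_score` and `hads_class`.
#'
#' @param df data.frame of per-subject parameters.
#' @return the input with score columns appended.
#' @export
score_subjects <- function(df) {
  stopifnot(all(c("sa", "sp", "acd") %in% names(df)))
  k <- fis_coefficients()
  df$fis_raw <- k[["sa"]] * df$sa + k[["sp"]] * df$sp +
    k[["acd"]] * df$acd + k[["intercept"]]
  df$fis_scale <- as.integer(pmin(pmax(floor(df$fis_raw + 0.5), 0), 90))
  df$anxiety_class <- classify_fis(df$fis_raw)
  item_cols <- paste0("hads_", 1:7)
  if (all(item_cols %in% names(df))) {
    df$hads_sub_score <- as.integer(rowSums(df[item_cols]))
    df$hads_class <- classify_hads(df$hads_sub_score)
  }
  df
}
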