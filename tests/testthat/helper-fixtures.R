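# Small-grid fixtures: a 10 px/mm grid gives a 61 x 61 tracking square,
# big enough for multi-square geometry but cheap to enumerate by hand.
small_grid <- function(center = c(31, 31), px_per_mm = 10) {
  tracking_grid(center_px = center, px_per_mm = px_per_mm)
}

squares_df <- function(x0, y0, side) {
  data.frame(x0 = as.integer(x0), y0 = as.integer(y0),
             side = as.integer(side))
}

# mask from explicit squares on a small grid
small_mask <- function(x0, y0, side, grid = small_grid()) {
  rasterize_squares(squares_df(x0, y0, side), grid)
}

# brute-force O(n^2) Mann-Whitney AUC (independent of roc_auc's rank form)
pairwise_auc <- function(scores, is_pos) {
  x <- scores[is_pos]; y <- scores[!is_pos]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# brute-force Youden scan over a dense threshold sweep
brute_youden <- function(scores, is_pos) {
  cand <- sort(unique(c(scores - 1e-9, scores + 1e-9,
                        min(scores) - 1, max(scores) + 1)))
  j <- vapply(cand, function(t)
    mean(scores[is_pos] > t) + mean(scores[!is_pos] <= t) - 1, numeric(1))
  max(j)
}

small_synth_config <- function(n_per_class = 4, seed = 99) {
  synthetic_config(n_per_class = n_per_class, seed = seed)
}
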