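#' Normalize per-cell reporter signals to the euchromatic red channel
#'
#' The red (E2C) reporter sits in euchromatin and acts as a per-cell noise
#' filter: dividing the compensated green (SF-GFP) and orange (mKO2) signals
#' by red cancels extrinsic cell-to-cell variation (size, expression
#' capacity). Cells at or below `red_floor` are excluded and counted.
#'
#' @param cells data.frame with columns `cell_id` (optional), `sample_id`,
#'   `green`, `orange`, `red` (compensated arbitrary units).
#' @param red_floor minimum red signal for a cell to be retained.
#' @return data.table with `green`, `orange` replaced by red-normalized
#'   ratios; attribute `n_excluded` holds the dropped-cell count.
#' @export
normalize_to_red <- function(cells, red_floor = 0) {
  dt <- data.table::as.data.table(cells)
  assert(all(c("green", "orange", "red") %in% names(dt)),
         "cells need columns green, orange, red", "hetscreen_format_error")
  assert(all(dt$green >= 0, na.rm = TRUE) && all(dt$orange >= 0, na.rm = TRUE),
         "green/orange must be non-negative", "hetscreen_domain_error")
  keep <- !is.na(dt$red) & dt$red > red_floor
  n_excluded <- sum(!keep)
  dt <- dt[keep]
  if (nrow(dt) == 0L)
    stop_hetscreen("all cells excluded by the red floor", "hetscreen_precondition_error")
  dt[, `:=`(green = green / red, orange = orange / red)]
  data.table::setattr(dt, "n_excluded", n_excluded)
  dt[]
}

#' Fit the gating model from the two control strains
#'
#' Two controls define the gate. (1) A strain expressing only E2C mimics a
#' fully repressed state: the `cutoff_quantile` of its red-normalized green
#' and orange signals sets the minimum cutoff below which a cell counts as
#' color-negative. (2) A heterochromatin-deficient (clr4-delete) strain should
#' have all reporters ON, but reporters inserted in heterochromatin are prone
#' to recombination in that background, so color-negative cells (reporter
#' lost) are excluded first; the 'max' expression per channel is then the
#' `max_estimator` over the remaining color-positive cells.
#'
#' @param control_red_only red-only control `CellTable` (raw signals).
#' @param control_no_het no-heterochromatin control `CellTable` (raw signals).
#' @param cutoff_quantile quantile of the red-only control defining the
#'   color-negative cutoff (default 0.995).
#' @param max_estimator `"mean"` (default) or `"median"` over color-positive
#'   control cells.
#' @param min_cells minimum cells required per control.
#' @return a `GatingModel` list: `min_cutoff_green`, `min_cutoff_orange`,
#'   `max_green`, `max_orange`, plus the parameters used.
#' @export
fit_gating <- function(control_red_only, control_no_het,
                       cutoff_quantile = 0.995,
                       max_estimator = c("mean", "median"),
                       min_cells = 200L) {
  max_estimator <- match.arg(max_estimator)
  assert(cutoff_quantile > 0 && cutoff_quantile <= 1,
         "cutoff_quantile must be in (0, 1]", "hetscreen_config_error")
  ro <- normalize_to_red(control_red_only)
  nh <- normalize_to_red(control_no_het)
  assert(nrow(ro) >= min_cells && nrow(nh) >= min_cells,
         sprintf("both controls need >= %d cells", min_cells),
         "hetscreen_precondition_error")
  min_g <- unname(stats::quantile(ro$green, cutoff_quantile, type = 7))
  min_o <- unname(stats::quantile(ro$orange, cutoff_quantile, type = 7))
  est <- if (max_estimator == "mean") mean else stats::median
  pos_g <- nh$green[nh$green > min_g]
  pos_o <- nh$orange[nh$orange > min_o]
  if (length(pos_g) == 0L || length(pos_o) == 0L)
    stop_hetscreen(paste("no color-positive cells in the no-heterochromatin",
                         "control (reporter lost to recombination?)"),
                   "hetscreen_precondition_error")
  model <- list(min_cutoff_green = min_g, min_cutoff_orange = min_o,
                max_green = est(pos_g), max_orange = est(pos_o),
                cutoff_quantile = cutoff_quantile, max_estimator = max_estimator)
  assert(model$max_green > min_g && model$max_orange > min_o,
         "gating degenerate: max not above min cutoff", "hetscreen_degenerate_error")
  structure(model, class = "GatingModel")
}

#' Scale gated cells to the control maximum and summarize reporter states
#'
#' Red-normalized signals are divided by the gate's per-channel 'max' so that
#' 1 means full (no-heterochromatin) expression, then clipped at
#' `scale_ceiling`. Color-negative cells (both channels below their minimum
#' cutoffs) are excluded. State fractions are computed on the scaled orange
#' (distal sensor) channel: OFF `< off_bound`, ON `>= on_bound`, intermediate
#' in between. The bounds are this package's explicit convention for turning
#' the bimodal density into fractions; the bimodality itself is what the
#' density output shows.
#'
#' @param cells analysis-strain `CellTable` (raw signals).
#' @param gate a [fit_gating()] model.
#' @param off_bound,on_bound state boundaries on the scaled orange axis.
#' @param hexbin_bins number of bins per axis for the 2D histogram
#'   (rectangular binning; hexagonal tiling is presentation-only).
#' @param scale_ceiling clip for scaled values.
#' @return a `StateSummary` list: `n_cells`, `n_color_negative`,
#'   `fraction_off`, `fraction_intermediate`, `fraction_on`, `density_curve`
#'   (data.table x/density of scaled orange, Silverman bandwidth), `hexbin`
#'   (data.table x_bin, y_bin, count over scaled green x orange) and `scaled`
#'   (per-cell table).
#' @export
scale_and_summarize <- function(cells, gate, off_bound = 0.1, on_bound = 0.8,
                                hexbin_bins = 50L, scale_ceiling = 1.5) {
  assert(inherits(gate, "GatingModel"), "gate must be a GatingModel")
  assert(off_bound < on_bound, "off_bound must be < on_bound",
         "hetscreen_config_error")
  dt <- normalize_to_red(cells)
  color_neg <- dt$green <= gate$min_cutoff_green &
               dt$orange <= gate$min_cutoff_orange
  n_neg <- sum(color_neg)
  dt <- dt[!color_neg]
  if (nrow(dt) == 0L)
    stop_hetscreen("no cells left after color-negative gating",
                   "hetscreen_precondition_error")
  dt[, `:=`(green = pmin(green / gate$max_green, scale_ceiling),
            orange = pmin(orange / gate$max_orange, scale_ceiling))]

  fr_off <- mean(dt$orange < off_bound)
  fr_on <- mean(dt$orange >= on_bound)
  fr_int <- 1 - fr_off - fr_on

  dens <- stats::density(dt$orange, bw = "nrd0",
                         from = 0, to = scale_ceiling, n = 512L)
  density_curve <- data.table::data.table(x = dens$x, density = dens$y)

  brk <- seq(0, scale_ceiling, length.out = hexbin_bins + 1L)
  xb <- pmin(findInterval(dt$green, brk, rightmost.closed = TRUE), hexbin_bins)
  yb <- pmin(findInterval(dt$orange, brk, rightmost.closed = TRUE), hexbin_bins)
  hex <- data.table::data.table(x_bin = xb, y_bin = yb)[, .(count = .N),
                                                        by = .(x_bin, y_bin)]
  data.table::setorder(hex, x_bin, y_bin)

  structure(list(n_cells = nrow(dt), n_color_negative = n_neg,
                 fraction_off = fr_off, fraction_intermediate = fr_int,
                 fraction_on = fr_on, density_curve = density_curve,
                 hexbin = hex[], scaled = dt[],
                 off_bound = off_bound, on_bound = on_bound,
                 scale_ceiling = scale_ceiling),
            class = "StateSummary")
}

#' @export
print.StateSummary <- function(x, ...) {
  cat(sprintf(paste0("StateSummary: %d cells (%d color-negative excluded)\n",
                     "  OFF %.3f | intermediate %.3f | ON %.3f\n"),
              x$n_cells, x$n_color_negative,
              x$fraction_off, x$fraction_intermediate, x$fraction_on))
  invisible(x)
}
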