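#' Relative growth of a colony on selective vs non-selective medium
#'
#' `ratio = selective / nonselective`. A missing or zero size on either medium
#' yields a missing ratio: a zero colony call usually reflects a failed pin or
#' segmentation dropout, and no pseudocount is used.
#'
#' @param selective_size,nonselective_size non-negative sizes (vectorized),
#'   `NA` for missing.
#' @return positive ratio or `NA`.
#' @export
relative_growth <- function(selective_size, nonselective_size) {
  assert(all(selective_size >= 0, na.rm = TRUE) &&
           all(nonselective_size >= 0, na.rm = TRUE),
         "colony sizes must be non-negative", "hetscreen_domain_error")
  out <- selective_size / nonselective_size
  out[is.na(selective_size) | is.na(nonselective_size) |
        selective_size <= 0 | nonselective_size <= 0] <- NA_real_
  out
}

#' Normalize relative-growth ratios to their 384-plate median
#'
#' Compensates plate-to-plate variation: every ratio is divided by the median
#' ratio of its plate, one plate = one (screen, readout, plate_id, bio_rep,
#' tech_rep) group. Plates whose median is 0 or that contain no usable ratio
#' are dropped with a warning.
#'
#' @param dt data.table with columns `screen`, `readout`, `plate_id`,
#'   `bio_rep`, `tech_rep`, `ratio`.
#' @return data.table with `ratio` replaced by the plate-normalized value.
#' @export
plate_median_normalize <- function(dt) {
  dt <- data.table::as.data.table(dt)
  grp <- c("screen", "readout", "plate_id", "bio_rep", "tech_rep")
  assert(all(c(grp, "ratio") %in% names(dt)),
         "need columns screen, readout, plate_id, bio_rep, tech_rep, ratio",
         "hetscreen_format_error")
  dt <- data.table::copy(dt)
  dt[, plate_median := stats::median(ratio, na.rm = TRUE), by = grp]
  bad <- dt[is.na(plate_median) | plate_median == 0]
  if (nrow(bad)) {
    flagged <- unique(bad[, grp, with = FALSE])
    warning(sprintf("dropping %d plate group(s) with undefined or zero median", nrow(flagged)))
    dt <- dt[!is.na(plate_median) & plate_median != 0]
  }
  dt[, ratio := ratio / plate_median]
  dt[, plate_median := NULL]
  dt[]
}

#' Average technical replicates into a biological-replicate value
#'
#' Arithmetic mean of the log2 relative-growth values over the available
#' technical replicates (2 by design, 2-4 supported); the mean defines the
#' biological-replicate value. All-missing groups stay missing.
#'
#' @param dt data.table with columns `screen`, `readout`, `strain_id`,
#'   `gene_name`, `bio_rep`, `log2_value`.
#' @return data.table, one row per (screen, readout, strain, bio_rep), with
#'   `value` (mean log2) and `n_tech` (contributing replicates).
#' @export
aggregate_technical <- function(dt) {
  dt <- data.table::as.data.table(dt)
  grp <- c("screen", "readout", "strain_id", "gene_name", "bio_rep")
  assert(all(c(grp, "log2_value") %in% names(dt)),
         "need columns screen, readout, strain_id, gene_name, bio_rep, log2_value",
         "hetscreen_format_error")
  out <- dt[, .(value = if (all(is.na(log2_value))) NA_real_
                else mean(log2_value, na.rm = TRUE),
                n_tech = sum(!is.na(log2_value))), by = grp]
  out[]
}

#' Scale and center one (screen, readout) dataset
#'
#' Makes the four reporter screens comparable: values are centered at the
#' screen median (so an unperturbed mutant sits at 0) and divided by the
#' sample standard deviation (n-1 denominator), computed over non-missing
#' values pooled across all biological replicates of the dataset.
#'
#' @param x numeric vector (one dataset), may contain `NA`.
#' @return vector of the same length; `median = 0`, `sd = 1` over non-missing
#'   values.
#' @export
scale_and_center <- function(x) {
  obs <- x[!is.na(x)]
  assert(length(obs) >= 3L, "need >= 3 non-missing values to scale",
         "hetscreen_precondition_error")
  s <- stats::sd(obs)
  if (!is.finite(s) || s == 0)
    stop_hetscreen("degenerate dataset: standard deviation is 0",
                   "hetscreen_degenerate_error")
  (x - stats::median(obs)) / s
}

#' Combined FOA/URA score
#'
#' A silencing defect de-represses the ura4+ reporter: growth without uracil
#' improves (positive scaled -URA score) and FOA turns toxic (negative scaled
#' +FOA score). Multiplying the FOA score by -1 before adding makes both
#' readouts point the same way, so `combined = ura - foa`; positive values
#' mean loss of silencing. Missing on either readout propagates.
#'
#' @param ura_scaled,foa_scaled scaled scores for the same
#'   (screen, strain, bio_rep); vectorized.
#' @return combined score or `NA`.
#' @export
combine_readouts <- function(ura_scaled, foa_scaled) {
  ura_scaled - foa_scaled
}

#' Run the full scoring pipeline on a PlateSet
#'
#' Fixed stage order: selective/NS ratio -> plate-median normalization ->
#' log2 -> technical-replicate mean -> per-(screen, readout) scale/center ->
#' combine readouts. Selective observations are matched to the non-selective
#' observation at the same (screen, plate_id, row, col, bio_rep, tech_rep)
#' position.
#'
#' If a (screen, readout) dataset is fully degenerate (zero variance), its
#' scaled scores are set to `value - median` (all zero) with a warning instead
#' of erroring, so that noise-free simulations flow through end-to-end; the
#' low-level [scale_and_center()] keeps its strict contract.
#'
#' @param plateset a `PlateSet`.
#' @return list with data.tables `relative_growth` (per technical replicate,
#'   columns `ratio`, `log2_value`), `bio_log2` (per biological replicate,
#'   the clustering feature source), `scaled` (per readout scaled scores) and
#'   `combined` (per-gene, per-screen, per-bio-rep combined FOA/URA score).
#' @export
score_screens <- function(plateset) {
  assert(inherits(plateset, "PlateSet"), "plateset must be a PlateSet")
  obs <- plateset$observations
  ns <- obs[medium == "NS",
            .(screen, plate_id, row, col, bio_rep, tech_rep, ns_size = size)]
  sel <- obs[medium != "NS",
             .(screen, readout = medium, plate_id, row, col, strain_id,
               gene_name, bio_rep, tech_rep, sel_size = size)]
  assert(nrow(sel) > 0L, "no selective (URA/FOA) observations",
         "hetscreen_precondition_error")
  rg <- ns[sel, on = c("screen", "plate_id", "row", "col", "bio_rep", "tech_rep")]
  assert(!anyNA(rg$strain_id), "selective observation without NS partner")
  rg[, ratio := relative_growth(sel_size, ns_size)]
  rg <- rg[, .(screen, readout, plate_id, row, col, strain_id, gene_name,
               bio_rep, tech_rep, ratio)]

  rg <- plate_median_normalize(rg)
  rg[, log2_value := log2(ratio)]

  bio <- aggregate_technical(rg)

  scaled <- data.table::copy(bio)
  scaled[, value := {
    obs_v <- value[!is.na(value)]
    s <- if (length(obs_v) >= 2L) stats::sd(obs_v) else NA_real_
    if (!is.finite(s) || s == 0) {
      warning(sprintf("degenerate dataset %s/%s: zero variance, centred only",
                      screen[1L], readout[1L]))
      value - stats::median(obs_v)
    } else scale_and_center(value)
  }, by = .(screen, readout)]

  wide <- data.table::dcast(scaled, screen + strain_id + gene_name + bio_rep ~ readout,
                            value.var = "value")
  for (nm in READOUTS) if (!nm %in% names(wide)) wide[, (nm) := NA_real_]
  combined <- wide[, .(screen, strain_id, gene = gene_name, bio_rep,
                       value = combine_readouts(URA, FOA))]

  list(relative_growth = rg[], bio_log2 = bio[],
       scaled = scaled[], combined = combined[])
}
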