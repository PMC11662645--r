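#' Per-gene, per-screen replicate statistics
#'
#' One-sample Student's t-test of the combined FOA/URA scores against 0 (the
#' screen median), per gene and screen, over biological replicates. Both the
#' mean (used by the t-test) and the median (the effect size used for hit
#' calling) are reported.
#'
#' Degenerate cases: fewer than 2 replicates -> untestable (`NA` statistics);
#' zero spread with nonzero mean -> `p = 0` with `degenerate = TRUE`; zero
#' spread with zero mean -> `p = 1`.
#'
#' @param combined data.table with columns `gene`, `screen`, `bio_rep`,
#'   `value` (one row per biological replicate).
#' @return data.table, one row per (gene, screen): `n_bio`, `mean`, `median`,
#'   `t_stat`, `p_value`, `degenerate`, `testable`, plus `p_bh`
#'   (Benjamini-Hochberg within screen, informational only — hit calling uses
#'   the raw p, as does the screen design).
#' @export
gene_statistics <- function(combined) {
  dt <- data.table::as.data.table(combined)
  assert(all(c("gene", "screen", "bio_rep", "value") %in% names(dt)),
         "need columns gene, screen, bio_rep, value", "hetscreen_format_error")
  stats_dt <- dt[!is.na(value),
    {
      n <- .N
      m <- mean(value)
      s <- stats::sd(value)
      if (n < 2L) {
        list(n_bio = n, mean = m, median = stats::median(value),
             t_stat = NA_real_, p_value = NA_real_,
             degenerate = FALSE, testable = FALSE)
      } else if (s == 0) {
        list(n_bio = n, mean = m, median = stats::median(value),
             t_stat = if (m == 0) 0 else sign(m) * Inf,
             p_value = if (m == 0) 1 else 0,
             degenerate = m != 0, testable = TRUE)
      } else {
        tv <- m / (s / sqrt(n))
        list(n_bio = n, mean = m, median = stats::median(value),
             t_stat = tv, p_value = 2 * stats::pt(-abs(tv), df = n - 1L),
             degenerate = FALSE, testable = TRUE)
      }
    },
    by = .(gene, screen)]
  stats_dt[, p_bh := stats::p.adjust(p_value, method = "BH"), by = screen]
  data.table::setorder(stats_dt, screen, gene)
  stats_dt[]
}

#' Default hit-calling thresholds
#'
#' Raw `P < 0.05` plus an effect-size threshold on the median combined score:
#' silencing hits need median `> 2.5` (MAT, SUBTEL, TEL) or `> 3` (CEN — the
#' pericentromeric imr1L reporter is leaky, so a stricter cut is used);
#' anti-silencing hits need median `< -2` (MAT, SUBTEL, TEL) or `< -3` (CEN).
#' The asymmetry (+2.5 vs -2) is intentional and preserved.
#'
#' @param p_max p-value cutoff.
#' @param silencing_min,antisilencing_max named per-screen effect thresholds.
#' @return a `ThresholdConfig` list.
#' @export
threshold_config <- function(p_max = 0.05,
                             silencing_min = c(CEN = 3, MAT = 2.5, SUBTEL = 2.5, TEL = 2.5),
                             antisilencing_max = c(CEN = -3, MAT = -2, SUBTEL = -2, TEL = -2)) {
  assert(all(SCREENS %in% names(silencing_min)) &&
           all(SCREENS %in% names(antisilencing_max)),
         "thresholds must name all screens (CEN, MAT, SUBTEL, TEL)",
         "hetscreen_config_error")
  assert(all(silencing_min > 0) && all(antisilencing_max < 0),
         "silencing_min must be > 0 > antisilencing_max", "hetscreen_config_error")
  structure(list(p_max = p_max, silencing_min = silencing_min,
                 antisilencing_max = antisilencing_max),
            class = "ThresholdConfig")
}

#' Call silencing / anti-silencing hits
#'
#' @param stats_dt output of [gene_statistics()].
#' @param cfg a [threshold_config()].
#' @return data.table of stats plus `direction` in
#'   `{"silencing","anti_silencing","none"}`; untestable genes (n_bio < 2)
#'   keep `direction = NA` and are reported, not silently dropped.
#' @export
call_hits <- function(stats_dt, cfg = threshold_config()) {
  assert(inherits(cfg, "ThresholdConfig"), "cfg must be a ThresholdConfig",
         "hetscreen_config_error")
  dt <- data.table::copy(data.table::as.data.table(stats_dt))
  missing_scr <- setdiff(unique(dt$screen), names(cfg$silencing_min))
  if (length(missing_scr))
    stop_hetscreen(sprintf("no thresholds configured for screen(s): %s",
                           paste(missing_scr, collapse = ", ")),
                   "hetscreen_config_error")
  smin <- cfg$silencing_min[dt$screen]
  amax <- cfg$antisilencing_max[dt$screen]
  dt[, direction := data.table::fifelse(!testable, NA_character_,
        data.table::fifelse(p_value < cfg$p_max & median > smin, "silencing",
        data.table::fifelse(p_value < cfg$p_max & median < amax, "anti_silencing",
                            "none")))]
  dt[]
}

#' Domain-overlap summary of hit calls
#'
#' For each hit gene, counts in how many of the four heterochromatin domains
#' it is called in the given direction; returns the histogram over 1..4
#' domains and, for single-domain genes, the per-domain breakdown.
#'
#' @param hits output of [call_hits()] covering all four screens.
#' @param direction `"silencing"` or `"anti_silencing"`.
#' @return list with `histogram` (named counts for "1".."4"), `single_domain`
#'   (named per-screen counts) and `n_genes` (total hit genes).
#' @export
overlap_summary <- function(hits, direction = c("silencing", "anti_silencing")) {
  dirv <- match.arg(direction)
  dt <- data.table::as.data.table(hits)
  is_dir <- !is.na(dt$direction) & dt$direction == dirv
  per_gene <- dt[is_dir, .(n_domains = data.table::uniqueN(screen)), by = gene]
  histogram <- setNames(integer(4L), as.character(1:4))
  if (nrow(per_gene)) {
    tab <- table(factor(per_gene$n_domains, levels = 1:4))
    histogram[] <- as.integer(tab)
  }
  singles <- dt[is_dir & gene %in% per_gene[n_domains == 1L, gene]]
  single_domain <- setNames(integer(length(SCREENS)), SCREENS)
  if (nrow(singles)) {
    tab <- table(factor(singles$screen, levels = SCREENS))
    single_domain[] <- as.integer(tab)
  }
  list(histogram = histogram, single_domain = single_domain,
       n_genes = nrow(per_gene))
}

#' Recall against a gold-standard factor list
#'
#' Fraction of known heterochromatin factors (restricted to genes actually
#' tested in the screen) retrieved as silencing hits.
#'
#' @param hits output of [call_hits()].
#' @param gold character vector of gold-standard gene names.
#' @param screen screen to evaluate.
#' @param direction hit direction counted as retrieved.
#' @return recall in `[0, 1]`.
#' @export
compute_recall <- function(hits, gold, screen,
                           direction = "silencing") {
  assert(length(gold) > 0L, "gold list is empty", "hetscreen_precondition_error")
  dt <- data.table::as.data.table(hits)
  scr <- screen; dirv <- direction
  sub <- dt[dt$screen == scr & !is.na(dt$direction)]
  denom <- intersect(gold, sub$gene)
  if (length(denom) == 0L)
    stop_hetscreen("no gold-standard gene was tested in this screen",
                   "hetscreen_precondition_error")
  hit_genes <- sub$gene[sub$direction == dirv]
  length(intersect(denom, hit_genes)) / length(denom)
}

#' Group-normalize act1-normalized transcript levels
#'
#' Divides each act1-normalized transcript level by the mean of all samples
#' from the same experiment batch, putting batches on a common relative scale
#' (output mean = 1).
#'
#' @param levels positive numeric vector (one batch).
#' @return relative values, mean exactly 1.
#' @export
group_normalize_expression <- function(levels) {
  assert(length(levels) >= 1L && all(is.finite(levels)) && all(levels > 0),
         "levels must be positive and finite", "hetscreen_domain_error")
  levels / mean(levels)
}

#' Precision (positive predictive value) from transcript validation
#'
#' Fraction of validated hit genes whose reporter transcript shows a
#' fold-change strictly above `fold_threshold` relative to wild type.
#'
#' @param hit_genes character vector of hit genes.
#' @param validation data.frame with columns `gene`, `fold_change`.
#' @param fold_threshold strict lower bound (default 1.5).
#' @return precision in `[0, 1]`.
#' @export
compute_precision <- function(hit_genes, validation, fold_threshold = 1.5) {
  dt <- data.table::as.data.table(validation)
  assert(all(c("gene", "fold_change") %in% names(dt)),
         "validation needs columns gene, fold_change", "hetscreen_format_error")
  dt <- dt[gene %in% hit_genes]
  if (nrow(dt) == 0L)
    stop_hetscreen("no hit gene has validation data", "hetscreen_precondition_error")
  mean(dt$fold_change > fold_threshold)
}

#' Fisher's exact test for cluster-pathway enrichment
#'
#' Two-sided Fisher's exact test on the 2x2 table of pathway membership vs
#' cluster membership over a gene universe. The odds ratio is the conditional
#' maximum-likelihood estimate reported by `stats::fisher.test`.
#'
#' @param cluster_genes,pathway_genes,universe gene sets;
#'   `cluster_genes`, `pathway_genes` must be subsets of `universe`.
#' @return list with `odds_ratio`, `p_value` and the 2x2 `table`.
#' @export
fisher_enrichment <- function(cluster_genes, pathway_genes, universe) {
  assert(length(universe) > 0L, "empty universe", "hetscreen_precondition_error")
  universe <- unique(universe)
  cluster_genes <- unique(cluster_genes); pathway_genes <- unique(pathway_genes)
  assert(all(cluster_genes %in% universe) && all(pathway_genes %in% universe),
         "cluster and pathway genes must be subsets of the universe",
         "hetscreen_precondition_error")
  a <- length(intersect(cluster_genes, pathway_genes))
  b <- length(setdiff(pathway_genes, cluster_genes))
  c_ <- length(setdiff(cluster_genes, pathway_genes))
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE,
                dimnames = list(pathway = c("in", "out"),
                                cluster = c("in", "out")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}
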