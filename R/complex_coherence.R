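#' Per-gene domain profiles from combined scores
#'
#' The phenotypic profile of a gene is the 4-vector of its mean combined
#' FOA/URA scores over biological replicates, one entry per screen in the
#' fixed order CEN, MAT, SUBTEL, TEL. An 8-dimensional (screen x readout)
#' mode over scaled per-readout scores is available because a Pearson
#' correlation over 4 points is coarse; the mode is recorded in the result.
#'
#' @param scores `combined` table (`gene`, `screen`, `bio_rep`, `value`) for
#'   mode `"combined4"`, or `scaled` table (with `readout`) for `"readout8"`.
#' @param mode profile dimensionality.
#' @return a `GeneProfileSet`: list with `matrix` (genes x features),
#'   `mode`, `features`.
#' @export
build_gene_profiles <- function(scores, mode = c("combined4", "readout8")) {
  mode <- match.arg(mode)
  dt <- data.table::as.data.table(scores)
  if (!"gene" %in% names(dt) && "gene_name" %in% names(dt))
    data.table::setnames(dt, "gene_name", "gene")
  if (mode == "combined4") {
    assert(all(c("gene", "screen", "bio_rep", "value") %in% names(dt)),
           "need columns gene, screen, bio_rep, value", "hetscreen_format_error")
    agg <- dt[, .(value = mean(value, na.rm = TRUE)), by = .(gene, screen)]
    wide <- data.table::dcast(agg, gene ~ screen, value.var = "value")
    feats <- SCREENS
  } else {
    assert(all(c("gene", "screen", "readout", "bio_rep", "value") %in% names(dt)),
           "need columns gene, screen, readout, bio_rep, value",
           "hetscreen_format_error")
    agg <- dt[, .(value = mean(value, na.rm = TRUE)), by = .(gene, screen, readout)]
    wide <- data.table::dcast(agg, gene ~ screen + readout, value.var = "value")
    feats <- as.vector(outer(SCREENS, READOUTS, paste, sep = "_"))
  }
  for (nm in feats) if (!nm %in% names(wide)) wide[, (nm) := NA_real_]
  data.table::setcolorder(wide, c("gene", feats))
  mat <- as.matrix(wide[, feats, with = FALSE])
  rownames(mat) <- wide$gene
  structure(list(matrix = mat, mode = mode, features = feats),
            class = "GeneProfileSet")
}

#' Pairwise Pearson correlation of phenotypic profiles
#'
#' @param profiles a `GeneProfileSet` or a numeric matrix (genes in rows).
#'   Genes with a missing or zero-variance profile are excluded with a
#'   warning.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pairwise_profile_correlation <- function(profiles) {
  mat <- if (inherits(profiles, "GeneProfileSet")) profiles$matrix else as.matrix(profiles)
  assert(ncol(mat) >= 3L, "profiles need >= 3 points", "hetscreen_precondition_error")
  bad <- apply(mat, 1L, function(x) anyNA(x) || stats::sd(x) == 0)
  if (any(bad)) {
    warning(sprintf("excluding %d gene(s) with missing or zero-variance profile: %s",
                    sum(bad), paste(head(rownames(mat)[bad], 5L), collapse = ", ")))
    mat <- mat[!bad, , drop = FALSE]
  }
  assert(nrow(mat) >= 2L, "need >= 2 usable profiles", "hetscreen_precondition_error")
  cm <- stats::cor(t(mat), method = "pearson")
  diag(cm) <- 1
  cm
}

# complex map as a validated named membership vector gene -> complex_id
complex_membership <- function(complexes, genes_present) {
  dt <- data.table::as.data.table(complexes)
  assert(all(c("complex_id", "gene") %in% names(dt)),
         "complex map needs columns complex_id, gene", "hetscreen_format_error")
  dup <- dt[, .N, by = gene][N > 1L, gene]
  if (length(dup))
    stop_hetscreen(sprintf("gene(s) in more than one complex: %s",
                           paste(dup, collapse = ", ")),
                   "hetscreen_integrity_error")
  missing_g <- setdiff(dt$gene, genes_present)
  assert(length(missing_g) == 0L,
         sprintf("complex gene(s) absent from the correlation matrix: %s",
                 paste(head(missing_g, 5L), collapse = ", ")),
         "hetscreen_precondition_error")
  setNames(dt$complex_id, dt$gene)
}

# indices of within/between pairs for a membership vector (upper triangle)
pair_classes <- function(member) {
  same <- outer(member, member, `==`)
  ut <- upper.tri(same)
  list(within = same & ut, between = (!same) & ut)
}

#' Within- vs between-complex correlation summary
#'
#' Classifies every unordered pair of complex-annotated genes as within-complex
#' or between-complex and reports the fraction of pairs in each class with
#' Pearson `r >= r_threshold`. Genes with no complex annotation are ignored.
#'
#' @param corr correlation matrix from [pairwise_profile_correlation()].
#' @param complexes complex-membership table (`complex_id`, `gene`).
#' @param r_threshold correlation cutoff (default 0.9).
#' @return list: `within_pairs`, `between_pairs`, `frac_within_ge_r`,
#'   `frac_between_ge_r`, `r_threshold`, `mean_within_r`, `mean_between_r`.
#' @export
within_between_summary <- function(corr, complexes, r_threshold = 0.9) {
  member <- complex_membership(complexes, rownames(corr))
  genes <- names(member)
  cm <- corr[genes, genes, drop = FALSE]
  pc <- pair_classes(member)
  n_within <- sum(pc$within); n_between <- sum(pc$between)
  if (n_within == 0L)
    stop_hetscreen("no within-complex pairs (all complexes singleton?)",
                   "hetscreen_precondition_error")
  list(within_pairs = n_within, between_pairs = n_between,
       frac_within_ge_r = mean(cm[pc$within] >= r_threshold),
       frac_between_ge_r = if (n_between) mean(cm[pc$between] >= r_threshold) else NA_real_,
       r_threshold = r_threshold,
       mean_within_r = mean(cm[pc$within]),
       mean_between_r = if (n_between) mean(cm[pc$between]) else NA_real_)
}

coherence_stat <- function(cm, member, type = c("mean_diff", "frac_diff"),
                           r_threshold = 0.9) {
  type <- match.arg(type)
  pc <- pair_classes(member)
  if (type == "mean_diff")
    mean(cm[pc$within]) - mean(cm[pc$between])
  else
    mean(cm[pc$within] >= r_threshold) - mean(cm[pc$between] >= r_threshold)
}

#' Permutation test for protein-complex coherence
#'
#' Tests whether subunits of the same complex have more similar phenotypic
#' profiles than subunits of different complexes. The observed statistic is
#' mean(within-pair r) - mean(between-pair r); the null is built by permuting
#' the gene-to-complex assignment among the annotated genes, preserving
#' complex sizes. One-sided (within > between), add-one estimator
#' `p = (1 + #permutations >= observed) / (1 + n_perm)`, never 0.
#'
#' On tiny inputs where the number of distinct label arrangements is at most
#' `n_perm`, the full arrangement set is enumerated instead and the exact p
#' (fraction of arrangements with statistic >= observed, observed included)
#' is returned with `method = "exhaustive"`.
#'
#' @param corr correlation matrix.
#' @param complexes complex-membership table.
#' @param n_perm Monte-Carlo permutations (default 10000).
#' @param seed RNG seed (Monte-Carlo path only).
#' @param stat permutation statistic: difference of mean correlations
#'   (default) or difference of fractions at `r_threshold`.
#' @param r_threshold cutoff for `stat = "frac_diff"`.
#' @return list: `perm_p`, `observed_stat`, `n_perm`, `method`, `stat`.
#' @export
permutation_test <- function(corr, complexes, n_perm = 10000L, seed = 1L,
                             stat = c("mean_diff", "frac_diff"),
                             r_threshold = 0.9) {
  stat <- match.arg(stat)
  assert(n_perm >= 1L, "n_perm must be >= 1", "hetscreen_config_error")
  member <- complex_membership(complexes, rownames(corr))
  genes <- names(member)
  cm <- corr[genes, genes, drop = FALSE]
  pc <- pair_classes(member)
  assert(sum(pc$within) > 0L && sum(pc$between) > 0L,
         "need both within- and between-complex pairs",
         "hetscreen_precondition_error")
  observed <- coherence_stat(cm, member, stat, r_threshold)

  m <- length(member)
  sizes <- table(member)
  n_arrangements <- exp(lgamma(m + 1) - sum(lgamma(sizes + 1)))
  if (n_arrangements <= n_perm && m <= 8L) {
    perms <- all_permutations(m)
    stats_v <- apply(perms, 1L, function(idx) {
      lab <- member
      names(lab) <- NULL
      coherence_stat(cm, setNames(lab[idx], genes), stat, r_threshold)
    })
    p <- mean(stats_v >= observed - 1e-12)
    return(list(perm_p = p, observed_stat = observed,
                n_perm = nrow(perms), method = "exhaustive", stat = stat))
  }

  count <- with_seed(seed, permutation_count(cm, member, n_perm, stat,
                                             r_threshold, observed))
  list(perm_p = (1 + count) / (1 + n_perm), observed_stat = observed,
       n_perm = n_perm, method = "monte_carlo", stat = stat)
}

permutation_count <- function(cm, member, n_perm, stat, r_threshold, observed) {
  m <- length(member)
  genes <- names(member)
  count <- 0L
  lab <- unname(member)
  if (stat == "mean_diff") {
    # under permutation only the within-pair sum W changes: the pair counts
    # and the total pair sum are fixed, and mean_diff is monotone in W
    groups <- split(seq_len(m), lab)
    within_sum <- function(idx_perm) {
      w <- 0
      for (g in groups) {
        v <- idx_perm[g]
        w <- w + (sum(cm[v, v]) - length(v)) / 2
      }
      w
    }
    w_obs <- within_sum(seq_len(m))
    for (i in seq_len(n_perm))
      if (within_sum(sample.int(m)) >= w_obs - 1e-12) count <- count + 1L
  } else {
    for (i in seq_len(n_perm)) {
      perm_member <- setNames(lab[sample.int(m)], genes)
      if (coherence_stat(cm, perm_member, stat, r_threshold) >= observed - 1e-12)
        count <- count + 1L
    }
  }
  count
}

# all permutations of 1..n (n small), rows = permutations
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 1L
  for (pos in seq_len(n)) for (i in seq_len(nrow(sub))) {
    out[r, ] <- append(sub[i, ], n, after = pos - 1L)
    r <- r + 1L
  }
  out
}
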