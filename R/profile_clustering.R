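#' Build the clustering feature matrix
#'
#' Features are the 8 per-gene median log2 relative-growth values (4 screens x
#' {FOA, URA}), medians taken over biological replicates — the quantity shown
#' in the screen heatmaps. Column weights are applied by scaling the values
#' (halving a column halves its contribution to Euclidean distance, i.e.
#' quarters its squared-distance contribution); SUBTEL and TEL columns are
#' half-weighted by default. Genes with any missing feature are dropped and
#' reported.
#'
#' @param bio_log2 data.table with columns `gene_name` (or `gene`), `screen`,
#'   `readout`, `bio_rep`, `value` (log2 relative growth per biological
#'   replicate).
#' @param weights named per-screen column weights.
#' @return a `FeatureMatrix`: list with `matrix` (genes x 8, weighted),
#'   `unweighted` (same before weighting), `weights` (per column) and
#'   `dropped` (data.table gene/reason).
#' @export
build_feature_matrix <- function(bio_log2,
                                 weights = c(CEN = 1, MAT = 1, SUBTEL = 0.5, TEL = 0.5)) {
  dt <- data.table::as.data.table(bio_log2)
  if (!"gene" %in% names(dt) && "gene_name" %in% names(dt))
    data.table::setnames(dt, "gene_name", "gene")
  assert(all(c("gene", "screen", "readout", "bio_rep", "value") %in% names(dt)),
         "need columns gene, screen, readout, bio_rep, value",
         "hetscreen_format_error")
  assert(all(SCREENS %in% names(weights)) && all(weights > 0),
         "weights must name all screens and be positive", "hetscreen_config_error")
  med <- dt[, .(value = stats::median(value, na.rm = FALSE)),
            by = .(gene, screen, readout)]
  wide <- data.table::dcast(med, gene ~ screen + readout, value.var = "value")
  feat_cols <- as.vector(outer(SCREENS, READOUTS, paste, sep = "_"))
  for (nm in feat_cols) if (!nm %in% names(wide)) wide[, (nm) := NA_real_]
  data.table::setcolorder(wide, c("gene", feat_cols))
  mat <- as.matrix(wide[, feat_cols, with = FALSE])
  rownames(mat) <- wide$gene
  incomplete <- rowSums(is.na(mat)) > 0L
  dropped <- data.table::data.table(gene = rownames(mat)[incomplete],
                                    reason = "missing feature value")
  mat <- mat[!incomplete, , drop = FALSE]
  if (nrow(mat) == 0L)
    stop_hetscreen("all genes dropped: no complete feature rows",
                   "hetscreen_precondition_error")
  col_w <- weights[sub("_.*$", "", feat_cols)]
  names(col_w) <- feat_cols
  weighted <- sweep(mat, 2L, col_w, `*`)
  structure(list(matrix = weighted, unweighted = mat,
                 weights = col_w, dropped = dropped),
            class = "FeatureMatrix")
}

# deterministic sub-seeds below .Machine$integer.max
sub_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

# map labels of `lab` onto reference labels by greedy maximal overlap
align_labels <- function(ref, lab, k) {
  ov <- table(factor(lab, levels = 1:k), factor(ref, levels = 1:k))
  mapping <- integer(k)
  used_from <- logical(k); used_to <- logical(k)
  for (i in seq_len(k)) {
    ov_work <- ov
    ov_work[used_from, ] <- -1L
    ov_work[, used_to] <- -1L
    idx <- which(ov_work == max(ov_work), arr.ind = TRUE)[1L, ]
    mapping[idx[1L]] <- idx[2L]
    used_from[idx[1L]] <- TRUE; used_to[idx[2L]] <- TRUE
  }
  mapping[lab]
}

#' Consensus k-means clustering of phenotypic profiles
#'
#' Runs `stats::kmeans` `n_runs` times from distinct random initialisations,
#' aligns the arbitrary cluster labels of every run to the first run by greedy
#' maximal-overlap matching, and assigns each gene its most frequent aligned
#' label. `support` is the fraction of runs agreeing with the assignment; ties
#' are broken toward the lower cluster id. Deterministic given `seed`. The
#' number of clusters `k` is a user choice (the screen analysis used 7 per
#' direction, chosen on biological grounds); there is no automatic selection.
#'
#' @param fm a [build_feature_matrix()] result, or a plain numeric matrix with
#'   gene rownames.
#' @param k number of clusters (`2 <= k <=` rows, `k = 1` allowed as the
#'   trivial single cluster).
#' @param n_runs number of k-means rounds (>= 10 recommended).
#' @param seed master seed.
#' @param iter_max max iterations per k-means run.
#' @return a `ClusterAssignment` data.table: `gene`, `cluster_id`, `support`.
#' @export
kmeans_consensus <- function(fm, k, n_runs = 20L, seed = 1L, iter_max = 100L) {
  mat <- if (inherits(fm, "FeatureMatrix")) fm$matrix else as.matrix(fm)
  assert(!is.null(rownames(mat)), "feature matrix needs gene rownames")
  assert(k >= 1L, "k must be >= 1", "hetscreen_config_error")
  if (k > nrow(mat))
    stop_hetscreen("k exceeds the number of genes", "hetscreen_config_error")
  if (k == 1L)
    return(data.table::data.table(gene = rownames(mat), cluster_id = 1L,
                                  support = 1))
  with_seed(seed, kmeans_consensus_impl(mat, k, n_runs, seed, iter_max))
}

kmeans_consensus_impl <- function(mat, k, n_runs, seed, iter_max) {
  seeds <- sub_seeds(seed, n_runs)
  labels <- matrix(NA_integer_, nrow = nrow(mat), ncol = n_runs)
  for (r in seq_len(n_runs)) {
    fit <- NULL
    for (attempt in 0:9) {           # empty-cluster runs are re-initialized
      set.seed((seeds[r] + attempt * 7919L) %% 2147483647L)
      fit <- tryCatch(stats::kmeans(mat, centers = k, iter.max = iter_max,
                                    nstart = 5L),
                      error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit) && all(fit$size > 0L)) break
      fit <- NULL
    }
    assert(!is.null(fit), "k-means failed repeatedly (empty clusters?)")
    labels[, r] <- if (r == 1L) fit$cluster
                   else align_labels(labels[, 1L], fit$cluster, k)
  }
  vote <- apply(labels, 1L, function(l) {
    tab <- tabulate(l, nbins = k)
    win <- which.max(tab)            # which.max takes the lowest id on ties
    c(win, tab[win] / length(l))
  })
  data.table::data.table(gene = rownames(mat),
                         cluster_id = as.integer(vote[1L, ]),
                         support = vote[2L, ])
}

#' Apply manual cluster-assignment overrides
#'
#' Rare genes sit between clusters; the original analysis resolved them by
#' the behaviour of related genes (e.g. complex subunits) — a judgement call,
#' not an algorithm. Overrides are a two-column table (`gene`,
#' `cluster_id`); overridden genes get `support = NA` to mark the manual
#' assignment.
#'
#' @param assignment a [kmeans_consensus()] result.
#' @param overrides data.frame with columns `gene`, `cluster_id`.
#' @return updated assignment table.
#' @export
apply_cluster_overrides <- function(assignment, overrides) {
  dt <- data.table::copy(data.table::as.data.table(assignment))
  ov <- data.table::as.data.table(overrides)
  assert(all(c("gene", "cluster_id") %in% names(ov)),
         "overrides need columns gene, cluster_id", "hetscreen_format_error")
  unknown <- setdiff(ov$gene, dt$gene)
  if (length(unknown))
    warning(sprintf("override for unknown gene(s): %s",
                    paste(unknown, collapse = ", ")))
  dt[ov, on = "gene", `:=`(cluster_id = as.integer(i.cluster_id),
                           support = NA_real_)]
  dt[]
}

#' Within-cluster hierarchical leaf order
#'
#' Orders the genes of each k-means cluster by agglomerative hierarchical
#' clustering on Euclidean distance (complete linkage by default,
#' configurable), as used to arrange genes inside each heatmap block.
#'
#' @param fm [build_feature_matrix()] result or numeric matrix with rownames.
#' @param assignment a [kmeans_consensus()] result (or any data.table with
#'   `gene`, `cluster_id`).
#' @param linkage `hclust` agglomeration method.
#' @return named list: cluster id -> ordered character vector of genes.
#' @export
hierarchical_order <- function(fm, assignment,
                               linkage = c("complete", "average", "single", "ward.D2")) {
  linkage <- match.arg(linkage)
  mat <- if (inherits(fm, "FeatureMatrix")) fm$matrix else as.matrix(fm)
  dt <- data.table::as.data.table(assignment)
  assert(all(dt$gene %in% rownames(mat)), "assignment gene missing from matrix")
  out <- list()
  for (cl in sort(unique(dt$cluster_id))) {
    genes <- dt[cluster_id == cl, gene]
    if (length(genes) <= 2L) {
      ord <- genes
    } else {
      hc <- stats::hclust(stats::dist(mat[genes, , drop = FALSE]), method = linkage)
      ord <- genes[hc$order]
    }
    out[[as.character(cl)]] <- ord
  }
  out
}
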