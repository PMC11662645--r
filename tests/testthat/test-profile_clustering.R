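bio_log2_from_matrix <- function(mat) {
  # one bio rep per value: medians equal the matrix entries
  dt <- data.table::as.data.table(as.table(mat))
  data.table::setnames(dt, c("gene", "feat", "value"))
  dt[, c("screen", "readout") := data.table::tstrsplit(feat, "_")]
  dt[, `:=`(bio_rep = 1L, feat = NULL)]
  dt[]
}

test_that("feature matrix: medians, half-weighting, missing-gene exclusion", {
  mk <- function(gene, screen, readout, vals)
    data.table::data.table(gene = gene, screen = screen, readout = readout,
                           bio_rep = seq_along(vals), value = vals)
  full_gene <- function(g, base) data.table::rbindlist(
    lapply(SCREENS, function(s) data.table::rbindlist(
      lapply(READOUTS, function(r) mk(g, s, r, base)))))
  dt <- rbind(full_gene("gA", c(-1, -2, -3)), full_gene("gB", c(0, 1, 5)))
  # gC misses its TEL_FOA cell entirely -> dropped
  dtC <- full_gene("gC", c(1, 1, 1))[!(screen == "TEL" & readout == "FOA")]
  fm <- build_feature_matrix(rbind(dt, dtC))
  expect_equal(rownames(fm$matrix), c("gA", "gB"))
  expect_equal(fm$dropped$gene, "gC")
  # median of {-1,-2,-3} = -2; MAT weight 1, SUBTEL/TEL weight 0.5
  expect_equal(fm$matrix["gA", "MAT_FOA"], -2)
  expect_equal(fm$matrix["gA", "SUBTEL_FOA"], -1)
  expect_equal(fm$unweighted["gA", "SUBTEL_FOA"], -2)
  expect_equal(fm$matrix["gB", "TEL_URA"], 0.5 * 1)
  expect_error(build_feature_matrix(dtC), class = "hetscreen_precondition_error")
})

test_that("weight-by-scaling equals a weighted-distance oracle", {
  set.seed(5)
  for (i in 1:10) {
    m <- matrix(rnorm(6 * 8), nrow = 6,
                dimnames = list(sprintf("g%d", 1:6),
                                as.vector(outer(SCREENS, READOUTS, paste, sep = "_"))))
    w <- c(CEN = 1, MAT = 1, SUBTEL = 0.5, TEL = 0.5)
    colw <- w[sub("_.*", "", colnames(m))]
    d_scaled <- as.matrix(dist(sweep(m, 2, colw, `*`)))
    # oracle: weighted squared distance with weight^2 on squared differences
    d_oracle <- matrix(0, 6, 6)
    for (a in 1:6) for (b in 1:6)
      d_oracle[a, b] <- sqrt(sum(colw^2 * (m[a, ] - m[b, ])^2))
    expect_equal(unname(d_scaled), d_oracle, tolerance = 1e-12)
  }
})

test_that("consensus k-means recovers well-separated clouds with full support", {
  set.seed(8)
  centers <- rbind(rep(0, 8), rep(10, 8))   # 10x the intra-cloud SD of 1
  m <- rbind(centers[rep(1, 15), ] + rnorm(15 * 8),
             centers[rep(2, 15), ] + rnorm(15 * 8))
  rownames(m) <- sprintf("g%02d", 1:30)
  ca <- kmeans_consensus(m, k = 2, n_runs = 12, seed = 3)
  expect_true(all(ca$support == 1))
  # brute-force nearest-centroid check of the partition
  truth <- rep(1:2, each = 15)
  agree <- max(mean(ca$cluster_id == truth), mean(ca$cluster_id == 3 - truth))
  expect_equal(agree, 1)

  # identical rows, k = 1: single cluster with support 1
  m1 <- matrix(1, nrow = 4, ncol = 8,
               dimnames = list(letters[1:4], colnames(m)))
  ca1 <- kmeans_consensus(m1, k = 1, seed = 1)
  expect_equal(unique(ca1$cluster_id), 1L)
  expect_true(all(ca1$support == 1))

  # determinism and config errors
  expect_identical(kmeans_consensus(m, 2, n_runs = 12, seed = 3), ca)
  expect_error(kmeans_consensus(m, 31), class = "hetscreen_config_error")
})

test_that("consensus stability across master seeds on 7 planted clusters", {
  # orthogonal centers at distance 8*sqrt(2) ~ 11x the within-cluster SD of 1,
  # comfortably past the stated >= 5x separation
  set.seed(77)
  k <- 7L; per <- 12L
  centers <- diag(8)[1:k, ] * 8
  m <- centers[rep(1:k, each = per), ] + matrix(rnorm(k * per * 8, sd = 1), ncol = 8)
  rownames(m) <- sprintf("g%03d", seq_len(k * per))
  truth <- rep(1:k, each = per)
  same_truth <- outer(truth, truth, `==`)[upper.tri(diag(k * per))]
  for (master in 1:5) {
    ca <- kmeans_consensus(m, k = k, n_runs = 12, seed = master)
    same_call <- outer(ca$cluster_id, ca$cluster_id, `==`)[upper.tri(diag(k * per))]
    expect_gte(mean(same_call == same_truth), 0.95)
    expect_equal(sum(table(ca$cluster_id)), nrow(m))  # sizes sum to genes
  }
})

test_that("manual overrides reassign genes and mark them", {
  asg <- data.table::data.table(gene = c("a", "b", "c"),
                                cluster_id = c(1L, 1L, 2L),
                                support = c(1, 0.6, 1))
  out <- apply_cluster_overrides(
    asg, data.frame(gene = "b", cluster_id = 2))
  expect_equal(out[gene == "b", cluster_id], 2L)
  expect_true(is.na(out[gene == "b", support]))
  expect_equal(out[gene == "a", cluster_id], 1L)
  expect_warning(apply_cluster_overrides(
    asg, data.frame(gene = "zzz", cluster_id = 1)), "unknown")
})

test_that("hierarchical leaf order: first merge adjacent, outlier at a boundary", {
  m <- matrix(c(0, 1, 10), ncol = 1)
  m <- cbind(m, m, m)   # >= 3 features, still collinear
  rownames(m) <- c("A", "B", "C")
  asg <- data.table::data.table(gene = c("A", "B", "C"), cluster_id = 1L)
  ord <- hierarchical_order(m, asg)[["1"]]
  expect_setequal(ord, c("A", "B", "C"))
  expect_equal(abs(which(ord == "A") - which(ord == "B")), 1L)  # AB merge first
  expect_true(which(ord == "C") %in% c(1L, 3L))                 # C at an end

  # singleton cluster maps to itself; duplicated rows come out adjacent
  asg2 <- data.table::data.table(gene = c("A", "B", "C"),
                                 cluster_id = c(1L, 2L, 2L))
  expect_equal(hierarchical_order(m, asg2)[["1"]], "A")
  m2 <- rbind(m, D = m["A", ] + 100, E = m["A", ])  # E duplicates A
  asg3 <- data.table::data.table(gene = rownames(m2), cluster_id = 1L)
  ord3 <- hierarchical_order(m2, asg3)[["1"]]
  expect_equal(abs(which(ord3 == "A") - which(ord3 == "E")), 1L)
})
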