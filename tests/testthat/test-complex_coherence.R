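test_that("pairwise Pearson correlations match the direct covariance oracle", {
  p1 <- c(1, 2, 3, 4); p2 <- c(2, 4, 5, 9)
  m <- rbind(gA = p1, gB = p2, gC = -p1 + 10)
  cm <- pairwise_profile_correlation(m)
  expect_equal(diag(cm), setNames(rep(1, 3), rownames(m)))
  expect_equal(cm["gA", "gB"], oracle_pearson(p1, p2), tolerance = 1e-12)
  expect_equal(cm["gA", "gB"], 0.9647638212, tolerance = 1e-9)
  expect_equal(cm["gA", "gC"], -1)            # negation after centering
  expect_equal(cm["gA", "gA"], 1)             # identical profiles
  expect_true(isSymmetric(cm))

  # zero-variance profile excluded with a warning
  m2 <- rbind(m, gD = rep(2, 4))
  expect_warning(cm2 <- pairwise_profile_correlation(m2), "zero-variance")
  expect_false("gD" %in% rownames(cm2))
  expect_error(suppressWarnings(
    pairwise_profile_correlation(rbind(a = rep(1, 4), b = rep(2, 4)))),
    class = "hetscreen_precondition_error")
})

test_that("within/between summary counts pairs and fractions correctly", {
  set.seed(2)
  m <- matrix(rnorm(16), nrow = 4, dimnames = list(paste0("g", 1:4), NULL))
  cm <- pairwise_profile_correlation(m)
  cx <- data.table::data.table(complex_id = c("c1", "c1", "c2", "c2"),
                               gene = paste0("g", 1:4))
  s <- within_between_summary(cm, cx, r_threshold = 0.9)
  expect_equal(s$within_pairs, 2L)             # C(4,2)=6 total
  expect_equal(s$between_pairs, 4L)
  expect_equal(s$within_pairs + s$between_pairs, choose(4, 2))
  # boundary threshold -1: everything counts
  s2 <- within_between_summary(cm, cx, r_threshold = -1)
  expect_equal(s2$frac_within_ge_r, 1)
  expect_equal(s2$frac_between_ge_r, 1)
  # all-correlation-1 matrix
  ones <- matrix(1, 4, 4, dimnames = dimnames(cm))
  s3 <- within_between_summary(ones, cx)
  expect_equal(s3$frac_within_ge_r, 1)
  expect_equal(s3$frac_between_ge_r, 1)
  # overlapping membership rejected; singleton-only complexes rejected
  bad <- rbind(cx, data.table::data.table(complex_id = "c3", gene = "g1"))
  expect_error(within_between_summary(cm, bad),
               class = "hetscreen_integrity_error")
  solo <- data.table::data.table(complex_id = c("c1", "c2"), gene = c("g1", "g2"))
  expect_error(within_between_summary(cm, solo),
               class = "hetscreen_precondition_error")
})

test_that("permutation test: exhaustive enumeration on 4-gene instances", {
  set.seed(4)
  m <- matrix(rnorm(16), nrow = 4, dimnames = list(paste0("g", 1:4), NULL))
  cm <- pairwise_profile_correlation(m)
  cx <- data.table::data.table(complex_id = c("c1", "c1", "c2", "c2"),
                               gene = paste0("g", 1:4))
  res <- permutation_test(cm, cx, n_perm = 1000, seed = 1)
  expect_equal(res$method, "exhaustive")

  # independent oracle: enumerate the 3 distinct partitions directly
  stat_for <- function(pairing) {
    within <- sapply(pairing, function(p) cm[p[1], p[2]])
    all_pairs <- combn(paste0("g", 1:4), 2)
    allr <- apply(all_pairs, 2, function(p) cm[p[1], p[2]])
    wsum <- sum(within)
    mean(within) - (sum(allr) - wsum) / (length(allr) - 2)
  }
  partitions <- list(list(c("g1", "g2"), c("g3", "g4")),
                     list(c("g1", "g3"), c("g2", "g4")),
                     list(c("g1", "g4"), c("g2", "g3")))
  stats_v <- sapply(partitions, stat_for)
  obs <- stats_v[1]
  p_oracle <- mean(stats_v >= obs - 1e-12)
  expect_equal(res$observed_stat, obs, tolerance = 1e-12)
  expect_equal(res$perm_p, p_oracle, tolerance = 1e-12)

  # Monte-Carlo path (forced by tiny n_perm) agrees within MC error
  res_mc <- permutation_test(cm, cx, n_perm = 2, seed = 5)
  expect_equal(res_mc$method, "monte_carlo")
  expect_gte(res_mc$perm_p, 1 / 3)   # add-one floor with n_perm = 2
})

test_that("permutation p: determinism, add-one floor, invariances", {
  gen <- generate_complex_profiles(n_complexes = 4, sizes = c(3, 4),
                                   within_rho = 0.9, seed = 21)
  cm <- pairwise_profile_correlation(gen$profiles)
  r1 <- permutation_test(cm, gen$complexes, n_perm = 500, seed = 9)
  r2 <- permutation_test(cm, gen$complexes, n_perm = 500, seed = 9)
  expect_identical(r1, r2)
  expect_gte(r1$perm_p, 1 / 501)

  # invariant to complex relabeling and gene reordering
  relab <- data.table::copy(gen$complexes)
  relab[, complex_id := paste0("X_", complex_id)]
  r3 <- permutation_test(cm, relab, n_perm = 500, seed = 9)
  expect_equal(r3$perm_p, r1$perm_p)
  perm <- sample(nrow(cm))
  cm_shuf <- cm[perm, perm]
  r4 <- permutation_test(cm_shuf, gen$complexes, n_perm = 500, seed = 9)
  expect_equal(r4$observed_stat, r1$observed_stat, tolerance = 1e-12)

  # perfectly coherent complexes: p at the add-one estimator floor.
  # 4 complexes x 4 members sharing exact profiles up to positive scaling
  # (within r = 1); the observed statistic is then the unique global maximum
  # over partitions, so no sampled permutation reaches it.
  set.seed(6)
  bases <- matrix(rnorm(16), nrow = 4)
  prof <- do.call(rbind, lapply(1:4, function(i)
    t(sapply(1:4, function(j) bases[i, ] * j))))
  rownames(prof) <- sprintf("p%02d", 1:16)
  cmp <- pairwise_profile_correlation(prof)
  cxp <- data.table::data.table(complex_id = rep(paste0("K", 1:4), each = 4),
                                gene = rownames(prof))
  rp <- permutation_test(cmp, cxp, n_perm = 2000, seed = 2)
  expect_equal(rp$method, "monte_carlo")
  expect_equal(rp$perm_p, 1 / 2001, tolerance = 1e-12)
})

test_that("null calibration: p roughly uniform for random labels", {
  # scaled-down version of the 200-dataset calibration (kept in acceptance)
  set.seed(31)
  pvals <- replicate(60, {
    gen <- generate_complex_profiles(n_complexes = 3, sizes = c(3, 3, 4),
                                     within_rho = 0, seed = sample.int(1e6, 1))
    cm <- pairwise_profile_correlation(gen$profiles)
    permutation_test(cm, gen$complexes, n_perm = 200, seed = 1)$perm_p
  })
  frac <- mean(pvals < 0.05)
  expect_gte(frac, 0.0); expect_lte(frac, 0.12)
})
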