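test_that("gene statistics match the independent t-CDF oracle (n = 2..8)", {
  set.seed(7)
  cases <- list(c(2, 3, 4))  # frozen spec case first: t = 5.196, p ~ 0.0351
  for (n in 2:8) cases[[length(cases) + 1L]] <- rnorm(n, mean = runif(1, -2, 2))
  tab <- toy_combined(setNames(cases, sprintf("gene%02d", seq_along(cases))))
  st <- gene_statistics(tab)
  for (i in seq_along(cases)) {
    g <- sprintf("gene%02d", i)
    expect_equal(st[gene == g, p_value], oracle_t_pvalue(cases[[i]]),
                 tolerance = 1e-10, label = g)
  }
  frozen <- st[gene == "gene01"]
  expect_equal(frozen$t_stat, 5.196152, tolerance = 1e-6)
  expect_equal(frozen$p_value, 0.03509871864598, tolerance = 1e-9)
  # closed form for df = 2: p = 1 - t/sqrt(t^2 + 2)
  expect_equal(frozen$p_value, 1 - frozen$t_stat / sqrt(frozen$t_stat^2 + 2),
               tolerance = 1e-12)
})

test_that("gene statistics degenerate cases", {
  st <- gene_statistics(toy_combined(list(
    z = c(0, 0, 0, 0), c_pos = c(3, 3, 3), single = 5)))
  expect_equal(st[gene == "z", p_value], 1)
  expect_false(st[gene == "z", degenerate])
  expect_equal(st[gene == "c_pos", p_value], 0)
  expect_true(st[gene == "c_pos", degenerate])
  expect_false(st[gene == "single", testable])
  expect_true(is.na(st[gene == "single", p_value]))
})

test_that("hit calling applies the per-screen asymmetric thresholds", {
  mk <- function(screen, median, p)
    data.table::data.table(gene = paste0(screen, median), screen = screen,
                           n_bio = 6L, mean = median, median = median,
                           t_stat = 5, p_value = p, degenerate = FALSE,
                           testable = TRUE, p_bh = p)
  st <- rbind(mk("MAT", 2.6, 0.01),   # silencing (> 2.5)
              mk("CEN", 2.6, 0.01),   # none: CEN needs > 3
              mk("CEN", 3.2, 0.01),   # silencing
              mk("TEL", -2.2, 0.03),  # anti-silencing (< -2)
              mk("TEL", -2.2, 0.2),   # none: p too high
              mk("SUBTEL", 2.4, 0.001)) # none: below effect threshold
  h <- call_hits(st)
  expect_equal(h$direction,
               c("silencing", "none", "silencing", "anti_silencing",
                 "none", "none"))
  # screens missing from the config are a configuration error
  cfg <- threshold_config(silencing_min = c(CEN = 3, MAT = 2.5, SUBTEL = 2.5,
                                            TEL = 2.5))
  bad <- data.table::copy(st)[1, screen := "MAT2"]
  expect_error(call_hits(bad, cfg), class = "hetscreen_config_error")
  expect_error(threshold_config(silencing_min = c(CEN = 3)),
               class = "hetscreen_config_error")
})

test_that("overlap summary counts domains per gene", {
  mk <- function(gene, screen, dir)
    data.table::data.table(gene = gene, screen = screen, direction = dir)
  h <- rbind(
    data.table::rbindlist(lapply(SCREENS, function(s) mk("A", s, "silencing"))),
    mk("B", "MAT", "silencing"),
    mk("B", "TEL", "none"),
    mk("C", "TEL", "anti_silencing"))
  ov <- overlap_summary(h, "silencing")
  expect_equal(unname(ov$histogram), c(1L, 0L, 0L, 1L))
  expect_equal(unname(ov$single_domain), c(0L, 1L, 0L, 0L))  # B at MAT only
  expect_equal(ov$n_genes, 2L)
  expect_equal(sum(ov$histogram), ov$n_genes)
  # no hits -> all-zero histogram
  ov0 <- overlap_summary(h[direction == "none"], "silencing")
  expect_equal(sum(ov0$histogram), 0L)
})

test_that("recall and precision follow the counting rules", {
  h <- data.table::data.table(
    gene = c("a", "b", "c", "x", "d"), screen = "CEN",
    direction = c("silencing", "silencing", "silencing", "silencing", "none"))
  expect_equal(compute_recall(h, gold = c("a", "b", "c", "d"), screen = "CEN"),
               0.75)
  expect_equal(compute_recall(h, gold = c("d"), screen = "CEN"), 0)
  expect_equal(compute_recall(h, gold = c("a", "b"), screen = "CEN"), 1)
  # gold genes never tested are excluded from the denominator
  expect_equal(compute_recall(h, gold = c("a", "zzz"), screen = "CEN"), 1)
  expect_error(compute_recall(h, gold = "zzz", screen = "CEN"),
               class = "hetscreen_precondition_error")

  val <- data.table::data.table(gene = c("a", "b", "c"),
                                fold_change = c(2.0, 1.2, 1.6))
  expect_equal(compute_precision(c("a", "b", "c"), val), 2 / 3)
  # strict inequality at exactly 1.5
  val15 <- data.table::data.table(gene = "a", fold_change = 1.5)
  expect_equal(compute_precision("a", val15), 0)
  expect_equal(compute_precision(c("a", "b"), val[1:2][, fold_change := c(2, 3)]), 1)
  expect_error(compute_precision("nope", val),
               class = "hetscreen_precondition_error")
})

test_that("group normalization puts the batch mean at 1", {
  expect_equal(group_normalize_expression(c(2, 4)), c(2 / 3, 4 / 3))
  expect_equal(group_normalize_expression(5), 1)
  set.seed(3)
  x <- rlnorm(40)
  expect_equal(mean(group_normalize_expression(x)), 1, tolerance = 1e-12)
  expect_error(group_normalize_expression(c(1, 0)),
               class = "hetscreen_domain_error")
})

test_that("Fisher enrichment matches exhaustive hypergeometric enumeration", {
  # frozen spec case: [[4,1],[1,4]] in a universe of 10
  u <- letters[1:10]
  res <- fisher_enrichment(cluster_genes = u[c(1:4, 6)],
                           pathway_genes = u[1:5], universe = u)
  expect_equal(res$table["in", "in"], 4)
  expect_equal(res$p_value, 52 / 252, tolerance = 1e-10)
  expect_equal(res$p_value, oracle_fisher_p(4, 1, 1, 4), tolerance = 1e-10)

  # perfect overlap: each tail is the hypergeometric point mass 1/C(20,10),
  # and the opposite extreme (a = 0) is exactly as improbable, so the
  # two-sided p doubles it — confirmed by the enumeration oracle
  u20 <- sprintf("g%02d", 1:20)
  res2 <- fisher_enrichment(u20[1:10], u20[1:10], u20)
  expect_equal(res2$p_value, 2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(res2$p_value, oracle_fisher_p(10, 0, 0, 10), tolerance = 1e-10)

  # random tables with margins <= 12 against the enumeration oracle
  set.seed(12)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    u_i <- sprintf("u%02d", 1:n)
    cl <- sample(u_i, sample(1:(n - 1), 1))
    pw <- sample(u_i, sample(1:(n - 1), 1))
    res_i <- fisher_enrichment(cl, pw, u_i)
    a <- length(intersect(cl, pw))
    expect_equal(res_i$p_value,
                 oracle_fisher_p(a, length(setdiff(pw, cl)),
                                 length(setdiff(cl, pw)),
                                 n - length(union(cl, pw))),
                 tolerance = 1e-9)
  }
  expect_error(fisher_enrichment("a", "a", character(0)),
               class = "hetscreen_precondition_error")
})

test_that("type-I error and planted-effect recovery on a synthetic screen", {
  # 2000 genes, 6 bio reps, noise_sd 0.5, planted |effect| 4 (seed-pinned)
  cfg <- sim_config(n_genes = 2000L, screens = "TEL", n_bio = c(TEL = 6L),
                    noise_sd = 0.5, effect_size = 4, seed = 2024L)
  sim <- generate_screen(cfg)
  sc <- score_screens(sim$plateset)
  st <- gene_statistics(sc$combined)
  merged <- merge(st, sim$truth, by = "gene")

  null_rate <- merged[class_label == "null", mean(p_value < 0.05)]
  expect_gte(null_rate, 0.03); expect_lte(null_rate, 0.07)

  h <- call_hits(st)
  hm <- merge(h, sim$truth, by = "gene")
  called_sil <- hm[direction == "silencing", gene]
  truth_sil <- hm[class_label == "silencing", gene]
  recall <- length(intersect(called_sil, truth_sil)) / length(truth_sil)
  fdp <- if (length(called_sil))
    mean(!called_sil %in% truth_sil) else 0
  expect_gte(recall, 0.95)
  expect_lte(fdp, 0.02)
  # essentially no null gene passes the joint p + effect rule
  expect_lte(hm[class_label == "null",
                mean(direction != "none", na.rm = TRUE)], 0.005)
})
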