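# fixtures built in code; no binary data anywhere

# minimal long colony table: one screen, all three media, n strains on one plate
toy_colony_dt <- function(n = 6L, screen = "MAT", bio_rep = 1L, tech_rep = 1L,
                          sizes_ns = rep(400, n), sizes_ura = rep(200, n),
                          sizes_foa = rep(300, n)) {
  strains <- sprintf("s%02d", seq_len(n))
  genes <- sprintf("g%02d", seq_len(n))
  mk <- function(medium, size)
    data.table::data.table(screen = screen, medium = medium, plate_id = "P01",
                           row = 1L, col = seq_len(n), strain_id = strains,
                           gene_name = genes, bio_rep = bio_rep,
                           tech_rep = tech_rep, size = size)
  data.table::rbindlist(list(mk("NS", sizes_ns), mk("URA", sizes_ura),
                             mk("FOA", sizes_foa)))
}

# independent t-test oracle: two-sided p by numerical integration of the
# t density (never touches stats::pt)
t_density <- function(x, df)
  gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + x^2 / df)^(-(df + 1) / 2)

oracle_t_pvalue <- function(values) {
  n <- length(values)
  tv <- mean(values) / (sd(values) / sqrt(n))
  2 * stats::integrate(t_density, abs(tv), Inf, df = n - 1,
                       rel.tol = 1e-13)$value
}

# independent Fisher oracle: exhaustive hypergeometric enumeration via choose()
oracle_fisher_p <- function(a, b, c_, d) {
  rs1 <- a + b; rs2 <- c_ + d; cs1 <- a + c_
  n <- rs1 + rs2
  amin <- max(0L, cs1 - rs2); amax <- min(rs1, cs1)
  probs <- vapply(amin:amax, function(x)
    choose(rs1, x) * choose(rs2, cs1 - x) / choose(n, cs1), numeric(1))
  p_obs <- choose(rs1, a) * choose(rs2, cs1 - a) / choose(n, cs1)
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# independent Pearson oracle: direct covariance formula
oracle_pearson <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# tiny combined-score table for hit-calling tests
toy_combined <- function(values_by_gene, screen = "MAT") {
  data.table::rbindlist(lapply(names(values_by_gene), function(g) {
    v <- values_by_gene[[g]]
    data.table::data.table(gene = g, screen = screen,
                           bio_rep = seq_along(v), value = v)
  }))
}
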