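#' Simulation configuration for a synthetic silencing screen
#'
#' Defaults mirror the real screen design: 384-position plates, two technical
#' replicates per biological replicate (duplication at germination), and
#' per-screen biological replicate numbers CEN 8, MAT 7, SUBTEL 3, TEL 6.
#' Gene classes plant per-gene effects on the combined-score scale
#' (pre-standardization): `silencing`-class genes get `+effect_size` (their
#' deletion de-represses the reporter), `anti_silencing`-class genes
#' `-effect_size`, `null` genes 0. The effect is split between readouts:
#' `+alpha * effect` on the log2 -URA growth, `-beta * effect` on +FOA.
#' Colony noise is lognormal (`noise_sd`, log2 units, per observation);
#' plates carry a shared multiplicative effect (`plate_effect_sd`, log2
#' units) applied to the selective plates, which is exactly what plate-median
#' normalization must remove.
#'
#' @param n_genes number of genes (arrayed 384 per plate).
#' @param prop_silencing,prop_anti fractions of silencing / anti-silencing
#'   genes (rest are null).
#' @param effect_size planted combined-score displacement magnitude.
#' @param screens screens to simulate.
#' @param n_bio named per-screen biological replicate counts.
#' @param n_tech technical replicates per biological replicate.
#' @param noise_sd per-colony lognormal noise SD (log2 units).
#' @param plate_effect_sd plate-effect SD (log2 units).
#' @param alpha,beta fraction of the effect expressed on URA / FOA.
#' @param baseline_meanlog,baseline_sdlog non-selective colony-size
#'   distribution (natural-log lognormal).
#' @param seed RNG seed.
#' @return a validated `SimConfig` list.
#' @export
sim_config <- function(n_genes = 2000L,
                       prop_silencing = 0.05, prop_anti = 0.05,
                       effect_size = 4,
                       screens = SCREENS,
                       n_bio = c(CEN = 8L, MAT = 7L, SUBTEL = 3L, TEL = 6L),
                       n_tech = 2L,
                       noise_sd = 0.5,
                       plate_effect_sd = 0.25,
                       alpha = 0.5, beta = 0.5,
                       baseline_meanlog = log(400), baseline_sdlog = 0.1,
                       seed = 1L) {
  assert(prop_silencing >= 0 && prop_anti >= 0 &&
           prop_silencing + prop_anti <= 1,
         "class proportions must be in [0,1] and sum to <= 1",
         "hetscreen_config_error")
  assert(noise_sd >= 0 && plate_effect_sd >= 0 && baseline_sdlog >= 0,
         "SDs must be >= 0", "hetscreen_config_error")
  assert(all(screens %in% SCREENS), "unknown screen", "hetscreen_config_error")
  assert(all(screens %in% names(n_bio)), "n_bio must name every screen",
         "hetscreen_config_error")
  assert(n_tech >= 1L && n_genes >= 1L, "counts must be positive",
         "hetscreen_config_error")
  structure(list(n_genes = as.integer(n_genes),
                 prop_silencing = prop_silencing, prop_anti = prop_anti,
                 effect_size = effect_size, screens = screens,
                 n_bio = n_bio, n_tech = as.integer(n_tech),
                 noise_sd = noise_sd, plate_effect_sd = plate_effect_sd,
                 alpha = alpha, beta = beta,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Generate a synthetic multi-domain silencing screen
#'
#' Generative model (the inverse of the scoring pipeline): per position the
#' non-selective (NS) size is lognormal; the selective size is
#' `NS * plate_effect * 2^(signal + eps)` with `signal = +alpha*effect` on
#' URA and `-beta*effect` on FOA, `eps ~ N(0, noise_sd)` per colony and
#' `plate_effect = 2^N(0, plate_effect_sd)` shared by all colonies of one
#' selective plate. Deterministic given `cfg$seed`. The returned truth table
#' is for evaluation only and is never consumed by analysis code.
#'
#' @param cfg a [sim_config()].
#' @return list with `plateset` (a `PlateSet`) and `truth` (data.table:
#'   `gene`, `strain_id`, `class_label`, `effect`).
#' @export
generate_screen <- function(cfg) {
  assert(inherits(cfg, "SimConfig"), "cfg must be a SimConfig",
         "hetscreen_config_error")
  with_seed(cfg$seed, generate_screen_impl(cfg))
}

generate_screen_impl <- function(cfg) {
  n <- cfg$n_genes
  n_sil <- round(cfg$prop_silencing * n)
  n_anti <- round(cfg$prop_anti * n)
  class_label <- rep("null", n)
  if (n_sil + n_anti > 0) {
    idx <- sample.int(n, n_sil + n_anti)
    class_label[idx[seq_len(n_sil)]] <- "silencing"
    if (n_anti > 0) class_label[idx[n_sil + seq_len(n_anti)]] <- "anti_silencing"
  }
  gene <- sprintf("gene%04d", seq_len(n))
  strain_id <- sprintf("strain%04d", seq_len(n))
  effect <- ifelse(class_label == "silencing", cfg$effect_size,
                   ifelse(class_label == "anti_silencing", -cfg$effect_size, 0))
  truth <- data.table::data.table(gene = gene, strain_id = strain_id,
                                  class_label = class_label, effect = effect)

  # fixed 384-array layout shared by all media/replicates of a screen
  pos <- seq_len(n) - 1L
  layout <- data.table::data.table(
    strain_id = strain_id, gene_name = gene,
    plate_id = sprintf("P%02d", pos %/% 384L + 1L),
    row = as.integer((pos %% 384L) %/% 24L + 1L),
    col = as.integer(pos %% 24L + 1L))

  obs_list <- list()
  for (scr in cfg$screens) {
    for (b in seq_len(cfg$n_bio[[scr]])) {
      for (tr in seq_len(cfg$n_tech)) {
        ns_size <- stats::rlnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog)
        base <- data.table::copy(layout)
        base[, `:=`(screen = scr, bio_rep = b, tech_rep = tr)]
        ns <- data.table::copy(base)[, `:=`(medium = "NS", size = ns_size)]
        sel_list <- list(ns)
        for (ro in READOUTS) {
          signal <- if (ro == "URA") cfg$alpha * effect else -cfg$beta * effect
          plates <- unique(layout$plate_id)
          pe <- setNames(2^stats::rnorm(length(plates), 0, cfg$plate_effect_sd),
                         plates)
          eps <- stats::rnorm(n, 0, cfg$noise_sd)
          sel <- data.table::copy(base)
          sel[, `:=`(medium = ro,
                     size = ns_size * pe[layout$plate_id] * 2^(signal + eps))]
          sel_list[[length(sel_list) + 1L]] <- sel
        }
        obs_list[[length(obs_list) + 1L]] <- data.table::rbindlist(sel_list)
      }
    }
  }
  obs <- data.table::rbindlist(obs_list)
  data.table::setcolorder(obs, c("screen", "medium", "plate_id", "row", "col",
                                 "strain_id", "gene_name", "bio_rep",
                                 "tech_rep", "size"))
  list(plateset = as_plateset(obs), truth = truth)
}

#' Generate synthetic complex-coherence profiles
#'
#' Members of a complex share a latent standard-normal 4-vector; each member
#' observes `sqrt(within_rho) * latent + sqrt(1 - within_rho) * noise`, so
#' the expected within-pair Pearson correlation (over the 4 screen
#' coordinates) is approximately `within_rho`. Background genes are
#' independent noise.
#'
#' @param n_complexes number of complexes.
#' @param sizes member counts (recycled to `n_complexes`).
#' @param within_rho target within-complex profile correlation in `[-1, 1]`.
#' @param n_background unannotated background genes.
#' @param seed RNG seed.
#' @param n_features profile length (4 = per-screen combined scores).
#' @return list with `profiles` (matrix, genes x features), `complexes`
#'   (data.table `complex_id`, `gene`) and `truth` (same as complexes plus
#'   background rows with `complex_id = NA`).
#' @export
generate_complex_profiles <- function(n_complexes = 12L,
                                      sizes = c(4L, 5L, 6L, 7L, 8L),
                                      within_rho = 0.9,
                                      n_background = 0L, seed = 1L,
                                      n_features = 4L) {
  assert(abs(within_rho) <= 1, "within_rho must be in [-1, 1]",
         "hetscreen_config_error")
  sizes <- rep_len(as.integer(sizes), n_complexes)
  assert(any(sizes >= 2L), "at least one complex needs >= 2 members",
         "hetscreen_config_error")
  with_seed(seed, generate_complex_profiles_impl(n_complexes, sizes,
                                                 within_rho, n_background,
                                                 n_features))
}

generate_complex_profiles_impl <- function(n_complexes, sizes, within_rho,
                                           n_background, n_features) {
  rows <- list(); cx <- list()
  g <- 0L
  for (i in seq_len(n_complexes)) {
    latent <- stats::rnorm(n_features)
    for (j in seq_len(sizes[i])) {
      g <- g + 1L
      gene <- sprintf("cg%03d", g)
      rows[[gene]] <- sqrt(abs(within_rho)) * sign(within_rho) * latent +
        sqrt(1 - abs(within_rho)) * stats::rnorm(n_features)
      cx[[gene]] <- sprintf("complex%02d", i)
    }
  }
  for (j in seq_len(n_background)) {
    g <- g + 1L
    rows[[sprintf("bg%03d", j)]] <- stats::rnorm(n_features)
  }
  profiles <- do.call(rbind, rows)
  colnames(profiles) <- if (n_features == 4L) SCREENS
                        else paste0("f", seq_len(n_features))
  complexes <- data.table::data.table(complex_id = unlist(cx),
                                      gene = names(cx))
  truth <- data.table::data.table(
    gene = rownames(profiles),
    complex_id = c(unlist(cx), rep(NA_character_, n_background)))
  list(profiles = profiles, complexes = complexes, truth = truth)
}

#' Generate a synthetic single-cell reporter population
#'
#' Bimodal reporter model: each cell is OFF (fully repressed, residual
#' red-normalized level `off_mean`) or ON (de-repressed, level `on_mean`)
#' with probability `on_fraction`. Per-cell red is lognormal
#' (`red_meanlog`, `red_sdlog`); orange and green are
#' `red * level * lognormal(cv)`, so red-normalization recovers the level up
#' to the intrinsic noise `cv` (extrinsic noise cancels by construction —
#' the point of the red channel).
#'
#' @param n_cells cells to simulate.
#' @param off_mean,on_mean red-normalized component levels.
#' @param on_fraction probability a cell is ON.
#' @param cv coefficient of variation of the intrinsic lognormal noise.
#' @param red_meanlog,red_sdlog red-channel lognormal parameters.
#' @param sample_id sample label.
#' @param seed RNG seed.
#' @return list with `cells` (data.table: `cell_id`, `sample_id`, `green`,
#'   `orange`, `red`) and `truth` (data.table with per-cell `component`).
#' @export
generate_cell_population <- function(n_cells = 10000L,
                                     off_mean = 0.08, on_mean = 1.0,
                                     on_fraction = 0.3, cv = 0.12,
                                     red_meanlog = log(1000), red_sdlog = 0.3,
                                     sample_id = "sample", seed = 1L) {
  assert(on_fraction >= 0 && on_fraction <= 1, "on_fraction must be in [0,1]",
         "hetscreen_config_error")
  assert(off_mean > 0 && on_mean > 0 && cv >= 0, "means must be > 0, cv >= 0",
         "hetscreen_config_error")
  with_seed(seed, generate_cell_population_impl(
    n_cells, off_mean, on_mean, on_fraction, cv, red_meanlog, red_sdlog,
    sample_id))
}

generate_cell_population_impl <- function(n_cells, off_mean, on_mean,
                                          on_fraction, cv, red_meanlog,
                                          red_sdlog, sample_id) {
  comp <- ifelse(stats::runif(n_cells) < on_fraction, "on", "off")
  level <- ifelse(comp == "on", on_mean, off_mean)
  red <- stats::rlnorm(n_cells, red_meanlog, red_sdlog)
  sdlog <- sqrt(log(1 + cv^2))
  lnoise <- function() stats::rlnorm(n_cells, -sdlog^2 / 2, sdlog)
  orange <- red * level * lnoise()
  green <- red * level * lnoise()
  cells <- data.table::data.table(cell_id = sprintf("c%06d", seq_len(n_cells)),
                                  sample_id = sample_id,
                                  green = green, orange = orange, red = red)
  truth <- data.table::data.table(cell_id = cells$cell_id, component = comp)
  list(cells = cells, truth = truth)
}

#' Generate the red-only and no-heterochromatin flow controls
#'
#' The red-only control expresses E2C alone; its apparent green/orange are
#' background at `background_mean` of red. The no-heterochromatin control is
#' all-ON at `on_mean` with a `loss_fraction` of reporter-loss
#' (color-negative) cells at background level, emulating recombination loss.
#'
#' @param n_cells cells per control.
#' @param background_mean red-normalized background level.
#' @param on_mean ON level of the no-heterochromatin control.
#' @param loss_fraction reporter-loss fraction in the no-het control.
#' @param cv,red_meanlog,red_sdlog as in [generate_cell_population()].
#' @param seed RNG seed.
#' @return list with `red_only` and `no_het` cell tables.
#' @export
generate_flow_controls <- function(n_cells = 5000L, background_mean = 0.005,
                                   on_mean = 1.0, loss_fraction = 0.05,
                                   cv = 0.12, red_meanlog = log(1000),
                                   red_sdlog = 0.3, seed = 1L) {
  ro <- generate_cell_population(n_cells, off_mean = background_mean,
                                 on_mean = background_mean, on_fraction = 0,
                                 cv = cv, red_meanlog = red_meanlog,
                                 red_sdlog = red_sdlog,
                                 sample_id = "red_only", seed = seed)
  nh <- generate_cell_population(n_cells, off_mean = background_mean,
                                 on_mean = on_mean,
                                 on_fraction = 1 - loss_fraction,
                                 cv = cv, red_meanlog = red_meanlog,
                                 red_sdlog = red_sdlog,
                                 sample_id = "no_het", seed = seed + 1L)
  list(red_only = ro$cells, no_het = nh$cells)
}
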