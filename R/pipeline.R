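#' Read a flat key=value pipeline configuration file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Values are parsed as numbers when numeric, comma-separated lists become
#' vectors, `true`/`false` become logicals.
#'
#' @param path config file path.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  assert(file.exists(path), sprintf("config not found: %s", path),
         "hetscreen_io_error")
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    assert(length(kv) >= 2L, sprintf("bad config line: %s", ln),
           "hetscreen_config_error")
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    parsed <- if (!anyNA(num)) num
              else if (all(tolower(parts) %in% c("true", "false")))
                tolower(parts) == "true"
              else parts
    out[[key]] <- parsed
  }
  out
}

hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2L)        # content hash via a canonical serialization
  unname(tools::md5sum(f))
}

#' Run the screen-analysis pipeline end to end
#'
#' Stages run in dependency order: simulate (or load) -> score -> call-hits ->
#' cluster + coherence; flow is independent. Every numeric output is written
#' as TSV via [write_scores()]; a machine-readable `manifest.json` records the
#' package version, seed, config hash and per-output md5, and `summary.txt`
#' gives the human-readable counts. Identical config + seed give byte-identical
#' outputs.
#'
#' @param config named list. Recognized keys: `stages` (subset of
#'   `c("simulate","score","call_hits","cluster","coherence","flow")`),
#'   `input_colony_table` (path; replaces simulate), `input_score_table`
#'   (path to a per-replicate combined-score table; replaces simulate+score),
#'   `corrections` (path), `gold_list` (path), `complex_map` (path),
#'   `n_genes`, `effect_size`, `noise_sd`, `k`, `n_runs`, `linkage`,
#'   `n_perm`, `coherence_mode`, plus threshold overrides `p_max`.
#' @param outdir output directory (created).
#' @param seed integer seed for every stochastic stage.
#' @return (invisibly) list of in-memory stage results; side effect: files in
#'   `outdir`.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("hetscreen_run_"),
                         seed = 1L) {
  stages <- config$stages %||% c("simulate", "score", "call_hits",
                                 "cluster", "coherence")
  known <- c("simulate", "score", "call_hits", "cluster", "coherence", "flow")
  assert(all(stages %in% known),
         sprintf("unknown stage(s): %s", paste(setdiff(stages, known), collapse = ", ")),
         "hetscreen_config_error")
  for (key in c("input_colony_table", "input_score_table", "corrections",
                "gold_list", "complex_map")) {
    if (!is.null(config[[key]]))
      assert(file.exists(config[[key]]),
             sprintf("config path %s does not exist: %s", key, config[[key]]),
             "hetscreen_config_error")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  results <- list()
  emit <- function(tab, name) {
    p <- file.path(outdir, name)
    write_scores(tab, p)
    outputs <<- c(outputs, p)
    p
  }

  status <- "ok"
  tryCatch({
    combined <- NULL; bio_log2 <- NULL; truth <- NULL

    if (!is.null(config$input_score_table)) {
      combined <- read_score_table(config$input_score_table)
    } else {
      if ("simulate" %in% stages && is.null(config$input_colony_table)) {
        cfg <- sim_config(
          n_genes = config$n_genes %||% 2000L,
          prop_silencing = config$prop_silencing %||% 0.05,
          prop_anti = config$prop_anti %||% 0.05,
          effect_size = config$effect_size %||% 4,
          noise_sd = config$noise_sd %||% 0.5,
          plate_effect_sd = config$plate_effect_sd %||% 0.25,
          seed = seed)
        sim <- generate_screen(cfg)
        plateset <- sim$plateset
        truth <- sim$truth
        emit(sim$truth, "truth_screen.tsv")
        results$sim_config <- cfg
      } else {
        assert(!is.null(config$input_colony_table),
               "need input_colony_table when simulate is disabled",
               "hetscreen_config_error")
        plateset <- read_colony_table(config$input_colony_table)
      }
      if (!is.null(config$corrections))
        plateset <- apply_strain_corrections(
          plateset, read_strain_corrections(config$corrections))
      results$plateset <- plateset

      if (any(c("score", "call_hits", "cluster", "coherence") %in% stages)) {
        scored <- score_screens(plateset)
        combined <- scored$combined
        bio_log2 <- scored$bio_log2
        emit(scored$combined, "combined_scores.tsv")
        emit(scored$scaled, "scaled_scores.tsv")
        emit(scored$bio_log2, "bio_log2.tsv")
        results$scored <- scored
      }
    }

    if ("call_hits" %in% stages && !is.null(combined)) {
      cfg_thr <- threshold_config(p_max = config$p_max %||% 0.05)
      stats_dt <- gene_statistics(combined)
      hits <- call_hits(stats_dt, cfg_thr)
      emit(hits, "hit_calls.tsv")
      results$hits <- hits
      for (dirn in c("silencing", "anti_silencing")) {
        ov <- overlap_summary(hits, dirn)
        emit(data.table::data.table(direction = dirn,
                                    n_domains = names(ov$histogram),
                                    n_genes = as.integer(ov$histogram)),
             sprintf("overlap_%s.tsv", dirn))
        results$overlap[[dirn]] <- ov
      }
      if (!is.null(config$gold_list)) {
        gold <- read_gene_list(config$gold_list)
        rec <- data.table::data.table(
          screen = SCREENS,
          recall = vapply(SCREENS, function(s)
            tryCatch(compute_recall(hits, gold, s), error = function(e) NA_real_),
            numeric(1)))
        emit(rec, "recall.tsv")
        results$recall <- rec
      }
    }

    if ("cluster" %in% stages && !is.null(bio_log2) && !is.null(results$hits)) {
      hit_genes <- unique(results$hits[direction == "silencing", gene])
      if (length(hit_genes) >= max(2L, config$k %||% 7L)) {
        fm <- build_feature_matrix(bio_log2[gene_name %in% hit_genes])
        ca <- kmeans_consensus(fm, k = config$k %||% 7L,
                               n_runs = config$n_runs %||% 20L, seed = seed)
        emit(ca, "cluster_assignments.tsv")
        ord <- hierarchical_order(fm, ca,
                                  linkage = config$linkage %||% "complete")
        emit(data.table::data.table(
          cluster_id = rep(names(ord), lengths(ord)),
          position = unlist(lapply(ord, seq_along)),
          gene = unlist(ord)), "leaf_order.tsv")
        results$clusters <- list(features = fm, assignment = ca, order = ord)
      }
    }

    if ("coherence" %in% stages && !is.null(combined) &&
        !is.null(config$complex_map)) {
      cmap <- read_complex_map(config$complex_map)
      prof <- build_gene_profiles(combined,
                                  mode = config$coherence_mode %||% "combined4")
      keep <- rownames(prof$matrix) %in% cmap$gene
      prof$matrix <- prof$matrix[keep, , drop = FALSE]
      corr <- pairwise_profile_correlation(prof)
      cmap <- cmap[gene %in% rownames(corr)]
      wb <- within_between_summary(corr, cmap)
      pt_res <- permutation_test(corr, cmap,
                                 n_perm = config$n_perm %||% 10000L,
                                 seed = seed)
      coh <- c(wb, pt_res[c("perm_p", "observed_stat", "method")],
               list(mode = prof$mode))
      jsonlite::write_json(coh, file.path(outdir, "coherence.json"),
                           auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, file.path(outdir, "coherence.json"))
      results$coherence <- coh
    }

    if ("flow" %in% stages) {
      ctrl <- generate_flow_controls(seed = seed)
      pop <- generate_cell_population(
        n_cells = config$flow_n_cells %||% 10000L,
        on_fraction = config$flow_on_fraction %||% 0.3, seed = seed + 2L)
      gate <- fit_gating(ctrl$red_only, ctrl$no_het)
      ss <- scale_and_summarize(pop$cells, gate)
      emit(ss$density_curve, "flow_density.tsv")
      emit(ss$hexbin, "flow_hexbin.tsv")
      jsonlite::write_json(
        ss[c("n_cells", "n_color_negative", "fraction_off",
             "fraction_intermediate", "fraction_on")],
        file.path(outdir, "flow_states.json"), auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, file.path(outdir, "flow_states.json"))
      results$flow <- ss
    }
  }, error = function(e) {
    status <<- paste("failed:", conditionMessage(e))
  })

  manifest <- list(
    package = "hetscreen",
    version = as.character(utils::packageVersion("hetscreen")),
    seed = seed, status = status, stages = stages,
    config_hash = hash_object(config),
    outputs = lapply(setNames(nm = basename(outputs)), function(b)
      unname(tools::md5sum(file.path(outdir, b)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  summary_lines <- c(sprintf("hetscreen run (seed %d): %s", seed, status))
  if (!is.null(results$hits)) {
    cnt <- results$hits[!is.na(direction) & direction != "none",
                        .N, by = .(screen, direction)]
    summary_lines <- c(summary_lines, "hit counts:",
                       utils::capture.output(print(cnt)))
  }
  if (!is.null(results$coherence))
    summary_lines <- c(summary_lines,
                       sprintf("coherence perm_p = %g (%s)",
                               results$coherence$perm_p,
                               results$coherence$method))
  writeLines(summary_lines, file.path(outdir, "summary.txt"))

  if (status != "ok")
    stop_hetscreen(sprintf("pipeline %s (partial outputs in %s)", status, outdir),
                   "hetscreen_pipeline_error")
  invisible(c(results, list(outdir = outdir, manifest = manifest)))
}
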