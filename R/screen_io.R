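#' Read a long-format colony-size table
#'
#' Reads the tidy long table produced by colony-measurement tools (one row per
#' colony observation) and returns a validated `PlateSet`. Required columns:
#' `screen`, `medium`, `plate_id`, `row`, `col`, `strain_id`, `gene_name`,
#' `bio_rep`, `tech_rep`, `size`. `screen` must be one of CEN/MAT/SUBTEL/TEL;
#' `medium` one of NS (non-selective EMM), URA (EMM-uracil), FOA (EMM+FOA).
#' Empty or `NA` size cells become missing; an explicit size of 0 is kept as 0
#' on input and treated as missing later, at the relative-growth step.
#'
#' @param path path to a `.tsv` or `.csv` file.
#' @param dialect field delimiter; `"auto"` picks tab for `.tsv`/`.txt` and
#'   comma for `.csv`.
#' @return a `PlateSet`: list with `observations` (data.table) and `strains`
#'   (data.table of distinct `strain_id`/`gene_name`).
#' @export
read_colony_table <- function(path, dialect = c("auto", "tab", "comma")) {
  dialect <- match.arg(dialect)
  assert(file.exists(path), sprintf("file not found: %s", path), "hetscreen_io_error")
  sep <- switch(dialect,
    tab = "\t", comma = ",",
    auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          na.strings = c("", "NA"), colClasses = list(character = "plate_id"))
  as_plateset(dt)
}

#' Build a PlateSet from an in-memory long table
#'
#' @param dt data.frame/data.table with the colony-table columns.
#' @return a `PlateSet` (see [read_colony_table()]).
#' @export
as_plateset <- function(dt) {
  dt <- data.table::as.data.table(dt)
  required <- c("screen", "medium", "plate_id", "row", "col",
                "strain_id", "gene_name", "bio_rep", "tech_rep", "size")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop_hetscreen(sprintf("missing required column(s): %s",
                           paste(missing_cols, collapse = ", ")),
                   "hetscreen_format_error")
  dt <- dt[, required, with = FALSE]
  dt[, `:=`(screen = as.character(screen), medium = as.character(medium),
            plate_id = as.character(plate_id), strain_id = as.character(strain_id),
            gene_name = as.character(gene_name),
            row = as.integer(row), col = as.integer(col),
            bio_rep = as.integer(bio_rep), tech_rep = as.integer(tech_rep),
            size = as.numeric(size))]

  bad <- character(0)
  chk <- function(mask, what) {
    i <- which(mask)
    if (length(i)) bad <<- c(bad, sprintf("row %d: %s", i, what))
  }
  chk(!dt$screen %in% SCREENS, "unknown screen")
  chk(!dt$medium %in% MEDIA, "unknown medium")
  chk(is.na(dt$row) | dt$row < 1L | dt$row > 16L, "row outside 1..16")
  chk(is.na(dt$col) | dt$col < 1L | dt$col > 24L, "col outside 1..24")
  chk(is.na(dt$bio_rep) | dt$bio_rep < 1L, "bio_rep < 1")
  chk(is.na(dt$tech_rep) | dt$tech_rep < 1L, "tech_rep < 1")
  chk(!is.na(dt$size) & dt$size < 0, "negative size")
  if (length(bad))
    stop_hetscreen(paste(c("malformed rows:", head(bad, 20L)), collapse = "\n"),
                   "hetscreen_format_error")

  key <- c("screen", "medium", "plate_id", "row", "col", "bio_rep", "tech_rep")
  ndup <- anyDuplicated(dt, by = key)
  if (ndup)
    stop_hetscreen(sprintf("duplicate observation key at input row %d", ndup),
                   "hetscreen_integrity_error")

  strains <- unique(dt[, .(strain_id, gene_name)])
  dupg <- strains[duplicated(strain_id), strain_id]
  if (length(dupg))
    stop_hetscreen(sprintf("strain_id mapped to multiple gene names: %s",
                           paste(unique(dupg), collapse = ", ")),
                   "hetscreen_integrity_error")
  structure(list(observations = dt[], strains = strains[]), class = "PlateSet")
}

#' @export
print.PlateSet <- function(x, ...) {
  cat(sprintf("PlateSet: %d observations, %d strains, screens: %s\n",
              nrow(x$observations), nrow(x$strains),
              paste(sort(unique(x$observations$screen)), collapse = ", ")))
  invisible(x)
}

#' Read a strain-annotation correction table
#'
#' Columns: `strain_id`, `gene_name`, `status` (verified/corrected/excluded),
#' `corrected_name`, `exclusion_reason`. Corrected names must end with the
#' literal `*` that marks re-annotated deletions in all downstream outputs.
#'
#' @param path TSV/CSV path.
#' @return data.table of `StrainRecord` rows.
#' @export
read_strain_corrections <- function(path) {
  assert(file.exists(path), sprintf("file not found: %s", path), "hetscreen_io_error")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE, na.strings = character(0),
                          colClasses = "character")
  validate_strain_records(dt)
}

validate_strain_records <- function(dt) {
  dt <- data.table::as.data.table(dt)
  for (nm in c("corrected_name", "exclusion_reason"))
    if (!nm %in% names(dt)) dt[, (nm) := ""]
  required <- c("strain_id", "gene_name", "status", "corrected_name", "exclusion_reason")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols))
    stop_hetscreen(sprintf("correction table missing column(s): %s",
                           paste(missing_cols, collapse = ", ")),
                   "hetscreen_format_error")
  dt <- dt[, required, with = FALSE]
  dt[is.na(corrected_name), corrected_name := ""]
  dt[is.na(exclusion_reason), exclusion_reason := ""]
  assert(all(dt$status %in% c("verified", "corrected", "excluded")),
         "status must be verified/corrected/excluded", "hetscreen_format_error")
  both <- dt$corrected_name != "" & dt$exclusion_reason != ""
  if (any(both))
    stop_hetscreen(sprintf("ambiguous correction (both corrected_name and exclusion_reason) for: %s",
                           paste(dt$strain_id[both], collapse = ", ")),
                   "hetscreen_ambiguity_error")
  bad_corr <- dt$status == "corrected" & (dt$corrected_name == "" | !grepl("\\*$", dt$corrected_name))
  assert(!any(bad_corr),
         "corrected records need a nonempty corrected_name ending in '*'",
         "hetscreen_format_error")
  assert(all(dt$exclusion_reason[dt$status == "excluded"] != ""),
         "excluded records need an exclusion_reason", "hetscreen_format_error")
  dt[]
}

#' Apply strain-annotation corrections to a PlateSet
#'
#' Mis-annotated deletion strains confirmed by genotyping are renamed to the
#' correct gene with a trailing `*`; contaminated or unconfirmed strains are
#' excluded. When a corrected strain collides with an existing strain that
#' already carries the same gene name, only the explicitly confirmed
#' (asterisked) mutant is kept.
#'
#' @param plateset a `PlateSet`.
#' @param corrections `StrainRecord` table (see [read_strain_corrections()]).
#' @return corrected `PlateSet`; idempotent.
#' @export
apply_strain_corrections <- function(plateset, corrections) {
  assert(inherits(plateset, "PlateSet"), "plateset must be a PlateSet")
  corrections <- validate_strain_records(corrections)
  obs <- data.table::copy(plateset$observations)
  if (nrow(corrections) == 0L) return(plateset)

  unknown <- setdiff(corrections$strain_id, obs$strain_id)
  if (length(unknown))
    warning(sprintf("corrections reference %d unknown strain id(s): %s",
                    length(unknown), paste(head(unknown, 5L), collapse = ", ")))

  excl <- corrections[status == "excluded", strain_id]
  obs <- obs[!strain_id %in% excl]

  corr <- corrections[status == "corrected"]
  if (nrow(corr)) {
    # drop the pre-existing strain whose annotation the corrected mutant claims
    for (i in seq_len(nrow(corr))) {
      claimed <- sub("\\*$", "", corr$corrected_name[i])
      obs <- obs[!(gene_name %in% c(claimed, corr$corrected_name[i]) &
                     strain_id != corr$strain_id[i])]
    }
    obs[corr, on = "strain_id", gene_name := i.corrected_name]
  }
  if (nrow(obs) == 0L)
    stop_hetscreen("all observations removed by corrections", "hetscreen_integrity_error")
  strains <- unique(obs[, .(strain_id, gene_name)])
  structure(list(observations = obs[], strains = strains[]), class = "PlateSet")
}

#' Write a result table as TSV
#'
#' Stable column order, UTF-8, missing values as empty cells, full double
#' precision (round-trips to < 1e-12).
#'
#' @param table nonempty data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(table, path) {
  assert(is.data.frame(table), "table must be a data.frame")
  if (nrow(table) == 0L)
    stop_hetscreen("refusing to write a 0-row table", "hetscreen_precondition_error")
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    data.table::fwrite(data.table::as.data.table(table), path, sep = "\t",
                       na = "", quote = FALSE, logical01 = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_hetscreen(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
                   "hetscreen_io_error")
  invisible(path)
}

#' Read back a table written by [write_scores()]
#' @param path TSV path.
#' @return data.table.
#' @export
read_scores <- function(path) {
  assert(file.exists(path), sprintf("file not found: %s", path), "hetscreen_io_error")
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = "")
}

#' Read a one-gene-per-line gold-standard list
#'
#' The gold standard used for recall calibration is a curated list of bona
#' fide heterochromatin factors (assembled from GO/FYPO annotation:
#' GO:0000792 heterochromatin, GO:0000781 chromosome telomeric region,
#' GO:0033696 heterochromatin boundary formation, FYPO:0004604 decreased
#' chromatin silencing at subtelomere). This reader takes the flat file; no
#' live ontology query is performed.
#'
#' @param path text file, one gene per line; `#` comments and blanks ignored.
#' @return character vector of unique gene names.
#' @export
read_gene_list <- function(path) {
  assert(file.exists(path), sprintf("file not found: %s", path), "hetscreen_io_error")
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- trimws(sub("#.*$", "", x))
  unique(x[nzchar(x)])
}

#' Read a two-column complex-membership table
#'
#' @param path TSV/CSV with columns `complex_id`, `gene`.
#' @return data.table with columns `complex_id`, `gene`.
#' @export
read_complex_map <- function(path) {
  assert(file.exists(path), sprintf("file not found: %s", path), "hetscreen_io_error")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE, colClasses = "character")
  assert(all(c("complex_id", "gene") %in% names(dt)),
         "complex map needs columns complex_id, gene", "hetscreen_format_error")
  unique(dt[, .(complex_id, gene)])
}

#' Read a supplementary-style per-replicate score table (replication mode)
#'
#' Expects a TSV/CSV export with columns `gene`, `screen`, `bio_rep`, `value`
#' (combined FOA/URA score per biological replicate). Used to re-run hit
#' calling on previously processed scores, skipping the colony stages.
#'
#' @param path TSV/CSV path.
#' @return data.table keyed by (gene, screen, bio_rep).
#' @export
read_score_table <- function(path) {
  assert(file.exists(path), sprintf("file not found: %s", path), "hetscreen_io_error")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE, na.strings = "")
  assert(all(c("gene", "screen", "bio_rep", "value") %in% names(dt)),
         "score table needs columns gene, screen, bio_rep, value",
         "hetscreen_format_error")
  dt[, .(gene = as.character(gene), screen = as.character(screen),
         bio_rep = as.integer(bio_rep), value = as.numeric(value))]
}
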