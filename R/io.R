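#' Delimited-text readers and writers
#'
#' Terminal and precerebellar-cell tables travel as comma-separated
#' UTF-8 text with a mandatory header, "." decimal and unquoted
#' numerics. Readers validate the schema and report offending row
#' numbers (header excluded) for bad enumerations or non-finite
#' coordinates.
#'
#' @name io
NULL

.TERMINAL_COLS <- c("animal_id", "origin", "x_um", "y_um", "z_um",
                    "side", "lobule", "stripe")
.CELL_COLS <- c("animal_id", "origin_or_target", "nucleus", "category",
                "side", "label_mode", "n_cells")

.bad_rows <- function(idx, what) {
  stop("invalid ", what, " at rows: ",
       paste(utils::head(idx, 10), collapse = ", "),
       if (length(idx) > 10) sprintf(" (and %d more)", length(idx) - 10),
       call. = FALSE)
}

#' Read / write a terminal table
#'
#' Schema: `animal_id, origin, x_um, y_um, z_um, side, lobule, stripe`.
#'
#' @param path File path.
#' @return `read_terminal_table`: a data frame with columns `animal`,
#'   `origin`, `x`, `y`, `z`, `side`, `lobule`, `stripe` (the internal
#'   terminal-point layout).
#' @export
read_terminal_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(.TERMINAL_COLS, names(df))
  if (length(miss))
    stop("terminal table lacks columns: ", paste(miss, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) .bad_rows(bad, paste0("numeric value in ", col))
    v
  }
  out <- data.frame(animal = df$animal_id, origin = df$origin,
                    x = if (nrow(df)) num("x_um") else numeric(0),
                    y = if (nrow(df)) num("y_um") else numeric(0),
                    z = if (nrow(df)) num("z_um") else numeric(0),
                    side = df$side, lobule = df$lobule,
                    stripe = df$stripe, stringsAsFactors = FALSE)
  bad <- which(!out$side %in% .SIDES)
  if (length(bad)) .bad_rows(bad, "side label")
  bad <- which(!out$lobule %in% .LOBULE_IDS)
  if (length(bad)) .bad_rows(bad, "lobule label")
  bad <- which(!out$stripe %in% .STRIPE_LABELS)
  if (length(bad)) .bad_rows(bad, "stripe label")
  out
}

#' @rdname read_terminal_table
#' @param terminals Terminal data frame (internal layout, as produced by
#'   [simulate_study()]).
#' @export
write_terminal_table <- function(terminals, path) {
  out <- data.frame(animal_id = terminals$animal,
                    origin = terminals$origin,
                    x_um = terminals$x, y_um = terminals$y,
                    z_um = terminals$z, side = terminals$side,
                    lobule = terminals$lobule, stripe = terminals$stripe)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a precerebellar cell table
#'
#' Schema: `animal_id, origin_or_target, nucleus, category, side,
#' label_mode, n_cells`.
#'
#' @param path File path.
#' @return `read_cell_table`: a data frame with the internal cell-record
#'   layout (`animal`, `origin`, `nucleus`, `category`, `side`,
#'   `label_mode`, `n_cells`).
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  miss <- setdiff(.CELL_COLS, names(df))
  if (length(miss))
    stop("cell table lacks columns: ", paste(miss, collapse = ", "))
  n <- suppressWarnings(as.integer(df$n_cells))
  bad <- which(!is.finite(n) | n < 0)
  if (length(bad) && nrow(df)) .bad_rows(bad, "n_cells")
  bad <- which(!df$category %in% c("pontine", "extra-pontine"))
  if (length(bad)) .bad_rows(bad, "category label")
  data.frame(animal = df$animal_id, origin = df$origin_or_target,
             nucleus = df$nucleus, category = df$category,
             side = df$side, label_mode = df$label_mode,
             n_cells = if (nrow(df)) n else integer(0),
             stringsAsFactors = FALSE)
}

#' Write a synthetic study to disk
#'
#' Emits the terminal and cell tables in their delimited-text schemas,
#' the atlas and stripe map as JSON, and a ground-truth sidecar
#' (realized per-animal mixing simplexes, contralateral fractions and
#' MF-per-cell ratios) for downstream recovery checks.
#'
#' @param study A `mossy_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "mossy_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_terminal_table(study$terminals, file.path(dir, "terminals.csv"))
  write_cell_table(study$cells, file.path(dir, "cells.csv"))
  write_atlas(study$atlas, file.path(dir, "atlas.json"))
  write_stripe_map(study$stripe_map, file.path(dir, "stripe_map.json"))
  jsonlite::write_json(
    list(mixing = study$ground_truth$mixing,
         contra_fraction = as.list(study$ground_truth$contra_fraction),
         mf_per_cell = as.list(study$ground_truth$mf_per_cell),
         seed = study$seed, n_animals = study$n_animals),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a pipeline run configuration
#'
#' Structured-text (JSON, or YAML when the `yaml` package is available)
#' parameter file for [run_pipeline()]. Recognized fields mirror
#' `run_pipeline()` arguments; unspecified fields fall back to the
#' standard defaults (4% input floor, 15% multimodal threshold, k = 5,
#' 500 um radius, t = 60 um, 100 CSR simulations). Unknown fields are
#' an error.
#'
#' @param path Path to a `.json`/`.yaml` file.
#' @return Named list of arguments, ready for
#'   `do.call(run_pipeline, ...)` after adding the data inputs.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  allowed <- setdiff(names(formals(run_pipeline)),
                     c("terminals", "cells", "atlas"))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown run-config fields: ", paste(bad, collapse = ", "))
  cfg
}

#' @rdname read_cell_table
#' @param cells Cell data frame (internal layout).
#' @export
write_cell_table <- function(cells, path) {
  out <- data.frame(animal_id = cells$animal,
                    origin_or_target = cells$origin,
                    nucleus = cells$nucleus, category = cells$category,
                    side = cells$side, label_mode = cells$label_mode,
                    n_cells = cells$n_cells)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
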