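#' Run the full analysis pipeline
#'
#' Executes quantification, co-innervation classification and (when
#' toggled) the spatial analyses on a terminal/cell table pair, writing
#' tidy delimited-text result tables, a structured JSON report and a run
#' manifest (versions, seed, parameters) into an output directory. With
#' identical inputs, configuration and seed the outputs are
#' byte-identical.
#'
#' @param terminals Terminal data frame (internal layout) or path to a
#'   terminal table CSV.
#' @param cells Cell data frame or path to a cell table CSV (optional;
#'   `NULL` skips cell analyses).
#' @param out_dir Output directory (created if needed).
#' @param atlas A `cerebellar_atlas`.
#' @param input_floor,multimodal_threshold,min_origins Classifier
#'   parameters (percent, percent, count).
#' @param k Neighbors for the kNN origin analysis.
#' @param radius_um Pairwise-distance radius (um).
#' @param t_eval_um Ripley evaluation distance (um).
#' @param n_sim CSR simulations per lobule test.
#' @param seed Integer seed for the CSR Monte Carlo tests.
#' @param variance_mode `"pooled"` or `"welch"` t-test variant.
#' @param p_method CSR p-value method (`"empirical_rank"` or
#'   `"kde_tail"`).
#' @param normalization Lobule-percentage normalization (`"combined"` or
#'   `"per_side"`).
#' @param run_spatial Toggle the spatial analyses (kNN, CSR tests).
#' @param min_points_spatial Minimum pooled points per (origin, side,
#'   lobule) for a CSR test.
#' @param max_points_spatial Cap per CSR test; larger point sets are
#'   subsampled (deterministically under `seed`) to keep the pairwise
#'   computations tractable.
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(terminals, cells = NULL, out_dir,
                         atlas = default_atlas(),
                         input_floor = 4, multimodal_threshold = 15,
                         min_origins = 2, k = 5, radius_um = 500,
                         t_eval_um = 60, n_sim = 100, seed = 1L,
                         variance_mode = "pooled",
                         p_method = "empirical_rank",
                         normalization = "combined",
                         run_spatial = TRUE, min_points_spatial = 30,
                         max_points_spatial = 2000) {
  if (is.character(terminals)) terminals <- read_terminal_table(terminals)
  if (is.character(cells)) cells <- read_cell_table(cells)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  counts <- count_terminals(terminals, atlas = atlas)
  pct_side <- side_percentages(counts, "side", atlas)
  pct_div <- side_percentages(counts, "division", atlas)
  pct_lob <- side_percentages(counts, "lobule", atlas,
                              normalization = normalization)
  dens <- terminal_density(counts, atlas)
  lat <- laterality_ratio(counts, variance_mode = variance_mode)
  sym <- symmetry_score(counts)
  labels <- classify_coinnervation(counts, input_floor,
                                   multimodal_threshold, min_origins,
                                   atlas = atlas)
  wcsv(pct_side$summary, "pct_side_summary.csv")
  wcsv(pct_div$summary, "pct_division_summary.csv")
  wcsv(pct_lob$summary, "pct_lobule_summary.csv")
  wcsv(dens, "density.csv")
  wcsv(lat$per_animal, "laterality_per_animal.csv")
  wcsv(sym, "symmetry.csv")
  wcsv(as.data.frame(labels), "coinnervation_labels.csv")

  report <- list(
    n_terminals = nrow(terminals),
    laterality = list(by_group = lat$by_group, test = lat$test),
    coinnervation = list(
      high = labels$lobule[labels$label == "high"],
      high_side = labels$side[labels$label == "high"],
      moderate = labels$lobule[labels$label == "moderate"],
      moderate_side = labels$side[labels$label == "moderate"]))

  if (!is.null(cells)) {
    split_pct <- cell_category_split(cells)
    term_per_animal <- table(terminals$animal)
    ratio_all <- mf_per_cell(
      stats::setNames(as.integer(term_per_animal),
                      names(term_per_animal)), cells, "all")
    ratio_pont <- mf_per_cell(
      stats::setNames(as.integer(term_per_animal),
                      names(term_per_animal)), cells, "pontine_only")
    report$cells <- list(pontine_pct = split_pct[["pontine"]],
                         extra_pontine_pct = split_pct[["extra-pontine"]],
                         mf_per_cell_all = ratio_all$ratio,
                         mf_per_cell_pontine = ratio_pont$ratio)
  }

  if (run_spatial) {
    set.seed(seed)
    pooled <- .sum_by(counts, c("origin", "side", "lobule"))
    pooled <- pooled[pooled$n >= min_points_spatial, , drop = FALSE]
    csr_rows <- list()
    for (i in seq_len(nrow(pooled))) {
      sel <- terminals$origin == pooled$origin[i] &
        terminals$side == pooled$side[i] &
        terminals$lobule == pooled$lobule[i]
      pts <- as.matrix(terminals[sel, c("x", "y", "z")])
      if (nrow(pts) > max_points_spatial)
        pts <- pts[sample.int(nrow(pts), max_points_spatial), , drop = FALSE]
      reg <- bounding_cuboid(pts)
      if (min(reg$hi - reg$lo) <= t_eval_um) next
      ct <- csr_test(pts, reg, t_eval = t_eval_um, n_sim = n_sim,
                     p_method = p_method)
      csr_rows[[length(csr_rows) + 1L]] <- data.frame(
        origin = pooled$origin[i], side = pooled$side[i],
        lobule = pooled$lobule[i], n = pooled$n[i],
        K_obs = ct$K_obs, p_one_sided = ct$p_one_sided,
        p_two_sided = ct$p_two_sided)
    }
    if (length(csr_rows)) {
      csr_df <- do.call(rbind, csr_rows)
      wcsv(csr_df, "csr_tests.csv")
      report$csr <- csr_df
    }
    if (length(unique(terminals$origin)) > 1 &&
        nrow(terminals) >= k + 1) {
      ev <- data.frame(x = terminals$x, y = terminals$y,
                       z = terminals$z, label = terminals$origin)
      if (nrow(ev) > 4000) ev <- ev[seq_len(4000), ]
      knn <- knn_origin_proportions(ev, k = k)
      wcsv(as.data.frame.table(knn, responseName = "proportion"),
           "knn_proportions.csv")
      report$knn <- as.data.frame.table(knn, responseName = "proportion")
    }
  }

  manifest <- list(package = "mossymap",
                   version = as.character(utils::packageVersion("mossymap")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = seed,
                   parameters = list(input_floor = input_floor,
                                     multimodal_threshold = multimodal_threshold,
                                     min_origins = min_origins, k = k,
                                     radius_um = radius_um,
                                     t_eval_um = t_eval_um, n_sim = n_sim,
                                     variance_mode = variance_mode,
                                     p_method = p_method,
                                     normalization = normalization))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(report)
}
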