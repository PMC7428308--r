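#' Counting and normalization of labeled terminals
#'
#' The quantification layer turns annotated terminal points into the
#' study's summary numbers: per-(animal, origin) counts over sides,
#' gross divisions and lobules; percentages (within-animal, then
#' averaged with s.e.m. across animals, or pooled); volume-normalized
#' terminal density D = N / (V_lobule / 2) per hemisphere; laterality
#' ratios with a primary-vs-association group comparison; bilateral
#' symmetry scores; mossy-fibers-per-precerebellar-cell ratios; and
#' Pearson correlations for cross-animal consistency checks.
#'
#' @name quantification
NULL

.sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Injection-site volume
#'
#' The injection core is treated as an elliptic cylinder:
#' `V = pi * a * b * h`, with `a` the maximum radius parallel to the
#' cortical layers (mediolateral, mm), `b` the rostrocaudal extent of the
#' core (mm) and `h` the maximum dorsoventral height (mm).
#'
#' @param a,b,h Dimensions in mm, all strictly positive.
#' @return Volume in mm^3.
#' @examples
#' injection_volume(0.2, 0.4, 0.5)  # pi * 0.04
#' @export
injection_volume <- function(a, b, h) {
  if (any(!is.finite(c(a, b, h))) || any(c(a, b, h) <= 0))
    stop("injection dimensions a, b, h must be positive")
  pi * a * b * h
}

.validate_points <- function(points, atlas = NULL) {
  req <- c("animal", "origin", "side", "lobule")
  miss <- setdiff(req, names(points))
  if (length(miss))
    stop("points table lacks columns: ", paste(miss, collapse = ", "))
  bad_side <- which(!points$side %in% .SIDES)
  lobs <- if (is.null(atlas)) .LOBULE_IDS else atlas$lobule
  bad_lob <- which(!points$lobule %in% lobs)
  bad <- sort(unique(c(bad_side, bad_lob)))
  if (length(bad))
    stop("invalid side/lobule labels at rows: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10))
  invisible(points)
}

#' Count terminals into a count matrix
#'
#' Exact multiplicity counts per `(animal, origin, side, lobule)` tuple
#' (optionally stratified by stripe). Tuples with zero observed
#' terminals are implicit zeros for all downstream operations.
#'
#' @param points Terminal table (data frame) with columns `animal`,
#'   `origin`, `side`, `lobule` and optionally `stripe`.
#' @param by Index columns.
#' @param atlas Optional atlas for lobule-label validation.
#' @return A `count_matrix`: data frame of index columns plus `n`.
#' @export
count_terminals <- function(points,
                            by = c("animal", "origin", "side", "lobule"),
                            atlas = NULL) {
  .validate_points(points, atlas)
  if (nrow(points) == 0) {
    out <- stats::setNames(
      data.frame(matrix(character(0), 0, length(by)), n = integer(0)),
      c(by, "n"))
  } else {
    out <- stats::aggregate(list(n = rep(1L, nrow(points))),
                            points[by], sum)
    out <- out[do.call(order, out[by]), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("count_matrix", "data.frame"), by = by)
}

.sum_by <- function(counts, by) {
  if (nrow(counts) == 0)
    return(stats::setNames(
      data.frame(matrix(character(0), 0, length(by)), n = integer(0)),
      c(by, "n")))
  out <- stats::aggregate(counts["n"], counts[by], sum)
  out[do.call(order, out[by]), , drop = FALSE]
}

#' Percentage split of a pooled count vector
#'
#' The elementary percentage routine shared by all tables: each element
#' as a percentage of the total.
#'
#' @param x Named non-negative numeric vector with positive sum.
#' @return Named percentages summing to 100.
#' @examples
#' percent_of_total(c(pontine = 6429, `extra-pontine` = 2378))
#' @export
percent_of_total <- function(x) {
  if (any(x < 0) || sum(x) <= 0)
    stop("counts must be non-negative with positive total")
  100 * x / sum(x)
}

#' Percentage tables per animal and origin
#'
#' Computes, within each (animal, origin), the percentage of that
#' animal's terminals per category at the requested level, then
#' summarizes across animals per origin as mean +/- s.e.m. At level
#' `"side"` the categories are ipsilateral/contralateral; at
#' `"division"` the three gross divisions; at `"lobule"` the 16 lobules.
#' `normalization = "combined"` expresses lobule/division percentages
#' relative to the animal's total over both sides (percent of total
#' cerebellar input); `"per_side"` normalizes within each side
#' separately (rows then sum to 100 per (animal, origin, side)).
#'
#' @param counts A `count_matrix`.
#' @param level `"side"`, `"division"` or `"lobule"`.
#' @param atlas Atlas (needed for the division map).
#' @param normalization `"combined"` or `"per_side"` (lobule/division
#'   levels only).
#' @return A `pct_table` list with `per_animal` and `summary` data
#'   frames.
#' @export
side_percentages <- function(counts, level = c("side", "division", "lobule"),
                             atlas = default_atlas(),
                             normalization = c("combined", "per_side")) {
  level <- match.arg(level)
  normalization <- match.arg(normalization)
  stopifnot(inherits(counts, "count_matrix"))
  df <- as.data.frame(counts)
  if (nrow(df) == 0) stop("empty count matrix")
  if (level == "division")
    df$category <- gross_division(atlas, df$lobule)
  else if (level == "lobule") df$category <- df$lobule
  else df$category <- df$side
  grp <- c("animal", "origin",
           if (level != "side" && normalization == "per_side") "side")
  agg <- stats::aggregate(df["n"], df[c(grp, "category")], sum)
  tot <- stats::aggregate(list(total = agg$n), agg[grp], sum)
  agg <- merge(agg, tot, by = grp)
  if (any(agg$total == 0)) stop("zero total for an (animal, origin) cell")
  agg$pct <- 100 * agg$n / agg$total
  # complete missing categories as zeros so summaries are comparable
  cats <- switch(level, side = .SIDES, division = .DIVISIONS,
                 lobule = atlas$lobule)
  keys <- unique(agg[grp])
  full <- merge(keys, data.frame(category = cats), by = NULL)
  agg <- merge(full, agg[c(grp, "category", "n", "pct")],
               by = c(grp, "category"), all.x = TRUE)
  agg$n[is.na(agg$n)] <- 0L
  agg$pct[is.na(agg$pct)] <- 0
  sgrp <- setdiff(c("origin", grp[-1], "category"), "animal")
  summ <- do.call(rbind, lapply(split(agg, agg[sgrp], drop = TRUE),
    function(d) {
      out <- d[1, sgrp, drop = FALSE]
      out$mean_pct <- mean(d$pct); out$sem_pct <- .sem(d$pct)
      out$n_animals <- nrow(d)
      out
    }))
  rownames(summ) <- NULL
  agg <- agg[do.call(order, agg[c(grp, "category")]), ]
  rownames(agg) <- NULL
  structure(list(per_animal = agg, summary = summ, level = level,
                 normalization = normalization),
            class = "pct_table")
}

#' @export
print.pct_table <- function(x, ...) {
  cat(sprintf("Percentage table (level = %s, normalization = %s)\n",
              x$level, x$normalization))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Pooled pontine vs extra-pontine percentage split
#'
#' Pools `n_cells` over all animals/nuclei per category and applies the
#' percentage routine (the retrograde worked example: 6429 pontine and
#' 2378 extra-pontine cells give 73% / 27%).
#'
#' @param cells Precerebellar cell table with columns `category`,
#'   `n_cells`.
#' @return Named percentages (`pontine`, `extra-pontine`).
#' @export
cell_category_split <- function(cells) {
  stopifnot(all(c("category", "n_cells") %in% names(cells)))
  tot <- tapply(cells$n_cells, cells$category, sum)
  percent_of_total(c(pontine = tot[["pontine"]],
                     `extra-pontine` = tot[["extra-pontine"]]))
}

#' Volume-normalized terminal density
#'
#' Pools counts across animals per (origin, side, lobule) and divides by
#' half the lobule volume, representing each hemisphere separately:
#' `D = N / (V_lobule * 1/2)`, in terminals per mm^3.
#'
#' @param counts A `count_matrix`.
#' @param atlas A `cerebellar_atlas` covering all lobules present.
#' @return Data frame `origin`, `side`, `lobule`, `n`, `density_mm3`.
#' @export
terminal_density <- function(counts, atlas = default_atlas()) {
  stopifnot(inherits(counts, "count_matrix"))
  agg <- .sum_by(counts, c("origin", "side", "lobule"))
  agg$density_mm3 <- agg$n / (atlas_volume(atlas, agg$lobule) * 0.5)
  rownames(agg) <- NULL
  agg
}

#' Laterality ratios and primary-vs-association comparison
#'
#' Per (animal, origin) ipsilateral:contralateral terminal-count ratio,
#' summarized per origin, and a two-sample t-test comparing the
#' per-animal ratios of two origin groups (primary sensory/motor vs
#' association/secondary areas by default).
#'
#' @param counts A `count_matrix`.
#' @param grouping Named character vector mapping origin to group.
#' @param variance_mode `"pooled"` (default) or `"welch"`.
#' @return A list: `per_animal` (data frame with `ratio`), `by_origin`
#'   and `by_group` summaries, and `test` (t statistic, df, p).
#' @export
laterality_ratio <- function(counts,
                             grouping = c(M1 = "primary", S1 = "primary",
                                          V1 = "primary", A1 = "primary",
                                          PPC = "association",
                                          AuD = "association"),
                             variance_mode = c("pooled", "welch")) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(inherits(counts, "count_matrix"))
  agg <- .sum_by(counts, c("animal", "origin", "side"))
  w <- stats::reshape(agg, idvar = c("animal", "origin"),
                      timevar = "side", direction = "wide")
  ipsi <- if ("n.ipsilateral" %in% names(w)) w$n.ipsilateral
          else rep(0L, nrow(w))
  contra <- if ("n.contralateral" %in% names(w)) w$n.contralateral
            else rep(NA_integer_, nrow(w))
  ipsi[is.na(ipsi)] <- 0L
  if (anyNA(contra) || any(contra == 0))
    stop("zero contralateral count for some (animal, origin): ratio undefined")
  per <- data.frame(animal = w$animal, origin = w$origin,
                    ipsi = ipsi, contra = contra, ratio = ipsi / contra)
  per$group <- unname(grouping[per$origin])
  by_origin <- do.call(rbind, lapply(split(per, per$origin), function(d)
    data.frame(origin = d$origin[1], mean_ratio = mean(d$ratio),
               sem_ratio = .sem(d$ratio), n = nrow(d))))
  rownames(by_origin) <- NULL
  by_group <- do.call(rbind, lapply(split(per, per$group), function(d)
    data.frame(group = d$group[1], mean_ratio = mean(d$ratio),
               sem_ratio = .sem(d$ratio), n = nrow(d))))
  rownames(by_group) <- NULL
  test <- NULL
  groups <- unique(stats::na.omit(per$group))
  if (length(groups) == 2) {
    test <- two_sample_ttest(per$ratio[per$group == groups[1]],
                             per$ratio[per$group == groups[2]],
                             variance_mode = variance_mode)
    test$groups <- groups
  }
  list(per_animal = per, by_origin = by_origin, by_group = by_group,
       test = test)
}

#' Bilateral symmetry of the lobular pattern
#'
#' Per (animal, origin) Pearson correlation between the ipsilateral and
#' contralateral lobule-proportion vectors; 1 means the relative lobular
#' pattern is identical on both sides regardless of absolute counts.
#'
#' @param counts A `count_matrix`.
#' @return Data frame `animal`, `origin`, `symmetry` (in \[-1, 1\]).
#' @export
symmetry_score <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  agg <- .sum_by(counts, c("animal", "origin", "side", "lobule"))
  out <- do.call(rbind, lapply(
    split(agg, list(agg$animal, agg$origin), drop = TRUE), function(d) {
      lobs <- sort(unique(d$lobule))
      if (sum(tapply(d$n, d$lobule, sum) > 0) < 3)
        stop("symmetry_score needs >= 3 lobules with nonzero counts")
      v <- function(s) {
        x <- stats::setNames(rep(0, length(lobs)), lobs)
        dd <- d[d$side == s, ]
        x[dd$lobule] <- dd$n
        if (sum(x) == 0) x else x / sum(x)
      }
      data.frame(animal = d$animal[1], origin = d$origin[1],
                 symmetry = pearson_cor(v("ipsilateral"),
                                        v("contralateral"))$r)
    }))
  rownames(out) <- NULL
  out
}

#' Pearson product-moment correlation
#'
#' Standard correlation with a two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal lengths n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Mossy fibers per precerebellar cell
#'
#' Ratio of labeled terminals to labeled precerebellar cells, either
#' over all cells or restricted to pontine cells. With per-animal
#' terminal totals (a named vector), per-animal ratios and their mean
#' +/- s.e.m. are reported alongside the pooled ratio.
#'
#' @param total_terminals Single count, or named per-animal counts.
#' @param cells Precerebellar cell table (`animal`, `category`,
#'   `n_cells`).
#' @param scope `"all"` or `"pontine_only"`.
#' @return List with `ratio` (pooled), and when per-animal totals are
#'   given `per_animal`, `mean`, `sem`.
#' @export
mf_per_cell <- function(total_terminals, cells,
                        scope = c("all", "pontine_only")) {
  scope <- match.arg(scope)
  sel <- if (scope == "pontine_only") cells$category == "pontine"
         else rep(TRUE, nrow(cells))
  cells <- cells[sel, , drop = FALSE]
  tot_cells <- sum(cells$n_cells)
  if (tot_cells <= 0) stop("no cells in scope: ratio undefined")
  pooled <- sum(total_terminals) / tot_cells
  out <- list(ratio = pooled, scope = scope)
  if (length(total_terminals) > 1 && !is.null(names(total_terminals))) {
    percell <- tapply(cells$n_cells, cells$animal, sum)
    ids <- intersect(names(total_terminals), names(percell))
    if (any(percell[ids] == 0)) stop("animal with zero cells in scope")
    per <- stats::setNames(as.numeric(total_terminals[ids] / percell[ids]),
                           ids)
    out$per_animal <- per
    out$mean <- mean(per)
    out$sem <- .sem(per)
  }
  out
}

#' Cross-animal consistency of lobular frequency patterns
#'
#' Within each origin, all pairwise Pearson correlations between the
#' animals' frequency vectors over a shared lobule (or lobule-by-stripe)
#' index — the internal validation that stripe alignment and labeling
#' pattern are consistent across animals.
#'
#' @param counts A `count_matrix` (include `stripe` in its `by` columns
#'   and set `by = "lobule_stripe"` to validate stripe-resolved
#'   patterns).
#' @param by `"lobule"` or `"lobule_stripe"`.
#' @param threshold Pairs with `r` below this are flagged.
#' @return List: `pairs` data frame (`origin`, `animal_1`, `animal_2`,
#'   `r`, `p`, `flagged`) and `threshold`.
#' @export
cross_animal_consistency <- function(counts, by = c("lobule", "lobule_stripe"),
                                     threshold = 0.5) {
  by <- match.arg(by)
  stopifnot(inherits(counts, "count_matrix"))
  df <- as.data.frame(counts)
  df$cat <- if (by == "lobule_stripe") {
    if (!"stripe" %in% names(df))
      stop("counts lack a stripe column; build with by including 'stripe'")
    paste(df$lobule, df$stripe, sep = ":")
  } else df$lobule
  rows <- list()
  for (org in unique(df$origin)) {
    d <- df[df$origin == org, ]
    cats <- sort(unique(d$cat))
    animals <- sort(unique(d$animal))
    if (length(animals) < 2)
      stop("need >= 2 animals per origin (", org, ")")
    freq <- sapply(animals, function(a) {
      x <- stats::setNames(rep(0, length(cats)), cats)
      dd <- d[d$animal == a, ]
      v <- tapply(dd$n, dd$cat, sum)
      x[names(v)] <- v
      x / sum(x)
    })
    cmb <- utils::combn(animals, 2)
    for (j in seq_len(ncol(cmb))) {
      pc <- pearson_cor(freq[, cmb[1, j]], freq[, cmb[2, j]])
      rows[[length(rows) + 1L]] <- data.frame(
        origin = org, animal_1 = cmb[1, j], animal_2 = cmb[2, j],
        r = pc$r, p = pc$p, flagged = pc$r < threshold)
    }
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  list(pairs = pairs, threshold = threshold)
}
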