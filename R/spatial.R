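#' Point-pattern analyses of labeled events
#'
#' Spatial analyses operate on labeled events: 3D coordinates (um) with
#' a categorical origin label (cortical injection site for terminals,
#' injection source for precerebellar cells). They quantify whether
#' events of one origin lie closer to their own kind than to events of
#' other origins (pairwise distances within a radius, k-nearest-neighbor
#' label proportions) and whether terminal counts are enriched in one
#' AldoC stripe class.
#'
#' @name spatial
NULL

.event_xyz <- function(events, planar = FALSE) {
  stopifnot(all(c("x", "y", "z") %in% names(events)))
  m <- as.matrix(events[, c("x", "y", "z")])
  # planar mode: distances within the section plane only (the z of a
  # terminal is section index x section thickness, so cross-section
  # distances are a modelling choice, not a measurement)
  if (planar) m[, "z"] <- 0
  m
}

#' Same-origin vs cross-origin pairwise distances
#'
#' All pairwise Euclidean distances at or below `radius` are split into
#' same-label pairs (both events carry `seed_label`) and cross-label
#' pairs (one event carries `seed_label`, the other any other label);
#' self-pairs are excluded. Means and s.e.m. are computed over pairs and
#' the two distance samples compared with a two-sample t-test.
#'
#' @param events Data frame with `x`, `y`, `z` (um) and `label`.
#' @param seed_label The origin whose spatial segregation is tested.
#' @param radius Maximum pair distance (um).
#' @param variance_mode Passed to [two_sample_ttest()].
#' @param planar If `TRUE`, ignore the rostrocaudal (z) coordinate and
#'   measure distances within the section plane only.
#' @return List: `same` and `cross` (each `mean`, `sem`, `n_pairs`),
#'   `t`, `df`, `p`.
#' @export
pairwise_distance_summary <- function(events, seed_label, radius = 500,
                                      variance_mode = c("pooled", "welch"),
                                      planar = FALSE) {
  variance_mode <- match.arg(variance_mode)
  xyz <- .event_xyz(events, planar)
  lab <- events$label
  if (sum(lab == seed_label) < 2)
    stop("need >= 2 events with seed label '", seed_label, "'")
  d <- as.matrix(stats::dist(xyz))
  is_seed <- lab == seed_label
  ut <- upper.tri(d)
  same_sel <- ut & outer(is_seed, is_seed, `&`)
  cross_sel <- ut & (outer(is_seed, !is_seed, `&`) |
                     outer(!is_seed, is_seed, `&`))
  same <- d[same_sel]; same <- same[same <= radius]
  cross <- d[cross_sel]; cross <- cross[cross <= radius]
  if (!length(same))
    stop("no same-label pairs within radius for '", seed_label, "'")
  if (!length(cross))
    stop("no cross-label pairs within radius for '", seed_label, "'")
  tt <- if (length(same) >= 2 && length(cross) >= 2)
    two_sample_ttest(same, cross, variance_mode = variance_mode)
  else list(t = NA_real_, df = NA_real_, p = NA_real_)  # too few pairs
  list(seed_label = seed_label, radius = radius,
       same = list(mean = mean(same), sem = .sem(same),
                   n_pairs = length(same)),
       cross = list(mean = mean(cross), sem = .sem(cross),
                    n_pairs = length(cross)),
       t = tt$t, df = tt$df, p = tt$p)
}

#' k-nearest-neighbor origin proportions
#'
#' For every event, its `k` nearest other events by Euclidean distance
#' are identified (ties broken by distance then stable input index; `k`
#' is exact, no tie expansion) and indexed by origin label. Neighbor
#' labels are aggregated per seed label; each seed label's proportions
#' sum to one.
#'
#' @param events Data frame with `x`, `y`, `z`, `label`.
#' @param k Number of neighbors (the study used 5).
#' @param planar If `TRUE`, ignore the z coordinate (per-section mode).
#' @return Matrix of proportions: rows seed labels, columns neighbor
#'   labels; attribute `counts` holds the raw tallies.
#' @export
knn_origin_proportions <- function(events, k = 5, planar = FALSE) {
  xyz <- .event_xyz(events, planar)
  lab <- events$label
  n <- nrow(xyz)
  if (n < k + 1) stop("need at least k + 1 = ", k + 1, " events")
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  labs <- sort(unique(lab))
  counts <- matrix(0L, length(labs), length(labs),
                   dimnames = list(seed = labs, neighbor = labs))
  for (i in seq_len(n)) {
    nb <- order(d[i, ], seq_len(n))[seq_len(k)]   # distance, then index
    tally <- table(factor(lab[nb], labs))
    counts[lab[i], ] <- counts[lab[i], ] + as.integer(tally)
  }
  props <- counts / rowSums(counts)
  attr(props, "counts") <- counts
  attr(props, "k") <- k
  props
}

#' Two-sample t-test
#'
#' Plain two-sample t-test with pooled variance (default) or the Welch
#' unequal-variance form, returning the statistic, degrees of freedom
#' and two-sided p-value.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param variance_mode `"pooled"` or `"welch"`.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_ttest <- function(x, y, variance_mode = c("pooled", "welch")) {
  variance_mode <- match.arg(variance_mode)
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero variance in both samples")
  ht <- stats::t.test(x, y, var.equal = (variance_mode == "pooled"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Stripe enrichment of terminals
#'
#' Per (origin, lobule): observed AldoC+ vs AldoC- terminal counts and
#' shares, compared against the area-based expectation (AldoC+
#' mediolateral extent / total mapped extent) with a two-sided exact
#' binomial test. Terminals labelled `unassigned`, unmapped lobules, and
#' degenerate maps (expected share 0 or 1) are flagged and excluded from
#' testing.
#'
#' @param terminals Terminal table with `origin`, `lobule`, `stripe`
#'   columns (or `x`/`z` plus a map to assign on the fly).
#' @param map A `stripe_map`.
#' @return Data frame per (origin, lobule): `n_plus`, `n_minus`,
#'   `observed_share`, `expected_share`, `p`, `flag`.
#' @export
stripe_enrichment <- function(terminals, map) {
  stopifnot(inherits(map, "stripe_map"))
  if (!"stripe" %in% names(terminals))
    terminals$stripe <- assign_stripe(terminals, map)
  rows <- list()
  for (org in unique(terminals$origin)) {
    for (lb in unique(terminals$lobule[terminals$origin == org])) {
      d <- terminals[terminals$origin == org & terminals$lobule == lb, ]
      np <- sum(d$stripe == "AldoC+"); nm <- sum(d$stripe == "AldoC-")
      ext <- stripe_extents(map, lb)
      row <- data.frame(origin = org, lobule = lb, n_plus = np,
                        n_minus = nm, observed_share = NA_real_,
                        expected_share = NA_real_, p = NA_real_,
                        flag = "ok", stringsAsFactors = FALSE)
      if (sum(ext) == 0) {
        row$flag <- "unmapped_lobule"
      } else {
        row$expected_share <- ext[["AldoC+"]] / sum(ext)
        if (np + nm == 0) {
          row$flag <- "no_assigned_terminals"
        } else if (row$expected_share %in% c(0, 1)) {
          row$observed_share <- np / (np + nm)
          row$flag <- "degenerate_expectation"
        } else {
          row$observed_share <- np / (np + nm)
          row$p <- stats::binom.test(np, np + nm,
                                     row$expected_share)$p.value
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
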