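#' Multimodal co-innervation classification
#'
#' Cerebellar lobule-sides are classified by the degree of convergence
#' of mossy-fiber input from functionally distinct cortical areas, using
#' the study's two-threshold rule. Counts are pooled across animals per
#' origin. For each (lobule, side):
#'
#' 1. The lobule's share of that side's total mossy-fiber input (summed
#'    over origins) must exceed the input floor (default > 4%),
#'    otherwise the lobule-side is `excluded`.
#' 2. The dominant origin is the one with the largest within-lobule
#'    count share. Let S be the combined within-lobule share of all
#'    non-dominant origins. Provided at least `min_origins` distinct
#'    non-dominant origins contribute nonzero terminals, the lobule-side
#'    is `high` if S > the multimodal threshold (default 15%) and
#'    `moderate` otherwise. If fewer than `min_origins` non-dominant
#'    origins are present the lobule-side is `excluded` with reason
#'    `"too_few_origins"`.
#'
#' An alternative reading of the rule — each of at least two
#' non-dominant origins must individually exceed the threshold for
#' `high` — is available via `share_mode = "each"`.
#'
#' @name coinnervation
NULL

#' Classify lobule-sides by multimodal co-innervation
#'
#' @param counts A `count_matrix` (animal-level counts are pooled per
#'   origin internally).
#' @param input_floor Minimum percent of the side's total input
#'   (strict `>`) for a lobule-side to be classified.
#' @param multimodal_threshold Percent of within-lobule input from
#'   non-dominant origins separating `high` (strict `>`) from
#'   `moderate`.
#' @param min_origins Minimum number of distinct non-dominant origins
#'   with nonzero terminals.
#' @param share_mode `"combined"` (default; S = summed non-dominant
#'   share) or `"each"` (at least `min_origins` non-dominant origins
#'   each individually above the threshold).
#' @param dominance `"count"` (default) or `"density"`: whether the
#'   dominant origin is identified by count share or volume-normalized
#'   density (equivalent within a lobule, provided for symmetry with
#'   density-based reporting).
#' @param atlas Atlas used when `dominance = "density"`.
#' @return A `coinnervation` data frame: `lobule`, `side`, `label`,
#'   `reason`, `dominant_origin`, `dominant_share`, `nondominant_share`,
#'   `n_nondominant_origins`, `side_share`, `tie` (TRUE when the
#'   dominant origin was tied and broken lexicographically).
#' @export
classify_coinnervation <- function(counts, input_floor = 4,
                                   multimodal_threshold = 15,
                                   min_origins = 2,
                                   share_mode = c("combined", "each"),
                                   dominance = c("count", "density"),
                                   atlas = default_atlas()) {
  share_mode <- match.arg(share_mode)
  dominance <- match.arg(dominance)
  stopifnot(inherits(counts, "count_matrix"))
  pooled <- .sum_by(counts, c("origin", "side", "lobule"))
  if (dominance == "density")
    pooled$w <- pooled$n / (atlas_volume(atlas, pooled$lobule) * 0.5)
  else pooled$w <- pooled$n
  rows <- list()
  for (sd_ in unique(pooled$side)) {
    d <- pooled[pooled$side == sd_, ]
    side_total <- sum(d$n)
    if (side_total <= 0) stop("zero total for side ", sd_)
    for (lb in unique(d$lobule)) {
      dl <- d[d$lobule == lb & d$n > 0, ]
      lob_total <- sum(dl$n)
      side_share <- 100 * lob_total / side_total
      shares <- 100 * dl$w / sum(dl$w)
      ord <- order(-shares, dl$origin)   # lexicographic tie-break
      tie <- length(shares) > 1 &&
        isTRUE(all.equal(shares[ord[1]], shares[ord[2]]))
      dom <- dl$origin[ord[1]]
      dom_share <- shares[ord[1]]
      nondom <- dl$origin != dom
      s_comb <- sum(shares[nondom])
      n_nd <- sum(nondom)
      if (side_share <= input_floor) {
        label <- "excluded"; reason <- "below_floor"
      } else if (n_nd < min_origins) {
        label <- "excluded"; reason <- "too_few_origins"
      } else {
        hit <- if (share_mode == "combined") s_comb > multimodal_threshold
               else sum(shares[nondom] > multimodal_threshold) >= min_origins
        label <- if (hit) "high" else "moderate"
        reason <- "classified"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        lobule = lb, side = sd_, label = label, reason = reason,
        dominant_origin = dom, dominant_share = dom_share,
        nondominant_share = s_comb, n_nondominant_origins = n_nd,
        side_share = side_share, tie = tie, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$side, out$lobule), ]
  rownames(out) <- NULL
  structure(out, class = c("coinnervation", "data.frame"),
            input_floor = input_floor,
            multimodal_threshold = multimodal_threshold,
            min_origins = min_origins, share_mode = share_mode)
}

#' Summarize a co-innervation classification
#'
#' Groups lobule-sides by label and lists the dominant origin and the
#' combined non-dominant share for each classified lobule-side.
#'
#' @param labels Result of [classify_coinnervation()].
#' @return A list with one data frame per label (`high`, `moderate`,
#'   `excluded`), of class `coinnervation_report`.
#' @export
coinnervation_report <- function(labels) {
  stopifnot(inherits(labels, "coinnervation"))
  out <- lapply(c(high = "high", moderate = "moderate",
                  excluded = "excluded"), function(lb) {
    d <- labels[labels$label == lb,
                c("lobule", "side", "dominant_origin",
                  "nondominant_share", "side_share", "reason")]
    rownames(d) <- NULL
    d
  })
  structure(out, class = "coinnervation_report",
            thresholds = attributes(labels)[c("input_floor",
                                              "multimodal_threshold",
                                              "min_origins")])
}

#' @export
print.coinnervation <- function(x, ...) {
  cat(sprintf(
    "Co-innervation classification (floor > %g%%, threshold > %g%%)\n",
    attr(x, "input_floor"), attr(x, "multimodal_threshold")))
  tab <- table(factor(x$label, c("high", "moderate", "excluded")))
  cat(sprintf("  high: %d, moderate: %d, excluded: %d lobule-sides\n",
              tab[["high"]], tab[["moderate"]], tab[["excluded"]]))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
print.coinnervation_report <- function(x, ...) {
  for (lb in names(x)) {
    cat("==", lb, "==\n")
    if (nrow(x[[lb]])) print(x[[lb]], digits = 3) else cat("(none)\n")
  }
  invisible(x)
}
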