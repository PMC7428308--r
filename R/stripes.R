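#' Parasagittal stripe maps
#'
#' Aldolase-C (zebrin II) is expressed by Purkinje cells in alternating
#' parasagittal stripes that are conserved across animals and are used to
#' align terminal positions between individuals. A stripe map describes,
#' per lobule and rostrocaudal bin, the ordered mediolateral boundary
#' positions (um) of the alternating AldoC+/AldoC- compartments. Terminals
#' are assigned to the half-open interval `[left, right)` containing their
#' mediolateral coordinate; points outside the mapped extent (or in an
#' unmapped lobule) are `unassigned`.
#'
#' @name stripes
NULL

.STRIPE_LABELS <- c("AldoC+", "AldoC-", "unassigned")

#' Build one stripe-map entry
#'
#' @param lobule Lobule identifier the entry applies to.
#' @param boundaries Strictly increasing mediolateral boundary positions
#'   (um); `k` boundaries delimit `k - 1` alternating stripes.
#' @param first_label Label of the first (most medial) stripe, `"AldoC+"`
#'   or `"AldoC-"`; subsequent stripes alternate.
#' @param z_min,z_max Rostrocaudal extent `[z_min, z_max)` (um) of the bin
#'   this entry describes; defaults cover all z.
#' @return A `stripe_entry` list.
#' @export
stripe_entry <- function(lobule, boundaries, first_label = "AldoC+",
                         z_min = -Inf, z_max = Inf) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2 || any(diff(boundaries) <= 0))
    stop("stripe boundaries must be strictly increasing with length >= 2")
  if (!first_label %in% c("AldoC+", "AldoC-"))
    stop("first_label must be 'AldoC+' or 'AldoC-'")
  if (!(z_min < z_max)) stop("z_min must be < z_max")
  structure(list(lobule = lobule, boundaries = boundaries,
                 first_label = first_label, z_min = z_min, z_max = z_max),
            class = "stripe_entry")
}

#' Assemble a stripe map from entries
#'
#' @param ... `stripe_entry` objects (or a single list of them).
#' @return A `stripe_map` object.
#' @export
stripe_map <- function(...) {
  entries <- list(...)
  if (length(entries) == 1 && !inherits(entries[[1]], "stripe_entry"))
    entries <- entries[[1]]
  if (!all(vapply(entries, inherits, logical(1), "stripe_entry")))
    stop("all elements must be stripe_entry objects")
  structure(list(entries = entries), class = "stripe_map")
}

.entry_labels <- function(entry) {
  n <- length(entry$boundaries) - 1L
  lab <- rep(c("AldoC+", "AldoC-"), length.out = n)
  if (entry$first_label == "AldoC-") lab <- rep(c("AldoC-", "AldoC+"), length.out = n)
  lab
}

#' Assign terminals to AldoC stripes
#'
#' Vectorized over points. A point matches the first map entry whose
#' lobule equals the point's and whose rostrocaudal bin contains its z
#' coordinate; within the entry the stripe is the half-open interval
#' `[left, right)` containing the mediolateral coordinate `x`. Points in
#' unmapped lobules/bins or outside the mapped mediolateral extent are
#' labelled `"unassigned"`.
#'
#' @param points Data frame with at least columns `lobule`, `x`, `z`
#'   (um); a terminal table works directly.
#' @param map A `stripe_map`.
#' @return Character vector of stripe labels, one per row of `points`.
#' @export
assign_stripe <- function(points, map) {
  stopifnot(inherits(map, "stripe_map"),
            all(c("lobule", "x", "z") %in% names(points)))
  out <- rep("unassigned", nrow(points))
  for (entry in map$entries) {
    sel <- which(points$lobule == entry$lobule &
                 points$z >= entry$z_min & points$z < entry$z_max &
                 out == "unassigned")
    if (!length(sel)) next
    # findInterval: boundaries[i] <= x < boundaries[i+1]  (half-open)
    idx <- findInterval(points$x[sel], entry$boundaries)
    lab <- .entry_labels(entry)
    hit <- idx >= 1L & idx <= length(lab)
    out[sel[hit]] <- lab[idx[hit]]
  }
  out
}

#' Mediolateral extent of each stripe label
#'
#' Sums the interval lengths carrying each label over all entries for a
#' lobule; used as the area-based null expectation in
#' [stripe_enrichment()].
#'
#' @param map A `stripe_map`.
#' @param lobule Lobule identifier.
#' @return Named numeric vector `c("AldoC+" = ..., "AldoC-" = ...)` (um);
#'   zeros if the lobule is unmapped.
#' @export
stripe_extents <- function(map, lobule) {
  ext <- c("AldoC+" = 0, "AldoC-" = 0)
  for (entry in map$entries) {
    if (entry$lobule != lobule) next
    len <- diff(entry$boundaries)
    lab <- .entry_labels(entry)
    ext["AldoC+"] <- ext[["AldoC+"]] + sum(len[lab == "AldoC+"])
    ext["AldoC-"] <- ext[["AldoC-"]] + sum(len[lab == "AldoC-"])
  }
  ext
}

#' @export
print.stripe_map <- function(x, ...) {
  cat("Stripe map:", length(x$entries), "entries over",
      length(unique(vapply(x$entries, `[[`, "", "lobule"))), "lobules\n")
  invisible(x)
}

#' Write / read a stripe map as JSON
#'
#' @param map A `stripe_map`.
#' @param path File path.
#' @export
write_stripe_map <- function(map, path) {
  stopifnot(inherits(map, "stripe_map"))
  recs <- lapply(map$entries, function(e) {
    r <- list(lobule = e$lobule, boundaries = e$boundaries,
              first_label = e$first_label)
    # infinite z bounds are the default; omit them (JSON has no Inf)
    if (is.finite(e$z_min)) r$z_min <- e$z_min
    if (is.finite(e$z_max)) r$z_max <- e$z_max
    r
  })
  jsonlite::write_json(recs, path, digits = NA, pretty = TRUE,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stripe_map
#' @export
read_stripe_map <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  stripe_map(lapply(recs, function(r)
    stripe_entry(r$lobule, unlist(r$boundaries), r$first_label,
                 if (is.null(r$z_min)) -Inf else r$z_min,
                 if (is.null(r$z_max)) Inf else r$z_max)))
}
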