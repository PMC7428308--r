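#' Cerebellar lobule atlas
#'
#' The atlas is the fixed anatomical reference used throughout the package:
#' the 16 cerebellar lobules of the mouse, their total volumes (mm^3, from
#' 16.4T MRT measurements), and their membership in the three gross
#' divisions (vermis, hemisphere, vestibulocerebellum).
#'
#' @section Lobule identifiers:
#' `I, II, III, IV/V, VI, VII, VIII, IX, X` (vermal lobules),
#' `Sim` (simplex), `CrusI`, `CrusII` (ansiform lobule), `PM` (paramedian),
#' `Cop` (copula pyramis), `PFl` (paraflocculus), `Fl` (flocculus).
#'
#' Lobules IX and X sit in the vermis anatomically but belong functionally
#' to the vestibulocerebellum; the default division map places them there,
#' and the map is a plain column of the atlas so alternative groupings can
#' be supplied.
#'
#' @name atlas
NULL

.LOBULE_IDS <- c("I", "II", "III", "IV/V", "VI", "VII", "VIII", "IX", "X",
                 "Sim", "CrusI", "CrusII", "PM", "Cop", "PFl", "Fl")

.ORIGINS <- c("M1", "S1", "PPC", "V1", "A1", "AuD")

.SIDES <- c("ipsilateral", "contralateral")

.DIVISIONS <- c("vermis", "hemisphere", "vestibulocerebellum")

#' Default cerebellar atlas
#'
#' Builds the reference atlas: 16 lobules with MRT-based total volumes in
#' mm^3 and the default gross-division map (I-VIII vermis; Sim, CrusI,
#' CrusII, PM, Cop hemisphere; IX, X, PFl, Fl vestibulocerebellum).
#'
#' @return A `cerebellar_atlas` object: a data frame with columns
#'   `lobule`, `volume_mm3`, `division`.
#' @examples
#' atl <- default_atlas()
#' atlas_volume(atl, "Cop")     # 2 mm^3
#' gross_division(atl, "CrusI") # "hemisphere"
#' @export
default_atlas <- function() {
  vol <- c("I" = 0.14, "II" = 1.16, "III" = 1.79, "IV/V" = 5.61,
           "VI" = 2.5, "VII" = 0.67, "VIII" = 1.52, "IX" = 2.81,
           "X" = 1.26, "Sim" = 4.67, "CrusI" = 4.17, "CrusII" = 4.18,
           "PM" = 3.59, "Cop" = 2, "PFl" = 3.35, "Fl" = 0.79)
  div <- c(rep("vermis", 7), "vestibulocerebellum", "vestibulocerebellum",
           rep("hemisphere", 5), "vestibulocerebellum", "vestibulocerebellum")
  names(div) <- .LOBULE_IDS
  new_atlas(data.frame(lobule = .LOBULE_IDS,
                       volume_mm3 = unname(vol[.LOBULE_IDS]),
                       division = unname(div[.LOBULE_IDS]),
                       stringsAsFactors = FALSE))
}

new_atlas <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("lobule", "volume_mm3", "division") %in% names(df)))
  if (anyDuplicated(df$lobule))
    stop("duplicate lobule ids in atlas")
  if (any(!is.finite(df$volume_mm3)) || any(df$volume_mm3 <= 0))
    stop("atlas volumes must be finite and strictly positive")
  if (!all(df$division %in% .DIVISIONS))
    stop("unknown division label in atlas: ",
         paste(setdiff(df$division, .DIVISIONS), collapse = ", "))
  class(df) <- c("cerebellar_atlas", "data.frame")
  df
}

.atlas_row <- function(atlas, lobule_id) {
  stopifnot(inherits(atlas, "cerebellar_atlas"), length(lobule_id) >= 1)
  idx <- match(lobule_id, atlas$lobule)
  if (anyNA(idx))
    stop("unknown lobule id: ",
         paste(lobule_id[is.na(idx)], collapse = ", "))
  idx
}

#' Look up a lobule volume
#'
#' @param atlas A `cerebellar_atlas`.
#' @param lobule_id Lobule identifier(s).
#' @return Volume(s) in mm^3.
#' @export
atlas_volume <- function(atlas, lobule_id) {
  atlas$volume_mm3[.atlas_row(atlas, lobule_id)]
}

#' Gross division of a lobule
#'
#' @inheritParams atlas_volume
#' @return `"vermis"`, `"hemisphere"` or `"vestibulocerebellum"` under the
#'   atlas's division map.
#' @export
gross_division <- function(atlas, lobule_id) {
  atlas$division[.atlas_row(atlas, lobule_id)]
}

#' @export
print.cerebellar_atlas <- function(x, ...) {
  cat("Cerebellar atlas:", nrow(x), "lobules, total volume",
      format(sum(x$volume_mm3), digits = 4), "mm^3\n")
  cat("Divisions:",
      paste(sprintf("%s (%d)", .DIVISIONS, table(factor(x$division, .DIVISIONS))),
            collapse = ", "), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write / read an atlas as JSON
#'
#' The serialized form is a JSON array of records
#' `{lobule, volume_mm3, division}`.
#'
#' @param atlas A `cerebellar_atlas`.
#' @param path File path.
#' @return `read_atlas` returns a `cerebellar_atlas`; `write_atlas` returns
#'   `path` invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "cerebellar_atlas"))
  jsonlite::write_json(as.data.frame(atlas), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  df <- jsonlite::fromJSON(path)
  new_atlas(df)
}
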