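#' Pen geometry
#'
#' Describes the floor plan of one experimental pen: a shared open area plus
#' `n_crates` individual stalls. The geometry determines the area-proportional
#' null occupancy used by the preference test: an animal that is indifferent
#' between the two resources is expected to be observed in the open area in
#' proportion to its share of the total floor space.
#'
#' Defaults are the trial's printed dimensions: a 3.1 x 2.7 m open area and
#' three 1.9 x 0.6 m self-catching stalls, i.e. 71% of floor space open and
#' 2.8 m^2 of open area per animal in a trio.
#'
#' @param open_len,open_wid Length and width of the open area, metres.
#' @param crate_len,crate_wid Length and width of one crate (stall), metres.
#' @param n_crates Number of crates available to the group.
#' @return An object of class `pen_geometry`.
#' @examples
#' g <- pen_geometry()
#' null_space_fraction(g)      # 0.7099...
#' open_space_per_animal(g)    # 2.79 m^2
#' @export
pen_geometry <- function(open_len = 3.1, open_wid = 2.7,
                         crate_len = 1.9, crate_wid = 0.6,
                         n_crates = 3) {
  for (f in c("open_len", "open_wid", "crate_len", "crate_wid")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop_field(f, "must be a positive length in metres")
  }
  n_crates <- check_count(n_crates, "n_crates", min = 0L)
  structure(
    list(open_len = open_len, open_wid = open_wid,
         crate_len = crate_len, crate_wid = crate_wid,
         n_crates = n_crates),
    class = "pen_geometry"
  )
}

#' Area-proportional null occupancy
#'
#' Fraction of total floor space taken by the open area,
#' `open_area / (open_area + n_crates * crate_area)`. This is the expected
#' proportion of scans spent out of a crate for an animal without a
#' preference, and the null value against which simulated confidence
#' intervals are compared.
#'
#' @param geom A [pen_geometry()].
#' @return A single probability.
#' @export
null_space_fraction <- function(geom) {
  stopifnot(inherits(geom, "pen_geometry"))
  open_area <- geom$open_len * geom$open_wid
  crate_area <- geom$n_crates * geom$crate_len * geom$crate_wid
  open_area / (open_area + crate_area)
}

#' Open area per animal
#'
#' Open-area floor space divided by the number of crates (one crate per
#' animal in the group), in square metres.
#'
#' @param geom A [pen_geometry()].
#' @return Square metres of open area per animal.
#' @export
open_space_per_animal <- function(geom) {
  stopifnot(inherits(geom, "pen_geometry"))
  if (geom$n_crates == 0L) stop("geometry has no crates; per-animal space undefined")
  geom$open_len * geom$open_wid / geom$n_crates
}

#' @export
print.pen_geometry <- function(x, ...) {
  open_area <- x$open_len * x$open_wid
  cat(sprintf("Pen geometry: open %.2f x %.2f m (%.2f m^2), %d crates %.2f x %.2f m\n",
              x$open_len, x$open_wid, open_area, x$n_crates, x$crate_len, x$crate_wid))
  cat(sprintf("  open-space fraction (null occupancy): %.4f\n", null_space_fraction(x)))
  invisible(x)
}
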