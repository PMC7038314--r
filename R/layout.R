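#' Canonical sensor site labels
#'
#' The eight anatomical sensor sites of one instrumented insole, in the
#' canonical column order used by all recordings: heel, lateral midfoot,
#' first/third/fifth metatarsal heads, hallux, second toe, fifth toe.
#'
#' @format Character vector of length 8.
#' @export
SENSOR_SITES <- c("heel", "midfoot_lateral", "met1", "met3", "met5",
                  "hallux", "toe2", "toe5")

#' Construct a sensor layout
#'
#' A sensor layout places the eight pressure sensors of one insole in a
#' foot-local coordinate frame: the origin is at the heel-most point of the
#' insole, `y_ap` (anteroposterior, mm) increases toward the toes, and `x_ml`
#' (medial--lateral, mm) increases toward the lateral border of the *right*
#' foot, so that a left layout is the mirror image (negated `x_ml`) of the
#' matching right layout.
#'
#' @param foot_side `"left"` or `"right"`.
#' @param x_ml,y_ap Numeric vectors of length 8, sensor coordinates in mm,
#'   ordered as [SENSOR_SITES].
#' @param foot_length Foot length in mm (default 260, EU size 41).
#' @param sites Site labels; must be a permutation-free copy of
#'   [SENSOR_SITES] in canonical order.
#' @return An object of class `sensor_layout`: a list with `foot_side`,
#'   `foot_length` and a `sensors` data frame (`site`, `x_ml`, `y_ap`).
#' @seealso [default_layout()], [mirror_layout()], [read_layout()]
#' @export
sensor_layout <- function(foot_side, x_ml, y_ap, foot_length = 260,
                          sites = SENSOR_SITES) {
  foot_side <- match.arg(foot_side, c("left", "right"))
  if (length(sites) != 8L || anyDuplicated(sites) ||
      !setequal(sites, SENSOR_SITES)) {
    stop("layout must name exactly the 8 canonical sensor sites", call. = FALSE)
  }
  if (!identical(as.character(sites), SENSOR_SITES)) {
    ord <- match(SENSOR_SITES, sites)
    sites <- sites[ord]; x_ml <- x_ml[ord]; y_ap <- y_ap[ord]
  }
  if (length(x_ml) != 8L || length(y_ap) != 8L) {
    stop("x_ml and y_ap must each have 8 coordinates", call. = FALSE)
  }
  if (!is.finite(foot_length) || foot_length <= 0) {
    stop("foot_length must be positive", call. = FALSE)
  }
  if (any(y_ap < 0) || any(y_ap > foot_length)) {
    stop("y_ap coordinates must lie in [0, foot_length]", call. = FALSE)
  }
  y <- stats::setNames(y_ap, sites)
  if (y[["heel"]] != min(y_ap)) {
    stop("heel must be the rear-most sensor (minimal y_ap)", call. = FALSE)
  }
  if (max(y[c("hallux", "toe2", "toe5")]) != max(y_ap)) {
    stop("hallux/toe sensors must be the front-most (maximal y_ap)",
         call. = FALSE)
  }
  structure(list(
    foot_side = foot_side,
    foot_length = foot_length,
    sensors = data.frame(site = as.character(sites), x_ml = as.numeric(x_ml),
                         y_ap = as.numeric(y_ap), stringsAsFactors = FALSE)
  ), class = "sensor_layout")
}

# Anatomical placement fractions for the default EU 41 layout.  The y
# positions are documented fractions of foot length (heel pad ~12%, lateral
# midfoot ~40%, metatarsal heads ~68-72%, hallux ~88%, toes ~90%); the x
# positions are plausible mm offsets from the heel line for a right foot.
.default_site_fractions <- data.frame(
  site = SENSOR_SITES,
  y_frac = c(0.12, 0.40, 0.72, 0.70, 0.68, 0.88, 0.90, 0.90),
  x_right = c(0, 30, -25, 0, 25, -18, 0, 22),
  stringsAsFactors = FALSE
)

#' Default EU 41 sensor layout
#'
#' Builds the canonical sensor layout for a 260 mm (EU 41) foot, with the
#' eight sites placed at documented anatomical fractions of foot length. The
#' exact in-insole coordinates of any particular hardware are not published,
#' so this layout is an informed, fully user-overridable stand-in; a JSON
#' copy ships with the package (`system.file("extdata", "layout_eu41.json",
#' package = "gaitseg")`).
#'
#' @inheritParams sensor_layout
#' @return A `sensor_layout`.
#' @examples
#' default_layout("left")
#' @export
default_layout <- function(foot_side = c("left", "right"), foot_length = 260) {
  foot_side <- match.arg(foot_side)
  f <- .default_site_fractions
  x <- if (foot_side == "right") f$x_right else -f$x_right
  sensor_layout(foot_side, x_ml = x, y_ap = f$y_frac * foot_length,
                foot_length = foot_length, sites = f$site)
}

#' Mirror a sensor layout to the other foot
#'
#' Negates the medial--lateral coordinates and flips the foot side; applying
#' it twice returns the original layout.
#'
#' @param layout A `sensor_layout`.
#' @return The mirrored `sensor_layout`.
#' @export
mirror_layout <- function(layout) {
  stopifnot(inherits(layout, "sensor_layout"))
  sensor_layout(
    foot_side = if (layout$foot_side == "left") "right" else "left",
    x_ml = -layout$sensors$x_ml,
    y_ap = layout$sensors$y_ap,
    foot_length = layout$foot_length,
    sites = layout$sensors$site
  )
}

#' Read / write sensor layouts as JSON
#'
#' The JSON schema (one object per foot side) is shipped in
#' `inst/schemas/layout.schema.json`.
#'
#' @param path File path.
#' @param foot_side Which foot to extract when the file stores both.
#' @return `read_layout()` returns a `sensor_layout`; `write_layout()`
#'   returns `path` invisibly.
#' @export
read_layout <- function(path, foot_side = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feet <- if (!is.null(obj$feet)) obj$feet else
    stats::setNames(list(obj), obj$foot_side)
  if (is.null(foot_side)) {
    if (length(feet) > 1L) {
      return(lapply(stats::setNames(nm = names(feet)), function(s)
        .layout_from_list(feet[[s]], s)))
    }
    foot_side <- names(feet)[1L]
  }
  if (is.null(feet[[foot_side]])) {
    stop("layout file has no entry for foot '", foot_side, "'", call. = FALSE)
  }
  .layout_from_list(feet[[foot_side]], foot_side)
}

.layout_from_list <- function(x, foot_side) {
  s <- x$sensors
  sensor_layout(foot_side, x_ml = s$x_ml_mm, y_ap = s$y_ap_mm,
                foot_length = x$foot_length_mm, sites = s$site)
}

#' @rdname read_layout
#' @param left,right The two `sensor_layout` objects to persist.
#' @export
write_layout <- function(left, right, path) {
  stopifnot(inherits(left, "sensor_layout"), inherits(right, "sensor_layout"),
            left$foot_side == "left", right$foot_side == "right")
  as_entry <- function(l) list(
    foot_length_mm = l$foot_length,
    sensors = data.frame(site = l$sensors$site, x_ml_mm = l$sensors$x_ml,
                         y_ap_mm = l$sensors$y_ap)
  )
  jsonlite::write_json(
    list(format = "gaitseg-layout", version = "1.0",
         feet = list(left = as_entry(left), right = as_entry(right))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("<sensor_layout> %s foot, length %.0f mm\n",
              x$foot_side, x$foot_length))
  print(x$sensors, row.names = FALSE)
  invisible(x)
}
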