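#' Quadrant corner points of view
#'
#' The in-line-of-sight method ranks attributes by proximity to the
#' extreme corner of one quadrant of the Better-Worse plane (the point
#' most clearly representing that category), viewed in the signed
#' convention (Worse on \[-1, 0\], Better on \[0, 1\]):
#' must-be = (-1, 0), attractive = (0, 1), one-dimensional = (-1, 1),
#' indifferent = (0, 0).
#'
#' Each corner carries an angle convention: the angle alpha of an
#' attribute is measured at the corner between one quadrant edge (the
#' alpha = 0 reference ray) and the line to the attribute, growing from 0
#' to 90 degrees *toward* a named neighbouring corner. At equal distance a
#' smaller alpha ranks better, so the `angle_toward` corner is the
#' direction one accepts losing against. The defaults are: from must-be
#' and from attractive, alpha grows toward the one-dimensional corner;
#' from one-dimensional and from indifferent it grows toward must-be
#' (the conservative choice for professional products, where essential
#' qualities outrank merely attractive ones). For the must-be corner this
#' makes alpha the angle between the Worse axis and the line from
#' (-1, 0) to the attribute, i.e. `atan(better / (1 + worse))`.
#'
#' @param name One of `"must-be"`, `"attractive"`, `"one-dimensional"`,
#'   `"indifferent"`.
#' @param angle_toward Name of the corner toward which alpha increases;
#'   `NULL` picks the default above. Must be one of the two corners
#'   adjacent to `name` along the square's edges.
#' @return Object of class `corner_pov`: list with `name`, `corner`
#'   (named c(worse, better)), `angle_toward`, and `reference` (unit
#'   vector of the alpha = 0 ray, which is the edge toward the other
#'   adjacent corner).
#' @examples
#' corner_pov("must-be")
#' @export
corner_pov <- function(name = c("must-be", "attractive", "one-dimensional",
                                "indifferent"),
                       angle_toward = NULL) {
  name <- match.arg(name)
  corners <- list("must-be" = c(worse = -1, better = 0),
                  "attractive" = c(worse = 0, better = 1),
                  "one-dimensional" = c(worse = -1, better = 1),
                  "indifferent" = c(worse = 0, better = 0))
  is_adjacent <- function(a, b) sum(abs(corners[[a]] - corners[[b]])) == 1
  adjacent <- names(corners)[vapply(names(corners), is_adjacent, logical(1), a = name)]
  defaults <- c("must-be" = "one-dimensional", "attractive" = "one-dimensional",
                "one-dimensional" = "must-be", "indifferent" = "must-be")
  if (is.null(angle_toward)) angle_toward <- defaults[[name]]
  if (!angle_toward %in% adjacent) {
    stop("'angle_toward' must be a corner adjacent to ", name, ": ",
         paste(adjacent, collapse = " or "), call. = FALSE)
  }
  ref_corner <- setdiff(adjacent, angle_toward)
  ref <- corners[[ref_corner]] - corners[[name]]
  structure(list(name = name, corner = corners[[name]],
                 angle_toward = angle_toward,
                 reference = ref / sqrt(sum(ref^2))),
            class = "corner_pov")
}

#' @export
print.corner_pov <- function(x, ...) {
  cat(sprintf("Corner POV %s at (Worse = %g, Better = %g), alpha growing toward %s\n",
              sQuote(x$name), x$corner["worse"], x$corner["better"],
              sQuote(x$angle_toward)))
  invisible(x)
}

as_corner_pov <- function(pov) {
  if (inherits(pov, "corner_pov")) pov else corner_pov(pov)
}

check_in_square <- function(worse, better, tol = 1e-9) {
  if (any(worse < -1 - tol | worse > tol | better < -tol | better > 1 + tol)) {
    stop("coordinate outside the unit Better/Worse rectangle ",
         "(worse in [-1, 0], better in [0, 1])", call. = FALSE)
  }
}

#' Distance and angle from a corner point of view
#'
#' `distance_to_corner()` is the Euclidean distance from the attribute's
#' (worse, better) coordinate to the POV corner; larger distances mean
#' greater proximity to the other categories. `angle_from_corner()` is
#' the angle in degrees, in \[0, 90\], between the POV's alpha = 0
#' reference ray and the line from the corner to the coordinate; a point
#' equal to the corner is assigned alpha = 0 (the unique choice that
#' keeps the corner itself ranked best).
#'
#' @param worse,better Coordinates in the signed convention (worse in
#'   \[-1, 0\], better in \[0, 1\]); vectorized.
#' @param pov A [corner_pov] or a corner name.
#' @return Numeric vector of distances, or angles in degrees.
#' @examples
#' distance_to_corner(-0.8, 0.25, "must-be")
#' angle_from_corner(-0.8, 0.25, "must-be")   # atan(0.25/0.2) in degrees
#' @export
distance_to_corner <- function(worse, better, pov = "must-be") {
  pov <- as_corner_pov(pov)
  check_in_square(worse, better)
  unname(sqrt((worse - pov$corner[["worse"]])^2 + (better - pov$corner[["better"]])^2))
}

#' @rdname distance_to_corner
#' @export
angle_from_corner <- function(worse, better, pov = "must-be") {
  pov <- as_corner_pov(pov)
  check_in_square(worse, better)
  dx <- worse - pov$corner[["worse"]]
  dy <- better - pov$corner[["better"]]
  along <- dx * pov$reference[1L] + dy * pov$reference[2L]
  # perpendicular component always points into the square from the ray
  perp <- abs(dx * (-pov$reference[2L]) + dy * pov$reference[1L])
  ang <- atan2(perp, along) * 180 / pi
  ang[dx == 0 & dy == 0] <- 0
  if (any(ang > 90 + 1e-9)) {
    stop("angle outside [0, 90]: point not in the POV quadrant's field of view",
         call. = FALSE)
  }
  unname(pmin(ang, 90))
}

#' Ranking coefficient
#'
#' Combines distance and angle into the scalar used for ordering:
#' `f = d + (alpha / 90) * 0.05 * sqrt(2)`. The angle term is the angle
#' rescaled to at most 5% of the maximal in-square distance sqrt(2), so
#' it only discriminates between attributes of (nearly) equal distance,
#' never overturning a clear distance ordering. Smaller f is better.
#'
#' @param d Distance(s), non-negative.
#' @param alpha Angle(s) in degrees, in \[0, 90\].
#' @return Numeric coefficient(s).
#' @examples
#' ranking_coefficient(0.52, 0)    # 0.52: on the reference ray f equals d
#' ranking_coefficient(0.19, 70)
#' @export
ranking_coefficient <- function(d, alpha) {
  if (any(d < 0)) stop("'d' must be non-negative", call. = FALSE)
  if (any(alpha < 0 | alpha > 90)) stop("'alpha' must lie in [0, 90]", call. = FALSE)
  d + (alpha / 90) * 0.05 * sqrt(2)
}

#' Rank attributes from a corner point of view
#'
#' Computes distance, angle and ranking coefficient for every attribute
#' and assigns ranks 1..n by ascending coefficient. Exact ties keep the
#' input order and are flagged in the `tied` column.
#'
#' @param coords Data.frame with columns `attribute`, `worse`, `better`
#'   (signed convention), e.g. the weighted coordinates from
#'   [timko_indices()] renamed, or any coordinate table.
#' @param pov A [corner_pov] or corner name; default the must-be corner.
#' @return Object of class `kano_ranking`: data.frame with columns
#'   `attribute`, `worse`, `better`, `distance`, `angle`, `coefficient`,
#'   `rank`, `tied`, ordered as the input. Values at full precision.
#' @examples
#' tab <- data.frame(attribute = c("a", "b"),
#'                   worse = c(-0.8, -0.4), better = c(0.2, 0.3))
#' rank_attributes(tab)
#' @export
rank_attributes <- function(coords, pov = "must-be") {
  stopifnot(is.data.frame(coords),
            all(c("attribute", "worse", "better") %in% names(coords)))
  if (!nrow(coords)) stop("no attributes to rank", call. = FALSE)
  pov <- as_corner_pov(pov)
  d <- distance_to_corner(coords$worse, coords$better, pov)
  a <- angle_from_corner(coords$worse, coords$better, pov)
  f <- ranking_coefficient(d, a)
  out <- data.frame(attribute = as.character(coords$attribute),
                    worse = coords$worse, better = coords$better,
                    distance = unname(d), angle = unname(a),
                    coefficient = unname(f), stringsAsFactors = FALSE)
  # ties broken by input order (ties.method = "first"), reported explicitly
  out$rank <- rank(out$coefficient, ties.method = "first")
  out$tied <- duplicated(out$coefficient) | duplicated(out$coefficient, fromLast = TRUE)
  structure(out, class = c("kano_ranking", "data.frame"), pov = pov)
}

#' @export
print.kano_ranking <- function(x, digits = 2, ...) {
  pov <- attr(x, "pov")
  cat(sprintf("In-line-of-sight ranking from the %s corner (ascending f)\n",
              pov$name))
  shown <- data.frame(attribute = x$attribute,
                      d = round_half_up(x$distance, digits),
                      alpha = round_half_up(x$angle, 0),
                      f = round_half_up(x$coefficient, digits),
                      rank = x$rank)
  if (any(x$tied)) shown$tied <- ifelse(x$tied, "*", "")
  print(shown[order(shown$rank), ], row.names = FALSE)
  invisible(x)
}
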