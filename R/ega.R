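#' Clarke error grid zone of a CGM--reference pair
#'
#' Classifies (reference, measured) glucose pairs into the Clarke error grid
#' zones A--E using the standard published inequality set (implemented as
#' inequalities, not digitized polygons, to avoid digitization error):
#' zone A is agreement within 20% of the reference or both values in the
#' hypoglycemic range (<= 70 mg/dL); E is hypoglycemia read as hyperglycemia
#' or vice versa; C is overcorrection-inducing error; D is failure to detect
#' an out-of-range value; B is the benign remainder. Rules are evaluated in
#' the canonical order A, E, C, D, else B.
#'
#' @param pg Reference plasma glucose, mg/dL (vectorized).
#' @param cgm Measured/sensor glucose, mg/dL.
#' @return Character vector of zones `"A"`--`"E"`.
#' @export
#' @examples
#' clarke_zone(c(100, 50), c(110, 200)) # "A" "E"
clarke_zone <- function(pg, cgm) {
  if (length(pg) != length(cgm)) stop("pg and cgm length mismatch")
  if (any(is.na(pg)) || any(is.na(cgm)) || any(pg <= 0) || any(cgm <= 0))
    stop("glucose values must be positive and non-missing")
  zone <- rep("B", length(pg))
  a <- (pg <= 70 & cgm <= 70) | (cgm >= 0.8 * pg & cgm <= 1.2 * pg)
  e <- !a & ((pg >= 180 & cgm <= 70) | (pg <= 70 & cgm >= 180))
  c_ <- !a & !e & ((pg >= 70 & pg <= 290 & cgm >= pg + 110) |
                     (pg >= 130 & pg <= 180 & cgm <= 7 / 5 * pg - 182))
  d <- !a & !e & !c_ &
    ((pg >= 240 & cgm >= 70 & cgm <= 180) |
       (pg <= 175 / 3 & cgm >= 70 & cgm <= 180) |
       (pg >= 175 / 3 & pg <= 70 & cgm >= 6 / 5 * pg))
  zone[a] <- "A"; zone[e] <- "E"; zone[c_] <- "C"; zone[d] <- "D"
  zone
}

# Parkes boundary polylines, loaded once from the bundled vertex table.
parkes_env <- new.env(parent = emptyenv())

#' Parkes (consensus) grid boundary vertices
#'
#' The type-1 diabetes consensus error grid boundaries as polyline vertices,
#' shipped as a versioned data file
#' (`inst/extdata/parkes_grid_type1.csv`) so zone assignments are bit-stable
#' across releases. Each boundary separates two adjacent zones (e.g. `AB`
#' upper is the line above which a point is at least zone B on the
#' measured-too-high side).
#'
#' @param grid `"type1"`. The type-2 grid is not bundled.
#' @return Data frame `boundary`, `side`, `vertex`, `reference_mgdl`,
#'   `measured_mgdl`.
#' @export
parkes_vertices <- function(grid = c("type1", "type2")) {
  grid <- match.arg(grid)
  if (grid == "type2")
    stop("only the type 1 consensus grid vertex table is bundled")
  if (is.null(parkes_env$type1)) {
    path <- system.file("extdata", "parkes_grid_type1.csv", package = "ecgm",
                        mustWork = TRUE)
    parkes_env$type1 <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  parkes_env$type1
}

# Evaluate a boundary polyline as a function of reference glucose, extending
# the final segment's slope beyond the last vertex. Lower boundaries start
# with a vertical segment at x0; for x <= x0 they are undefined (no lower
# boundary there) and NA is returned.
polyline_y <- function(vx, vy, x) {
  if (vx[1] == vx[2]) {  # initial vertical segment (lower boundaries)
    vx <- vx[-1]; vy <- vy[-1]
    out <- rep(NA_real_, length(x))
    inside <- x > vx[1]
  } else {
    out <- rep(NA_real_, length(x))
    inside <- x >= vx[1]
  }
  k <- length(vx)
  y <- stats::approx(vx, vy, xout = pmin(x, vx[k]), rule = 2)$y
  slope <- (vy[k] - vy[k - 1]) / (vx[k] - vx[k - 1])
  beyond <- x > vx[k]
  y[beyond] <- vy[k] + slope * (x[beyond] - vx[k])
  out[inside] <- y[inside]
  out
}

#' Parkes (consensus) error grid zone
#'
#' Point-in-region assignment against the published type-1 consensus-grid
#' boundary polylines (see [parkes_vertices()]); the final boundary segments
#' are extended with their own slope beyond the last published vertex.
#' Points exactly on a boundary belong to the less severe zone. On the
#' measured-too-low side the most severe type-1 zone is D; E exists only on
#' the measured-too-high side.
#'
#' @inheritParams clarke_zone
#' @param grid Grid variant; only `"type1"` is bundled.
#' @return Character vector of zones `"A"`--`"E"`.
#' @export
#' @examples
#' parkes_zone(c(100, 50), c(105, 200)) # "A" "D"
parkes_zone <- function(pg, cgm, grid = c("type1", "type2")) {
  grid <- match.arg(grid)
  if (length(pg) != length(cgm)) stop("pg and cgm length mismatch")
  if (any(is.na(pg)) || any(is.na(cgm)) || any(pg <= 0) || any(cgm <= 0))
    stop("glucose values must be positive and non-missing")
  v <- parkes_vertices(grid)
  bnd <- function(boundary, side) {
    b <- v[v$boundary == boundary & v$side == side, ]
    polyline_y(b$reference_mgdl, b$measured_mgdl, pg)
  }
  above <- function(y) !is.na(y) & cgm > y
  below <- function(y) !is.na(y) & cgm < y
  sev_up <- above(bnd("AB", "upper")) + above(bnd("BC", "upper")) +
    above(bnd("CD", "upper")) + above(bnd("DE", "upper"))
  sev_lo <- below(bnd("AB", "lower")) + below(bnd("BC", "lower")) +
    below(bnd("CD", "lower"))
  c("A", "B", "C", "D", "E")[1 + pmax(sev_up, sev_lo)]
}

#' ISO 15197:2013 acceptance of a CGM--reference pair
#'
#' A measurement is acceptable when it is within +/-15 mg/dL of the
#' reference for references below 100 mg/dL, and within +/-15% at or above
#' 100 mg/dL. Comparisons are inclusive: a pair exactly on the band edge is
#' acceptable.
#'
#' @inheritParams clarke_zone
#' @return Logical vector.
#' @export
#' @examples
#' iso_acceptable(c(90, 90, 200), c(104, 106, 230)) # TRUE FALSE TRUE
iso_acceptable <- function(pg, cgm) {
  if (length(pg) != length(cgm)) stop("pg and cgm length mismatch")
  if (any(is.na(pg)) || any(pg <= 0))
    stop("reference glucose must be positive and non-missing")
  ifelse(pg < 100, abs(cgm - pg) <= 15, abs(cgm - pg) <= 0.15 * pg)
}

#' Zone summary table by period and source
#'
#' Percentage of paired samples per zone (Clarke or Parkes A--E, or ISO
#' OK/not-OK), split by trial period (exercise / rest / total) and by source
#' (original `cgm` vs enhanced `ecgm`, when present). Percentages are
#' rounded to one decimal. Periods with no pairs are omitted with a warning.
#'
#' @param pairs Data frame with columns `pg`, `cgm`, optionally `ecgm`, and
#'   `in_exercise`.
#' @param method `"clarke"`, `"parkes"` or `"iso"`.
#' @return Data frame `method`, `period`, `source`, `zone`, `pct`, `n`.
#' @export
zone_summary <- function(pairs, method = c("clarke", "parkes", "iso")) {
  method <- match.arg(method)
  stopifnot(all(c("pg", "cgm", "in_exercise") %in% names(pairs)),
            nrow(pairs) >= 1)
  classify <- switch(method,
                     clarke = function(pg, x) clarke_zone(pg, x),
                     parkes = function(pg, x) parkes_zone(pg, x),
                     iso = function(pg, x)
                       ifelse(iso_acceptable(pg, x), "OK", "not_OK"))
  levels <- if (method == "iso") c("OK", "not_OK") else c("A", "B", "C", "D", "E")
  sources <- intersect(c("cgm", "ecgm"), names(pairs))
  periods <- list(exercise = pairs$in_exercise, rest = !pairs$in_exercise,
                  total = rep(TRUE, nrow(pairs)))
  rows <- list()
  for (p in names(periods)) {
    sel <- periods[[p]]
    if (!any(sel)) {
      warning("no pairs in the ", p, " period; row omitted")
      next
    }
    for (src in sources) {
      z <- factor(classify(pairs$pg[sel], pairs[[src]][sel]), levels = levels)
      tab <- table(z)
      rows[[length(rows) + 1]] <-
        data.frame(method = method, period = p, source = src,
                   zone = levels, pct = round(100 * as.numeric(tab) / sum(tab), 1),
                   n = as.integer(tab), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
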