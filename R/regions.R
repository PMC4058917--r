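# Partition of the (transfer cost, loss cost) plane into equivalence
# regions.
#
# With duplication cost normalized to 1, the cost of a vector
# v = <delta, theta, l> at the point (x, y) = (C_transfer, C_loss) is the
# affine function delta + theta x + l y.  The region of v inside the user
# box is the set of points where v is no more expensive than any other
# front vector: an intersection of half-planes with the box, hence a convex
# polygon that may degenerate to a segment or a point.  All geometry is
# exact rational: degeneracy (the zero-area regions) is a knife-edge
# condition that floating point cannot decide.

#' A box of transfer and loss costs
#'
#' Bounds may be numerics or exact fraction strings (`"1/10"`); they are
#' held as exact rationals.  Duplication cost is fixed at 1.
#'
#' @param tmin,tmax transfer-cost range (relative to duplication cost 1).
#' @param lmin,lmax loss-cost range.
#' @return an object of class `cost_box`.
#' @export
cost_box <- function(tmin = 0.1, tmax = 5, lmin = 0.1, lmax = 5) {
  b <- list(tmin = as_rational(tmin), tmax = as_rational(tmax),
            lmin = as_rational(lmin), lmax = as_rational(lmax))
  if (b$tmin[1] <= 0 || b$lmin[1] <= 0)
    stop("cost box bounds must be strictly positive")
  if (r_lt(b$tmax, b$tmin) || r_lt(b$lmax, b$lmin))
    stop("cost box bounds must satisfy min <= max")
  structure(b, class = "cost_box")
}

#' @export
print.cost_box <- function(x, ...) {
  cat("Cost box: transfer [", r_str(x$tmin), ", ", r_str(x$tmax),
      "], loss [", r_str(x$lmin), ", ", r_str(x$lmax),
      "] (duplication = 1)\n", sep = "")
  invisible(x)
}

box_area <- function(box)
  r_mul(r_sub(box$tmax, box$tmin), r_sub(box$lmax, box$lmin))

box_polygon <- function(box) list(
  list(x = box$tmin, y = box$lmin),
  list(x = box$tmax, y = box$lmin),
  list(x = box$tmax, y = box$lmax),
  list(x = box$tmin, y = box$lmax))

# clip a convex polygon against the closed half-plane a + b x + c y <= 0
# (a, b, c exact rationals); Sutherland-Hodgman with exact intersections
clip_halfplane <- function(poly, a, b, c) {
  n <- length(poly)
  if (n == 0) return(poly)
  f <- vapply(poly, function(v)
    r_cmp(r_add(a, r_add(r_mul(b, v$x), r_mul(c, v$y))), r_zero()),
    numeric(1))
  out <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    vi <- poly[[i]]; vj <- poly[[j]]
    if (f[i] <= 0) out[[length(out) + 1L]] <- vi
    if ((f[i] < 0 && f[j] > 0) || (f[i] > 0 && f[j] < 0)) {
      fi <- r_add(a, r_add(r_mul(b, vi$x), r_mul(c, vi$y)))
      fj <- r_add(a, r_add(r_mul(b, vj$x), r_mul(c, vj$y)))
      t <- r_div(fi, r_sub(fi, fj))
      out[[length(out) + 1L]] <- list(
        x = r_add(vi$x, r_mul(t, r_sub(vj$x, vi$x))),
        y = r_add(vi$y, r_mul(t, r_sub(vj$y, vi$y))))
    }
  }
  # drop consecutive duplicate vertices
  if (length(out) > 1) {
    keep <- logical(length(out))
    for (i in seq_along(out)) {
      j <- if (i == length(out)) 1L else i + 1L
      keep[i] <- !(r_eq(out[[i]]$x, out[[j]]$x) && r_eq(out[[i]]$y, out[[j]]$y))
    }
    if (any(keep)) out <- out[keep] else out <- out[1]
  }
  out
}

poly_distinct <- function(poly) {
  if (length(poly) < 2) return(poly)
  keys <- vapply(poly, function(v) paste(r_str(v$x), r_str(v$y)), character(1))
  poly[!duplicated(keys)]
}

# signed shoelace area (rational); vertices in order
poly_area <- function(poly) {
  n <- length(poly)
  if (n < 3) return(r_zero())
  acc <- r_zero()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    acc <- r_add(acc, r_sub(r_mul(poly[[i]]$x, poly[[j]]$y),
                            r_mul(poly[[j]]$x, poly[[i]]$y)))
  }
  r_abs(r_div(acc, as_rational(2)))
}

#' Dimension and area of a region geometry
#'
#' Exact degeneracy test: a single point has dimension 0, a collinear
#' segment dimension 1 (area 0), a polygon of positive shoelace area
#' dimension 2.
#'
#' @param region a region record (from [cost_regions()]) or a list of
#'   vertices with rational `x`, `y`.
#' @return list with `dimension` (0, 1 or 2) and `area` (numeric, exact
#'   fraction as attribute).
#' @export
classify_region <- function(region) {
  poly <- if (!is.null(region$vertices)) region$vertices else region
  poly <- poly_distinct(poly)
  n <- length(poly)
  if (n == 0) return(list(dimension = NA_integer_,
                          area = structure(0, fraction = "0")))
  if (n == 1) return(list(dimension = 0L, area = structure(0, fraction = "0")))
  ar <- poly_area(poly)
  if (ar[1] == 0) return(list(dimension = 1L,
                              area = structure(0, fraction = "0")))
  list(dimension = 2L, area = structure(r_num(ar), fraction = r_str(ar)))
}

# reduce a degenerate (zero-area) vertex set to its extreme points
segment_endpoints <- function(poly) {
  if (length(poly) <= 2) return(poly)
  ord <- order(vapply(poly, function(v) r_num(v$x), numeric(1)),
               vapply(poly, function(v) r_num(v$y), numeric(1)))
  poly[c(ord[1], ord[length(ord)])]
}

#' Partition a cost box into equivalence regions
#'
#' For every Pareto-optimal event count vector `v`, computes the region of
#' the box where `v` is cost-optimal, by clipping the box against the
#' half-plane of every competing vector.  Regions are closed, so boundary
#' points belong to every touching region; vectors optimal nowhere in the
#' box are dropped from the region list but reported separately.  Regions
#' inherit the vector's reconciliation count and common-event set and are
#' sorted by area, largest first.
#'
#' @param x a `pareto_recon` fit (or a `recon_input`, which is fitted
#'   first).
#' @param box a [cost_box()].
#' @return an object of class `cost_regions`: list of region records
#'   (`vector`, `speciations`, `count`, `events`, `vertices`, `dimension`,
#'   `area`), with the box, the front and the out-of-box vectors attached
#'   as attributes.
#' @examples
#' reg <- cost_regions(pareto_reconcile(fig1_instance()), cost_box(0.1, 5, 0.1, 5))
#' summary(reg)
#' @export
cost_regions <- function(x, box = cost_box()) {
  if (inherits(x, "recon_input")) x <- pareto_reconcile(x)
  if (!inherits(x, "pareto_recon")) stop("x must be a pareto_recon fit")
  front <- x$front
  k <- front_size(front)
  if (k == 0) stop("empty front")
  m <- x$input$gene$n_tip
  regions <- list()
  empties <- matrix(numeric(0), 0, 3)
  for (i in seq_len(k)) {
    poly <- box_polygon(box)
    for (j in seq_len(k)) {
      if (i == j) next
      dv <- front$vec[i, ] - front$vec[j, ]
      poly <- clip_halfplane(poly, as_rational(dv[1]), as_rational(dv[2]),
                             as_rational(dv[3]))
      if (length(poly) == 0) break
    }
    poly <- poly_distinct(poly)
    if (length(poly) == 0) {
      empties <- rbind(empties, front$vec[i, ])
      next
    }
    cls <- classify_region(poly)
    if (cls$dimension == 1L) poly <- segment_endpoints(poly)
    regions[[length(regions) + 1L]] <- list(
      vector = front$vec[i, ],
      speciations = (m - 1) - front$vec[i, 1] - front$vec[i, 2],
      count = if (!is.null(front$count)) front$count[i] else NA_real_,
      events = if (!is.null(front$events)) front$events[[i]] else NULL,
      vertices = poly,
      dimension = cls$dimension,
      area = cls$area)
  }
  ord <- order(-vapply(regions, function(r) as.numeric(r$area), numeric(1)),
               vapply(regions, function(r) paste(r$vector, collapse = ","),
                      character(1)))
  structure(regions[ord], class = "cost_regions", box = box,
            fit = x, empty_vectors = empties)
}

#' Optimal vectors at one cost point
#'
#' The argmin set of the reconciliation cost over the front at an exact
#' point; on a region boundary several vectors tie.
#'
#' @param x a `pareto_recon` fit.
#' @param point `c(transfer_cost, loss_cost)`, numerics or fraction strings.
#' @return matrix of the optimal event count vectors.
#' @export
locate_point <- function(x, point) {
  if (!inherits(x, "pareto_recon")) stop("x must be a pareto_recon fit")
  px <- as_rational(point[[1]]); py <- as_rational(point[[2]])
  if (px[1] <= 0 || py[1] <= 0) stop("cost point must be strictly positive")
  costs <- event_costs(transfer = r_str(px), loss = r_str(py))
  vec <- x$front$vec
  cs <- lapply(seq_len(nrow(vec)), function(i) cost_rational(vec[i, ], costs))
  best <- Reduce(function(a, b) if (r_le(a, b)) a else b, cs)
  opt <- vapply(cs, function(c) r_eq(c, best), logical(1))
  v <- vec[opt, , drop = FALSE]
  colnames(v) <- c("duplications", "transfers", "losses")
  v
}

#' @export
print.cost_regions <- function(x, ...) {
  nz <- sum(vapply(x, function(r) r$dimension < 2L, logical(1)))
  cat("Cost-space partition:", length(x), "regions (",
      nz, "with zero area ) in box ", sep = " ")
  print(attr(x, "box"))
  invisible(x)
}

#' @export
summary.cost_regions <- function(object, ...) {
  df <- data.frame(
    duplications = vapply(object, function(r) r$vector[1], numeric(1)),
    transfers = vapply(object, function(r) r$vector[2], numeric(1)),
    losses = vapply(object, function(r) r$vector[3], numeric(1)),
    speciations = vapply(object, function(r) r$speciations, numeric(1)),
    count = vapply(object, function(r) r$count, numeric(1)),
    dimension = vapply(object, function(r) r$dimension, integer(1)),
    area = vapply(object, function(r) as.numeric(r$area), numeric(1)),
    area_exact = vapply(object, function(r) attr(r$area, "fraction"),
                        character(1)))
  structure(list(table = df, box = attr(object, "box"),
                 empty = attr(object, "empty_vectors")),
            class = "summary.cost_regions")
}

#' @export
print.summary.cost_regions <- function(x, ...) {
  print(x$box)
  print(x$table, row.names = FALSE)
  if (nrow(x$empty))
    cat(nrow(x$empty), "front vector(s) optimal only outside the box\n")
  invisible(x)
}

#' @export
plot.cost_regions <- function(x, col = NULL, legend = TRUE, ...) {
  box <- attr(x, "box")
  if (is.null(col))
    col <- grDevices::hcl.colors(max(length(x), 2), "Set 3")[seq_along(x)]
  graphics::plot(NA, xlim = c(r_num(box$tmin), r_num(box$tmax)),
                 ylim = c(r_num(box$lmin), r_num(box$lmax)),
                 xlab = "transfer cost", ylab = "loss cost",
                 main = "Pareto-optimal regions", ...)
  lab <- character(length(x))
  for (i in seq_along(x)) {
    r <- x[[i]]
    vx <- vapply(r$vertices, function(v) r_num(v$x), numeric(1))
    vy <- vapply(r$vertices, function(v) r_num(v$y), numeric(1))
    if (r$dimension == 2L)
      graphics::polygon(vx, vy, col = col[i], border = "grey30")
    else if (r$dimension == 1L)
      graphics::lines(vx, vy, col = col[i], lwd = 3)
    else
      graphics::points(vx, vy, col = col[i], pch = 19)
    lab[i] <- sprintf("%ds %dd %dt %dl (count %s)", r$speciations,
                      r$vector[1], r$vector[2], r$vector[3],
                      format(r$count))
  }
  if (legend)
    graphics::legend("topright", legend = lab, fill = col, cex = 0.7,
                     bg = "white")
  invisible(x)
}
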