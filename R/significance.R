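# Permutation significance of reconciliation cost across the cost box.
#
# The null hypothesis is that the congruence between the two trees is no
# better than expected for random tip associations.  The observed Pareto
# front and one front per permuted mapping are computed once; each grid
# cell (a cost point) then only needs the minimum front cost, so N
# permutations serve every cell.  Cell costs are evaluated in
# integer-scaled arithmetic (the common denominator of all cell
# coordinates is cleared), making the permuted-vs-observed comparisons
# exact.

#' Permute the tip associations of an instance
#'
#' `"shuffle"` permutes the observed species targets among the gene tips,
#' preserving the per-species tip counts; `"uniform"` redraws each gene
#' tip's target uniformly from the species tips.  Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param input a `recon_input`.
#' @param mode `"shuffle"` (default) or `"uniform"`.
#' @return a new `recon_input` with the same trees.
#' @export
permute_mapping <- function(input, mode = c("shuffle", "uniform")) {
  mode <- match.arg(mode)
  m <- input$mapping
  g <- names(m)
  new_targets <- if (mode == "shuffle") {
    sample(unname(m))
  } else {
    sl <- input$species$labels[input$species$is_tip]
    sample(sl, length(m), replace = TRUE)
  }
  recon_input(input$gene, input$species, stats::setNames(new_targets, g))
}

# exact integer-scaled cell-center coordinates: centers of g cells per axis
grid_centers <- function(lo, hi, g) {
  w <- r_div(r_sub(hi, lo), as_rational(g))
  lapply(seq_len(g), function(i)
    r_add(lo, r_mul(w, r_div(as_rational(2 * i - 1), as_rational(2)))))
}

#' Permutation significance map over a cost box
#'
#' For each of `grid` x `grid` cell centers, compares the observed minimum
#' reconciliation cost against the minima of `n_perm` permuted instances
#' and reports the add-one permutation p-value
#' `(1 + #\{permuted <= observed\}) / (n_perm + 1)`.
#'
#' @param input a `recon_input`.
#' @param box a [cost_box()].
#' @param grid cells per axis (default 100).
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed driving all permutations.
#' @param mode permutation null, see [permute_mapping()].
#' @return an object of class `sig_grid`: p-value matrix (`grid` x `grid`,
#'   rows = transfer axis, columns = loss axis), cell-center coordinates,
#'   and the run parameters.
#' @examples
#' g <- significance_grid(fig1_instance(), cost_box(0.5, 2, 0.5, 2),
#'                        grid = 4, n_perm = 19, seed = 1)
#' area_fractions(g)
#' @export
significance_grid <- function(input, box = cost_box(), grid = 100,
                              n_perm = 1000, seed = 1,
                              mode = c("shuffle", "uniform")) {
  mode <- match.arg(mode)
  stopifnot(grid >= 1, n_perm >= 1)
  set.seed(seed)
  xc <- grid_centers(box$tmin, box$tmax, grid)
  yc <- grid_centers(box$lmin, box$lmax, grid)
  dens <- vapply(c(xc, yc), function(r) r[2], numeric(1))
  D <- Reduce(r_lcm, unique(dens))
  X <- vapply(xc, function(r) r[1] * (D / r[2]), numeric(1))
  Y <- vapply(yc, function(r) r[1] * (D / r[2]), numeric(1))
  # cells in column-major order of the (transfer, loss) matrix
  A <- cbind(D, rep(X, times = grid), rep(Y, each = grid))
  front_mins <- function(front) {
    v <- front$vec
    do.call(pmin, lapply(seq_len(nrow(v)), function(i)
      as.vector(A %*% v[i, ])))
  }
  obs <- front_mins(pareto_reconcile(input, events = FALSE)$front)
  r <- numeric(length(obs))
  for (i in seq_len(n_perm)) {
    perm <- permute_mapping(input, mode)
    pm <- front_mins(pareto_reconcile(perm, events = FALSE)$front)
    r <- r + (pm <= obs)
  }
  p <- matrix((1 + r) / (n_perm + 1), grid, grid)
  structure(list(p = p,
                 transfer_centers = vapply(xc, r_num, numeric(1)),
                 loss_centers = vapply(yc, r_num, numeric(1)),
                 grid = grid, n_perm = n_perm, seed = seed, mode = mode,
                 box = box),
            class = "sig_grid")
}

#' Fractions of the cost space by significance class
#'
#' Splits the grid cells into p below the first threshold, between the
#' thresholds, and at or above the second; the three fractions sum to 1.
#'
#' @param grid a `sig_grid`.
#' @param thresholds two increasing p-value cutoffs (default 0.01, 0.05).
#' @return named numeric vector of three fractions.
#' @export
area_fractions <- function(grid, thresholds = c(0.01, 0.05)) {
  stopifnot(inherits(grid, "sig_grid"), length(thresholds) == 2,
            thresholds[1] < thresholds[2])
  p <- grid$p
  n <- length(p)
  out <- c(sum(p < thresholds[1]),
           sum(p >= thresholds[1] & p < thresholds[2]),
           sum(p >= thresholds[2])) / n
  names(out) <- c(paste0("p<", thresholds[1]),
                  paste0(thresholds[1], "<=p<", thresholds[2]),
                  paste0("p>=", thresholds[2]))
  out
}

#' @export
print.sig_grid <- function(x, ...) {
  cat("Permutation significance map: ", x$grid, "x", x$grid, " cells, ",
      x$n_perm, " permutations (mode '", x$mode, "', seed ", x$seed,
      ")\n", sep = "")
  fr <- area_fractions(x)
  cat(sprintf("  %s: %.1f%%   %s: %.1f%%   %s: %.1f%%\n",
              names(fr)[1], 100 * fr[1], names(fr)[2], 100 * fr[2],
              names(fr)[3], 100 * fr[3]))
  invisible(x)
}

#' @export
plot.sig_grid <- function(x, thresholds = c(0.01, 0.05), ...) {
  # class hue (significant / borderline / not), brightness by -log10(p)
  p <- x$p
  cls <- 1L + (p >= thresholds[1]) + (p >= thresholds[2])
  bright <- pmin(-log10(p) / max(-log10(p), 1e-9), 1)
  base <- c("#00AA00", "#DDCC00", "#CC0000")
  cols <- matrix("", nrow(p), ncol(p))
  for (idx in seq_along(p)) {
    cv <- grDevices::col2rgb(base[cls[idx]])[, 1] / 255
    w <- 0.5 * (1 - bright[idx])      # wash low-significance cells out
    cv <- cv + (1 - cv) * w
    cols[idx] <- grDevices::rgb(cv[1], cv[2], cv[3])
  }
  graphics::plot(NA, xlim = range(x$transfer_centers),
                 ylim = range(x$loss_centers),
                 xlab = "transfer cost", ylab = "loss cost",
                 main = "Permutation significance", ...)
  wx <- diff(x$transfer_centers[1:2] %||% c(0, 1)) / 2
  wy <- diff(x$loss_centers[1:2] %||% c(0, 1)) / 2
  if (x$grid == 1) { wx <- 0.5; wy <- 0.5 }
  for (i in seq_len(nrow(p)))
    for (j in seq_len(ncol(p)))
      graphics::rect(x$transfer_centers[i] - wx, x$loss_centers[j] - wy,
                     x$transfer_centers[i] + wx, x$loss_centers[j] + wy,
                     col = cols[i, j], border = NA)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a) || anyNA(a)) b else a
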