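# Event consensus across the cost-space regions.
#
# Inside a region every maximum-parsimony reconciliation achieves the
# region's event count vector, so the events common to all reconciliations
# in the region are exactly the common-event annotation of that vector.
# Collecting these sets across regions gives (i) the partition of events by
# the number of regions they are common in, and (ii) consensus support:
# the fraction of regions (or of box area) in which an event occurs in
# every reconciliation.

#' Common events per region
#'
#' @param regions a `cost_regions` object fitted with event tracking.
#' @return named list: one sorted character vector of event keys per region,
#'   named by the region's event count vector.
#' @export
region_event_table <- function(regions) {
  if (!inherits(regions, "cost_regions")) stop("regions must be cost_regions")
  if (any(vapply(regions, function(r) is.null(r$events), logical(1))))
    stop("regions carry no event annotations; refit with events = TRUE")
  out <- lapply(regions, function(r) sort(r$events))
  names(out) <- vapply(regions, function(r)
    paste0("<", paste(r$vector, collapse = ","), ">"), character(1))
  out
}

#' Partition events by the number of regions sharing them
#'
#' @param regions a `cost_regions` object with event annotations.
#' @return list indexed `k = 1..K`: the events common to every
#'   reconciliation in exactly `k` regions.  Buckets are disjoint and union
#'   to all common events.
#' @export
partition_by_region_count <- function(regions) {
  tab <- region_event_table(regions)
  all_ev <- unlist(tab, use.names = FALSE)
  cnt <- table(all_ev)
  out <- vector("list", length(tab))
  for (k in seq_along(out))
    out[[k]] <- sort(names(cnt)[cnt == k])
  names(out) <- seq_along(out)
  out
}

#' Consensus support of events across the cost space
#'
#' An event has region-fraction support `s` if it is common to every
#' reconciliation in a fraction `s` of the regions; area-fraction support
#' replaces the region count by the fraction of box area covered
#' (zero-area regions then contribute nothing).  Zero-area regions count as
#' full regions for the region fraction.
#'
#' @param regions a `cost_regions` object with event annotations.
#' @param measure which fraction fills the `support` column
#'   (both are always reported).
#' @return a data frame of class `support_table`: one row per event with
#'   `event`, `type`, `n_regions`, `region_fraction`, `area_fraction`,
#'   `support` and a readable `description`.
#' @export
consensus_support <- function(regions,
                              measure = c("region_fraction", "area_fraction")) {
  measure <- match.arg(measure)
  tab <- region_event_table(regions)
  n_reg <- length(tab)
  areas <- lapply(regions, function(r) as_rational(attr(r$area, "fraction")))
  tot <- box_area(attr(regions, "box"))
  events <- sort(unique(unlist(tab, use.names = FALSE)))
  n_in <- integer(length(events))
  afrac <- numeric(length(events))
  for (i in seq_along(events)) {
    inreg <- vapply(tab, function(e) events[i] %in% e, logical(1))
    n_in[i] <- sum(inreg)
    cover <- r_sum(areas[inreg])
    afrac[i] <- if (tot[1] == 0) 0 else r_num(r_div(cover, tot))
  }
  type <- c(S = "speciation", D = "duplication", T = "transfer",
            L = "loss")[substr(events, 1, 1)]
  df <- data.frame(event = events, type = unname(type),
                   n_regions = n_in,
                   region_fraction = n_in / n_reg,
                   area_fraction = afrac,
                   stringsAsFactors = FALSE)
  df$support <- df[[measure]]
  fit <- attr(regions, "fit")
  df$description <- describe_events(fit$input, df$event)
  df <- df[order(-df$support, df$event), ]
  rownames(df) <- NULL
  structure(df, class = c("support_table", "data.frame"),
            measure = measure, n_regions = n_reg)
}

#' @export
print.support_table <- function(x, ...) {
  cat("Event consensus support over", attr(x, "n_regions"),
      "regions (measure:", attr(x, "measure"), ")\n")
  print.data.frame(x[, c("type", "n_regions", "region_fraction",
                         "area_fraction", "description")],
                   row.names = FALSE, digits = 3)
  invisible(x)
}

#' Number of events supported at or above each threshold
#'
#' The step function behind support-profile plots: for each threshold `s`,
#' how many events have consensus support at least `s`.  Non-increasing in
#' `s` by construction.
#'
#' @param support a `support_table`.
#' @param thresholds numeric vector of support levels in `[0, 1]`.
#' @param measure which support measure to threshold.
#' @return data frame with `threshold` and `n_events`.
#' @export
support_curve <- function(support, thresholds = seq(0, 1, by = 0.05),
                          measure = c("region_fraction", "area_fraction")) {
  measure <- match.arg(measure)
  s <- support[[measure]]
  data.frame(threshold = thresholds,
             n_events = vapply(thresholds, function(t) sum(s >= t),
                               numeric(1)))
}
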