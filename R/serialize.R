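# Result serialization: JSON (canonical, round-trippable) and CSV.
#
# Vectors are rendered as [delta, theta, loss]; region vertices as exact
# fraction strings "p/q" so that nothing is lost to binary floating point.

#' Serialize analysis results to JSON or CSV
#'
#' Methods exist for Pareto fronts (`pareto_recon`), region partitions
#' (`cost_regions`), significance maps (`sig_grid`) and support tables.
#' JSON output for a front round-trips through [read_front_json()].
#'
#' @param x a result object produced by this package.
#' @param format `"json"` or `"csv"`.
#' @return a character scalar (the serialized text).
#' @export
serialize_results <- function(x, format = c("json", "csv")) {
  format <- match.arg(format)
  UseMethod("serialize_results")
}

#' @export
serialize_results.default <- function(x, format = c("json", "csv")) {
  stop("no serializer for objects of class ", paste(class(x), collapse = "/"))
}

#' @export
serialize_results.pareto_recon <- function(x, format = c("json", "csv")) {
  format <- match.arg(format)
  front <- x$front
  k <- front_size(front)
  if (format == "json") {
    recs <- lapply(seq_len(k), function(i) {
      r <- list(vector = as.numeric(front$vec[i, ]))
      if (!is.null(front$count)) r$count <- front$count[i]
      if (!is.null(front$events)) r$events <- as.list(sort(front$events[[i]]))
      r
    })
    as.character(jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA))
  } else {
    df <- data.frame(duplications = front$vec[, 1],
                     transfers = front$vec[, 2],
                     losses = front$vec[, 3])
    if (!is.null(front$count)) df$count <- front$count
    if (!is.null(front$events))
      df$events <- vapply(front$events,
                          function(e) paste(sort(e), collapse = ";"),
                          character(1))
    csv_string(df)
  }
}

#' Rebuild an annotated front from its JSON serialization
#'
#' @param text JSON produced by [serialize_results()] on a `pareto_recon`.
#' @return an annotated front (`vec`, `count`, `events`), comparable to
#'   `fit$front`.
#' @export
read_front_json <- function(text) {
  recs <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  vec <- do.call(rbind, lapply(recs, function(r) as.numeric(unlist(r$vector))))
  if (is.null(vec)) vec <- matrix(numeric(0), 0, 3)
  counts <- vapply(recs, function(r) r$count %||% NA_real_, numeric(1))
  has_ev <- length(recs) > 0 && !is.null(recs[[1]]$events)
  events <- if (has_ev)
    lapply(recs, function(r) as.character(unlist(r$events)))
  else NULL
  annotated_front(vec, counts = if (all(is.na(counts))) NULL else counts,
                  events = events)
}

#' @export
serialize_results.cost_regions <- function(x, format = c("json", "csv")) {
  format <- match.arg(format)
  recs <- lapply(unclass(x), function(r) {
    list(vector = as.numeric(r$vector),
         speciations = r$speciations,
         count = r$count,
         dimension = r$dimension,
         area = attr(r$area, "fraction"),
         area_value = as.numeric(r$area),
         vertices = lapply(r$vertices, function(v) c(r_str(v$x), r_str(v$y))),
         events = as.list(sort(r$events %||% character(0))))
  })
  if (format == "json")
    return(as.character(jsonlite::toJSON(recs, auto_unbox = TRUE,
                                         digits = NA)))
  df <- data.frame(
    duplications = vapply(recs, function(r) r$vector[1], numeric(1)),
    transfers = vapply(recs, function(r) r$vector[2], numeric(1)),
    losses = vapply(recs, function(r) r$vector[3], numeric(1)),
    speciations = vapply(recs, function(r) r$speciations, numeric(1)),
    count = vapply(recs, function(r) r$count, numeric(1)),
    dimension = vapply(recs, function(r) r$dimension, integer(1)),
    area = vapply(recs, function(r) r$area, character(1)),
    area_value = vapply(recs, function(r) r$area_value, numeric(1)),
    vertices = vapply(recs, function(r)
      paste(vapply(r$vertices, paste, character(1), collapse = " "),
            collapse = ";"), character(1)))
  csv_string(df)
}

#' @export
serialize_results.sig_grid <- function(x, format = c("json", "csv")) {
  format <- match.arg(format)
  cells <- expand.grid(i = seq_len(x$grid), j = seq_len(x$grid))
  df <- data.frame(transfer_cost = x$transfer_centers[cells$i],
                   loss_cost = x$loss_centers[cells$j],
                   p = x$p[cbind(cells$i, cells$j)])
  if (format == "json") {
    obj <- list(grid = x$grid, n_perm = x$n_perm, seed = x$seed,
                mode = x$mode, cells = df)
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                         digits = NA, dataframe = "rows")))
  }
  csv_string(df)
}

#' @export
serialize_results.support_table <- function(x, format = c("json", "csv")) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  if (format == "json")
    return(as.character(jsonlite::toJSON(df, auto_unbox = TRUE, digits = NA,
                                         dataframe = "rows")))
  csv_string(df)
}

csv_string <- function(df) {
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  paste0(paste(out, collapse = "\n"), "\n")
}
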