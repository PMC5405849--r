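# Object morphometry (label splitter / label statistics): per-connected-
# object metrics on a chosen feature channel, rule-based reclassification,
# and CSV export.

#' Per-object morphometry table
#'
#' Finds the maximal connected components of one label and computes, for
#' each object: voxel count, bounding box (0-based, half-open), centroid,
#' and the mean, variance and standard deviation of a chosen channel
#' inside the object. Variance is the population variance (so a
#' single-voxel object has sd 0). Rows are ordered by decreasing voxel
#' count, then centroid (z, y, x); metrics are invariant to object id
#' renumbering.
#'
#' @param labels_grid 3D integer label grid.
#' @param label label id to analyse; an absent label yields an empty table.
#' @param channel 3D numeric array (feature channel or raw data).
#' @param connectivity object connectivity: 6, 18 or 26 (default).
#' @return An `object_table` data.frame.
#' @export
object_stats <- function(labels_grid, label, channel, connectivity = 26L) {
  channel <- as_array3d(channel, "channel")
  d <- dim(labels_grid)
  stopifnot(identical(d, dim(channel)))
  mask <- labels_grid == label
  empty <- data.frame(object_id = integer(), label = integer(),
                      voxel_count = integer(),
                      zmin = integer(), zmax = integer(), ymin = integer(),
                      ymax = integer(), xmin = integer(), xmax = integer(),
                      bbox_z = integer(), bbox_y = integer(), bbox_x = integer(),
                      centroid_z = numeric(), centroid_y = numeric(),
                      centroid_x = numeric(), avg_intensity = numeric(),
                      intensity_variance = numeric(), intensity_std = numeric())
  if (!any(mask)) return(structure(empty, class = c("object_table", "data.frame")))
  comp <- array(cpp_connected_components(as.vector(mask), d, as.integer(connectivity)), d)
  ids <- seq_len(max(comp))
  idx <- which(comp > 0)
  ci <- comp[idx]
  z <- ((idx - 1L) %% d[1])
  y <- (((idx - 1L) %/% d[1]) %% d[2])
  x <- ((idx - 1L) %/% (d[1] * d[2]))
  val <- channel[idx]
  n <- tabulate(ci, nbins = length(ids))
  cif <- factor(ci, levels = ids)
  agg <- function(v) rowsum_at(v, ci, length(ids))
  mins <- function(v) vapply(split(v, cif), min, numeric(1))
  maxs <- function(v) vapply(split(v, cif), max, numeric(1))
  s1 <- agg(val)
  s2 <- agg(val^2)
  mu <- s1 / n
  varp <- pmax(s2 / n - mu^2, 0)
  tab <- data.frame(
    object_id = ids, label = label, voxel_count = n,
    zmin = as.integer(mins(z)), zmax = as.integer(maxs(z)) + 1L,
    ymin = as.integer(mins(y)), ymax = as.integer(maxs(y)) + 1L,
    xmin = as.integer(mins(x)), xmax = as.integer(maxs(x)) + 1L,
    centroid_z = agg(z) / n, centroid_y = agg(y) / n, centroid_x = agg(x) / n,
    avg_intensity = mu, intensity_variance = varp, intensity_std = sqrt(varp))
  tab$bbox_z <- tab$zmax - tab$zmin
  tab$bbox_y <- tab$ymax - tab$ymin
  tab$bbox_x <- tab$xmax - tab$xmin
  ord <- order(-tab$voxel_count, tab$centroid_z, tab$centroid_y, tab$centroid_x)
  tab <- tab[ord, c("object_id", "label", "voxel_count",
                    "zmin", "zmax", "ymin", "ymax", "xmin", "xmax",
                    "bbox_z", "bbox_y", "bbox_x",
                    "centroid_z", "centroid_y", "centroid_x",
                    "avg_intensity", "intensity_variance", "intensity_std")]
  rownames(tab) <- NULL
  attr(tab, "components") <- comp
  structure(tab, class = c("object_table", "data.frame"))
}

# one rule: list(metric, op in c("<","<=",">",">=","=="), value)
check_rules <- function(rules, metrics) {
  ops <- c("<", "<=", ">", ">=", "==")
  lo <- -Inf; hi <- Inf; by_metric <- list()
  for (r in rules) {
    if (!r$metric %in% metrics)
      stop("rule references unknown metric: ", r$metric)
    if (!r$op %in% ops) stop("unknown comparator: ", r$op)
    b <- by_metric[[r$metric]] %||% c(-Inf, Inf)
    if (r$op %in% c(">", ">=")) b[1] <- max(b[1], r$value)
    if (r$op %in% c("<", "<=")) b[2] <- min(b[2], r$value)
    if (r$op == "==") { b[1] <- max(b[1], r$value); b[2] <- min(b[2], r$value) }
    if (b[1] > b[2])
      stop("contradictory rule on metric ", r$metric, " (min > max)")
    by_metric[[r$metric]] <- b
  }
  invisible(TRUE)
}

#' Rule-based object classification (label splitter)
#'
#' Each class is an AND-chain of threshold rules on object metrics; the
#' first matching class (in declared order) wins and unmatched objects
#' retain their source label. Contradictory rule sets (an empty interval
#' on some metric) are rejected at parse time.
#'
#' @param t an [object_stats()] table.
#' @param classes named list; each element is a list of rules
#'   `list(metric =, op =, value =)` combined with AND.
#' @return Character vector over table rows: class name or `NA` (retain
#'   source label).
#' @export
apply_rules <- function(t, classes) {
  metrics <- names(t)[vapply(t, is.numeric, TRUE)]
  for (cl in classes) check_rules(cl, metrics)
  out <- rep(NA_character_, nrow(t))
  for (nm in names(classes)) {
    match_cl <- rep(TRUE, nrow(t))
    for (r in classes[[nm]]) {
      v <- t[[r$metric]]
      match_cl <- match_cl & switch(r$op,
        "<" = v < r$value, "<=" = v <= r$value,
        ">" = v > r$value, ">=" = v >= r$value,
        "==" = v == r$value)
    }
    out[is.na(out) & match_cl] <- nm
  }
  out
}

#' Write class assignments back to a label grid
#'
#' Objects assigned to a class receive that class's new label id;
#' unmatched objects keep the source label. Recombining all outputs
#' reproduces the source label's voxel set exactly.
#'
#' @param t an [object_stats()] table (must carry its component grid).
#' @param assignment result of [apply_rules()].
#' @param class_labels named integer vector: class name -> new label id.
#' @param labels_grid the source label grid.
#' @return 3D integer label grid with split labels.
#' @export
split_labels <- function(t, assignment, class_labels, labels_grid) {
  comp <- attr(t, "components")
  if (is.null(comp)) stop("object table lacks its component grid")
  out <- labels_grid
  for (i in seq_len(nrow(t))) {
    if (is.na(assignment[i])) next
    new_id <- class_labels[[assignment[i]]]
    out[comp == t$object_id[i]] <- as.integer(new_id)
  }
  out
}

#' Export object statistics as CSV
#'
#' Writes the full metric table (lossless round trip via [read.csv()]) and
#' returns a per-class summary (object count and size quantiles).
#'
#' @param t an [object_stats()] table.
#' @param path output CSV path for the metrics table.
#' @param assignment optional [apply_rules()] result used for grouping;
#'   default groups everything under its source label.
#' @param summary_path optional path for the summary CSV.
#' @return The summary data.frame, invisibly.
#' @export
export_statistics <- function(t, path, assignment = NULL, summary_path = NULL) {
  tt <- as.data.frame(t)
  attr(tt, "components") <- NULL
  write.csv(tt, path, row.names = FALSE)
  grp <- if (is.null(assignment)) as.character(tt$label) else
    ifelse(is.na(assignment), as.character(tt$label), assignment)
  if (nrow(tt)) {
    qs <- t(vapply(split(tt$voxel_count, grp),
                   function(v) quantile(v, c(0, .25, .5, .75, 1)),
                   numeric(5)))
    summ <- data.frame(class = rownames(qs),
                       n_objects = as.integer(table(grp)[rownames(qs)]),
                       size_min = qs[, 1], size_q25 = qs[, 2],
                       size_median = qs[, 3], size_q75 = qs[, 4],
                       size_max = qs[, 5], row.names = NULL)
  } else {
    summ <- data.frame(class = character(), n_objects = integer(),
                       size_min = numeric(), size_q25 = numeric(),
                       size_median = numeric(), size_q75 = numeric(),
                       size_max = numeric())
  }
  if (!is.null(summary_path)) write.csv(summ, summary_path, row.names = FALSE)
  invisible(summ)
}
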