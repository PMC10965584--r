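#' Compose annual ALAN rasters from two product versions
#'
#' Cell-wise arithmetic mean of the Version-1 and Version-2 annual radiance
#' composites, with pass-through modes for sensitivity analyses that use a
#' single version.
#'
#' @param v1,v2 co-registered numeric matrices.
#' @param mode `"mean"` (default), `"v1-only"`, or `"v2-only"`.
#' @return A matrix on the shared grid.
#' @export
compose_alan <- function(v1, v2, mode = c("mean", "v1-only", "v2-only")) {
  mode <- match.arg(mode)
  if (!identical(dim(v1), dim(v2)))
    stop("rasters are not co-registered: dims ",
         paste(dim(v1), collapse = "x"), " vs ",
         paste(dim(v2), collapse = "x"))
  switch(mode, "mean" = (v1 + v2) / 2, "v1-only" = v1, "v2-only" = v2)
}

#' Per-cell modal land-cover class across years
#'
#' Classifies each cell by its most frequent class over the supplied years.
#' Ties are broken toward the most recent year holding a tied class.
#'
#' @param class_rasters list of integer/character class matrices, one per
#'   year, in chronological order.
#' @param years optional numeric year labels (defaults to the list order).
#' @return A matrix of modal classes.
#' @export
mode_composite <- function(class_rasters, years = seq_along(class_rasters)) {
  if (length(class_rasters) == 0) stop("no class rasters supplied")
  dims <- lapply(class_rasters, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("class rasters are not on a shared grid")
  if (length(class_rasters) == 1) return(class_rasters[[1]])
  ord <- order(years)
  class_rasters <- class_rasters[ord]
  classes <- sort(unique(unlist(lapply(class_rasters, as.vector))))
  ncell <- length(class_rasters[[1]])
  count <- matrix(0L, length(classes), ncell)
  last <- matrix(0L, length(classes), ncell)  # recency index of last use
  for (t in seq_along(class_rasters)) {
    m <- match(as.vector(class_rasters[[t]]), classes)
    idx <- cbind(m, seq_len(ncell))
    count[idx] <- count[idx] + 1L
    last[idx] <- t
  }
  # lexicographic (count, recency) argmax
  score <- count * (length(class_rasters) + 1L) + last
  win <- max.col(t(score), ties.method = "first")
  matrix(classes[win], nrow(class_rasters[[1]]), ncol(class_rasters[[1]]))
}

#' Gap-fill a land-cover classification with a secondary inventory
#'
#' Cells carrying one of the primary product's classes keep that class;
#' remaining cells take the secondary product's class. Cells classified by
#' neither get an all-zero indicator (documented: such cells count as "no
#' cover" in every class). Returns one 0/1 indicator raster per final
#' class, from which buffer means yield proportion covers.
#'
#' @param primary,secondary class matrices on a shared grid.
#' @param primary_classes classes honoured in `primary`.
#' @param secondary_classes classes honoured in `secondary`.
#' @return Named list of 0/1 matrices, one per class in
#'   `c(primary_classes, secondary_classes)`.
#' @export
gap_fill_cover <- function(primary, secondary, primary_classes,
                           secondary_classes) {
  if (!identical(dim(primary), dim(secondary)))
    stop("class rasters are not on a shared grid")
  known <- c(primary_classes, secondary_classes)
  bad <- setdiff(stats::na.omit(unique(c(primary, secondary))), known)
  if (length(bad))
    stop("class code outside either legend: ", paste(bad, collapse = ", "))
  final <- ifelse(primary %in% primary_classes, primary,
                  ifelse(secondary %in% secondary_classes, secondary, NA))
  final <- matrix(final, nrow(primary), ncol(primary))
  out <- lapply(known, function(cl) {
    m <- matrix(0, nrow(primary), ncol(primary))
    m[!is.na(final) & final == cl] <- 1
    m
  })
  names(out) <- known
  out
}

# buffer mean over a bare matrix; center-in rule. origin = xy of the
# lower-left corner; cell [i,j] has center ((j-0.5)res, (i-0.5)res).
buffer_mean_matrix <- function(raster, xy, radius, origin, res) {
  nx <- ncol(raster); ny <- nrow(raster)
  px <- xy[1] - origin[1]; py <- xy[2] - origin[2]
  if (px < 0 || py < 0 || px > nx * res || py > ny * res)
    stop("station outside raster extent")
  jr <- max(1L, ceiling((px - radius) / res)):min(nx, ceiling((px + radius) / res))
  ir <- max(1L, ceiling((py - radius) / res)):min(ny, ceiling((py + radius) / res))
  cx <- (jr - 0.5) * res
  cy <- (ir - 0.5) * res
  dist2 <- outer((cy - py)^2, (cx - px)^2, `+`)
  inside <- dist2 <= radius^2
  n_in <- sum(inside)
  if (n_in == 0) {
    # radius smaller than the distance to any center: use the station's cell
    j <- min(nx, max(1L, ceiling(px / res)))
    i <- min(ny, max(1L, ceiling(py / res)))
    return(structure(raster[i, j], coverage = 1))
  }
  # coverage: fraction of the in-radius centers of the full (untruncated) disc
  jr_full <- ceiling((px - radius) / res):ceiling((px + radius) / res)
  ir_full <- ceiling((py - radius) / res):ceiling((py + radius) / res)
  d2f <- outer(((ir_full - 0.5) * res - py)^2,
               ((jr_full - 0.5) * res - px)^2, `+`)
  n_full <- sum(d2f <= radius^2)
  structure(mean(raster[ir, jr][inside]),
            coverage = if (n_full > 0) n_in / n_full else 1)
}

#' Mean of a raster layer within a circular buffer around a station
#'
#' Averages the cells whose centers lie within `radius` of the station
#' (center-in rule). For stations nearer than `radius` to the raster edge
#' the mean uses the available cells only; the returned value carries a
#' `coverage` attribute giving the fraction of the full disc represented,
#' and a warning is raised when coverage < 1.
#'
#' @param landscape a `landscape` object (or a bare matrix, in which case
#'   `origin`/`res` must be given).
#' @param layer layer name when `landscape` is a `landscape`.
#' @param xy numeric length-2 station coordinate (metres).
#' @param radius buffer radius in metres (>= resolution recommended).
#' @param origin,res grid geometry when passing a bare matrix.
#' @return Numeric buffer mean with attribute `coverage`.
#' @export
buffer_mean <- function(landscape, layer = NULL, xy, radius,
                        origin = c(0, 0), res = NULL) {
  if (inherits(landscape, "landscape")) {
    raster <- landscape$layers[[layer]]
    if (is.null(raster)) stop("unknown layer: ", layer)
    origin <- landscape$origin
    res <- landscape$res
  } else raster <- landscape
  out <- buffer_mean_matrix(raster, xy, radius, origin, res)
  if (attr(out, "coverage") < 1)
    warning(sprintf("buffer truncated at raster edge (coverage %.2f)",
                    attr(out, "coverage")))
  out
}

#' Mean count in previous surveys at the same station
#'
#' Site-fidelity covariate: the mean count over qualifying earlier surveys
#' at the same station — surveys earlier in the same calendar year, or any
#' survey in the previous calendar year. Returns 0 when no survey
#' qualifies (documented default for the first visit).
#'
#' @param history data.frame with columns `station_id`, `year`, `doy`
#'   (day-of-year or any within-year ordering), `count`.
#' @param station station id.
#' @param year,doy the focal survey's year and day-of-year.
#' @return Numeric mean of qualifying counts, 0 if none.
#' @export
prior_mean_count <- function(history, station, year, doy) {
  h <- history[history$station_id == station, , drop = FALSE]
  qual <- (h$year == year & h$doy < doy) | (h$year == year - 1)
  if (!any(qual)) return(0)
  mean(h$count[qual])
}

#' Assemble the multi-scale design table for a set of surveys
#'
#' Extracts buffer means of every landscape layer at every configured
#' radius for each survey's station, draws/propagates temporal covariates,
#' and attaches the prior-count covariate computed from the survey history.
#'
#' @param landscape a `landscape`.
#' @param stations station table from [generate_survey_design()].
#' @param config a [sim_config()].
#' @param seed integer seed for the temporal covariate draws.
#' @return A data.frame, one row per survey, with columns
#'   `<layer>_<radius>`, `sun_angle`, `sun_angle_sq`, `day_of_year`,
#'   `day_of_year_sq`, `lunar`, `prior_count` (filled with 0; populated by
#'   the caller once counts exist), plus ids.
#' @export
build_design <- function(landscape, stations, config, seed = NULL) {
  stopifnot(inherits(landscape, "landscape"))
  set.seed(if (is.null(seed)) config$seed else seed + 2L)
  n_sv <- config$surveys_per_station * config$years
  idx <- rep(seq_len(nrow(stations)), each = n_sv)
  df <- data.frame(
    station_id = stations$station_id[idx],
    route_id = stations$route_id[idx],
    x = stations$x[idx], y = stations$y[idx],
    year = rep(rep(seq_len(config$years), each = config$surveys_per_station),
               nrow(stations)),
    survey = rep(seq_len(config$surveys_per_station),
                 nrow(stations) * config$years))
  buf <- extract_buffer_means(landscape, stations, config$radii)
  df <- cbind(df, buf[idx, , drop = FALSE])
  # crepuscular survey window: sun angle in [-9, +2] degrees, June-July
  # days of year, lunar illumination uniform
  df$sun_angle <- stats::runif(nrow(df), -9, 2)
  df$day_of_year <- stats::runif(nrow(df), 152, 212)
  df$lunar <- stats::runif(nrow(df), 0, 1)
  df$sun_angle_sq <- df$sun_angle^2
  df$day_of_year_sq <- df$day_of_year^2
  rownames(df) <- NULL
  df
}

#' Attach the prior-mean-count covariate to a survey table
#'
#' Computes [prior_mean_count()] for every row from the counts already in
#' the table (requires `station_id`, `year`, `day_of_year` and the count
#' column). The column is added in natural units; standardize afterwards
#' if it enters a model.
#'
#' @param table survey table.
#' @param count_col which count column to use (default `count_obs`).
#' @return `table` with an added `prior_count` column.
#' @export
add_prior_counts <- function(table, count_col = "count_obs") {
  stopifnot(!is.null(table[[count_col]]), !is.null(table$station_id),
            !is.null(table$year), !is.null(table$day_of_year))
  history <- data.frame(station_id = table$station_id, year = table$year,
                        doy = table$day_of_year, count = table[[count_col]])
  table$prior_count <- vapply(seq_len(nrow(table)), function(i)
    prior_mean_count(history, table$station_id[i], table$year[i],
                     table$day_of_year[i]), 0)
  table
}

#' Buffer means of every landscape layer at every radius
#'
#' @param landscape a `landscape`.
#' @param stations data.frame with `x`, `y` columns.
#' @param radii buffer radii (m).
#' @return data.frame of columns `<layer>_<radius>`, one row per station.
#' @export
extract_buffer_means <- function(landscape, stations, radii) {
  cols <- list()
  for (nm in names(landscape$layers)) {
    for (r in radii) {
      v <- vapply(seq_len(nrow(stations)), function(i)
        as.numeric(buffer_mean_matrix(
          landscape$layers[[nm]], c(stations$x[i], stations$y[i]), r,
          landscape$origin, landscape$res)), 0)
      cols[[paste(nm, r, sep = "_")]] <- v
    }
  }
  as.data.frame(cols)
}

std_excluded <- c("station_id", "route_id", "x", "y", "year", "survey",
                  "count", "count_true", "count_obs", "eta_true", "p_min",
                  "histories")

#' Standardize a multi-scale design table
#'
#' Z-scores every continuous covariate column (ids, coordinates and
#' response columns are left alone). Quadratic columns (suffix `_sq`) are
#' recomputed as the square of the standardized linear term and then
#' re-standardized, so that both enter the model on comparable scales. The
#' per-column means and standard deviations are stored in the `"scaling"`
#' attribute so predictions can be mapped back to natural units; the
#' operation is idempotent.
#'
#' @param design design data.frame.
#' @param exclude further columns to leave untouched.
#' @return The standardized design with attribute `scaling` (data.frame of
#'   `column`, `mean`, `sd` on the scale the column had *before* this
#'   standardization).
#' @export
standardize_design <- function(design, exclude = character()) {
  skip <- c(std_excluded, exclude)
  prev <- attr(design, "scaling")
  num_cols <- names(design)[vapply(design, is.numeric, TRUE)]
  cols <- setdiff(num_cols, skip)
  lin_of <- function(sq) sub("_sq$", "", sq)
  sq_cols <- cols[grepl("_sq$", cols) & lin_of(cols) %in% cols]
  lin_cols <- setdiff(cols, sq_cols)
  sc <- data.frame(column = character(), mean = numeric(), sd = numeric())
  for (cl in lin_cols) {
    if (any(is.na(design[[cl]]))) stop("missing values in column: ", cl)
    m <- mean(design[[cl]]); s <- stats::sd(design[[cl]])
    if (s == 0) stop("zero-variance column cannot be standardized: ", cl)
    design[[cl]] <- (design[[cl]] - m) / s
    sc <- rbind(sc, data.frame(column = cl, mean = m, sd = s))
  }
  for (cl in sq_cols) {
    z2 <- design[[lin_of(cl)]]^2
    m <- mean(z2); s <- stats::sd(z2)
    if (s == 0) stop("zero-variance column cannot be standardized: ", cl)
    design[[cl]] <- (z2 - m) / s
    sc <- rbind(sc, data.frame(column = cl, mean = m, sd = s))
  }
  # idempotence: carry forward the original scaling when re-standardizing
  if (!is.null(prev)) {
    keep <- prev[!(prev$column %in% sc$column), , drop = FALSE]
    reuse <- prev[prev$column %in% sc$column, , drop = FALSE]
    if (nrow(reuse)) {
      now <- sc[match(reuse$column, sc$column), ]
      reuse$sd <- reuse$sd * now$sd
      reuse$mean <- reuse$mean + now$mean * prev$sd[
        match(reuse$column, prev$column)]
      sc <- rbind(keep, reuse, sc[!(sc$column %in% prev$column), ])
    }
  }
  attr(design, "scaling") <- sc
  design
}

#' Map a standardized column value back to natural units (and back)
#'
#' @param design a standardized design (carries the `scaling` attribute).
#' @param column column name.
#' @param z standardized value(s).
#' @param x natural-unit value(s).
#' @return `unstandardize`: natural units; `standardize_value`: z-scores.
#' @export
unstandardize <- function(design, column, z) {
  sc <- attr(design, "scaling")
  i <- match(column, sc$column)
  if (is.na(i)) stop("no scaling stored for column: ", column)
  z * sc$sd[i] + sc$mean[i]
}

#' @rdname unstandardize
#' @export
standardize_value <- function(design, column, x) {
  sc <- attr(design, "scaling")
  i <- match(column, sc$column)
  if (is.na(i)) stop("no scaling stored for column: ", column)
  (x - sc$mean[i]) / sc$sd[i]
}

#' Write a design/survey table as CSV with a JSON metadata sidecar
#'
#' @param design design data.frame (standardized or not).
#' @param path CSV path; the sidecar goes to `<path>.json`.
#' @param radii buffer radii recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path, radii = NULL) {
  utils::write.csv(design, path, row.names = FALSE)
  sc <- attr(design, "scaling")
  jsonlite::write_json(
    list(radii = radii, columns = names(design),
         scaling = sc),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  design <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!is.null(meta$scaling) && length(meta$scaling))
    attr(design, "scaling") <- as.data.frame(meta$scaling)
  attr(design, "radii") <- meta$radii
  design
}
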