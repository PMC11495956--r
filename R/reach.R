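#' Landcover class raster
#'
#' A projected (planar) raster of integer class codes with a code-to-class
#' map. Classes are `urban`, `arable`, `pasture`, `other`; nodata cells are
#' excluded from all area accounting.
#'
#' @param classes integer matrix of class codes.
#' @param resolution metres per pixel (> 0).
#' @param class_map named character vector mapping code (as name) to class.
#' @param nodata nodata code (default `-9999L`).
#' @return object of class `landcover_raster`.
#' @export
landcover_raster <- function(classes, resolution,
                             class_map = c(`1` = "urban", `2` = "arable",
                                           `3` = "pasture", `4` = "other"),
                             nodata = -9999L) {
  if (!is.matrix(classes) || length(classes) == 0L)
    stop("`classes` must be a non-empty matrix", call. = FALSE)
  if (resolution <= 0) stop("resolution must be > 0", call. = FALSE)
  codes <- unique(as.vector(classes))
  unmapped <- setdiff(codes, c(as.integer(names(class_map)), nodata))
  if (length(unmapped) > 0)
    stop("unmapped class code(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  structure(list(classes = classes, resolution = resolution,
                 class_map = class_map, nodata = as.integer(nodata)),
            class = "landcover_raster")
}

#' @export
print.landcover_raster <- function(x, ...) {
  cat(sprintf("landcover raster: %d x %d cells at %g m\n", nrow(x$classes),
              ncol(x$classes), x$resolution))
  tab <- table(factor(x$class_map[as.character(x$classes)],
                      levels = unique(x$class_map)))
  for (cl in names(tab))
    cat(sprintf("  %-8s %6.2f%%\n", cl, 100 * tab[[cl]] / length(x$classes)))
  invisible(x)
}

# Codes whose mapped class is `cls`.
.codes_of <- function(raster, cls) {
  as.integer(names(raster$class_map)[raster$class_map == cls])
}

#' Distance to the nearest urban cell
#'
#' Exact Euclidean distance (centre to centre, in metres) from every cell to
#' the nearest urban cell; urban cells themselves have distance zero. When
#' the raster holds no urban cell, all distances are infinite and the result
#' carries `attr(, "no_urban") = TRUE`.
#'
#' @param raster a [landcover_raster()].
#' @return numeric matrix of distances in metres.
#' @export
distance_to_urban <- function(raster) {
  stopifnot(inherits(raster, "landcover_raster"))
  urban <- matrix(raster$classes %in% .codes_of(raster, "urban"),
                  nrow(raster$classes), ncol(raster$classes))
  if (!any(urban)) {
    warning("raster contains no urban cells; all distances are infinite")
    d <- matrix(Inf, nrow(urban), ncol(urban))
    attr(d, "no_urban") <- TRUE
    return(d)
  }
  sq <- edt_squared(urban)
  d <- sqrt(sq) * raster$resolution
  d[sq >= 1e17] <- Inf
  d
}

#' Fraction of each landcover class within reach of urban land
#'
#' For each foraging radius and class, the share of that class' area lying
#' within the radius of the nearest urban cell (urban land itself is within
#' reach at every radius). Nodata cells are excluded from numerator and
#' denominator. Default radii follow bumblebee/honeybee (750-1000 m),
#' large solitary bee (500 m) and small bee (250 m) foraging ranges.
#'
#' @param dist distance matrix from [distance_to_urban()].
#' @param raster the matching [landcover_raster()].
#' @param radii radii in metres (> 0).
#' @return a `reach_report` data.frame: `radius_m`, `class` (including an
#'   `"overall"` row per radius), `fraction`, `area_cells`.
#' @export
reach_fractions <- function(dist, raster, radii = c(250, 500, 750, 1000)) {
  stopifnot(inherits(raster, "landcover_raster"))
  if (any(radii <= 0)) stop("radii must be > 0", call. = FALSE)
  if (!all(dim(dist) == dim(raster$classes)))
    stop("distance matrix does not match the raster", call. = FALSE)
  cls <- raster$class_map[as.character(raster$classes)]
  valid <- raster$classes != raster$nodata
  classes <- unique(raster$class_map)
  rows <- list()
  for (r in sort(radii)) {
    within <- dist <= r
    for (cl in c(classes, "overall")) {
      sel <- valid & (if (cl == "overall") TRUE else cls == cl)
      n <- sum(sel)
      rows[[length(rows) + 1L]] <- data.frame(
        radius_m = r, class = cl,
        fraction = if (n > 0) sum(within[sel]) / n else NA_real_,
        area_cells = n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("reach_report", "data.frame")
  out
}

#' Read/write a landcover raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of class
#' codes, top row first.
#'
#' @param raster a [landcover_raster()].
#' @param path file path.
#' @param class_map class map to attach on read.
#' @return `read_ascii_grid` returns a [landcover_raster()];
#'   `write_ascii_grid` returns `path` invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "landcover_raster"))
  m <- raster$classes
  hdr <- c(sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
           "xllcorner 0", "yllcorner 0",
           sprintf("cellsize %g", raster$resolution),
           sprintf("NODATA_value %d", raster$nodata))
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, class_map = c(`1` = "urban", `2` = "arable",
                                                `3` = "pasture",
                                                `4` = "other")) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  nc <- val("ncols"); nr <- val("nrows")
  m <- matrix(as.integer(scan(text = paste(lines[-(1:6)], collapse = " "),
                              quiet = TRUE)),
              nrow = nr, ncol = nc, byrow = TRUE)
  landcover_raster(m, val("cellsize"), class_map = class_map,
                   nodata = as.integer(val("NODATA")))
}
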