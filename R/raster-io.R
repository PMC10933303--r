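# ESRI ASCII grid raster I/O and aligned environmental stacks. The .asc
# format is a plain-text header (ncols, nrows, xllcorner, yllcorner,
# cellsize, NODATA_value) followed by rows from north to south.

#' Read an ESRI ASCII grid
#'
#' @param path .asc file.
#' @param name layer name; defaults to the file name without extension.
#' @return object of class `env_grid`: `data` (matrix, row 1 = northernmost),
#'   `xll`, `yll`, `cellsize`, `nodata` cells as `NA`, `name`.
#' @export
read_ascii_grid <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("cell count mismatch in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  structure(list(data = m, xll = hdr$xllcorner, yll = hdr$yllcorner,
                 cellsize = hdr$cellsize, name = name),
            class = "env_grid")
}

#' Write an ESRI ASCII grid
#' @param grid an `env_grid`.
#' @param path output file.
#' @param nodata value written for `NA` cells.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  m <- grid$data
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)),
               paste("nrows", nrow(m)),
               paste("xllcorner", grid$xll),
               paste("yllcorner", grid$yll),
               paste("cellsize", grid$cellsize),
               paste("NODATA_value", nodata)), con)
  writeLines(apply(m, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Bundle congruent raster layers into an environmental stack
#'
#' @param grids list of `env_grid` objects (or a directory of .asc files).
#' @return object of class `env_stack`: `layers` (named list of matrices),
#'   grid geometry, and a shared `mask` of cells valid in every layer.
#' @export
env_stack <- function(grids) {
  if (is.character(grids) && length(grids) == 1 && dir.exists(grids))
    grids <- lapply(list.files(grids, "\\.asc$", full.names = TRUE),
                    read_ascii_grid)
  stopifnot(length(grids) >= 1)
  ref <- grids[[1]]
  for (g in grids) {
    if (!identical(dim(g$data), dim(ref$data)) ||
        !isTRUE(all.equal(c(g$xll, g$yll, g$cellsize),
                          c(ref$xll, ref$yll, ref$cellsize))))
      stop("layer ", g$name, " is not congruent with layer ", ref$name)
  }
  layers <- lapply(grids, `[[`, "data")
  names(layers) <- vapply(grids, `[[`, "", "name")
  mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  structure(list(layers = layers, nrow = nrow(ref$data),
                 ncol = ncol(ref$data), xll = ref$xll, yll = ref$yll,
                 cellsize = ref$cellsize, mask = mask),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat("<env_stack>", length(x$layers), "layers,", x$nrow, "x", x$ncol,
      "cells,", sum(x$mask), "valid\n")
  cat(paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

# lon/lat -> (row, col); NA outside the extent
.cell_of <- function(stack, lon, lat) {
  col <- floor((lon - stack$xll) / stack$cellsize) + 1
  row <- stack$nrow - floor((lat - stack$yll) / stack$cellsize)
  bad <- col < 1 | col > stack$ncol | row < 1 | row > stack$nrow
  col[bad] <- NA; row[bad] <- NA
  cbind(row = row, col = col)
}

#' Extract layer values at point locations
#'
#' Points falling outside the extent or on nodata cells are dropped with a
#' message (count in attribute `n_dropped`).
#'
#' @param stack an `env_stack`.
#' @param pts data.frame with `lon`, `lat` columns.
#' @return data.frame of layer values at the retained points, with the
#'   retained row indices as attribute `kept`.
#' @export
extract_env <- function(stack, pts) {
  rc <- .cell_of(stack, pts$lon, pts$lat)
  ok <- !is.na(rc[, 1])
  ok[ok] <- stack$mask[rc[ok, , drop = FALSE]]
  if (any(!ok))
    message(sum(!ok), " point(s) dropped (outside extent or nodata)")
  idx <- rc[ok, , drop = FALSE]
  out <- as.data.frame(lapply(stack$layers, function(m) m[idx]))
  attr(out, "kept") <- which(ok)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' All valid cell values of a stack
#' @param stack an `env_stack`.
#' @return data.frame, one row per valid cell, one column per layer.
#' @export
stack_values <- function(stack) {
  as.data.frame(lapply(stack$layers, function(m) m[stack$mask]))
}
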