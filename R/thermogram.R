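#' Per-pixel temperature grid
#'
#' The basic data unit of the pipeline: an `H x W` matrix of surface
#' temperatures in degrees Celsius together with a validity mask. Thermal
#' cameras export these grids as spreadsheets with one temperature per cell;
#' blank cells mean "background removed", not 0 degC, and are carried as
#' masked-out cells that every downstream statistic ignores.
#'
#' Coordinate convention (fixed package-wide): row-major, row 1 is the top of
#' the image, column 1 the left.
#'
#' @param values numeric matrix of temperatures (degC). Masked cells may be
#'   `NA`.
#' @param mask logical matrix of the same shape; `TRUE` marks a valid
#'   body/foreground cell. Defaults to the finite cells of `values`.
#' @param meta named list of free-form character metadata (patient id,
#'   source, laterality, ...).
#' @return An object of class `"thermogram"` with elements `values`, `mask`
#'   and `meta`.
#' @examples
#' tg <- thermogram(matrix(c(30, 29.5, 31, 32), 2, 2))
#' tg
#' @export
thermogram <- function(values, mask = NULL, meta = list()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("temperature grid must be at least 2 x 2", call. = FALSE)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- is.finite(values)
  if (!is.matrix(mask) || !is.logical(mask) || !identical(dim(mask), dim(values)))
    stop("'mask' must be a logical matrix with the same shape as 'values'",
         call. = FALSE)
  mask[is.na(mask)] <- FALSE
  v <- values[mask]
  if (any(!is.finite(v)))
    stop("valid cells must hold finite temperatures", call. = FALSE)
  if (length(v) && (min(v) < 0 || max(v) > 45))
    stop("temperatures outside the physically plausible range [0, 45] degC",
         call. = FALSE)
  structure(list(values = values, mask = mask, meta = as.list(meta)),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<thermogram %d x %d, %d/%d valid cells",
              nrow(x$values), ncol(x$values), sum(x$mask), length(x$mask)))
  if (length(v))
    cat(sprintf(", T in [%.2f, %.2f] degC", min(v), max(v)))
  cat(">\n")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.thermogram <- function(x) dim(x$values)

stop_io <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("thermotan_io_error",
                                                   "error", "condition")))
}

parse_grid_cells <- function(cells, path) {
  # cells: character matrix; "" or NA = masked
  cells[is.na(cells)] <- ""
  txt <- trimws(cells)
  blank <- txt == ""
  vals <- suppressWarnings(as.numeric(txt))
  bad <- which(!blank & is.na(vals))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(txt))
    stop_io("non-numeric cell '%s' at row %d, column %d of %s",
            txt[bad[1L]], i[1L], i[2L], path)
  }
  m <- matrix(vals, nrow(txt), ncol(txt))
  mask <- !blank
  dimnames(m) <- dimnames(mask) <- NULL
  thermogram(m, mask = mask, meta = list(source = path))
}

#' Read a temperature grid from a spreadsheet export
#'
#' Reads the camera-export format: a sheet of numbers, one temperature (degC)
#' per cell, blank cells marking removed background. CSV grids use a comma
#' separator, `.` decimal mark and no header row; for XLSX only the first
#' sheet is read.
#'
#' @param path file to read.
#' @param dialect `"csv"` or `"xlsx"`. Defaults to the file extension.
#' @return A [thermogram] with `mask` true exactly on the non-blank cells,
#'   row/column order preserved (row 1 = image top).
#' @seealso [write_temperature_grid()]
#' @export
read_temperature_grid <- function(path, dialect = c("auto", "csv", "xlsx")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  if (!file.exists(path)) stop_io("cannot read '%s': no such file", path)
  if (dialect == "xlsx") {
    df <- readxl::read_excel(path, col_names = FALSE, col_types = "text",
                             .name_repair = "minimal")
    if (nrow(df) == 0L || ncol(df) == 0L) stop_io("empty sheet in '%s'", path)
    cells <- as.matrix(df)
  } else {
    lines <- readLines(path, warn = FALSE)
    while (length(lines) && !nzchar(trimws(lines[length(lines)])))
      lines <- lines[-length(lines)]
    if (!length(lines)) stop_io("empty sheet in '%s'", path)
    parts <- strsplit(lines, ",", fixed = TRUE)
    w <- max(lengths(parts))
    cells <- t(vapply(parts, function(p) c(p, rep("", w - length(p))),
                      character(w)))
  }
  parse_grid_cells(cells, path)
}

#' Write a temperature grid as a spreadsheet
#'
#' Writes the grid in the same layout [read_temperature_grid()] consumes;
#' masked cells are written blank so the mask round-trips exactly. Only the
#' CSV dialect is supported for writing.
#'
#' @param grid a [thermogram].
#' @param path output file.
#' @param dialect only `"csv"` is available for writing.
#' @return `path`, invisibly.
#' @export
write_temperature_grid <- function(grid, path, dialect = c("csv", "xlsx")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(grid, "thermogram"))
  if (dialect == "xlsx")
    stop("writing xlsx is not supported; use dialect = \"csv\"", call. = FALSE)
  txt <- matrix("", nrow(grid$values), ncol(grid$values))
  txt[grid$mask] <- formatC(grid$values[grid$mask], format = "fg",
                            digits = 10, width = 1)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop_io("cannot write '%s': %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(apply(txt, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Render a temperature grid as a pseudocolor image
#'
#' Maps valid cells linearly onto a blue-to-red ramp over the temperature
#' window `[t_low, t_high]` (values outside the window are clipped, as when a
#' camera's red saturation point is adjusted); masked cells are rendered
#' black. The ramp is `R = u`, `G = 0`, `B = 1 - u` with
#' `u = (T - t_low) / (t_high - t_low)`, so the red channel is monotone in
#' temperature. The map is a declared visualization choice, not a
#' reconstruction of any camera's palette.
#'
#' @param grid a [thermogram].
#' @param t_low,t_high window bounds in degC, `t_low < t_high`.
#' @return An `H x W x 3` array of RGB values in `[0, 1]`, writable with
#'   [write_image()].
#' @export
render_pseudocolor <- function(grid, t_low = 22, t_high = 40) {
  stopifnot(inherits(grid, "thermogram"))
  if (!(t_low < t_high)) stop("'t_low' must be < 't_high'", call. = FALSE)
  u <- (grid$values - t_low) / (t_high - t_low)
  u[!grid$mask] <- NA
  u <- pmin(pmax(u, 0), 1)
  img <- array(0, c(dim(grid$values), 3L))
  r <- u; b <- 1 - u
  r[is.na(u)] <- 0; b[is.na(u)] <- 0
  img[, , 1L] <- r
  img[, , 3L] <- b
  img
}

#' Write an RGB array as a PNG file
#'
#' @param img `H x W x 3` array in `[0, 1]`, e.g. from [render_pseudocolor()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

# nearest-neighbour resize of a matrix to out_h x out_w; mapping and its
# inverse are used to carry explanation masks between image and grid coords
resize_index <- function(n_in, n_out) {
  pmin(pmax(floor((seq_len(n_out) - 0.5) * n_in / n_out) + 1L, 1L), n_in)
}

resize_nearest <- function(m, out_h, out_w) {
  m[resize_index(nrow(m), out_h), resize_index(ncol(m), out_w), drop = FALSE]
}
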