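#' Construct a lattice grid
#'
#' A minimal raster-like container: a numeric matrix of cell values with
#' cell size and origin bookkeeping.  Geographic projections are out of
#' scope; `NA` marks missing cells and propagates through every grid
#' operation.
#'
#' @param values numeric matrix (rows = y, columns = x).
#' @param cell_size positive cell edge length (default 25, emulating a
#'   25 km resolution in km units).
#' @param origin numeric length-2, coordinates of the lower-left corner.
#' @return Object of class `env_grid`.
#' @export
env_grid <- function(values, cell_size = 25, origin = c(0, 0)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("grid values must be numeric")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("cell_size must be a positive scalar")
  structure(list(values = values, cell_size = cell_size,
                 origin = as.numeric(origin)), class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("env_grid: %d x %d cells, cell size %g, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  values: [%g, %g], %d missing\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.env_grid <- function(x) dim(x$values)

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Aggregate a grid by an integer factor
#'
#' Each coarse cell is the mean of its `factor x factor` block of fine
#' cells, ignoring missing values; blocks that are entirely missing stay
#' missing.  Edge blocks average whatever fine cells are available when
#' the factor does not divide the dimensions.
#'
#' @param grid an [env_grid()].
#' @param factor integer aggregation factor >= 1.
#' @return Coarser [env_grid()] with `cell_size * factor`.
#' @export
aggregate_grid <- function(grid, factor) {
  stopifnot(inherits(grid, "env_grid"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("factor must be an integer >= 1")
  if (factor == 1) return(grid)
  v <- grid$values
  ri <- (seq_len(nrow(v)) - 1L) %/% factor
  ci <- (seq_len(ncol(v)) - 1L) %/% factor
  sums <- rowsum(ifelse(is.na(v), 0, v), ri, reorder = TRUE)
  cnts <- rowsum((!is.na(v)) * 1, ri, reorder = TRUE)
  sums <- t(rowsum(t(sums), ci, reorder = TRUE))
  cnts <- t(rowsum(t(cnts), ci, reorder = TRUE))
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  dimnames(out) <- NULL
  env_grid(out, cell_size = grid$cell_size * factor, origin = grid$origin)
}

#' Resample a grid to a coarser target cell size
#'
#' Block-mean (default) or nearest-neighbour resampling onto a lattice of
#' the target cell size sharing the origin.  Upsampling (target smaller
#' than source) is out of scope.
#'
#' @param grid an [env_grid()].
#' @param target_cell_size target resolution (>= source cell size).
#' @param method `"mean"` or `"nearest"`.
#' @return Resampled [env_grid()].
#' @export
resample_grid <- function(grid, target_cell_size,
                          method = c("mean", "nearest")) {
  stopifnot(inherits(grid, "env_grid"))
  method <- match.arg(method)
  if (target_cell_size <= 0) stop("target cell size must be positive")
  if (target_cell_size < grid$cell_size)
    stop("upsampling not supported: target must be >= source cell size")
  ratio <- target_cell_size / grid$cell_size
  if (isTRUE(all.equal(ratio, 1))) return(grid)
  if (isTRUE(all.equal(ratio, round(ratio))) && method == "mean") {
    g <- aggregate_grid(grid, round(ratio))
    return(env_grid(g$values, cell_size = target_cell_size,
                    origin = grid$origin))
  }
  v <- grid$values
  nr <- max(1L, ceiling(nrow(v) / ratio))
  nc <- max(1L, ceiling(ncol(v) / ratio))
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    rows <- which((seq_len(nrow(v)) - 0.5) / ratio > i - 1 &
                  (seq_len(nrow(v)) - 0.5) / ratio <= i)
    if (method == "nearest")
      rows <- rows[ceiling(length(rows) / 2)]
    for (j in seq_len(nc)) {
      cols <- which((seq_len(ncol(v)) - 0.5) / ratio > j - 1 &
                    (seq_len(ncol(v)) - 0.5) / ratio <= j)
      if (method == "nearest") cols <- cols[ceiling(length(cols) / 2)]
      block <- v[rows, cols]
      out[i, j] <- if (all(is.na(block))) NA_real_
                   else if (method == "nearest") block[1]
                   else mean(block, na.rm = TRUE)
    }
  }
  env_grid(out, cell_size = target_cell_size, origin = grid$origin)
}

#' Standardize a grid to the unit interval
#'
#' `(v - min) / (max - min)` over unmasked, non-missing cells.  Masked
#' cells are set missing in the output.  A constant grid maps to all
#' zeros with a warning (the range is degenerate).
#'
#' @param grid an [env_grid()].
#' @param mask optional logical matrix, `TRUE` = exclude cell.
#' @return Standardized [env_grid()] with values in `[0, 1]`.
#' @export
standardize01 <- function(grid, mask = NULL) {
  stopifnot(inherits(grid, "env_grid"))
  v <- grid$values
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(v))) stop("mask dimensions differ")
    v[mask] <- NA_real_
  }
  if (all(is.na(v))) stop("no unmasked finite cells to standardize")
  rng <- range(v, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    warning("constant grid: standardized values all set to 0")
    v[!is.na(v)] <- 0
  } else {
    v <- (v - rng[1]) / (rng[2] - rng[1])
  }
  env_grid(v, cell_size = grid$cell_size, origin = grid$origin)
}

#' Compare low- and high-practice scenario maps
#'
#' Classifies each cell by the difference `high - low` of the two
#' standardized maps against an equivalence band: above the band the cell
#' depends more on a high number of practices, below it on a low number,
#' inside it the scenarios are equivalent.
#'
#' @param low,high standardized [env_grid()]s on the same lattice.
#' @param band half-width of the equivalence band (default 0.1 on the
#'   standardized scale).
#' @return [env_grid()] of codes: -1 low-dependent, 0 equivalent,
#'   1 high-dependent, `NA` where either input is missing; the code
#'   legend is attached as attribute `legend`.
#' @export
compare_scenarios <- function(low, high, band = 0.1) {
  stopifnot(inherits(low, "env_grid"), inherits(high, "env_grid"))
  if (!same_geometry(low, high)) stop("misaligned grids")
  d <- high$values - low$values
  code <- matrix(0, nrow(d), ncol(d))
  code[d > band] <- 1
  code[d < -band] <- -1
  code[is.na(d)] <- NA_real_
  out <- env_grid(code, cell_size = low$cell_size, origin = low$origin)
  attr(out, "legend") <- c(`-1` = "low-dependent", `0` = "equivalent",
                           `1` = "high-dependent")
  out
}

#' Write a grid as a headered CSV matrix
#'
#' Plain-text interchange format: comment lines carry the geometry
#' (`# cell_size=...`, `# origin=x,y`), then the value matrix without
#' row or column names.  `NA` marks missing cells.
#'
#' @param grid an [env_grid()].
#' @param path output file path.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "env_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cell_size=%.17g", grid$cell_size),
               sprintf("# origin=%.17g,%.17g", grid$origin[1],
                       grid$origin[2])), con)
  # full-precision cells so grids round-trip losslessly
  lines <- apply(grid$values, 1, function(r)
    paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = ","))
  writeLines(lines, con)
  invisible(path)
}

#' Read a grid written by [write_grid_csv()]
#'
#' @param path file path.
#' @return An [env_grid()].
#' @export
read_grid_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s=", key), "",
                           grep(sprintf("^# %s=", key), hdr, value = TRUE))
  cell <- as.numeric(get("cell_size"))
  origin <- as.numeric(strsplit(get("origin"), ",")[[1]])
  vals <- utils::read.table(text = lines[!grepl("^#", lines)], sep = ",",
                            na.strings = "NA")
  env_grid(unname(as.matrix(vals)), cell_size = cell, origin = origin)
}
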