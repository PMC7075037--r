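# Sentinel membership label for grid cells outside the county.
GRID_SENTINEL <- "."

#' Exposure grid
#'
#' A regular rectangular lattice of modelled pollutant concentrations
#' together with a same-shape membership lattice assigning every cell to a
#' census tract (whole cells only, no area weighting). Cells outside the
#' county carry the sentinel label `"."` and are excluded from all
#' aggregation.
#'
#' @param values Numeric matrix of cell concentrations.
#' @param membership Character matrix of tract ids, same dimensions as
#'   `values`; `"."` marks out-of-county cells.
#' @param cell_size Cell edge length in metres (> 0).
#' @return An object of class `exposure_grid`.
#' @export
exposure_grid <- function(values, membership, cell_size) {
  stopifnot(is.matrix(values), is.numeric(values))
  stopifnot(is.matrix(membership), is.character(membership))
  if (!identical(dim(values), dim(membership))) {
    stop("values and membership grids must have identical dimensions",
      call. = FALSE
    )
  }
  stopifnot(is.numeric(cell_size), length(cell_size) == 1, cell_size > 0)
  structure(
    list(values = values, membership = membership, cell_size = cell_size),
    class = "exposure_grid"
  )
}

#' @export
print.exposure_grid <- function(x, ...) {
  n_out <- sum(x$membership == GRID_SENTINEL)
  cat(sprintf(
    "<exposure_grid> %d x %d cells of %g m (%d outside county), %d tracts\n",
    nrow(x$values), ncol(x$values), x$cell_size, n_out,
    length(setdiff(unique(as.vector(x$membership)), GRID_SENTINEL))
  ))
  invisible(x)
}

#' Read / write exposure grids as headered CSV matrices
#'
#' A grid is stored as two CSV files: a numeric concentration matrix and a
#' character membership matrix of the same shape (columns named `c1..cn`).
#'
#' @param values_path,membership_path CSV file paths.
#' @param cell_size Cell edge length in metres.
#' @return For `read_exposure_grid`, an [exposure_grid()]; for
#'   `write_exposure_grid`, the paths, invisibly.
#' @export
read_exposure_grid <- function(values_path, membership_path, cell_size) {
  vals <- as.matrix(readr::read_csv(values_path,
    col_types = readr::cols(.default = readr::col_double())
  ))
  mem <- as.matrix(readr::read_csv(membership_path,
    col_types = readr::cols(.default = readr::col_character())
  ))
  dimnames(vals) <- NULL
  dimnames(mem) <- NULL
  exposure_grid(vals, mem, cell_size)
}

#' @rdname read_exposure_grid
#' @param grid An [exposure_grid()].
#' @export
write_exposure_grid <- function(grid, values_path, membership_path) {
  stopifnot(inherits(grid, "exposure_grid"))
  name_cols <- function(m) {
    d <- as.data.frame(m)
    names(d) <- paste0("c", seq_len(ncol(d)))
    d
  }
  readr::write_csv(name_cols(grid$values), values_path)
  readr::write_csv(name_cols(grid$membership), membership_path)
  invisible(c(values_path, membership_path))
}

#' Down-average a fine exposure grid to a coarser resolution
#'
#' Each coarse cell takes the arithmetic mean of its `factor` x `factor`
#' block of fine cells, mirroring how high-resolution land-use-regression
#' rasters are down-averaged before tract assignment. Membership is
#' coarsened by majority vote within each block (ties broken by sorted
#' label order); blocks that fall wholly outside the county stay sentinel.
#'
#' @param fine An [exposure_grid()].
#' @param factor Positive integer; both grid dimensions must be divisible
#'   by it.
#' @return An [exposure_grid()] with cell size `fine$cell_size * factor`.
#' @export
downsample_grid <- function(fine, factor) {
  stopifnot(inherits(fine, "exposure_grid"))
  stopifnot(is.numeric(factor), length(factor) == 1, factor >= 1,
    factor == as.integer(factor))
  factor <- as.integer(factor)
  nr <- nrow(fine$values)
  nc <- ncol(fine$values)
  if (nr %% factor != 0 || nc %% factor != 0) {
    stop(sprintf(
      "grid dimensions %d x %d are not divisible by factor %d",
      nr, nc, factor
    ), call. = FALSE)
  }
  row_block <- (seq_len(nr) - 1L) %/% factor
  col_block <- (seq_len(nc) - 1L) %/% factor
  block_of <- outer(row_block, col_block, function(r, c) r + c * (nr %/% factor))
  vals <- matrix(
    as.vector(tapply(as.vector(fine$values), as.vector(block_of), mean)),
    nrow = nr %/% factor, ncol = nc %/% factor
  )
  majority <- function(labels) {
    tab <- sort(table(labels), decreasing = TRUE)
    names(tab)[1]
  }
  mem <- matrix(
    as.vector(tapply(as.vector(fine$membership), as.vector(block_of), majority)),
    nrow = nr %/% factor, ncol = nc %/% factor
  )
  exposure_grid(vals, mem, fine$cell_size * factor)
}

#' Tract-mean exposure from a grid
#'
#' Assigns each tract the arithmetic mean of all grid cells it contains;
#' sentinel (out-of-county) cells are excluded. If a universe of expected
#' tract ids is supplied, tracts with zero member cells are reported in an
#' exclusion list rather than silently dropped.
#'
#' @param grid An [exposure_grid()].
#' @param tract_ids Optional character vector of expected tract ids.
#' @return A list with `means` (tibble `tract_id`, `exposure`) and
#'   `excluded` (character vector of tract ids with no cells).
#' @export
tract_mean_exposure <- function(grid, tract_ids = NULL) {
  stopifnot(inherits(grid, "exposure_grid"))
  labels <- as.vector(grid$membership)
  vals <- as.vector(grid$values)
  keep <- labels != GRID_SENTINEL
  if (!any(keep)) stop("grid contains no in-county cells", call. = FALSE)
  means <- tapply(vals[keep], labels[keep], mean)
  out <- tibble::tibble(
    tract_id = names(means),
    exposure = as.numeric(means)
  )
  out <- out[order(out$tract_id), ]
  excluded <- character(0)
  if (!is.null(tract_ids)) {
    excluded <- sort(setdiff(tract_ids, out$tract_id))
    extra <- setdiff(out$tract_id, tract_ids)
    if (length(extra) > 0) {
      stop("grid labels not present in tract universe: ",
        paste(utils::head(extra, 5), collapse = ", "),
        call. = FALSE
      )
    }
  }
  list(means = out, excluded = excluded)
}
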