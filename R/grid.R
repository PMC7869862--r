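# Core containers: VoxelGrid (multi-channel intensity volume with physical
# voxel spacing) and LabelMap (integer object map sharing a grid's geometry).
#
# Array convention: intensities are indexed (channel, z, y, x); label arrays
# (z, y, x). Physical coordinates are reported (x, y, z) in micrometres at
# the table boundary only; the centre of voxel (i, j, k) (0-based) sits at
# ((i, j, k) + 0.5) * voxel_size_um.

#' Construct a VoxelGrid
#'
#' @param intensities numeric array indexed `(channel, z, y, x)`; a 3-D
#'   array is promoted to a single channel.
#' @param voxel_size_um numeric length-3 `(z, y, x)` voxel spacing in
#'   micrometres, all strictly positive.
#' @param channel_names character vector of unique non-empty names, one per
#'   channel.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(intensities, voxel_size_um, channel_names = NULL) {
  if (length(dim(intensities)) == 3L) {
    dim(intensities) <- c(1L, dim(intensities))
  }
  if (length(dim(intensities)) != 4L) {
    stopf("intensities must be a (channel, z, y, x) array")
  }
  storage.mode(intensities) <- "double"
  nc <- dim(intensities)[1L]
  if (nc < 1L) stopf("a VoxelGrid needs at least one channel")
  if (any(dim(intensities)[2:4] < 1L)) {
    stopf("spatial extents must be >= 1 in every axis")
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nc) {
    stopf("channel_names length (%d) != channel count (%d)",
          length(channel_names), nc)
  }
  if (anyDuplicated(channel_names) || any(!nzchar(channel_names))) {
    stopf("channel_names must be unique and non-empty")
  }
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0)) {
    stopf("voxel_size_um must be three strictly positive numbers (z, y, x)")
  }
  structure(
    list(
      intensities = intensities,
      voxel_size_um = voxel_size_um,
      channel_names = channel_names
    ),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<voxel_grid> %d channel(s) [%s], %d x %d x %d voxels (z,y,x), %.4g x %.4g x %.4g um\n",
    d[1L], paste(x$channel_names, collapse = ", "), d[2L], d[3L], d[4L],
    x$voxel_size_um[1L], x$voxel_size_um[2L], x$voxel_size_um[3L]
  ))
  invisible(x)
}

#' Spatial dimensions (z, y, x) of a grid or label map
#' @param x a `voxel_grid` or `label_map`.
#' @return integer length-3 vector.
#' @export
grid_dim <- function(x) {
  if (inherits(x, "voxel_grid")) return(dim(x$intensities)[2:4])
  if (inherits(x, "label_map")) return(dim(x$labels))
  stopf("not a voxel_grid or label_map")
}

#' Extract one channel of a VoxelGrid as a 3-D array
#' @param grid a `voxel_grid`.
#' @param channel channel name or index.
#' @return 3-D numeric array (z, y, x).
#' @export
get_channel <- function(grid, channel) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.character(channel)) {
    i <- match(channel, grid$channel_names)
    if (is.na(i)) stopf("unknown channel '%s'", channel)
  } else {
    i <- as.integer(channel)
    if (i < 1L || i > length(grid$channel_names)) stopf("channel index out of range")
  }
  d <- dim(grid$intensities)
  arr <- grid$intensities[i, , , , drop = FALSE]
  dim(arr) <- d[2:4]
  arr
}

#' Construct a LabelMap
#'
#' @param labels 3-D array (z, y, x) of non-negative integers; 0 marks
#'   background.
#' @param voxel_size_um voxel spacing `(z, y, x)` in micrometres.
#' @param class_name tag naming what the objects are (e.g. "glomeruli").
#' @return an object of class `label_map`.
#' @export
label_map <- function(labels, voxel_size_um, class_name = "objects") {
  if (length(dim(labels)) != 3L) stopf("labels must be a 3-D (z, y, x) array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE) || anyNA(labels)) {
    stopf("labels must be non-negative integers")
  }
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0)) {
    stopf("voxel_size_um must be three strictly positive numbers (z, y, x)")
  }
  structure(
    list(labels = labels, voxel_size_um = voxel_size_um,
         class_name = as.character(class_name)),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  n <- n_labels(x)
  cat(sprintf("<label_map> '%s': %d object(s), %d x %d x %d voxels (z,y,x)\n",
              x$class_name, n, d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Number of distinct non-background labels
#' @param x a `label_map`.
#' @return integer count.
#' @export
n_labels <- function(x) {
  stopifnot(inherits(x, "label_map"))
  m <- max(x$labels)
  if (m == 0L) return(0L)
  sum(tabulate(x$labels, nbins = m) > 0L)
}

#' Do two objects share voxel geometry?
#' @param a,b `voxel_grid` or `label_map` objects.
#' @return logical.
#' @export
same_geometry <- function(a, b) {
  identical(grid_dim(a), grid_dim(b)) &&
    isTRUE(all.equal(
      if (inherits(a, "voxel_grid")) a$voxel_size_um else a$voxel_size_um,
      if (inherits(b, "voxel_grid")) b$voxel_size_um else b$voxel_size_um
    ))
}

#' Foreground voxels of a label map as a table
#'
#' @param x a `label_map`.
#' @return data.table with 0-based voxel indices `z`, `y`, `x` and `label`.
#' @export
label_map_to_table <- function(x) {
  stopifnot(inherits(x, "label_map"))
  idx <- which(x$labels > 0L)
  pos <- decode_index(idx, grid_dim(x))
  data.table::data.table(z = pos$z, y = pos$y, x = pos$x,
                         label = x$labels[idx])
}

# physical centre coordinates for 0-based voxel indices along one axis
axis_centers_um <- function(n, step) (seq_len(n) - 0.5) * step

# linear (1-based) index -> 0-based (z, y, x) indices for dims (nz, ny, nx)
decode_index <- function(idx, dims) {
  idx0 <- idx - 1
  z <- idx0 %% dims[1L]
  y <- (idx0 %/% dims[1L]) %% dims[2L]
  x <- idx0 %/% (dims[1L] * dims[2L])
  list(z = z, y = y, x = x)
}
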