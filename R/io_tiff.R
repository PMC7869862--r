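# Stack reader/writer.
#
# No TIFF library is available to this package's dependency set, so a
# minimal baseline-TIFF codec is implemented here. The writer emits
# uncompressed little-endian TIFF, one page per (channel, z) plane, IEEE
# 64-bit float samples (so intensities round-trip bit-for-bit), one strip
# per page, and an OME-XML ImageDescription on the first page carrying
# dimension order, physical voxel sizes and channel names. The reader
# handles both byte orders, uncompressed strips, integer samples of
# 8/16/32 bit and float samples of 32/64 bit, SamplesPerPixel = 1.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

ome_description <- function(nc, nz, ny, nx, voxel_size_um, channel_names,
                            pixel_type = "double") {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    s <- gsub(">", "&gt;", s, fixed = TRUE)
    gsub('"', "&quot;", s, fixed = TRUE)
  }
  ch <- paste0(
    sprintf('<Channel ID="Channel:0:%d" Name="%s" SamplesPerPixel="1"/>',
            seq_len(nc) - 1L, vapply(channel_names, esc, "")),
    collapse = ""
  )
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<OME xmlns="http://www.openmicroscopy.org/Schemas/OME/2016-06">',
    '<Image ID="Image:0"><Pixels ID="Pixels:0" DimensionOrder="XYZCT" ',
    sprintf('Type="%s" BigEndian="false" ', pixel_type),
    sprintf('SizeX="%d" SizeY="%d" SizeZ="%d" SizeC="%d" SizeT="1" ', nx, ny, nz, nc),
    sprintf('PhysicalSizeX="%.17g" PhysicalSizeXUnit="µm" ', voxel_size_um[3L]),
    sprintf('PhysicalSizeY="%.17g" PhysicalSizeYUnit="µm" ', voxel_size_um[2L]),
    sprintf('PhysicalSizeZ="%.17g" PhysicalSizeZUnit="µm">', voxel_size_um[1L]),
    ch, "<TiffData/></Pixels></Image></OME>"
  )
}

#' Write a VoxelGrid as an OME-TIFF stack
#'
#' One page per (channel, z) plane in XYZCT order (z fastest), 64-bit float
#' samples, uncompressed. Channel names and physical voxel sizes are stored
#' in an OME-XML ImageDescription, so [read_stack()] recovers the grid
#' exactly.
#'
#' @param grid a [voxel_grid()].
#' @param path destination file path.
#' @param dtype `"float64"` (default; exact round trip of R doubles) or
#'   `"float32"` (half the file size, sufficient for photon-count-scale
#'   intensities).
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path, dtype = c("float64", "float32")) {
  if (!inherits(grid, "voxel_grid")) stopf("grid must be a voxel_grid")
  dtype <- match.arg(dtype)
  bytes <- if (dtype == "float64") 8 else 4
  d <- dim(grid$intensities)
  nc <- d[1L]; nz <- d[2L]; ny <- d[3L]; nx <- d[4L]
  con <- tryCatch(file(path, "wb"), condition = function(e) {
    stopf("cannot open '%s' for writing: %s", path, conditionMessage(e))
  })
  on.exit(close(con), add = TRUE)

  desc <- ome_description(nc, nz, ny, nx, grid$voxel_size_um, grid$channel_names,
                          if (dtype == "float64") "double" else "float")
  desc_raw <- c(charToRaw(enc2utf8(desc)), as.raw(0L))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))

  n_planes <- nc * nz
  plane_bytes <- as.numeric(nx) * ny * bytes
  data_start <- 8
  desc_offset <- data_start + n_planes * plane_bytes
  ifd_start <- desc_offset + length(desc_raw)
  n_tags <- function(first) if (first) 11L else 10L
  ifd_bytes <- function(first) 2 + 12 * n_tags(first) + 4
  ifd_offset <- numeric(n_planes)
  off <- ifd_start
  for (p in seq_len(n_planes)) {
    ifd_offset[p] <- off
    off <- off + ifd_bytes(p == 1L)
  }
  if (off > 2^32 - 1) stopf("stack too large for classic TIFF offsets")

  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  # unsigned 32-bit writer for offsets that may exceed .Machine$integer.max
  wu32 <- function(x) {
    x <- as.numeric(x)
    lo <- x %% 65536
    hi <- (x - lo) / 65536
    w16(lo); w16(hi)
  }
  entry <- function(tag, type, count, value, raw4 = NULL) {
    w16(tag); w16(type); w32(count)
    if (!is.null(raw4)) { writeBin(raw4, con); return(invisible()) }
    if (type == 3L) { w16(value); w16(0L) } else wu32(value)
  }

  writeBin(charToRaw("II"), con)
  w16(42L)
  wu32(ifd_start)
  # plane data: XYZCT order (z fastest across planes); within a plane x is
  # fastest (TIFF row order) -> permute once to (x, y, z, c) and dump
  payload <- as.double(aperm(grid$intensities, c(4L, 3L, 2L, 1L)))
  # writeBin caps at 2^31-1 elements; chunk by plane group
  chunk <- nx * ny * nz
  for (c in seq_len(nc)) {
    writeBin(payload[((c - 1) * chunk + 1):(c * chunk)], con,
             size = bytes, endian = "little")
  }
  writeBin(desc_raw, con)
  for (p in seq_len(n_planes)) {
    first <- p == 1L
    w16(n_tags(first))
    entry(256L, 4L, 1L, nx)
    entry(257L, 4L, 1L, ny)
    entry(258L, 3L, 1L, 8L * bytes)
    entry(259L, 3L, 1L, 1L)           # no compression
    entry(262L, 3L, 1L, 1L)           # BlackIsZero
    if (first) entry(270L, 2L, length(desc_raw), desc_offset)
    entry(273L, 4L, 1L, data_start + (p - 1) * plane_bytes)
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, ny)
    entry(279L, 4L, 1L, plane_bytes)
    entry(339L, 3L, 1L, 3L)           # IEEE float
    wu32(if (p < n_planes) ifd_offset[p + 1L] else 0)
  }
  invisible(path)
}

#' Read a TIFF / OME-TIFF stack into a VoxelGrid
#'
#' Axes are normalized to `(channel, z, y, x)`. Physical voxel sizes are
#' taken from OME-XML metadata when present; otherwise `voxel_size_um` must
#' be supplied — a stack without any voxel size is an error, never a silent
#' default.
#'
#' @param path TIFF file path.
#' @param voxel_size_um optional `(z, y, x)` voxel spacing override in
#'   micrometres; wins over metadata when given.
#' @return a [voxel_grid()].
#' @export
read_stack <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 8L) stopf("not a TIFF file: %s", path)
  bo <- rawToChar(buf[1:2])
  endian <- if (bo == "II") "little" else if (bo == "MM") "big" else
    stopf("not a TIFF file (bad byte-order mark): %s", path)
  u16 <- function(off) {
    v <- readBin(buf[(off + 1):(off + 2)], "integer", 1L, size = 2,
                 signed = FALSE, endian = endian)
    v
  }
  u32 <- function(off) {
    v <- readBin(buf[(off + 1):(off + 4)], "integer", 1L, size = 4, endian = endian)
    if (v < 0) v <- v + 2^32
    v
  }
  if (u16(2) != 42L) stopf("not a classic TIFF file: %s", path)

  read_values <- function(type, count, at) {
    # `at` is the byte offset of the 4-byte value/offset field
    size <- TIFF_TYPE_SIZE[[as.character(type)]]
    if (is.null(size)) return(NULL)
    total <- size * count
    off <- if (total <= 4) at else u32(at)
    if (type == 2L) {
      raw <- buf[(off + 1):(off + count)]
      raw <- raw[raw != as.raw(0L)]
      return(rawToChar(raw))
    }
    n <- count
    if (type == 3L) {
      vapply(seq_len(n) - 1L, function(i) u16(off + 2 * i), 0)
    } else if (type == 4L) {
      vapply(seq_len(n) - 1L, function(i) u32(off + 4 * i), 0)
    } else if (type == 1L) {
      as.integer(buf[(off + 1):(off + n)])
    } else { # RATIONAL
      vapply(seq_len(n) - 1L, function(i) {
        u32(off + 8 * i) / u32(off + 8 * i + 4)
      }, 0)
    }
  }

  pages <- list()
  description <- NULL
  ifd <- u32(4)
  while (ifd != 0) {
    nt <- u16(ifd)
    tags <- list()
    for (i in seq_len(nt)) {
      base <- ifd + 2 + 12 * (i - 1)
      tag <- u16(base); type <- u16(base + 2); count <- u32(base + 4)
      val <- read_values(type, count, base + 8)
      tags[[as.character(tag)]] <- val
    }
    g <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    width <- g(256); height <- g(257)
    if (is.null(width) || is.null(height)) stopf("TIFF page without dimensions")
    bits <- g(258, 1L)[1L]
    if (!is.null(g(259)) && g(259) != 1L) {
      stopf("compressed TIFF not supported (compression=%d)", g(259))
    }
    spp <- g(277, 1L)
    if (spp != 1L) {
      stopf("ambiguous axis order: SamplesPerPixel=%d not supported", spp)
    }
    fmt <- g(339, 1L)[1L]
    offs <- g(273); counts <- g(279)
    if (is.null(offs)) stopf("TIFF page without strip offsets")
    if (is.null(counts)) counts <- rep(width * height * bits / 8 / length(offs),
                                       length(offs))
    if (is.null(description)) description <- g(270)
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      nsamp <- counts[s] / (bits / 8)
      slice <- buf[(offs[s] + 1):(offs[s] + counts[s])]
      v <- if (fmt == 3L) {
        readBin(slice, "double", nsamp, size = bits / 8, endian = endian)
      } else {
        readBin(slice, "integer", nsamp, size = bits / 8,
                signed = bits >= 32, endian = endian)
      }
      if (fmt != 3L && bits < 32) v[v < 0] <- v[v < 0] + 2^bits
      vals <- c(vals, v)
    }
    m <- matrix(vals, nrow = width)   # x fastest within a row
    pages[[length(pages) + 1L]] <- t(m)  # -> (y, x)
    ifd <- u32(ifd + 2 + 12 * nt)
  }
  n_planes <- length(pages)
  if (n_planes == 0L) stopf("TIFF file contains no pages: %s", path)

  meta <- parse_ome_description(description)
  nc <- meta$size_c %||% 1L
  nz <- meta$size_z %||% n_planes
  nt_ <- meta$size_t %||% 1L
  if (nt_ != 1L) stopf("time series not supported (SizeT=%d)", nt_)
  if (nc * nz != n_planes) {
    stopf("metadata plane count (%d x %d) does not match pages (%d)",
          nc, nz, n_planes)
  }
  order <- meta$dimension_order %||% "XYZCT"
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  if (!all(vapply(pages, nrow, 0L) == ny) ||
      !all(vapply(pages, ncol, 0L) == nx)) {
    stopf("pages differ in size; not a simple stack")
  }
  arr <- array(0, dim = c(nc, nz, ny, nx))
  for (p in seq_len(n_planes)) {
    if (startsWith(order, "XYZ")) {
      z <- (p - 1L) %% nz + 1L
      c <- (p - 1L) %/% nz + 1L
    } else if (startsWith(order, "XYC")) {
      c <- (p - 1L) %% nc + 1L
      z <- (p - 1L) %/% nc + 1L
    } else {
      stopf("ambiguous axis order: DimensionOrder '%s' not supported", order)
    }
    arr[c, z, , ] <- pages[[p]]
  }
  vs <- voxel_size_um %||% meta$voxel_size_um
  if (is.null(vs)) {
    stopf("no voxel size in metadata and none supplied; pass voxel_size_um")
  }
  ch <- meta$channel_names
  if (is.null(ch) || length(ch) != nc) ch <- paste0("ch", seq_len(nc))
  voxel_grid(arr, vs, ch)
}

# pull what we need out of an OME-XML ImageDescription (lenient regex scan;
# only attributes this package writes are guaranteed)
parse_ome_description <- function(desc) {
  out <- list()
  if (is.null(desc) || !grepl("<", desc, fixed = TRUE)) return(out)
  num_attr <- function(name) {
    m <- regmatches(desc, regexec(sprintf('%s="([0-9eE.+-]+)"', name), desc))[[1L]]
    if (length(m) == 2L) as.numeric(m[2L]) else NULL
  }
  str_attr <- function(name) {
    m <- regmatches(desc, regexec(sprintf('%s="([^"]*)"', name), desc))[[1L]]
    if (length(m) == 2L) m[2L] else NULL
  }
  out$size_x <- as.integer(num_attr("SizeX") %||% NA)
  out$size_y <- as.integer(num_attr("SizeY") %||% NA)
  out$size_z <- if (!is.null(num_attr("SizeZ"))) as.integer(num_attr("SizeZ"))
  out$size_c <- if (!is.null(num_attr("SizeC"))) as.integer(num_attr("SizeC"))
  out$size_t <- if (!is.null(num_attr("SizeT"))) as.integer(num_attr("SizeT"))
  out$dimension_order <- str_attr("DimensionOrder")
  px <- num_attr("PhysicalSizeX"); py <- num_attr("PhysicalSizeY")
  pz <- num_attr("PhysicalSizeZ")
  if (!is.null(px) && !is.null(py) && !is.null(pz)) {
    out$voxel_size_um <- c(pz, py, px)
  }
  chm <- regmatches(desc, gregexpr('<Channel [^>]*Name="([^"]*)"', desc))[[1L]]
  if (length(chm)) {
    out$channel_names <- vapply(chm, function(s) {
      sub('.*Name="([^"]*)".*', "\\1", s)
    }, "", USE.NAMES = FALSE)
  }
  out
}
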