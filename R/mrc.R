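# MRC2014 volume / MRCS stack reader and writer (little-endian, modes
# 0/1/2/6 on read, mode 2 float32 on write). Only the crystallographic
# default axis order (mapc,mapr,maps = 1,2,3: x fastest, z sections) is
# accepted; data are held as an R array indexed [x, y, z].

MRC_HEADER_BYTES <- 1024L

read_mrc_raw <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  if (length(ints) < 10) stop("format error: truncated MRC header in ", path)
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  mx <- ints[8]; my <- ints[9]; mz <- ints[10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")      # cellb
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  if (nx <= 0 || ny <= 0 || nz <= 0 || nx > 1e5 || ny > 1e5 || nz > 1e7)
    stop("format error: implausible MRC dimensions (nx=", nx, ", ny=", ny,
         ", nz=", nz, ") in ", path)
  if (!all(mapcrs == c(1L, 2L, 3L)) && !all(mapcrs == 0L))
    stop("format error: unsupported MRC axis order (mapc,mapr,maps = ",
         paste(mapcrs, collapse = ","), ") in ", path)
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, MRC_HEADER_BYTES + max(0L, nsymbt))
  nvox <- as.double(nx) * ny * nz
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = nvox, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", n = nvox, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = nvox, size = 2, signed = FALSE,
                  endian = "little"),
    stop("format error: unsupported MRC mode ", mode, " in ", path))
  if (length(data) < nvox)
    stop("format error: truncated MRC data in ", path, " (expected ", nvox,
         " voxels, got ", length(data), ")")
  vsize <- if (mx > 0 && cella[1] > 0) cella[1] / mx else 1
  list(data = array(as.double(data), c(nx, ny, nz)), voxel_size = vsize)
}

#' Read an MRC volume
#'
#' @param path Path to an MRC file.
#' @return A [map_volume()]; voxel size taken from the header cell.
#' @export
read_map <- function(path) {
  raw <- read_mrc_raw(path)
  map_volume(raw$data, raw$voxel_size)
}

#' Read an MRCS particle image stack
#'
#' @param path Path to an MRC/MRCS stack (sections = images).
#' @return A [particle_stack()].
#' @export
read_stack <- function(path) {
  raw <- read_mrc_raw(path)
  d <- dim(raw$data)
  if (d[1] != d[2])
    stop("format error: non-square stack images (", d[1], "x", d[2], ") in ", path)
  particle_stack(raw$data, raw$voxel_size)
}

write_mrc_raw <- function(data, voxel_size, path) {
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L)), con, size = 4, endian = "little")  # nxyz, mode
  writeBin(integer(3), con, size = 4, endian = "little")            # nxyzstart
  writeBin(as.integer(d), con, size = 4, endian = "little")         # mxyz
  writeBin(as.numeric(d * voxel_size), con, size = 4, endian = "little")
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")
  writeBin(c(1L, 2L, 3L), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(data), max(data), mean(data))), con, size = 4,
           endian = "little")
  writeBin(integer(2), con, size = 4, endian = "little")            # ispg, nsymbt
  writeBin(integer(25), con, size = 4, endian = "little")           # extra
  writeBin(numeric(3), con, size = 4, endian = "little")            # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(c(68L, 65L, 0L, 0L), con, size = 1)                      # machst LE
  writeBin(as.numeric(stats::sd(data)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")                    # nlabl
  writeBin(raw(800), con)
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Write an MRC volume
#'
#' @param vol A [map_volume()].
#' @param path Output path.
#' @export
write_map <- function(vol, path) {
  write_mrc_raw(vol$data, vol$voxel_size, path)
}

#' Write an MRCS particle stack
#'
#' @param stack A [particle_stack()].
#' @param path Output path.
#' @export
write_stack <- function(stack, path) {
  write_mrc_raw(stack$images, stack$pixel_size, path)
}
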