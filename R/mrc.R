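#' Read and write MRC volumes
#'
#' Minimal MRC2014 I/O for cubic mode-2 (32-bit float) volumes, the dialect
#' used for EMDB-deposited cryo-EM maps.  The voxel size is stored in (and
#' read back from) the `CELLA`/`MX` header fields; the physical origin goes in
#' the `ORIGIN` words.  Only little-endian mode-2 files are supported, which
#' covers essentially all modern deposits.
#'
#' @param path File path.
#' @return `read_map()` returns a [density_map]; `write_map()` returns `path`
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".mrc")
#' write_map(density_map(array(rnorm(8^3), c(8, 8, 8))), f)
#' m <- read_map(f)
#' @export
read_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_ints[1]; ny <- hdr_ints[2]; nz <- hdr_ints[3]
  mode <- hdr_ints[4]
  mxyz <- hdr_ints[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  if (any(c(nx, ny, nz) <= 0) || any(c(nx, ny, nz) > 1e5) ||
      is.na(mode) || mode < 0 || mode > 101)
    abort(sprintf("unreadable MRC header in %s", path))
  if (mode != 2)
    abort(sprintf("unsupported MRC mode %d (only mode 2, 32-bit float)", mode))
  if (nx != ny || nx != nz)
    abort(sprintf("volume must be cubic; got extents %d x %d x %d", nx, ny, nz))
  seek(con, where = 92, origin = "start")   # word 24: NSYMBT
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, where = 196, origin = "start")  # words 50-52: ORIGIN
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  voxel <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else 1
  seek(con, where = 1024 + max(0, nsymbt), origin = "start")
  vals <- readBin(con, "numeric", n = nx * ny * nz, size = 4,
                  endian = "little")
  if (length(vals) < nx * ny * nz)
    abort(sprintf("truncated MRC data in %s", path))
  density_map(array(vals, c(nx, ny, nz)), voxel_size = voxel, origin = origin)
}

#' @rdname read_map
#' @param map A [density_map] to write.
#' @export
write_map <- function(map, path) {
  stopifnot(is_density_map(map))
  dir <- dirname(path)
  if (!dir.exists(dir)) abort(sprintf("directory does not exist: %s", dir))
  n <- map_side(map)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(n, n, n))                     # NX NY NZ
  wi(2)                              # MODE 2 = float32
  wi(c(0, 0, 0))                     # NXSTART..
  wi(c(n, n, n))                     # MX MY MZ
  wf(rep(n * map$voxel_size, 3))     # CELLA
  wf(c(90, 90, 90))                  # CELLB
  wi(c(1, 2, 3))                     # MAPC MAPR MAPS
  wf(c(min(map$data), max(map$data), mean(map$data)))
  wi(1)                              # ISPG
  wi(0)                              # NSYMBT
  wi(rep(0, 25))                     # EXTRA
  wf(map$origin)                     # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(map$data))                   # RMS
  wi(0)                              # NLABL
  writeBin(raw(800), con)            # labels
  wf(map$data)
  invisible(path)
}
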