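# LAS 1.2 reader/writer, point data format 0 (uncompressed). Coordinates are
# stored as int32 counts of a scale quantum (default 1 mm) from a per-file
# offset placed at the floor of the cloud bounds, so round-trips are exact to
# half a quantum. Header is the fixed 227-byte LAS 1.2 public header block.

LAS_HEADER_SIZE <- 227L
LAS_RECORD_LENGTH <- 20L

#' Write a point cloud as LAS 1.2 (point format 0)
#'
#' @param cloud A [point_cloud()].
#' @param path Output file path.
#' @param scale Coordinate quantum in metres, default 0.001 (millimetre
#'   fidelity at terrestrial scene scale).
#' @return `path`, invisibly.
#' @export
write_las <- function(cloud, path, scale = 0.001) {
  stopifnot(inherits(cloud, "point_cloud"), scale > 0)
  n <- n_points(cloud)
  if (n > 0L) {
    b <- cloud_bounds(cloud)
    offset <- floor(b["min", ])
  } else {
    b <- matrix(0, 2, 3, dimnames = list(c("min", "max"), c("x", "y", "z")))
    offset <- c(x = 0, y = 0, z = 0)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, width) {
    r <- charToRaw(s)
    c(r[seq_len(min(length(r), width))], raw(max(0L, width - length(r))))
  }
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  f64 <- function(x) writeBin(as.double(x), con, size = 8, endian = "little")
  writeBin(charToRaw("LASF"), con)
  u16(0); u16(0)                         # file source id, global encoding
  writeBin(raw(16), con)                 # project GUID
  writeBin(as.raw(c(1L, 2L)), con)       # version 1.2
  writeBin(pad("tlsbench", 32), con)     # system identifier
  writeBin(pad("tlsbench R package", 32), con)
  today <- as.POSIXlt(Sys.Date())
  u16(today$yday + 1L); u16(today$year + 1900L)
  u16(LAS_HEADER_SIZE)
  u32(LAS_HEADER_SIZE)                   # offset to point data
  u32(0)                                 # number of VLRs
  writeBin(as.raw(0L), con)              # point data format 0
  u16(LAS_RECORD_LENGTH)
  u32(n)
  u32(c(n, 0L, 0L, 0L, 0L))              # points by return
  f64(rep(scale, 3))
  f64(offset)
  f64(c(b["max", 1], b["min", 1], b["max", 2], b["min", 2],
        b["max", 3], b["min", 3]))
  if (n > 0L) {
    q <- function(v, o) as.integer(round((v - o) / scale))
    rec <- matrix(raw(1), nrow = LAS_RECORD_LENGTH, ncol = n)
    int_bytes <- function(x) matrix(writeBin(x, raw(), size = 4,
                                             endian = "little"), nrow = 4)
    rec[1:4, ] <- int_bytes(q(cloud$xyz[, 1], offset[1]))
    rec[5:8, ] <- int_bytes(q(cloud$xyz[, 2], offset[2]))
    rec[9:12, ] <- int_bytes(q(cloud$xyz[, 3], offset[3]))
    rec[15, ] <- as.raw(0x09)            # return 1 of 1
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}

#' Read a LAS file (point format 0, uncompressed)
#'
#' @param path Input file path.
#' @param device Device label for the returned cloud, default "unknown".
#' @return A [point_cloud()].
#' @export
read_las <- function(path, device = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  size <- file.info(path)$size
  if (size < LAS_HEADER_SIZE)
    stop(sprintf("malformed LAS header: file is %d bytes, header needs %d",
                 size, LAS_HEADER_SIZE))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, raw(), LAS_HEADER_SIZE)
  if (!identical(rawToChar(hdr[1:4]), "LASF"))
    stop("malformed LAS header: bad signature at offset 0 (expected 'LASF')")
  u16 <- function(at) readBin(hdr[at + 1:2], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(hdr[at + 1:4], "integer", size = 4,
                              endian = "little")
  f64 <- function(at, k = 1) readBin(hdr[at + 1:(8 * k)], "double", n = k,
                                     size = 8, endian = "little")
  version <- as.integer(hdr[25:26])
  header_size <- u16(94L)
  if (header_size < LAS_HEADER_SIZE)
    stop(sprintf("malformed LAS header: header size %d at offset 94", header_size))
  data_offset <- u32(96L)
  fmt <- as.integer(hdr[105])
  if (fmt != 0L)
    stop("unsupported LAS point data format ", fmt, " (only format 0)")
  reclen <- u16(105L)
  n <- u32(107L)
  scale <- f64(131L, 3)
  offset <- f64(155L, 3)
  if (size < data_offset + as.double(n) * reclen)
    stop(sprintf(paste0("truncated LAS file: %d point records declared at ",
                        "offset %d need %d bytes, file has %d"),
                 n, data_offset, n * reclen, size))
  if (is.null(device)) device <- "unknown"
  if (n == 0L)
    return(point_cloud(matrix(numeric(0), ncol = 3), device = device))
  seek(con, data_offset)
  block <- readBin(con, raw(), n * reclen)
  rec <- matrix(block, nrow = reclen)
  int32 <- function(rows) readBin(as.vector(rec[rows, ]), "integer",
                                  n = n, size = 4, endian = "little")
  xyz <- cbind(int32(1:4) * scale[1] + offset[1],
               int32(5:8) * scale[2] + offset[2],
               int32(9:12) * scale[3] + offset[3])
  point_cloud(xyz, device = device)
}
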