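# CCP4/MRC2014 volume I/O, mode 2 (float32), orthogonal cells only.
# Header: 256 four-byte words; word numbering below is 1-based as in the
# format documentation. Data follow at byte 1024 (+ NSYMBT), column axis
# (MAPC) fastest.

#' Read a density map in CCP4/MRC format
#'
#' Supports MRC2014/CCP4 mode-2 (float32) maps with orthogonal cells. The
#' data block is permuted using MAPC/MAPR/MAPS so the returned grid always
#' indexes as (x, y, z). The grid origin is taken from the ORIGIN header
#' words when any is nonzero, otherwise from NCSTART/NRSTART/NSSTART times
#' the voxel size (the two conventions in common use).
#'
#' @param path path to a CCP4/MRC map file.
#' @return a [density_grid()].
#' @export
read_ccp4 <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 1024L)
  if (length(hdr_raw) < 1024L) stop("truncated CCP4 header in ", path)
  word_int <- function(w) readBin(hdr_raw[(4 * (w - 1) + 1):(4 * w)],
                                  "integer", size = 4L, endian = "little")
  words_num <- function(w0, n) readBin(hdr_raw[(4 * (w0 - 1) + 1):(4 * (w0 + n - 1))],
                                       "numeric", size = 4L, n = n,
                                       endian = "little")
  magic <- rawToChar(hdr_raw[209:212])
  if (!identical(substr(magic, 1, 3), "MAP"))
    stop("not a CCP4/MRC map (missing MAP magic): ", path)
  nc <- word_int(1); nr <- word_int(2); ns <- word_int(3)
  mode <- word_int(4)
  if (mode != 2L) stop("unsupported CCP4 data mode ", mode,
                       " (only mode 2, float32): ", path)
  nstart <- c(word_int(5), word_int(6), word_int(7))
  m_grid <- c(word_int(8), word_int(9), word_int(10))
  cell <- words_num(11, 3)
  angles <- words_num(14, 3)
  if (any(abs(angles - 90) > 1e-3))
    stop("non-orthogonal cell (angles ", paste(round(angles, 2), collapse = ", "),
         ") unsupported: ", path)
  axes <- c(word_int(17), word_int(18), word_int(19))  # MAPC, MAPR, MAPS
  if (!setequal(axes, 1:3)) stop("invalid MAPC/MAPR/MAPS in ", path)
  nsymbt <- word_int(24)
  origin_words <- words_num(50, 3)
  if (any(m_grid <= 0L) || any(cell <= 0))
    stop("invalid cell/sampling in CCP4 header: ", path)
  voxel <- cell / m_grid                       # per crystal axis x,y,z
  nvox <- as.double(nc) * nr * ns
  if (nvox < 1) stop("empty map: ", path)
  if (nsymbt > 0L) readBin(con, "raw", n = nsymbt)
  vals <- readBin(con, "numeric", size = 4L, n = nvox, endian = "little")
  if (length(vals) < nvox) stop("truncated CCP4 data block in ", path)
  a <- array(vals, dim = c(nc, nr, ns))
  perm <- match(1:3, axes)  # file dimension holding crystal axis d
  a <- aperm(a, perm)
  if (any(abs(origin_words) > 0)) {
    origin <- origin_words
  } else {
    nstart_xyz <- nstart[perm]
    origin <- nstart_xyz * voxel
  }
  density_grid(a, voxel_size = voxel, origin = origin, axis_order = axes)
}

#' Write a density map in CCP4/MRC format
#'
#' Emits an MRC2014-conformant mode-2 (float32) file with MAPC/MAPR/MAPS =
#' 1,2,3, cell = dims x voxel_size, DMIN/DMAX/DMEAN/RMS filled from the data
#' and the grid origin stored in the ORIGIN words.
#'
#' @param grid a [density_grid()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ccp4 <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  d <- dim(grid$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  v <- as.numeric(grid$values)
  wi(d)                                  # 1-3  NC, NR, NS
  wi(2L)                                 # 4    MODE float32
  wi(c(0L, 0L, 0L))                      # 5-7  NCSTART..
  wi(d)                                  # 8-10 MX, MY, MZ
  wf(d * grid$voxel_size)                # 11-13 cell lengths
  wf(c(90, 90, 90))                      # 14-16 cell angles
  wi(1:3)                                # 17-19 MAPC, MAPR, MAPS
  wf(c(min(v), max(v), mean(v)))         # 20-22 DMIN, DMAX, DMEAN
  wi(1L)                                 # 23   ISPG (P1)
  wi(0L)                                 # 24   NSYMBT
  wi(rep(0L, 25))                        # 25-49 EXTRA
  wf(grid$origin)                        # 50-52 ORIGIN (x, y, z)
  writeBin(charToRaw("MAP "), con)       # 53   magic
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # 54 MACHST little-endian
  wf(sqrt(mean((v - mean(v))^2)))        # 55   RMS
  wi(0L)                                 # 56   NLABL
  writeBin(raw(4L * 200L), con)          # 57-256 labels
  wf(v)                                  # data, x fastest (column-major)
  invisible(path)
}
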