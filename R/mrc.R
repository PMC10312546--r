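## Minimal CCP4/MRC (MRC2014) volume I/O, mode 2 (float32), X axis fastest.
## No installed R package reads or writes this format, so the 1024-byte
## header is assembled by hand; only the fields this package needs are
## interpreted on read.

#' Write a density map as a CCP4/MRC file
#'
#' Mode-2 (float32) MRC2014 volume with cubic cell, axis order X fastest, and
#' the ORIGIN header words set to the box corner so atom coordinates map
#' correctly into the grid.
#'
#' @param map A `swaxs_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mrc <- function(map, path) {
  n <- map$spec$n
  vals <- as.numeric(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(n, n, n))                 # NX NY NZ
  wi(2)                          # MODE 2 = float32
  wi(c(0, 0, 0))                 # NXSTART..
  wi(c(n, n, n))                 # MX MY MZ
  wf(rep(map$spec$side, 3))      # CELLA
  wf(c(90, 90, 90))              # CELLB
  wi(c(1, 2, 3))                 # MAPC MAPR MAPS
  wf(c(min(vals), max(vals), mean(vals)))  # DMIN DMAX DMEAN
  wi(1)                          # ISPG
  wi(0)                          # NSYMBT
  wi(rep(0, 25))                 # EXTRA (words 26-50 incl. origin slot start)
  ## words 50-52 are ORIGIN in MRC2014; we wrote 25 extra words covering
  ## words 26-49 above, so write origin now (words 50-52)
  wf(map$spec$origin)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(vals))            # RMS
  wi(1)                          # NLABL
  lab <- sprintf("%-80s", "swaxsmap density map")
  writeChar(substr(lab, 1, 80), con, nchars = 80, eos = NULL)
  writeChar(paste(rep(" ", 80 * 9), collapse = ""), con, nchars = 720, eos = NULL)
  wf(vals)
  invisible(path)
}

#' Read a CCP4/MRC volume written by [write_mrc()]
#'
#' Supports mode-2 cubic volumes with default axis order.
#'
#' @param path File path.
#' @return A `swaxs_map` (role `"in_vacuo"` placeholder; set by caller if
#'   needed).
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", n = k, size = 4, endian = "little")
  rf <- function(k) readBin(con, "numeric", n = k, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only mode-2 (float32) MRC supported", call. = FALSE)
  ri(3)            # nxstart
  m <- ri(3)       # mx my mz
  cella <- rf(3)
  rf(3); mapcrs <- ri(3)
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported MRC axis order", call. = FALSE)
  rf(3)            # dmin dmax dmean
  ri(1); nsymbt <- ri(1)
  ri(25)
  origin <- rf(3)
  seek(con, 1024 + nsymbt)
  vals <- rf(prod(dims))
  spec <- structure(list(n = dims[1], voxel = cella[1] / m[1],
                         side = cella[1], origin = origin, dmax = NA_real_),
                    class = "grid_spec")
  .new_map(spec, array(vals, dims), "in_vacuo")
}
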