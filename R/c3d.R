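# Minimal C3D motion-capture file support.
#
# Implements the subset of the public C3D specification needed to exchange
# labelled 3-D point data with motion-capture exports: Intel (PC) processor
# type, float or scaled-integer point storage, POINT group parameters USED /
# LABELS / RATE / SCALE / UNITS / FRAMES.  Analog channels are ignored.

#' Read labelled point trajectories from a C3D file
#'
#' Positions are converted to metres (honouring `POINT:UNITS`, default mm)
#' and remapped into the package's axis convention via `axis_map`.
#'
#' @param path C3D file path.
#' @param axis_map named list mapping package axes to file axes, e.g.
#'   `list(x = "y", y = "-x", z = "z")` reads the package's anterior axis from
#'   the file's Y axis.  Default is the identity.
#' @param markers optional character vector of marker labels that must be
#'   present; an informative error names any that are missing.
#' @return named list of [marker_trajectory()] objects.
#' @export
read_c3d <- function(path, axis_map = list(x = "x", y = "y", z = "z"),
                     markers = NULL) {
  if (!file.exists(path)) stop(sprintf("read_c3d: no such file: %s", path))
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 1024L) stop("read_c3d: file too short to be a C3D file")
  u8 <- function(i) as.integer(raw[i])
  i16 <- function(i) readBin(raw[i:(i + 1L)], "integer", size = 2L,
                             endian = "little")
  f32 <- function(i) readBin(raw[i:(i + 3L)], "double", size = 4L,
                             endian = "little")

  param_block <- u8(1L)
  if (u8(2L) != 80L) stop("read_c3d: not a C3D file (magic byte != 0x50)")
  npoints <- i16(3L)
  first_frame <- i16(7L)
  last_frame <- i16(9L)
  hdr_scale <- f32(13L)
  data_block <- i16(17L)
  rate <- f32(21L)
  nframes <- last_frame - first_frame + 1L

  poff <- (param_block - 1L) * 512L
  proc <- u8(poff + 4L)
  if (proc != 84L)
    stop(sprintf("read_c3d: unsupported processor type %d (only Intel/84)", proc))

  # walk the parameter records
  params <- list(); groups <- character(0)
  pos <- poff + 5L
  repeat {
    nchar_raw <- readBin(raw[pos], "integer", size = 1L, signed = TRUE)
    id <- readBin(raw[pos + 1L], "integer", size = 1L, signed = TRUE)
    nlen <- abs(nchar_raw)
    if (nlen == 0L) break
    name <- rawToChar(raw[(pos + 2L):(pos + 1L + nlen)])
    off_pos <- pos + 2L + nlen
    offset <- i16(off_pos)
    if (id < 0L) {                       # group definition
      groups[as.character(-id)] <- toupper(name)
    } else if (id > 0L) {                # parameter
      p <- off_pos + 2L
      type <- readBin(raw[p], "integer", size = 1L, signed = TRUE)
      ndim <- u8(p + 1L)
      dims <- if (ndim > 0L)
        vapply(seq_len(ndim), function(k) u8(p + 1L + k), integer(1))
      else integer(0)
      dstart <- p + 2L + ndim
      nelem <- if (length(dims)) prod(dims) else 1L
      size <- c(`-1` = 1L, `1` = 1L, `2` = 2L, `4` = 4L)[[as.character(type)]]
      bytes <- raw[dstart:(dstart + nelem * size - 1L)]
      value <- switch(as.character(type),
        `-1` = rawToChar(bytes, multiple = FALSE),
        `1` = readBin(bytes, "integer", n = nelem, size = 1L, signed = TRUE),
        `2` = readBin(bytes, "integer", n = nelem, size = 2L,
                      endian = "little"),
        `4` = readBin(bytes, "double", n = nelem, size = 4L,
                      endian = "little"))
      params[[paste0(id, ":", toupper(name))]] <-
        list(value = value, dims = dims, type = type)
    }
    if (offset == 0L) break
    pos <- off_pos + 2L + offset
  }
  point_gid <- names(groups)[groups == "POINT"]
  if (!length(point_gid)) stop("read_c3d: no POINT group in parameter section")
  getp <- function(nm) params[[paste0(point_gid, ":", nm)]]

  pu <- getp("USED"); if (!is.null(pu)) npoints <- pu$value[1L]
  pr <- getp("RATE"); if (!is.null(pr)) rate <- pr$value[1L]
  pf <- getp("FRAMES"); if (!is.null(pf)) nframes <- pf$value[1L]
  ps <- getp("SCALE"); scale <- if (!is.null(ps)) ps$value[1L] else hdr_scale
  pdb <- getp("DATA_START"); if (!is.null(pdb)) data_block <- pdb$value[1L]

  labels <- NULL
  pl <- getp("LABELS")
  if (!is.null(pl) && length(pl$dims) == 2L) {
    w <- pl$dims[1L]
    labels <- vapply(seq_len(pl$dims[2L]), function(k)
      trimws(substr(pl$value, (k - 1L) * w + 1L, k * w)), character(1))
  }
  if (is.null(labels)) stop("read_c3d: file has unlabelled points")
  labels <- labels[seq_len(npoints)]
  if (anyDuplicated(labels)) stop("read_c3d: duplicate point labels")

  unit_scale <- 1 / 1000  # default: millimetres
  puu <- getp("UNITS")
  if (!is.null(puu)) {
    u <- trimws(puu$value)
    unit_scale <- switch(u, m = 1, mm = 1 / 1000, cm = 1 / 100,
                         stop(sprintf("read_c3d: unknown POINT:UNITS '%s'", u)))
  }

  doff <- (data_block - 1L) * 512L
  vals_per_frame <- npoints * 4L
  if (scale < 0) {                       # float storage
    need <- nframes * vals_per_frame * 4L
    dat <- readBin(raw[(doff + 1L):(doff + need)], "double",
                   n = nframes * vals_per_frame, size = 4L, endian = "little")
  } else {                               # scaled int16 storage
    need <- nframes * vals_per_frame * 2L
    dat <- readBin(raw[(doff + 1L):(doff + need)], "integer",
                   n = nframes * vals_per_frame, size = 2L,
                   endian = "little") * scale
  }
  arr <- array(dat, dim = c(4L, npoints, nframes))

  out <- list()
  for (k in seq_len(npoints)) {
    file_xyz <- t(arr[1:3, k, , drop = TRUE]) * unit_scale
    if (nframes == 1L) file_xyz <- matrix(file_xyz, nrow = 1L)
    colnames(file_xyz) <- c("x", "y", "z")
    xyz <- sapply(c("x", "y", "z"), function(ax) {
      spec <- axis_map[[ax]]
      sgn <- if (startsWith(spec, "-")) -1 else 1
      src <- sub("^-", "", spec)
      sgn * file_xyz[, src]
    })
    if (nframes == 1L) xyz <- matrix(xyz, nrow = 1L,
                                     dimnames = list(NULL, c("x", "y", "z")))
    out[[labels[k]]] <- marker_trajectory(labels[k], xyz, rate = rate)
  }
  if (!is.null(markers)) {
    miss <- setdiff(markers, names(out))
    if (length(miss))
      stop(sprintf("read_c3d: marker(s) not in file: %s",
                   paste(miss, collapse = ", ")))
  }
  out
}

#' Write marker trajectories to a minimal C3D file
#'
#' Fixture-grade writer producing Intel-format C3D with float point storage
#' and a POINT parameter group (USED, FRAMES, RATE, SCALE, DATA_START,
#' LABELS, UNITS).  Intended for round-trip tests and interoperability
#' checks, not as a full-featured exporter.
#'
#' @param markers named list of [marker_trajectory()] objects sharing rate
#'   and length.
#' @param path output path.
#' @param units `"mm"` (conventional for C3D) or `"m"`.
#' @return `path`, invisibly.
#' @export
write_c3d <- function(markers, path, units = c("mm", "m")) {
  units <- match.arg(units)
  stopifnot(length(markers) > 0L)
  rates <- vapply(markers, function(m) m$rate, numeric(1))
  lens <- vapply(markers, function(m) nrow(m$xyz), integer(1))
  if (length(unique(rates)) != 1L || length(unique(lens)) != 1L)
    stop("write_c3d: markers must share rate and length")
  npoints <- length(markers)
  nframes <- lens[1L]
  rate <- rates[1L]
  mult <- if (units == "mm") 1000 else 1
  labels <- names(markers)
  lw <- max(4L, max(nchar(labels)))
  pad <- function(s, w) formatC(s, width = w, flag = "-")

  # ---- parameter section ----
  con <- rawConnection(raw(0), "wb")
  w8 <- function(v) writeBin(as.integer(v), con, size = 1L)
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wchr <- function(s) writeBin(charToRaw(s), con)

  group <- function(name, id) {
    w8(nchar(name)); w8(-id); wchr(name)
    w16(1L)   # offset: next record follows the 1-byte description length
    w8(0L)    # no description
  }
  param <- function(name, gid, type, dims, writer, databytes) {
    w8(nchar(name)); w8(gid); wchr(name)
    # offset from after-offset-word to next record: type + ndim + dims + data + desclen
    w16(2L + length(dims) + databytes + 1L)
    w8(type); w8(length(dims)); for (d in dims) w8(d)
    writer()
    w8(0L)    # no description
  }

  w8(1L); w8(80L)   # first two magic bytes of the parameter section
  nparam_blocks_pos <- 3L
  w8(0L)            # parameter block count, patched below
  w8(84L)           # Intel processor type
  group("POINT", 1L)
  param("USED", 1L, 2L, integer(0), function() w16(npoints), 2L)
  param("FRAMES", 1L, 2L, integer(0), function() w16(nframes), 2L)
  param("RATE", 1L, 4L, integer(0), function() wf(rate), 4L)
  param("SCALE", 1L, 4L, integer(0), function() wf(-1), 4L)
  param("LABELS", 1L, -1L, c(lw, npoints),
        function() for (s in labels) wchr(pad(s, lw)), lw * npoints)
  param("UNITS", 1L, -1L, nchar(units), function() wchr(units), nchar(units))
  w8(0L); w8(0L)    # terminating record (nchar = 0)
  pbytes <- rawConnectionValue(con); close(con)
  n_pblocks <- ceiling(length(pbytes) / 512)
  pbytes[nparam_blocks_pos] <- as.raw(n_pblocks)
  pbytes <- c(pbytes, raw(n_pblocks * 512L - length(pbytes)))
  # patch DATA_START into header below
  data_block <- 2L + n_pblocks

  # ---- header block ----
  con <- rawConnection(raw(0), "wb")
  w8 <- function(v) writeBin(as.integer(v), con, size = 1L)
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  w8(2L); w8(80L)          # parameter block pointer, magic
  w16(npoints); w16(0L)    # points, analog per frame
  w16(1L); w16(nframes)    # first, last frame
  w16(0L)                  # max interpolation gap
  wf(-1)                   # scale (negative: float data)
  w16(data_block)          # data start block
  w16(0L)                  # analog samples per frame
  wf(rate)
  hdr <- rawConnectionValue(con); close(con)
  hdr <- c(hdr, raw(512L - length(hdr)))

  # ---- point data ----
  con <- rawConnection(raw(0), "wb")
  dat <- array(0, dim = c(4L, npoints, nframes))
  for (k in seq_len(npoints))
    dat[1:3, k, ] <- t(markers[[k]]$xyz) * mult
  writeBin(as.numeric(dat), con, size = 4L, endian = "little")
  dbytes <- rawConnectionValue(con); close(con)
  if (length(dbytes) %% 512L)
    dbytes <- c(dbytes, raw(512L - length(dbytes) %% 512L))

  writeBin(c(hdr, pbytes, dbytes), path)
  invisible(path)
}
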