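# Minimal C3D support (read, plus an internal writer used for round-trip
# tests). Covers the common modern variant: Intel (little-endian) byte order,
# 3D point data stored as floats (negative POINT:SCALE) or as scaled 16-bit
# integers, no analog channels required. Invalid points (negative residual)
# become NA.

c3d_read_params <- function(raw, pblock) {
  off <- (pblock - 1L) * 512L
  nparam_blocks <- as.integer(raw[off + 3L])
  proc <- as.integer(raw[off + 4L])
  if (proc != 84L) {
    stop_exerstep("FormatError",
                  sprintf("unsupported C3D processor type %d (only Intel/84)", proc))
  }
  bytes <- raw[(off + 1L):min(length(raw), off + 512L * max(nparam_blocks, 1L))]
  params <- list()
  groups <- character()  # id -> name
  p <- 5L
  repeat {
    if (p + 1L > length(bytes)) break
    nname <- readBin(bytes[p], "integer", size = 1L, signed = TRUE)
    gid <- readBin(bytes[p + 1L], "integer", size = 1L, signed = TRUE)
    if (nname == 0L || gid == 0L) break
    nname_abs <- abs(nname)
    name <- rawToChar(bytes[(p + 2L):(p + 1L + nname_abs)])
    q <- p + 2L + nname_abs
    offset <- readBin(bytes[q:(q + 1L)], "integer", size = 2L, signed = TRUE)
    nextp <- q + offset
    if (gid < 0L) {
      groups[as.character(-gid)] <- name
    } else {
      r <- q + 2L
      esize <- readBin(bytes[r], "integer", size = 1L, signed = TRUE)
      ndim <- as.integer(bytes[r + 1L])
      dims <- if (ndim > 0L) as.integer(bytes[(r + 2L):(r + 1L + ndim)]) else integer()
      ndat <- prod(c(1L, dims)) * abs(esize)
      dstart <- r + 2L + ndim
      dat_raw <- if (ndat > 0L) bytes[dstart:(dstart + ndat - 1L)] else raw(0)
      value <- switch(as.character(esize),
        "-1" = {
          ch <- rawToChar(dat_raw)
          if (length(dims) >= 2L && dims[1] > 0L && nchar(ch) >= dims[1]) {
            w <- dims[1]
            trimws(substring(ch, seq(1, nchar(ch), by = w), seq(w, nchar(ch), by = w)))
          } else if (nchar(ch)) trimws(ch) else character()
        },
        "1" = readBin(dat_raw, "integer", n = prod(c(1L, dims)), size = 1L, signed = TRUE),
        "2" = readBin(dat_raw, "integer", n = prod(c(1L, dims)), size = 2L,
                      signed = TRUE, endian = "little"),
        "4" = readBin(dat_raw, "double", n = prod(c(1L, dims)), size = 4L,
                      endian = "little"),
        stop_exerstep("FormatError", sprintf("bad C3D element size %d", esize))
      )
      params[[paste0("G", gid, ":", toupper(name))]] <- value
    }
    if (offset == 0L) break
    p <- nextp
  }
  # re-key by group name
  out <- list()
  for (k in names(params)) {
    gid <- sub("^G([0-9]+):.*$", "\\1", k)
    pname <- sub("^G[0-9]+:", "", k)
    gname <- groups[gid]
    if (is.na(gname)) gname <- paste0("G", gid)
    out[[paste0(toupper(gname), ":", pname)]] <- params[[k]]
  }
  out
}

read_c3d <- function(path, units = NULL, aliases = default_marker_aliases()) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 512L) stop_exerstep("EmptyRecording", sprintf("not a C3D file: %s", path))
  if (as.integer(raw[2]) != 80L) {
    stop_exerstep("FormatError", "missing C3D magic byte (0x50)")
  }
  pblock <- as.integer(raw[1])
  hdr_i2 <- function(w) readBin(raw[(2L * w - 1L):(2L * w)], "integer", size = 2L,
                                signed = TRUE, endian = "little")
  hdr_f4 <- function(w) readBin(raw[(2L * w - 1L):(2L * w + 2L)], "double", size = 4L,
                                endian = "little")
  npoints <- hdr_i2(2L)
  first_frame <- hdr_i2(4L)
  last_frame <- hdr_i2(5L)
  scale <- hdr_f4(7L)
  data_block <- hdr_i2(9L)
  rate <- hdr_f4(11L)

  pars <- c3d_read_params(raw, pblock)
  pick <- function(key, default) if (!is.null(pars[[key]])) pars[[key]] else default
  npoints <- as.integer(pick("POINT:USED", npoints))
  rate <- as.numeric(pick("POINT:RATE", rate))
  scale <- as.numeric(pick("POINT:SCALE", scale))
  nframes <- as.integer(pick("POINT:FRAMES", last_frame - first_frame + 1L))
  labels <- pick("POINT:LABELS", sprintf("M%03d", seq_len(npoints)))
  labels <- labels[seq_len(min(npoints, length(labels)))]
  if (length(labels) < npoints) {
    labels <- c(labels, sprintf("M%03d", seq(length(labels) + 1L, npoints)))
  }
  if (is.null(units)) {
    u <- tolower(pick("POINT:UNITS", "mm"))
    units <- if (identical(u, "m")) "m" else "mm"
  }
  if (npoints < 1L) stop_exerstep("EmptyRecording", "C3D declares 0 points")
  if (nframes < 1L) stop_exerstep("EmptyRecording", "C3D declares 0 frames")
  if (!is_scalar_number(rate) || rate <= 0) {
    stop_exerstep("FormatError", "unparseable C3D point rate")
  }

  off <- (data_block - 1L) * 512L
  per_frame <- 4L * npoints
  is_float <- scale < 0
  bytes_pf <- per_frame * if (is_float) 4L else 2L
  need <- off + bytes_pf * nframes
  if (length(raw) < need) {
    stop_exerstep("FormatError", "C3D point data section truncated")
  }
  dat <- raw[(off + 1L):need]
  if (is_float) {
    v <- readBin(dat, "double", n = per_frame * nframes, size = 4L, endian = "little")
    m <- matrix(v, nrow = 4L)  # x,y,z,residual per point, points x frames
    resid <- m[4L, ]
  } else {
    v <- readBin(dat, "integer", n = per_frame * nframes, size = 2L,
                 signed = TRUE, endian = "little")
    m <- matrix(v * abs(scale), nrow = 4L)
    resid <- matrix(v, nrow = 4L)[4L, ]
  }
  xyz <- m[1:3, , drop = FALSE]
  xyz[, resid < 0] <- NA_real_
  # -> frames x markers x 3
  pos <- array(NA_real_, dim = c(nframes, npoints, 3L))
  arr <- array(xyz, dim = c(3L, npoints, nframes))
  pos <- aperm(arr, c(3L, 2L, 1L))
  if (units == "mm") pos <- pos / 1000
  dimnames(pos) <- list(NULL, canonicalize_labels(labels, aliases), c("x", "y", "z"))
  trial_recording(pos, rate = rate)
}

# --- internal writer (round-trip fixture generation only) -------------------

c3d_param_record <- function(name, gid, value, esize, dims) {
  nm <- charToRaw(name)
  body <- c(as.raw(esize + 256L * (esize < 0)), as.raw(length(dims)), as.raw(dims))
  dat <- switch(as.character(esize),
    "-1" = charToRaw(value),
    "2"  = writeBin(as.integer(value), raw(), size = 2L, endian = "little"),
    "4"  = writeBin(as.numeric(value), raw(), size = 4L, endian = "little")
  )
  body <- c(body, dat, as.raw(0L))  # zero-length description
  offset <- length(body) + 2L
  c(as.raw(length(nm)), as.raw(gid), nm,
    writeBin(as.integer(offset), raw(), size = 2L, endian = "little"), body)
}

c3d_group_record <- function(name, gid) {
  nm <- charToRaw(name)
  body <- as.raw(0L)  # description length 0
  offset <- length(body) + 2L
  c(as.raw(length(nm)), as.raw(256L - gid), nm,
    writeBin(as.integer(offset), raw(), size = 2L, endian = "little"), body)
}

write_c3d <- function(rec, path) {
  pos <- rec$positions * 1000  # stored in mm, float
  nframes <- dim(pos)[1]
  npoints <- dim(pos)[2]
  labels <- dimnames(pos)[[2]]
  lw <- max(nchar(labels), 4L)
  lab_blob <- paste(formatC(labels, width = -lw), collapse = "")

  prec <- c(
    c3d_group_record("POINT", 1L),
    c3d_param_record("USED", 1L, npoints, 2L, 1L),
    c3d_param_record("FRAMES", 1L, nframes, 2L, 1L),
    c3d_param_record("RATE", 1L, rec$rate, 4L, 1L),
    c3d_param_record("SCALE", 1L, -1.0, 4L, 1L),
    c3d_param_record("UNITS", 1L, "mm  ", -1L, 4L),
    c3d_param_record("LABELS", 1L, lab_blob, -1L, c(lw, npoints))
  )
  nparam_blocks <- ceiling((length(prec) + 4L) / 512L)
  param <- c(as.raw(c(1L, 80L, nparam_blocks, 84L)), prec)
  param <- c(param, raw(512L * nparam_blocks - length(param)))

  data_block <- 2L + nparam_blocks
  hdr <- raw(512L)
  hdr[1] <- as.raw(2L); hdr[2] <- as.raw(80L)
  put_i2 <- function(h, w, v) { h[(2L*w-1L):(2L*w)] <- writeBin(as.integer(v), raw(), size=2L, endian="little"); h }
  put_f4 <- function(h, w, v) { h[(2L*w-1L):(2L*w+2L)] <- writeBin(as.numeric(v), raw(), size=4L, endian="little"); h }
  hdr <- put_i2(hdr, 2L, npoints)
  hdr <- put_i2(hdr, 3L, 0L)            # no analog
  hdr <- put_i2(hdr, 4L, 1L)            # first frame
  hdr <- put_i2(hdr, 5L, nframes)       # last frame
  hdr <- put_i2(hdr, 6L, 0L)            # max gap
  hdr <- put_f4(hdr, 7L, -1.0)          # scale (float data)
  hdr <- put_i2(hdr, 9L, data_block)
  hdr <- put_i2(hdr, 10L, 0L)           # analog samples / frame
  hdr <- put_f4(hdr, 11L, rec$rate)

  # frames: per point x,y,z,residual as float; NA -> residual -1
  arr <- aperm(pos, c(3L, 2L, 1L))      # 3 x points x frames
  out <- array(0, dim = c(4L, npoints, nframes))
  out[1:3, , ] <- arr
  bad <- apply(is.na(arr), c(2L, 3L), any)
  res <- matrix(0, npoints, nframes)
  res[bad] <- -1
  out[4L, , ] <- res
  out[is.na(out)] <- 0
  blob <- writeBin(as.numeric(out), raw(), size = 4L, endian = "little")
  pad <- (-length(blob)) %% 512L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(hdr, param, blob, raw(pad)), con)
  invisible(path)
}
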