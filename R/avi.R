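# Minimal uncompressed AVI (RIFF) codec.
#
# Writes 8-bit grayscale DIB frames ('00db' chunks, bottom-up rows padded to
# 4 bytes, grayscale palette); reads back 8-bit palette and 24-bit BGR
# uncompressed streams. No installed R package decodes AVI, and the grading
# deliverable must be self-contained, so the container plumbing lives here.
# Everything is little-endian per the RIFF spec.

fourcc <- function(s) charToRaw(s)

u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")

read_u32 <- function(buf, pos) {
  readBin(buf[pos:(pos + 3L)], "integer", size = 4L, endian = "little")
}
read_u16 <- function(buf, pos) {
  readBin(buf[pos:(pos + 1L)], "integer", size = 2L, endian = "little",
          signed = FALSE)
}

# stride of a bottom-up DIB row in bytes
dib_stride <- function(width, bytes_per_px) ((width * bytes_per_px + 3L) %/% 4L) * 4L

write_avi <- function(frames, fps, path) {
  d <- dim(frames)
  h <- d[1]; w <- d[2]; n <- d[3]
  stride <- dib_stride(w, 1L)
  frame_bytes <- stride * h
  scale <- 1000L
  rate <- as.integer(round(fps * 1000))

  avih <- c(u32(round(1e6 / fps)), u32(frame_bytes * as.integer(ceiling(fps))),
            u32(0L), u32(0x10L),        # flags: AVIF_HASINDEX
            u32(n), u32(0L), u32(1L), u32(frame_bytes),
            u32(w), u32(h), u32(rep(0L, 4)))
  strh <- c(fourcc("vids"), fourcc("DIB "), u32(0L), u16(0L), u16(0L),
            u32(0L), u32(scale), u32(rate), u32(0L), u32(n),
            u32(frame_bytes), u32(0L), u32(0L),
            u16(c(0L, 0L, w, h)))
  palette <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256)))  # BGR0, grey
  bmih <- c(u32(40L), u32(w), u32(h), u16(1L), u16(8L), u32(0L),
            u32(frame_bytes), u32(0L), u32(0L), u32(256L), u32(0L))
  strf <- c(bmih, palette)

  strl <- c(fourcc("LIST"), u32(4L + 8L + length(strh) + 8L + length(strf)),
            fourcc("strl"),
            fourcc("strh"), u32(length(strh)), strh,
            fourcc("strf"), u32(length(strf)), strf)
  hdrl <- c(fourcc("LIST"), u32(4L + 8L + length(avih) + length(strl)),
            fourcc("hdrl"),
            fourcc("avih"), u32(length(avih)), avih,
            strl)

  movi_size <- 4L + n * (8L + frame_bytes)
  idx1_size <- 16L * n
  riff_size <- 4L + length(hdrl) + 8L + movi_size + 8L + idx1_size

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(fourcc("RIFF"), u32(riff_size), fourcc("AVI ")), con)
  writeBin(hdrl, con)
  writeBin(c(fourcc("LIST"), u32(movi_size), fourcc("movi")), con)
  pad <- matrix(raw(1L), stride, h)
  for (i in seq_len(n)) {
    # bottom-up, row-major: column j of `pad` is image row h + 1 - j
    pad[seq_len(w), ] <- as.raw(t(frames[h:1, , i, drop = TRUE]))
    writeBin(c(fourcc("00db"), u32(frame_bytes), as.vector(pad)), con)
  }
  offs <- 4L + (seq_len(n) - 1L) * (8L + frame_bytes)
  idx <- vapply(seq_len(n), function(i) {
    c(fourcc("00db"), u32(0x10L), u32(offs[i]), u32(frame_bytes))
  }, raw(16L))
  writeBin(c(fourcc("idx1"), u32(idx1_size), as.vector(idx)), con)
  invisible(path)
}

read_avi <- function(path) {
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 12L || !identical(buf[1:4], fourcc("RIFF")) ||
      !identical(buf[9:12], fourcc("AVI ")))
    cw_abort("decode", sprintf("not a RIFF/AVI file: %s", path))

  width <- height <- bitcount <- NA_integer_
  palette_lum <- NULL
  rate <- scale <- micro_per_frame <- NA_real_
  frame_chunks <- list()

  pos <- 13L
  end <- min(length(buf), 8L + read_u32(buf, 5L))
  while (pos + 8L <= end) {
    id <- rawToChar(buf[pos:(pos + 3L)])
    size <- read_u32(buf, pos + 4L)
    if (size < 0 || pos + 8L + size - 1L > length(buf))
      cw_abort("decode", sprintf("corrupt chunk '%s' in %s", id, path))
    body <- pos + 8L
    if (id == "LIST") {
      pos <- body + 4L  # descend into the list
      next
    }
    if (id == "avih") {
      micro_per_frame <- read_u32(buf, body)
      width <- read_u32(buf, body + 32L)
      height <- read_u32(buf, body + 36L)
    } else if (id == "strh" &&
               identical(buf[body:(body + 3L)], fourcc("vids"))) {
      scale <- read_u32(buf, body + 20L)
      rate <- read_u32(buf, body + 24L)
    } else if (id == "strf" && is.na(bitcount)) {
      width <- read_u32(buf, body + 4L)
      height <- abs(read_u32(buf, body + 8L))
      bitcount <- read_u16(buf, body + 14L)
      if (bitcount == 8L && size >= 40L + 4L * 256L) {
        pal <- matrix(as.integer(buf[(body + 40L):(body + 40L + 1023L)]),
                      nrow = 4L)
        palette_lum <- as.integer(round(0.114 * pal[1, ] + 0.587 * pal[2, ] +
                                          0.299 * pal[3, ]))  # stored BGR0
      }
    } else if (grepl("^..d[bc]$", id) && size > 0L) {
      frame_chunks[[length(frame_chunks) + 1L]] <- c(body, size)
    }
    pos <- body + size + (size %% 2L)  # chunks are word-aligned
  }

  if (is.na(width) || is.na(height) || length(frame_chunks) == 0L)
    cw_abort("decode", sprintf("no decodable video stream in %s", path))
  if (!bitcount %in% c(8L, 24L))
    cw_abort("decode",
             sprintf("unsupported bit depth %d in %s (expect uncompressed 8/24)",
                     bitcount, path))

  bpp <- bitcount %/% 8L
  stride <- dib_stride(width, bpp)
  n <- length(frame_chunks)
  frames <- array(0L, c(height, width, n))
  for (i in seq_len(n)) {
    fc <- frame_chunks[[i]]
    if (fc[2] < stride * height)
      cw_abort("decode", sprintf("frame %d truncated in %s", i, path))
    v <- as.integer(buf[fc[1]:(fc[1] + stride * height - 1L)])
    if (bpp == 1L) {
      m <- matrix(v, stride, height)[seq_len(width), , drop = FALSE]
      g <- t(m)[height:1, , drop = FALSE]
      if (!is.null(palette_lum)) g[] <- palette_lum[g + 1L]
      frames[, , i] <- g
    } else {
      m <- matrix(v, stride, height)
      px <- m[seq_len(3L * width), , drop = FALSE]
      b <- t(px[seq(1L, by = 3L, length.out = width), ])[height:1, ]
      gch <- t(px[seq(2L, by = 3L, length.out = width), ])[height:1, ]
      r <- t(px[seq(3L, by = 3L, length.out = width), ])[height:1, ]
      frames[, , i] <- round(0.299 * r + 0.587 * gch + 0.114 * b)
    }
  }

  fps <- if (!is.na(rate) && !is.na(scale) && scale > 0 && rate > 0)
    rate / scale
  else if (!is.na(micro_per_frame) && micro_per_frame > 0)
    1e6 / micro_per_frame
  else NA_real_
  list(frames = frames, fps = fps)
}
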