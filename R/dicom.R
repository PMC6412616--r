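# Minimal multi-frame DICOM (modality XA) support: uncompressed implicit
# or explicit little-endian transfer syntaxes, pixel data only (no
# overlays, no sequences with undefined length). Enough to round-trip
# grayscale cine runs and to interoperate with standard DICOM toolkits.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_XA_STORAGE <- "1.2.840.10008.5.1.4.1.1.12.1"

u16le <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
u32le <- function(raw4) {
  as.double(raw4[1]) + 256 * as.double(raw4[2]) +
    65536 * as.double(raw4[3]) + 16777216 * as.double(raw4[4])
}

read_sequence_dicom <- function(path, frame_rate_hz = NULL) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    abort_format("not a DICOM part-10 file (missing DICM magic)")
  }
  pos <- 133L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  transfer <- UID_EXPLICIT_LE
  explicit <- TRUE
  in_meta <- TRUE
  n <- length(raw)
  while (pos + 8L <= n + 1L) {
    group <- u16le(raw[pos:(pos + 1L)])
    elem <- u16le(raw[(pos + 2L):(pos + 3L)])
    if (in_meta && group != 2L) {
      in_meta <- FALSE
      explicit <- identical(transfer, UID_EXPLICIT_LE)
      if (!transfer %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE)) {
        abort_format(paste0("unsupported transfer syntax: ", transfer))
      }
    }
    use_explicit <- in_meta || explicit
    if (use_explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32le(raw[(pos + 8L):(pos + 11L)])
        hdr <- 12L
      } else {
        len <- u16le(raw[(pos + 6L):(pos + 7L)])
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32le(raw[(pos + 4L):(pos + 7L)])
      hdr <- 8L
    }
    if (len == 4294967295) {
      abort_format("undefined-length DICOM elements are not supported")
    }
    vstart <- pos + hdr
    vend <- vstart + len - 1L
    if (len > 0 && vend > n) abort_format("truncated DICOM element")
    key <- sprintf("%04x,%04x", group, elem)
    val <- if (len > 0) raw[vstart:vend] else raw(0)
    if (key %in% c("0002,0010", "0008,0060", "0018,0040", "0018,1063",
                   "0028,0002", "0028,0008", "0028,0010", "0028,0011",
                   "0028,0100", "0028,0103", "7fe0,0010")) {
      tags[[key]] <- val
    }
    if (key == "0002,0010") transfer <- dicom_str(val)
    pos <- vstart + as.integer(len)
    if (key == "7fe0,0010") break
  }
  need <- c("0028,0010", "0028,0011", "0028,0100", "7fe0,0010")
  if (!all(need %in% names(tags))) {
    abort_format("DICOM file lacks Rows/Columns/BitsAllocated/PixelData")
  }
  rows <- u16le(tags[["0028,0010"]])
  cols <- u16le(tags[["0028,0011"]])
  bits <- u16le(tags[["0028,0100"]])
  if (!bits %in% c(8L, 16L)) abort_format("only 8/16-bit DICOM pixels supported")
  signed <- "0028,0103" %in% names(tags) && u16le(tags[["0028,0103"]]) == 1L
  if (signed) abort_format("signed DICOM pixel data not supported")
  nframes <- if ("0028,0008" %in% names(tags)) {
    as.integer(dicom_str(tags[["0028,0008"]]))
  } else {
    1L
  }
  px <- tags[["7fe0,0010"]]
  expected <- rows * cols * nframes * (bits / 8L)
  if (length(px) < expected) abort_format("DICOM pixel data shorter than expected")
  vals <- if (bits == 16L) {
    readBin(px, "integer", n = rows * cols * nframes, size = 2L,
            signed = FALSE, endian = "little")
  } else {
    as.integer(px[seq_len(rows * cols * nframes)])
  }
  frames <- lapply(seq_len(nframes) - 1L, function(i) {
    # DICOM pixel order is row-major (left-to-right, top-to-bottom)
    matrix(as.double(vals[(i * rows * cols + 1L):((i + 1L) * rows * cols)]),
           nrow = rows, ncol = cols, byrow = TRUE)
  })
  rate <- NULL
  if ("0018,1063" %in% names(tags)) {
    ft <- suppressWarnings(as.double(dicom_str(tags[["0018,1063"]])))
    if (is.finite(ft) && ft > 0) rate <- 1000 / ft
  }
  if (is.null(rate) && "0018,0040" %in% names(tags)) {
    cr <- suppressWarnings(as.double(dicom_str(tags[["0018,0040"]])))
    if (is.finite(cr) && cr > 0) rate <- cr
  }
  rate <- rate %||% frame_rate_hz %||% 12.5
  frame_sequence(frames, frame_rate_hz = rate,
                 id = sub("\\.dcm$", "", basename(path)), bit_depth = bits)
}

dicom_str <- function(val) trimws(rawToChar(val[val != as.raw(0L)]))

write_dicom_xa <- function(seq, path, bits = 16L) {
  rows <- frame_dims(seq)[1L]
  cols <- frame_dims(seq)[2L]
  nframes <- length(seq$frames)
  r16 <- function(x) {
    x <- as.integer(x)
    x <- ifelse(x > 32767L, x - 65536L, x)  # two's-complement for writeBin
    writeBin(x, raw(), size = 2L, endian = "little")
  }
  r32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  pad_str <- function(s, pad = as.raw(0x20)) {
    r <- charToRaw(s)
    if (length(r) %% 2L == 1L) r <- c(r, pad)
    r
  }
  el <- function(group, elem, vr, value) {
    hdr <- c(r16(group), r16(elem), charToRaw(vr))
    if (length(value) %% 2L == 1L) value <- c(value, as.raw(0L))
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      c(hdr, as.raw(c(0, 0)), r32(length(value)), value)
    } else {
      c(hdr, r16(length(value)), value)
    }
  }
  # deterministic instance UID suffix from the pixel content
  suffix <- sprintf("%.0f", sum(vapply(seq$frames, sum, 0)) %% 1e8)
  sop_uid <- paste0("1.2.826.0.1.3680043.9.7433.1.", suffix)
  meta_body <- c(
    el(2L, 1L, "OB", as.raw(c(0, 1))),
    el(2L, 2L, "UI", pad_str(UID_XA_STORAGE, as.raw(0L))),
    el(2L, 3L, "UI", pad_str(sop_uid, as.raw(0L))),
    el(2L, 16L, "UI", pad_str(UID_EXPLICIT_LE, as.raw(0L))),
    el(2L, 18L, "UI", pad_str("1.2.826.0.1.3680043.9.7433.0.1", as.raw(0L)))
  )
  meta <- c(el(2L, 0L, "UL", r32(length(meta_body))), meta_body)
  frame_time_ms <- format(1000 / seq$frame_rate_hz, digits = 10)
  pixels <- unlist(lapply(seq$frames, function(f) {
    r16(as.integer(t(f)))  # row-major
  }))
  if (bits == 8L) {
    pixels <- as.raw(unlist(lapply(seq$frames, function(f) as.integer(t(f)))))
  }
  body <- c(
    el(8L, 22L, "UI", pad_str(UID_XA_STORAGE, as.raw(0L))),        # SOPClassUID
    el(8L, 24L, "UI", pad_str(sop_uid, as.raw(0L))),               # SOPInstanceUID
    el(8L, 96L, "CS", pad_str("XA")),                          # Modality
    el(24L, 4195L, "DS", pad_str(frame_time_ms)),              # FrameTime
    el(40L, 2L, "US", r16(1L)),                                # SamplesPerPixel
    el(40L, 4L, "CS", pad_str("MONOCHROME2")),
    el(40L, 8L, "IS", pad_str(as.character(nframes))),         # NumberOfFrames
    el(40L, 16L, "US", r16(rows)),                             # Rows
    el(40L, 17L, "US", r16(cols)),                             # Columns
    el(40L, 256L, "US", r16(bits)),                            # BitsAllocated
    el(40L, 257L, "US", r16(bits)),                            # BitsStored
    el(40L, 258L, "US", r16(bits - 1L)),                       # HighBit
    el(40L, 259L, "US", r16(0L)),                              # PixelRepresentation
    el(32736L, 16L, "OW", pixels)                              # PixelData
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}
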