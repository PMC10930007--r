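#' @title Minimal single-frame DICOM codec
#' @description
#' A small reader/writer for classic single-frame MR Image Storage objects
#' in the explicit-VR little-endian transfer syntax, covering the header
#' attributes the QA analysis needs (slice location, coil/element name,
#' series description, pixel spacing, instance number, rescale).  Pixel
#' data are 16-bit unsigned; signed diagnostic images are stored via
#' RescaleIntercept so the file stays standard.
#' @name dicom-codec
#' @keywords internal
NULL

# transfer syntax / SOP UIDs
.ts_explicit_le <- "1.2.840.10008.1.2.1"
.sop_mr_image <- "1.2.840.10008.5.1.4.1.1.4"
.impl_uid <- "1.2.826.0.1.3680043.10.9000.1"

.pad_even <- function(raw, pad = as.raw(0x20)) {
  if (length(raw) %% 2L == 1L) c(raw, pad) else raw
}

.str_bytes <- function(x, pad = as.raw(0x20)) {
  .pad_even(charToRaw(enc2utf8(as.character(x))), pad)
}

.uint_bytes <- function(x, size) {
  x <- as.numeric(x)
  out <- raw(size)
  for (i in seq_len(size)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

# one data element, explicit VR little endian
.dcm_element <- function(group, elem, vr, value) {
  head <- c(.uint_bytes(group, 2L), .uint_bytes(elem, 2L), charToRaw(vr))
  if (vr %in% c("OB", "OW", "UT", "UN", "SQ")) {
    c(head, raw(2L), .uint_bytes(length(value), 4L), value)
  } else {
    c(head, .uint_bytes(length(value), 2L), value)
  }
}

.ds_format <- function(x) {
  paste(vapply(x, function(v) formatC(v, digits = 10, format = "g"),
               character(1)), collapse = "\\")
}

#' Write one image as a DICOM file
#'
#' @param pixels numeric matrix (rows x cols), image in stored row/col order.
#' @param path output file path.
#' @param slice_location signed axial position of the slice centre (mm).
#' @param instance_number ordinal of the image within the series; also used
#'   as acquisition-order proxy (lower = acquired first).
#' @param series_description free-text series label; the series kind and
#'   filter condition are encoded here.
#' @param coil_name receive coil / element label (e.g. `"VAP1"`), written to
#'   the Receive Coil Name tag (0018,1250); `NA` to omit.
#' @param pixel_spacing length-2 numeric, (row, col) spacing in mm.
#' @param slice_thickness slice thickness in mm.
#' @param series_number integer series number.
#'
#' Values are quantized to 16-bit unsigned integers; when the image holds
#' negative values (the signed gaussian diagnostic mode) a negative
#' RescaleIntercept is written so that `intercept + stored` recovers them.
#'
#' @return `path`, invisibly.
#' @export
dicom_write <- function(pixels, path, slice_location = 0,
                        instance_number = 1L,
                        series_description = "coilqa",
                        coil_name = NA_character_,
                        pixel_spacing = c(300 / 256, 300 / 256),
                        slice_thickness = 10,
                        series_number = 1L) {
  stopifnot(is.matrix(pixels), is.numeric(pixels), all(is.finite(pixels)))
  intercept <- min(0, floor(min(pixels)))
  stored <- round(pixels - intercept)
  stored[stored < 0] <- 0
  stored[stored > 65535] <- 65535
  nr <- nrow(pixels); nc <- ncol(pixels)

  # content-derived suffix keeps UIDs unique per image yet reproducible,
  # so identical simulation seeds give byte-identical files
  sop_uid <- sprintf("%s.%d.%d.%.0f", .impl_uid, as.integer(series_number),
                     as.integer(instance_number), sum(stored) %% 1e9)
  ui <- function(x) .str_bytes(x, pad = as.raw(0x00))

  meta <- c(
    .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    .dcm_element(0x0002, 0x0002, "UI", ui(.sop_mr_image)),
    .dcm_element(0x0002, 0x0003, "UI", ui(sop_uid)),
    .dcm_element(0x0002, 0x0010, "UI", ui(.ts_explicit_le)),
    .dcm_element(0x0002, 0x0012, "UI", ui(.impl_uid))
  )
  meta <- c(.dcm_element(0x0002, 0x0000, "UL", .uint_bytes(length(meta), 4L)),
            meta)

  # pixel data: row-major, 16-bit unsigned little endian
  v <- as.integer(as.vector(t(stored)))
  v <- ifelse(v > 32767L, v - 65536L, v)
  px <- writeBin(v, raw(), size = 2L, endian = "little")

  body <- c(
    .dcm_element(0x0008, 0x0016, "UI", ui(.sop_mr_image)),
    .dcm_element(0x0008, 0x0018, "UI", ui(sop_uid)),
    .dcm_element(0x0008, 0x0060, "CS", .str_bytes("MR")),
    .dcm_element(0x0008, 0x103E, "LO", .str_bytes(series_description)),
    if (!is.na(coil_name))
      .dcm_element(0x0018, 0x1250, "SH", .str_bytes(coil_name)),
    .dcm_element(0x0018, 0x0050, "DS", .str_bytes(.ds_format(slice_thickness))),
    .dcm_element(0x0020, 0x0011, "IS", .str_bytes(as.character(series_number))),
    .dcm_element(0x0020, 0x0013, "IS", .str_bytes(as.character(instance_number))),
    .dcm_element(0x0020, 0x0032, "DS",
                 .str_bytes(.ds_format(c(0, 0, slice_location)))),
    .dcm_element(0x0020, 0x1041, "DS", .str_bytes(.ds_format(slice_location))),
    .dcm_element(0x0028, 0x0002, "US", .uint_bytes(1L, 2L)),
    .dcm_element(0x0028, 0x0004, "CS", .str_bytes("MONOCHROME2")),
    .dcm_element(0x0028, 0x0010, "US", .uint_bytes(nr, 2L)),
    .dcm_element(0x0028, 0x0011, "US", .uint_bytes(nc, 2L)),
    .dcm_element(0x0028, 0x0030, "DS", .str_bytes(.ds_format(pixel_spacing))),
    .dcm_element(0x0028, 0x0100, "US", .uint_bytes(16L, 2L)),
    .dcm_element(0x0028, 0x0101, "US", .uint_bytes(16L, 2L)),
    .dcm_element(0x0028, 0x0102, "US", .uint_bytes(15L, 2L)),
    .dcm_element(0x0028, 0x0103, "US", .uint_bytes(0L, 2L)),
    .dcm_element(0x0028, 0x1052, "DS", .str_bytes(.ds_format(intercept))),
    .dcm_element(0x0028, 0x1053, "DS", .str_bytes(.ds_format(1))),
    .dcm_element(0x7FE0, 0x0010, "OW", px)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

.read_uint <- function(raw) sum(as.numeric(raw) * 256^(seq_along(raw) - 1L))

#' Read one DICOM file
#'
#' Parses a classic single-frame explicit-VR little-endian file and returns
#' the rescaled pixel matrix plus the header attributes used by the QA
#' pipeline.
#'
#' @param path DICOM file path.
#' @return list with `pixels` (numeric matrix, rescale applied) and `meta`
#'   (list: `slice_location`, `coil_name`, `series_description`,
#'   `instance_number`, `series_number`, `pixel_spacing`, `rows`, `cols`).
#' @export
dicom_read <- function(path) {
  buf <- readBin(path, raw(), n = file.info(path)$size)
  if (length(buf) < 132L || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "UT", "UN", "SQ")
  while (pos + 7L <= length(buf)) {
    group <- .read_uint(buf[pos:(pos + 1L)])
    elem <- .read_uint(buf[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- .read_uint(buf[(pos + 8L):(pos + 11L)])
      val_at <- pos + 12L
    } else {
      len <- .read_uint(buf[(pos + 6L):(pos + 7L)])
      val_at <- pos + 8L
    }
    key <- sprintf("%04X%04X", group, elem)
    tags[[key]] <- list(vr = vr, raw = if (len > 0)
      buf[val_at:(val_at + len - 1L)] else raw(0))
    pos <- val_at + len
  }
  g_str <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NA_character_)
    trimws(rawToChar(t$raw[t$raw != as.raw(0)]))
  }
  g_num <- function(key) {
    s <- g_str(key)
    if (is.na(s)) return(NA_real_)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  g_us <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NA_integer_)
    as.integer(.read_uint(t$raw))
  }
  rows <- g_us("00280010"); cols <- g_us("00280011")
  px_raw <- tags[["7FE00010"]]
  if (is.null(px_raw) || is.na(rows) || is.na(cols))
    stop("DICOM file lacks image pixel module: ", path)
  v <- readBin(px_raw$raw, integer(), n = rows * cols, size = 2L,
               signed = FALSE, endian = "little")
  slope <- g_num("00281053"); intercept <- g_num("00281052")
  if (is.na(slope[1])) slope <- 1
  if (is.na(intercept[1])) intercept <- 0
  pixels <- matrix(v * slope[1] + intercept[1], nrow = rows, ncol = cols,
                   byrow = TRUE)
  sl <- g_num("00201041")
  if (is.na(sl[1])) {
    ipp <- g_num("00200032")
    sl <- if (length(ipp) >= 3) ipp[3] else NA_real_
  }
  list(
    pixels = pixels,
    meta = list(
      slice_location = sl[1],
      coil_name = g_str("00181250"),
      series_description = g_str("0008103E"),
      instance_number = as.integer(g_num("00200013")[1]),
      series_number = as.integer(g_num("00200011")[1]),
      pixel_spacing = g_num("00280030"),
      slice_thickness = g_num("00180050")[1],
      rows = rows, cols = cols
    )
  )
}
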