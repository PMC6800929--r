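## Minimal DICOM codec for single-frame axial CT slices.
##
## Scope: explicit-VR little-endian transfer syntax only
## (1.2.840.10008.1.2.1), uncompressed 16-bit signed pixel data, one frame
## per file.  This covers the interchange format the pipeline needs; enhanced
## multi-frame objects and compressed transfer syntaxes are out of scope.

dcm_uid_root <- "1.2.826.0.1.3680043.10.474"
dcm_ts_explicit_le <- "1.2.840.10008.1.2.1"
dcm_sop_ct <- "1.2.840.10008.5.1.4.1.1.2"

## ---- byte-level helpers ---------------------------------------------------

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                endian = "little")
dcm_i16 <- dcm_u16  # writeBin is two's complement for negatives

dcm_str <- function(s, pad = charToRaw(" ")) {
  b <- charToRaw(s)
  if (length(b) %% 2L == 1L) b <- c(b, pad)
  b
}

## VRs with the 4-byte (long) length form
dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_element <- function(group, element, vr, bytes) {
  stopifnot(is.raw(bytes))
  head <- c(dcm_u16(group), dcm_u16(element), charToRaw(vr))
  if (vr %in% dcm_long_vrs)
    c(head, as.raw(c(0, 0)), dcm_u32(length(bytes)), bytes)
  else
    c(head, dcm_u16(length(bytes)), bytes)
}

el_ui <- function(g, e, s) dcm_element(g, e, "UI", dcm_str(s, pad = as.raw(0)))
el_txt <- function(g, e, vr, s) dcm_element(g, e, vr, dcm_str(s))
el_us <- function(g, e, v) dcm_element(g, e, "US", dcm_u16(v))

## DS formatting: up to 16 chars, no scientific notation surprises
dcm_ds <- function(x) paste(formatC(x, format = "fg", digits = 10),
                            collapse = "\\")

## ---- writer ---------------------------------------------------------------

dcm_write_slice <- function(path, pixels_i16, rows, cols, spacing_xy,
                            slice_thickness, position, series_uid, sop_uid,
                            instance_number, rescale = c(1, -1024),
                            metadata = list(), omit_tags = character()) {
  meta_body <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    el_ui(0x0002, 0x0002, dcm_sop_ct),
    el_ui(0x0002, 0x0003, sop_uid),
    el_ui(0x0002, 0x0010, dcm_ts_explicit_le),
    el_ui(0x0002, 0x0012, paste0(dcm_uid_root, ".1"))
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", dcm_u32(length(meta_body))),
            meta_body)

  stored <- as.integer(round_half_away((pixels_i16 - rescale[2]) / rescale[1]))
  if (any(stored < -32768L | stored > 32767L))
    stop("HU values outside the representable stored range for int16")

  ds <- list(
    list(0x0008, 0x0016, "UI", dcm_sop_ct),
    list(0x0008, 0x0018, "UI", sop_uid),
    list(0x0008, 0x0060, "CS", "CT"),
    list(0x0018, 0x0050, "DS", dcm_ds(slice_thickness)),
    if (!is.null(metadata$kvp)) list(0x0018, 0x0060, "DS", dcm_ds(metadata$kvp)),
    if (!is.null(metadata$ma))
      list(0x0018, 0x1151, "IS", as.character(metadata$ma)),
    if (!is.null(metadata$kernel)) list(0x0018, 0x1210, "SH", metadata$kernel),
    list(0x0020, 0x000D, "UI", paste0(series_uid, ".0")),
    list(0x0020, 0x000E, "UI", series_uid),
    list(0x0020, 0x0013, "IS", as.character(instance_number)),
    list(0x0020, 0x0032, "DS", dcm_ds(position)),
    list(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0))),
    list(0x0028, 0x0002, "US", 1L),
    list(0x0028, 0x0004, "CS", "MONOCHROME2"),
    list(0x0028, 0x0010, "US", rows),
    list(0x0028, 0x0011, "US", cols),
    # PixelSpacing is row spacing (dy) then column spacing (dx)
    list(0x0028, 0x0030, "DS", dcm_ds(c(spacing_xy[2], spacing_xy[1]))),
    list(0x0028, 0x0100, "US", 16L),
    list(0x0028, 0x0101, "US", 16L),
    list(0x0028, 0x0102, "US", 15L),
    list(0x0028, 0x0103, "US", 1L),
    list(0x0028, 0x1052, "DS", dcm_ds(rescale[2])),
    list(0x0028, 0x1053, "DS", dcm_ds(rescale[1]))
  )
  ds <- Filter(Negate(is.null), ds)
  body <- raw(0)
  for (e in ds) {
    tag <- sprintf("(%04x,%04x)", e[[1]], e[[2]])
    if (tag %in% omit_tags) next
    b <- switch(e[[3]],
                UI = el_ui(e[[1]], e[[2]], e[[4]]),
                US = el_us(e[[1]], e[[2]], e[[4]]),
                el_txt(e[[1]], e[[2]], e[[3]], e[[4]]))
    body <- c(body, b)
  }
  body <- c(body, dcm_element(0x7FE0, 0x0010, "OW", dcm_i16(stored)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

#' Write a CT volume as a DICOM series
#'
#' Writes one single-frame explicit-VR little-endian CT file per axial
#' slice.  HU values are stored with rescale slope 1 and intercept -1024 so
#' that [read_dicom_series()] recovers the HU lattice exactly.
#'
#' @param volume a [ct_volume] with integer HU values in `[-1024, 3071]`
#'   (apply [quantize_12bit()] first if needed).
#' @param directory output directory; created if missing.
#' @param series_uid DICOM series instance UID; a deterministic UID is
#'   derived from the lattice dimensions by default.
#' @return The output directory, invisibly.
#' @export
write_dicom_series <- function(volume, directory, series_uid = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  v <- volume$voxels
  if (any(v != round(v)))
    stop("HU lattice must be integer; apply quantize_12bit() first")
  if (any(v < hu_min_12bit | v > hu_max_12bit))
    stop("HU values outside [-1024, 3071]; volume violates 12-bit invariant")
  d <- dim(v)
  if (is.null(series_uid))
    series_uid <- paste(dcm_uid_root, "2", d[1], d[2], d[3], sep = ".")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (z in seq_len(d[3])) {
    dcm_write_slice(
      file.path(directory, sprintf("slice_%04d.dcm", z)),
      pixels_i16 = as.integer(v[, , z]),
      rows = d[2], cols = d[1],
      spacing_xy = volume$spacing[1:2],
      slice_thickness = volume$slice_thickness,
      position = c(0, 0, (z - 1) * volume$spacing[3]),
      series_uid = series_uid,
      sop_uid = paste(series_uid, z, sep = "."),
      instance_number = z,
      metadata = volume$metadata)
  }
  invisible(directory)
}

## ---- reader ---------------------------------------------------------------

rd_u16 <- function(b, at) readBin(b[at:(at + 1L)], "integer", size = 2L,
                                  signed = FALSE, endian = "little")
rd_u32 <- function(b, at) readBin(b[at:(at + 3L)], "integer", size = 4L,
                                  endian = "little")

## parse one explicit-VR element starting at `at`; returns list(tag, vr,
## value_raw, next_at)
dcm_parse_element <- function(b, at) {
  group <- rd_u16(b, at); element <- rd_u16(b, at + 2L)
  vr <- rawToChar(b[(at + 4L):(at + 5L)])
  if (vr %in% dcm_long_vrs) {
    len <- rd_u32(b, at + 8L)
    val_at <- at + 12L
  } else {
    len <- rd_u16(b, at + 6L)
    val_at <- at + 8L
  }
  if (len < 0) stop("undefined-length element not supported")
  value <- if (len > 0) b[val_at:(val_at + len - 1L)] else raw(0)
  list(tag = sprintf("(%04x,%04x)", group, element), group = group,
       vr = vr, value = value, next_at = val_at + len)
}

dcm_val_str <- function(x) {
  v <- x$value
  while (length(v) && v[length(v)] %in% as.raw(c(0L, 32L)))
    v <- v[-length(v)]
  rawToChar(v)
}
dcm_val_ds <- function(x) as.numeric(strsplit(dcm_val_str(x), "\\\\")[[1]])
dcm_val_us <- function(x) readBin(x$value, "integer", size = 2L,
                                  signed = FALSE, endian = "little")

dcm_read_file <- function(path) {
  b <- readBin(path, "raw", file.info(path)$size)
  if (length(b) < 160L || rawToChar(b[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  at <- 133L
  elements <- list()
  ## file meta group (always explicit little endian)
  while (at + 7L <= length(b) && rd_u16(b, at) == 0x0002) {
    e <- dcm_parse_element(b, at)
    elements[[e$tag]] <- e
    at <- e$next_at
  }
  ts <- elements[["(0002,0010)"]]
  if (is.null(ts) || dcm_val_str(ts) != dcm_ts_explicit_le)
    stop("unsupported transfer syntax (only explicit VR little endian): ",
         path)
  while (at + 7L <= length(b)) {
    e <- dcm_parse_element(b, at)
    elements[[e$tag]] <- e
    at <- e$next_at
  }
  elements
}

dcm_require <- function(el, tag, name, path) {
  if (is.null(el[[tag]]))
    stop(sprintf("missing DICOM tag %s (%s) in %s", tag, name, path))
  el[[tag]]
}

#' Read a DICOM series into a CT volume
#'
#' Reads every `.dcm` file in `directory` (single-frame axial CT slices of
#' one series), sorts the slices by their image-position coordinate along
#' the slice normal (never by file name), and maps stored pixel values to
#' HU via the rescale slope/intercept tags.  Fractional HU produced by the
#' rescale are rounded half away from zero.
#'
#' @param directory directory containing one DICOM series.
#' @return A [ct_volume].
#' @section Errors:
#' Mixed series identifiers, a missing rescale tag (named in the message),
#' or inter-slice spacing that is non-uniform beyond 0.01 mm all raise
#' errors.
#' @export
read_dicom_series <- function(directory) {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) stop("no .dcm files in ", directory)
  slices <- lapply(files, function(f) {
    el <- dcm_read_file(f)
    series <- dcm_val_str(dcm_require(el, "(0020,000e)", "SeriesInstanceUID", f))
    slope <- dcm_val_ds(dcm_require(el, "(0028,1053)", "RescaleSlope", f))
    icept <- dcm_val_ds(dcm_require(el, "(0028,1052)", "RescaleIntercept", f))
    rows <- dcm_val_us(dcm_require(el, "(0028,0010)", "Rows", f))
    cols <- dcm_val_us(dcm_require(el, "(0028,0011)", "Columns", f))
    ps <- dcm_val_ds(dcm_require(el, "(0028,0030)", "PixelSpacing", f))
    pos <- dcm_val_ds(dcm_require(el, "(0020,0032)", "ImagePositionPatient", f))
    orient <- el[["(0020,0037)"]]
    normal <- if (is.null(orient)) c(0, 0, 1) else {
      o <- dcm_val_ds(orient)
      c(o[2] * o[6] - o[3] * o[5], o[3] * o[4] - o[1] * o[6],
        o[1] * o[5] - o[2] * o[4])
    }
    st <- el[["(0018,0050)"]]
    pix <- dcm_require(el, "(7fe0,0010)", "PixelData", f)
    signed <- TRUE
    pr <- el[["(0028,0103)"]]
    if (!is.null(pr)) signed <- dcm_val_us(pr) == 1L
    stored <- readBin(pix$value, "integer", n = length(pix$value) / 2L,
                      size = 2L, signed = signed, endian = "little")
    if (length(stored) != rows * cols)
      stop("pixel data length does not match Rows x Columns in ", f)
    hu <- round_half_away(stored * slope[1] + icept[1])
    meta <- list()
    if (!is.null(el[["(0018,0060)"]])) meta$kvp <- dcm_val_ds(el[["(0018,0060)"]])
    if (!is.null(el[["(0018,1151)"]]))
      meta$ma <- as.numeric(dcm_val_str(el[["(0018,1151)"]]))
    if (!is.null(el[["(0018,1210)"]])) meta$kernel <- dcm_val_str(el[["(0018,1210)"]])
    list(series = series, rows = rows, cols = cols,
         spacing_xy = c(ps[2], ps[1]),  # (dx, dy)
         z = sum(pos * normal),
         thickness = if (is.null(st)) NA_real_ else dcm_val_ds(st),
         hu = hu, meta = meta)
  })
  if (length(unique(vapply(slices, `[[`, "", "series"))) != 1L)
    stop("mixed series identifiers in ", directory)
  rows <- slices[[1]]$rows; cols <- slices[[1]]$cols
  slices <- slices[order(vapply(slices, `[[`, 0, "z"))]
  zs <- vapply(slices, `[[`, 0, "z")
  dz <- if (length(zs) > 1L) diff(zs) else slices[[1]]$thickness
  if (length(zs) > 1L) {
    if (any(dz <= 0)) stop("duplicate slice positions in ", directory)
    if (max(dz) - min(dz) > 0.01)
      stop("non-uniform inter-slice spacing beyond 0.01 mm tolerance")
  }
  vox <- array(0L, dim = c(cols, rows, length(slices)))
  for (i in seq_along(slices))
    vox[, , i] <- as.integer(slices[[i]]$hu)
  ct_volume(vox,
            spacing = c(slices[[1]]$spacing_xy, mean(dz)),
            slice_thickness = if (is.na(slices[[1]]$thickness)) mean(dz)
                              else slices[[1]]$thickness,
            metadata = slices[[1]]$meta)
}

## ---- fast lossless archive ------------------------------------------------

#' Save / load a CT volume in the internal archive format
#'
#' A lossless two-file container used for fast fixtures and intermediate
#' results: `<prefix>.json` holds spacing, slice thickness and metadata;
#' `<prefix>.hu.gz` holds the HU lattice as gzip-compressed little-endian
#' 32-bit integers in array order.  DICOM remains the interchange format.
#'
#' @param volume a [ct_volume] with integer HU values.
#' @param prefix path prefix (no extension).
#' @return `write_volume_archive` returns `prefix` invisibly;
#'   `read_volume_archive` returns a [ct_volume].
#' @export
write_volume_archive <- function(volume, prefix) {
  stopifnot(inherits(volume, "ct_volume"))
  v <- volume$voxels
  if (any(v != round(v))) stop("archive stores integer HU only")
  side <- list(dim = dim(v), spacing = volume$spacing,
               slice_thickness = volume$slice_thickness,
               metadata = volume$metadata)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- gzfile(paste0(prefix, ".hu.gz"), "wb")
  on.exit(close(con))
  writeBin(as.integer(v), con, size = 4L, endian = "little")
  invisible(prefix)
}

#' @rdname write_volume_archive
#' @export
read_volume_archive <- function(prefix) {
  if (!file.exists(paste0(prefix, ".json")))
    stop("no such volume archive: ", prefix)
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- gzfile(paste0(prefix, ".hu.gz"), "rb")
  on.exit(close(con))
  n <- prod(side$dim)
  v <- readBin(con, "integer", n = n, size = 4L, endian = "little")
  if (length(v) != n) stop("archive truncated: ", prefix)
  ct_volume(array(v, dim = side$dim), spacing = side$spacing,
            slice_thickness = side$slice_thickness,
            metadata = as.list(side$metadata))
}
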