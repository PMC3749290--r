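#' Read a volumetric CT or mask image
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`) or MetaImage (`.mha`, `.mhd`) files
#' into the package's (slice, row, column) in-memory convention. Voxel
#' values are assumed to be in Hounsfield units. On disk the fastest-moving
#' axis is the column (NIfTI/MetaImage x axis), so files written by
#' [write_volume()] are valid for external viewers.
#'
#' DICOM series are not supported in this build; convert series to NIfTI
#' first (e.g. with `dcm2niix`).
#'
#' @param path File path.
#' @param format One of `"auto"` (by extension), `"nifti"`, `"metaimage"`,
#'   `"dicom_series"`.
#' @param as One of `"ct"` (returns a [ct_volume()]) or `"labels"` (returns
#'   a [label_volume()]).
#' @return A `ct_volume` or `label_volume`.
#' @export
read_volume <- function(path, format = c("auto", "nifti", "metaimage", "dicom_series"),
                        as = c("ct", "labels")) {
  format <- match.arg(format)
  as <- match.arg(as)
  if (format == "auto") format <- guess_format(path)
  if (format == "dicom_series")
    stop("DICOM series reading is not supported; convert the series to NIfTI first",
         call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  parsed <- switch(format,
    nifti = read_nifti_raw(path),
    metaimage = read_metaimage_raw(path))
  if (as == "ct") ct_volume(parsed$values, parsed$spacing, parsed$origin)
  else label_volume(parsed$values, parsed$spacing, parsed$origin)
}

#' Write a volumetric CT or mask image
#'
#' HU volumes are stored as signed 16-bit integers (values rounded to the
#' nearest integer), masks as unsigned 8- or 16-bit integers, so integer
#' content round-trips losslessly through [read_volume()].
#'
#' @param volume A [ct_volume()] or [label_volume()].
#' @param path Output path; extension selects default format.
#' @param format `"auto"`, `"nifti"` or `"metaimage"`.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path, format = c("auto", "nifti", "metaimage")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "dicom_series")
    stop("DICOM writing is not supported", call. = FALSE)
  is_labels <- inherits(volume, "label_volume")
  if (!is_labels && !inherits(volume, "ct_volume"))
    stop("`volume` must be a ct_volume or label_volume", call. = FALSE)
  arr <- if (is_labels) volume$labels else round(volume$values)
  type <- if (!is_labels) "int16"
  else if (max(arr) <= 255L) "uint8" else "uint16"
  switch(format,
    nifti = write_nifti_raw(arr, volume$spacing, volume$origin, path, type),
    metaimage = write_metaimage_raw(arr, volume$spacing, volume$origin, path, type))
  invisible(path)
}

guess_format <- function(path) {
  if (dir.exists(path)) return("dicom_series")
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) "nifti"
  else if (grepl("\\.(mha|mhd)$", low)) "metaimage"
  else stop(sprintf("cannot infer image format from path: %s", path), call. = FALSE)
}

# --- NIfTI backend (RNifti) -------------------------------------------------

# Disk order is (x = column, y = row, z = slice); permute to and from the
# in-memory (slice, row, column) order. Direction cosines beyond spacing are
# carried in the sform but ignored by all computations (densitometry is
# orientation-invariant).
write_nifti_raw <- function(arr, spacing, origin, path, type) {
  disk <- aperm(arr, c(3L, 2L, 1L))
  sp <- spacing[c(3L, 2L, 1L)]
  img <- RNifti::asNifti(disk)
  RNifti::pixdim(img) <- sp
  m <- diag(c(sp, 1))
  m[1:3, 4] <- origin[c(3L, 2L, 1L)]
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path, datatype = type)
}

read_nifti_raw <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("unreadable NIfTI file %s: %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop("only 3D NIfTI volumes are supported", call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  org <- xf[1:3, 4]
  list(values = aperm(arr, c(3L, 2L, 1L)),
       spacing = as.double(sp[c(3L, 2L, 1L)]),
       origin = as.double(org[c(3L, 2L, 1L)]))
}

# --- MetaImage backend ------------------------------------------------------

# MetaImage is a plain-text header followed by (or pointing at) raw binary
# voxel data, x fastest. Supported element types cover CT (MET_SHORT) and
# masks (MET_UCHAR/MET_USHORT); MET_FLOAT is read-only.
met_types <- list(
  MET_UCHAR  = list(size = 1L, signed = FALSE, what = "integer"),
  MET_SHORT  = list(size = 2L, signed = TRUE,  what = "integer"),
  MET_USHORT = list(size = 2L, signed = FALSE, what = "integer"),
  MET_FLOAT  = list(size = 4L, signed = TRUE,  what = "numeric"))

write_metaimage_raw <- function(arr, spacing, origin, path, type) {
  met <- switch(type, int16 = "MET_SHORT", uint8 = "MET_UCHAR", uint16 = "MET_USHORT")
  info <- met_types[[met]]
  d <- dim(arr)
  local_data <- grepl("\\.mha$", tolower(path))
  raw_path <- if (local_data) path else sub("\\.mhd$", ".raw", path)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[3], d[2], d[1]),
    sprintf("ElementSpacing = %.9g %.9g %.9g", spacing[3], spacing[2], spacing[1]),
    sprintf("Offset = %.9g %.9g %.9g", origin[3], origin[2], origin[1]),
    sprintf("ElementType = %s", met),
    sprintf("ElementDataFile = %s", if (local_data) "LOCAL" else basename(raw_path)))
  disk <- aperm(arr, c(3L, 2L, 1L))  # column fastest on disk
  vals <- as.integer(disk)
  if (met == "MET_USHORT") {
    # writeBin has no unsigned 16-bit; reinterpret via signed representation
    vals <- ifelse(vals > 32767L, vals - 65536L, vals)
  }
  con <- file(if (local_data) path else path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local_data) {
    writeBin(vals, con, size = info$size, endian = "little")
  } else {
    close(con); on.exit()
    rcon <- file(raw_path, "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(vals, rcon, size = info$size, endian = "little")
  }
  invisible(path)
}

read_metaimage_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop(sprintf("malformed MetaImage header (no ElementDataFile): %s", path),
           call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) next
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr$ObjectType, "Image") || !identical(hdr$NDims, "3"))
    stop(sprintf("unsupported MetaImage header in %s", path), call. = FALSE)
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.double(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  org <- as.double(strsplit(hdr$Offset %||% "0 0 0", "\\s+")[[1]])
  info <- met_types[[hdr$ElementType]]
  if (is.null(info))
    stop(sprintf("unsupported MetaImage element type %s", hdr$ElementType), call. = FALSE)
  msb <- identical(tolower(hdr$BinaryDataByteOrderMSB %||% "false"), "true")
  n <- prod(d)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- readBin(con, info$what, n = n, size = info$size, signed = info$signed,
                    endian = if (msb) "big" else "little")
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path))
      stop(sprintf("MetaImage data file not found: %s", raw_path), call. = FALSE)
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- readBin(rcon, info$what, n = n, size = info$size, signed = info$signed,
                    endian = if (msb) "big" else "little")
  }
  if (length(vals) != n)
    stop(sprintf("truncated MetaImage data in %s", path), call. = FALSE)
  disk <- array(vals, dim = d)  # (x, y, z)
  list(values = aperm(disk, c(3L, 2L, 1L)),
       spacing = sp[c(3L, 2L, 1L)],
       origin = org[c(3L, 2L, 1L)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
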