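#' Read a scalar image from NIfTI or MetaImage
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage (`.mha`, `.mhd`)
#' scalar volumes.  Spacing and origin come from the file header; single
#' slice files (third dimension 1, or genuinely 2D) are flagged 2D.
#' Non-identity orientations (direction cosines other than the identity)
#' are rejected: the package works on axis-aligned grids only.
#'
#' @param path path to the image file.
#' @return A [volume_image()].
#' @export
read_image <- function(path) {
  fmt <- image_format(path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    dm <- dim(img)
    if (length(dm) == 2L) dm <- c(dm, 1L)
    if (length(dm) != 3L)
      stop(sprintf("'%s' is not a scalar 2D/3D image (dims: %s)",
                   path, paste(dim(img), collapse = "x")))
    x <- RNifti::xform(img)
    check_axis_aligned(abs(x[1:3, 1:3]), path)
    spacing <- abs(diag(x[1:3, 1:3]))
    spacing[spacing == 0] <- 1
    origin <- as.numeric(x[1:3, 4])
    # NIfTI xforms are RAS-signed; with identity direction enforced we can
    # take magnitudes and keep the offset as-is.
    volume_image(array(as.numeric(img), dm), spacing, origin)
  } else {
    m <- read_metaimage(path)
    if (m$channels != 1L)
      stop(sprintf("'%s' has %d components per voxel; expected a scalar image",
                   path, m$channels))
    volume_image(array(m$data, m$dims), m$spacing, m$origin)
  }
}

#' Write a scalar image to NIfTI or MetaImage
#'
#' The output format follows the file extension.  Intensities are written
#' as 64-bit floats so read-back is exact.
#'
#' @param image a [volume_image()].
#' @param path output path (`.nii`, `.nii.gz`, `.mha`, or `.mhd`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot_volume(image)
  if (image_format(path) == "nifti") {
    write_nifti_array(image$data, image$spacing, image$origin, path)
  } else {
    write_metaimage(image$data, image$dims, 1L, image$spacing, image$origin,
                    path)
  }
  invisible(path)
}

#' Read and write dense displacement fields
#'
#' Vector fields are stored as a 4D NIfTI volume (components along the
#' fourth dimension) or a multi-channel MetaImage, chosen by extension.
#' Round-trips are exact to 64-bit float representation.
#'
#' @param field a [displacement_field()].
#' @param path file path (`.nii`, `.nii.gz`, `.mha`, `.mhd`).
#' @return `read_field()` returns a [displacement_field()];
#'   `write_field()` returns `path` invisibly.
#' @export
write_field <- function(field, path) {
  if (!inherits(field, "displacement_field"))
    stop("`field` must be a displacement_field")
  if (image_format(path) == "nifti") {
    write_nifti_array(field$vectors, field$spacing, field$origin, path)
  } else {
    write_metaimage(aperm(field$vectors, c(4, 1, 2, 3)), field$dims,
                    field$d, field$spacing, field$origin, path)
  }
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  if (image_format(path) == "nifti") {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 4L)
      stop(sprintf("'%s' is not a 4D vector volume", path))
    x <- RNifti::xform(img)
    spacing <- abs(diag(x[1:3, 1:3])); spacing[spacing == 0] <- 1
    displacement_field(array(as.numeric(img), dim(img)), spacing,
                       as.numeric(x[1:3, 4]))
  } else {
    m <- read_metaimage(path)
    v <- aperm(array(m$data, c(m$channels, m$dims)), c(2, 3, 4, 1))
    displacement_field(v, m$spacing, m$origin)
  }
}

image_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) return("metaimage")
  stop(sprintf("unsupported image format: '%s' (use .nii, .nii.gz, .mha or .mhd)",
               path))
}

check_axis_aligned <- function(m, path) {
  if (max(abs(m - diag(diag(m)))) > 1e-6)
    stop(sprintf("'%s' has a non-identity orientation; only axis-aligned grids are supported",
                 path))
}

write_nifti_array <- function(arr, spacing, origin, path) {
  img <- RNifti::asNifti(arr)
  # asNifti drops trailing singleton dimensions (a (n,m,1) array becomes
  # 2D), and a pixdim of the wrong length is silently ignored -- match it
  # to the stored dimensionality or the spacing is lost on write
  nd <- length(dim(img))
  RNifti::pixdim(img) <- c(spacing, rep(1, 5))[seq_len(nd)]
  q <- diag(c(spacing, 1))
  q[1:3, 4] <- origin
  RNifti::qform(img) <- structure(q, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
}

## --- MetaImage (.mha/.mhd) ---------------------------------------------
## Minimal reader/writer for uncompressed, axis-aligned MetaImage files.

metaimage_types <- list(
  MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR = list(what = "integer", size = 1L, signed = TRUE),
  MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT = list(what = "integer", size = 4L, signed = TRUE),
  MET_UINT = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

read_metaimage <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  nl <- which(raw == as.raw(10L))
  hdr <- character(0)
  data_offset <- NA_integer_
  start <- 1L
  for (pos in nl) {
    line <- rawToChar(raw[start:(pos - 1L)])
    line <- sub("\r$", "", line)
    hdr <- c(hdr, line)
    start <- pos + 1L
    if (grepl("^ElementDataFile", line)) { data_offset <- start; break }
  }
  if (is.na(data_offset))
    stop(sprintf("'%s' is not a MetaImage file (no ElementDataFile key)", path))
  kv <- strsplit(hdr, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), "")
  names(vals) <- keys
  get <- function(k, default = NULL) {
    if (k %in% keys) vals[[k]] else default
  }
  if (tolower(get("CompressedData", "False")) == "true")
    stop(sprintf("'%s': compressed MetaImage data is not supported", path))
  ndims <- as.integer(get("NDims", "3"))
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  if (length(dims) != ndims) stop(sprintf("'%s': DimSize/NDims mismatch", path))
  if (ndims == 2L) dims <- c(dims, 1L)
  if (length(dims) != 3L)
    stop(sprintf("'%s': only 2D/3D MetaImage supported", path))
  channels <- as.integer(get("ElementNumberOfChannels", "1"))
  spacing <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  if (length(spacing) == 2L) spacing <- c(spacing, 1)
  origin <- as.numeric(strsplit(get("Offset", get("Position", "0 0 0")), "\\s+")[[1]])
  if (length(origin) == 2L) origin <- c(origin, 0)
  tm <- get("TransformMatrix")
  if (!is.null(tm)) {
    tm <- as.numeric(strsplit(tm, "\\s+")[[1]])
    n <- as.integer(sqrt(length(tm)))
    check_axis_aligned(matrix(abs(tm), n, n), path)
  }
  type <- get("ElementType", "MET_FLOAT")
  spec <- metaimage_types[[type]]
  if (is.null(spec))
    stop(sprintf("'%s': unsupported ElementType %s", path, type))
  endian <- if (tolower(get("ElementByteOrderMSB",
                            get("BinaryDataByteOrderMSB", "False"))) == "true")
    "big" else "little"
  datafile <- get("ElementDataFile")
  nvox <- prod(dims) * channels
  if (identical(datafile, "LOCAL")) {
    con <- rawConnection(raw[data_offset:length(raw)])
    on.exit(close(con))
    data <- readBin(con, spec$what, nvox, size = spec$size,
                    signed = spec$signed, endian = endian)
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      stop(sprintf("'%s': data file '%s' not found", path, datafile))
    data <- readBin(rawpath, spec$what, nvox, size = spec$size,
                    signed = spec$signed, endian = endian)
  }
  if (length(data) != nvox)
    stop(sprintf("'%s': expected %d values, read %d", path, nvox, length(data)))
  list(data = as.numeric(data), dims = dims, channels = channels,
       spacing = spacing, origin = origin)
}

write_metaimage <- function(data, dims, channels, spacing, origin, path) {
  local <- grepl("\\.mha$", path, ignore.case = TRUE)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %s", paste(sprintf("%.17g", origin), collapse = " ")),
    sprintf("ElementSpacing = %s",
            paste(sprintf("%.17g", spacing), collapse = " ")),
    sprintf("DimSize = %s", paste(dims, collapse = " ")),
    if (channels > 1L) sprintf("ElementNumberOfChannels = %d", channels),
    "ElementType = MET_DOUBLE"
  )
  if (local) {
    hdr <- c(hdr, "ElementDataFile = LOCAL")
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.numeric(data), con, size = 8L, endian = "little")
  } else {
    rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    hdr <- c(hdr, sprintf("ElementDataFile = %s", rawname))
    writeLines(hdr, path)
    writeBin(as.numeric(data), file.path(dirname(path), rawname),
             size = 8L, endian = "little")
  }
  invisible(path)
}

## --- Landmarks ----------------------------------------------------------

#' Read and write landmark sets
#'
#' Landmarks travel as CSV with header `label,x,y,z` (physical mm) or as an
#' equivalent JSON array of objects.  Round-trips are lossless to full
#' double precision.
#'
#' @param path file path; `.json` selects JSON, anything else CSV.
#' @param set a [landmark_set()].
#' @return `read_landmarks()` returns a [landmark_set()];
#'   `write_landmarks()` returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(rows) == 0 || nrow(rows) == 0)
      return(landmark_set(matrix(0, 0, 3)))
    need <- c("label", "x", "y", "z")
    if (!all(need %in% names(rows)))
      stop(sprintf("'%s': JSON landmarks need fields label, x, y, z", path))
    return(landmark_set(as.matrix(rows[, c("x", "y", "z")]), rows$label))
  }
  lines <- readLines(path)
  if (length(lines) == 0 || trimws(lines[1]) != "label,x,y,z")
    stop(sprintf("'%s': expected header 'label,x,y,z'", path))
  lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(landmark_set(matrix(0, 0, 3)))
  parts <- strsplit(lines, ",", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 4L || anyNA(suppressWarnings(as.numeric(p[2:4]))))
      stop(sprintf("'%s': malformed landmark row at line %d", path, i + 1L))
  }
  labels <- vapply(parts, `[`, "", 1)
  coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  landmark_set(coords, labels)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(set, path) {
  if (!inherits(set, "landmark_set")) stop("`set` must be a landmark_set")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(set), path, digits = NA,
                         auto_unbox = TRUE)
  } else {
    lines <- c("label,x,y,z",
               sprintf("%s,%.17g,%.17g,%.17g", set$label, set$x, set$y, set$z))
    writeLines(lines, path)
  }
  invisible(path)
}
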