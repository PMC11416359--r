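#' Segmented 3D label volume
#'
#' Container for a segmented 3D ultrasound volume. Voxels hold semantic
#' labels: 0 = background (saline), 1 = specimen tissue, 2 = tumor,
#' 3 = fiducial channel (the 16-gauge IV cannula track). Axis roles follow
#' the acquisition geometry: x = in-plane lateral, y = in-plane depth,
#' z = elevation, i.e. the motorized sweep / sectioning axis running
#' anterior to posterior. The default elevation spacing of 0.5 mm matches
#' the reconstructed motorized sweep.
#'
#' World coordinates are physical millimetres at voxel centers:
#' `world = origin + (index - 1) * spacing` (indices are R's 1-based).
#'
#' @param voxels integer 3D array of labels in \{0, 1, 2, 3\}.
#' @param spacing numeric length-3, voxel spacing (dx, dy, dz) in mm.
#' @param origin numeric length-3, world position (mm) of the center of
#'   voxel (1, 1, 1).
#' @param validate run invariant checks (label set, spacing positivity,
#'   tumor connectivity to the specimen foreground).
#' @return object of class `label_volume` with fields `voxels`, `spacing`,
#'   `origin`.
#' @export
label_volume <- function(voxels, spacing = c(0.2, 0.2, 0.5),
                         origin = c(0, 0, 0), validate = TRUE) {
  if (length(dim(voxels)) != 3L)
    stopf("voxels must be a 3D array, got %s dims", length(dim(voxels)))
  storage.mode(voxels) <- "integer"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || length(origin) != 3L)
    stopf("spacing and origin must have length 3")
  vol <- structure(list(voxels = voxels, spacing = spacing, origin = origin),
                   class = "label_volume")
  if (validate) validate_label_volume(vol)
  vol
}

#' Validate label-volume invariants
#'
#' Checks positive spacing, the allowed label set \{0,1,2,3\}, and that
#' tumor voxels belong to the same connected foreground component as
#' specimen tissue (a tumor floating in saline is a segmentation defect).
#'
#' @param vol a `label_volume`.
#' @return the volume, invisibly; errors name the offending defect.
#' @export
validate_label_volume <- function(vol) {
  if (any(!is.finite(vol$spacing)) || any(vol$spacing <= 0))
    stopf("non-positive voxel spacing: (%s)", paste(vol$spacing, collapse = ", "))
  labs <- sort(unique(as.vector(vol$voxels)))
  bad <- setdiff(labs, 0:3)
  if (length(bad))
    stopf("invalid labels present: %s (allowed: 0,1,2,3)",
          paste(bad, collapse = ", "))
  if (any(vol$voxels == 2L)) {
    fg <- vol$voxels > 0L
    comp <- .label_components_3d(fg, dim(vol$voxels))
    tumor_comps <- unique(comp[vol$voxels == 2L])
    spec_comps <- unique(comp[vol$voxels == 1L])
    if (!all(tumor_comps %in% spec_comps))
      stopf("tumor voxels disconnected from specimen foreground (component %s)",
            paste(setdiff(tumor_comps, spec_comps), collapse = ", "))
  }
  invisible(vol)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_volume> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  tab <- table(factor(as.vector(x$voxels), levels = 0:3,
                      labels = c("background", "specimen", "tumor", "fiducial")))
  for (nm in names(tab)) cat(sprintf("  %-10s %d\n", nm, tab[[nm]]))
  invisible(x)
}

# world coordinates of voxel centers along each axis
volume_axis <- function(vol, axis) {
  axis_coords(vol$origin[axis], vol$spacing[axis], dim(vol$voxels)[axis])
}

## ---- NRRD ----------------------------------------------------------------

# Minimal NRRD reader/writer (attached header; encodings ascii, raw, gzip).
# No NRRD reader ships with this R stack, and the format is a plain
# key:value header followed by the data block.

nrrd_type_map <- c("signed char" = "int8", "int8" = "int8", "int8_t" = "int8",
                   "uchar" = "uint8", "unsigned char" = "uint8", "uint8" = "uint8",
                   "uint8_t" = "uint8",
                   "short" = "int16", "short int" = "int16", "int16" = "int16",
                   "int16_t" = "int16",
                   "ushort" = "uint16", "unsigned short" = "uint16",
                   "uint16" = "uint16", "uint16_t" = "uint16",
                   "int" = "int32", "signed int" = "int32", "int32" = "int32",
                   "int32_t" = "int32")

nrrd_parse_vector <- function(s) {
  s <- gsub("[()]", "", trimws(s))
  as.numeric(strsplit(s, ",")[[1]])
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[1-5]$", magic))
    stopf("'%s' is not an NRRD file (magic '%s')", path, magic)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stopf("'%s': header not terminated by blank line", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    if (length(kv) < 2L) next
    fields[[tolower(trimws(kv[1]))]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  if (is.null(fields$sizes)) stopf("'%s': NRRD header lacks 'sizes'", path)
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 3L)
    stopf("'%s': expected 3-dimensional NRRD, got sizes (%s)", path,
          paste(sizes, collapse = ", "))
  type <- nrrd_type_map[tolower(fields$type %||% "")]
  if (is.na(type))
    stopf("'%s': unsupported or non-integer NRRD type '%s'", path, fields$type)
  spacing <- NULL
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\([^)]*\\)", fields[["space directions"]]))[[1]]
    if (length(vecs) == 3L) {
      m <- sapply(vecs, nrrd_parse_vector)
      off <- m - diag(diag(m))
      if (any(abs(off) > 1e-9))
        stopf("'%s': non-axis-aligned space directions unsupported", path)
      spacing <- diag(m)
    }
  }
  if (is.null(spacing) && !is.null(fields$spacings))
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  if (is.null(spacing))
    stopf("'%s': NRRD header lacks voxel spacing ('space directions' or 'spacings')",
          path)
  if (!is.null(fields[["space origin"]]))
    origin <- nrrd_parse_vector(fields[["space origin"]])
  n <- prod(sizes)
  enc <- tolower(fields$encoding %||% "raw")
  bytes <- c(int8 = 1L, uint8 = 1L, int16 = 2L, uint16 = 2L, int32 = 4L)[[type]]
  signed <- !startsWith(type, "u")
  endian <- if (identical(fields$endian, "big")) "big" else "little"
  if (enc %in% c("ascii", "text", "txt")) {
    txt <- readLines(con)
    vals <- as.numeric(scan(text = paste(txt, collapse = " "), what = numeric(),
                            quiet = TRUE))
  } else if (enc == "raw") {
    vals <- readBin(con, "integer", n = n, size = bytes, signed = signed,
                    endian = endian)
  } else if (enc %in% c("gzip", "gz")) {
    blob <- readBin(con, "raw", n = file.info(path)$size)
    vals <- readBin(memDecompress(blob, type = "gzip"), "integer", n = n,
                    size = bytes, signed = signed, endian = endian)
  } else stopf("'%s': unsupported NRRD encoding '%s'", path, enc)
  if (length(vals) < n)
    stopf("'%s': data block has %d values, expected %d", path, length(vals), n)
  label_volume(array(as.integer(vals[seq_len(n)]), dim = sizes),
               spacing = spacing, origin = origin)
}

write_nrrd <- function(vol, path, encoding = c("gzip", "ascii", "raw")) {
  encoding <- match.arg(encoding)
  d <- dim(vol$voxels)
  hdr <- c("NRRD0004",
           "# ex-vivo specimen label volume",
           "type: short",
           "dimension: 3",
           "space dimension: 3",
           sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
           sprintf("space directions: (%.10g,0,0) (0,%.10g,0) (0,0,%.10g)",
                   vol$spacing[1], vol$spacing[2], vol$spacing[3]),
           sprintf("space origin: (%.10g,%.10g,%.10g)",
                   vol$origin[1], vol$origin[2], vol$origin[3]),
           "kinds: domain domain domain",
           "endian: little",
           sprintf("encoding: %s", encoding))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con)
  v <- as.vector(vol$voxels)
  if (encoding == "ascii") {
    writeLines(paste(v, collapse = " "), con)
  } else {
    raw_ <- writeBin(v, raw(), size = 2L, endian = "little")
    if (encoding == "gzip") raw_ <- memCompress(raw_, type = "gzip")
    writeBin(raw_, con)
  }
  invisible(path)
}

## ---- NIfTI-1 -------------------------------------------------------------

read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L)
  if (sizeof_hdr != 348L) stopf("'%s' is not a NIfTI-1 file", path)
  readBin(con, "raw", 36L)                       # unused header prelude
  dims <- readBin(con, "integer", 8L, size = 2L) # dim[0..7]
  if (dims[1] != 3L) stopf("'%s': expected 3-dimensional NIfTI", path)
  readBin(con, "raw", 14L)                       # intent_p1..3, intent_code
  datatype <- readBin(con, "integer", 1L, size = 2L)
  readBin(con, "integer", 2L, size = 2L)         # bitpix, slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4L)
  vox_offset <- readBin(con, "numeric", 1L, size = 4L)
  readBin(con, "raw", 348L - 4L - 36L - 16L - 14L - 2L - 4L - 32L - 4L)
  types <- list(`2` = c(1L, 0L), `4` = c(2L, 1L), `8` = c(4L, 1L),
                `256` = c(1L, 1L), `512` = c(2L, 0L))
  tk <- types[[as.character(datatype)]]
  if (is.null(tk)) stopf("'%s': non-integer NIfTI datatype %d", path, datatype)
  n <- prod(dims[2:4])
  skip <- as.integer(vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  vals <- readBin(con, "integer", n, size = tk[1], signed = tk[2] == 1L,
                  endian = "little")
  spacing <- pixdim[2:4]
  if (any(spacing <= 0)) stopf("'%s': NIfTI header lacks positive pixdim spacing", path)
  label_volume(array(as.integer(vals), dim = dims[2:4]), spacing = spacing,
               origin = c(0, 0, 0))
}

write_nifti <- function(vol, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  d <- dim(vol$voxels)
  writeBin(348L, con, size = 4L)
  writeBin(raw(36L), con)
  writeBin(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), con, size = 2L)
  writeBin(raw(14L), con)
  writeBin(4L, con, size = 2L)                       # datatype int16
  writeBin(c(16L, 0L), con, size = 2L)               # bitpix, slice_start
  writeBin(as.numeric(c(1, vol$spacing, 1, 1, 1, 1)), con, size = 4L)
  writeBin(352, con, size = 4L)                      # vox_offset
  pad <- 348L - 4L - 36L - 16L - 14L - 2L - 4L - 32L - 4L
  writeBin(raw(pad - 4L), con)
  writeBin(charToRaw("n+1"), con); writeBin(raw(1L), con)  # magic
  writeBin(raw(4L), con)                             # extension flag
  writeBin(as.integer(vol$voxels), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a segmented label volume from NRRD or NIfTI
#'
#' Dispatches on file extension: `.nrrd` (encodings ascii/raw/gzip) or
#' `.nii` / `.nii.gz`. Integer data and spacing metadata are required;
#' labels are validated against the \{0,1,2,3\} convention.
#'
#' @param path file path.
#' @return a [label_volume()].
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) read_nrrd(path)
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) read_nifti(path)
  else stopf("'%s': unsupported volume format (need .nrrd, .nii or .nii.gz)", path)
}

#' Write a label volume to NRRD or NIfTI
#'
#' @param vol a [label_volume()].
#' @param path destination; extension selects the format as in
#'   [read_label_volume()]. NIfTI output stores spacing but not origin
#'   (no affine is written); NRRD stores both.
#' @param encoding NRRD data encoding.
#' @return the path, invisibly.
#' @export
write_label_volume <- function(vol, path, encoding = "gzip") {
  stopifnot(inherits(vol, "label_volume"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) write_nrrd(vol, path, encoding)
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) write_nifti(vol, path)
  else stopf("'%s': unsupported volume format (need .nrrd, .nii or .nii.gz)", path)
}
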