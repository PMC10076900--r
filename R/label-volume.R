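#' Default OAI-ZIB-style label encoding
#'
#' The published OAI-ZIB segmentations encode structures as integers. The
#' integers are a dataset convention, not something this package can infer, so
#' they are shipped as an overridable default: 1 = femoral bone, 2 = femoral
#' cartilage, 3 = tibial bone, 4 = tibial cartilage (background = 0).
#'
#' @return Named integer vector mapping structure names to label integers.
#' @export
#' @examples
#' default_label_map()
default_label_map <- function() {
  c("femoral bone" = 1L, "femoral cartilage" = 2L,
    "tibial bone" = 3L, "tibial cartilage" = 4L)
}

#' Construct a segmented label volume
#'
#' A `label_volume` is the package's container for a segmented knee: a 3D
#' integer grid plus per-axis voxel spacing in mm and a structure-name to
#' integer label map. Axes follow a fixed anatomical convention:
#' x = anteroposterior (anterior at low x), y = mediolateral,
#' z = head-to-feet (so for the tibia, larger z is closer to bone).
#' Voxel indices are 0-based; the physical coordinate of a voxel center is
#' `index * spacing`.
#'
#' @param grid 3D integer array of voxel labels.
#' @param spacing Numeric length-3, mm per voxel along (x, y, z).
#' @param label_map Named integer vector; see [default_label_map()].
#' @return An object of class `label_volume`.
#' @export
#' @examples
#' vol <- label_volume(array(0L, c(4, 4, 4)), c(0.36, 0.7, 0.36))
#' dim(vol$grid)
label_volume <- function(grid, spacing = c(0.36, 0.7, 0.36),
                         label_map = default_label_map()) {
  if (length(dim(grid)) != 3) {
    stop_cartthick("`grid` must be a 3D array.", "cartthick_format_error")
  }
  spacing <- assert_spacing(spacing)
  storage.mode(grid) <- "integer"
  present <- sort(unique(as.integer(grid)))
  unknown <- setdiff(present, c(0L, unname(label_map)))
  if (length(unknown) > 0) {
    warn(paste0("grid contains labels not in `label_map` (retained): ",
                paste(unknown, collapse = ", ")))
  }
  structure(list(grid = grid, spacing = spacing, label_map = label_map),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$grid), collapse = " x "),
      " voxels, spacing (", paste(format(x$spacing), collapse = ", "),
      ") mm\n", sep = "")
  tab <- table(x$grid)
  for (nm in names(x$label_map)) {
    n <- tab[as.character(x$label_map[[nm]])]
    cat("  ", nm, " [", x$label_map[[nm]], "]: ",
        ifelse(is.na(n), 0L, as.integer(n)), " voxels\n", sep = "")
  }
  invisible(x)
}

#' Extract the voxel point set of one structure
#'
#' Returns every voxel whose label equals the structure's integer code, as a
#' tibble of 0-based indices `(i, j, k)` and physical coordinates
#' `(x, y, z) = index * spacing` in mm.
#'
#' @param vol A [label_volume()].
#' @param structure Structure name present in `vol$label_map`.
#' @return A tibble with columns `i, j, k, x, y, z`; attribute `spacing`.
#' @export
extract_structure_points <- function(vol, structure) {
  stopifnot(inherits(vol, "label_volume"))
  if (!structure %in% names(vol$label_map)) {
    stop_cartthick(paste0("unknown structure: '", structure, "'"),
                   "cartthick_key_error")
  }
  idx <- which(vol$grid == vol$label_map[[structure]], arr.ind = TRUE)
  if (nrow(idx) == 0) {
    stop_cartthick(paste0("structure '", structure, "' has no voxels"),
                   "cartthick_empty_structure_error")
  }
  voxel_points(idx[, 1] - 1L, idx[, 2] - 1L, idx[, 3] - 1L, vol$spacing)
}

# Build a voxel point-set tibble from 0-based indices.
voxel_points <- function(i, j, k, spacing) {
  out <- tibble::tibble(
    i = as.integer(i), j = as.integer(j), k = as.integer(k),
    x = i * spacing[1], y = j * spacing[2], z = k * spacing[3]
  )
  attr(out, "spacing") <- spacing
  out
}

# Re-derive physical coordinates after index manipulation.
refresh_coords <- function(points, spacing = attr(points, "spacing")) {
  points$x <- points$i * spacing[1]
  points$y <- points$j * spacing[2]
  points$z <- points$k * spacing[3]
  attr(points, "spacing") <- spacing
  points
}

#' Read a segmented label volume
#'
#' Reads MetaImage (`.mhd` + raw) or NIfTI (`.nii`/`.nii.gz`) label volumes.
#' Voxel spacing is taken from the file header; the stored axis order is taken
#' to already follow the package convention (x anteroposterior, y mediolateral,
#' z head-to-feet).
#'
#' @param path File path.
#' @param dialect `"metaimage"` or `"nifti"`; default guesses from extension.
#' @param label_map Structure-name to integer mapping.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, dialect = c("auto", "metaimage", "nifti"),
                              label_map = default_label_map()) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.mhd$", path, ignore.case = TRUE)) "metaimage" else "nifti"
  }
  if (!file.exists(path)) {
    stop_cartthick(paste0("file not found: ", path), "cartthick_io_error")
  }
  if (dialect == "metaimage") {
    read_mhd(path, label_map)
  } else {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop_cartthick(
                      paste0("cannot read NIfTI file: ", conditionMessage(e)),
                      "cartthick_format_error"))
    sp <- RNifti::pixdim(img)[1:3]
    grid <- array(as.integer(round(as.array(img))), dim = dim(img)[1:3])
    label_volume(grid, sp, label_map)
  }
}

#' Write a segmented label volume
#'
#' Writes a [label_volume()] so that [read_label_volume()] recovers an
#' identical grid and spacing. MetaImage output is an uncompressed `.mhd`
#' header plus `.raw` payload (MET_INT, little-endian); NIfTI output goes
#' through RNifti.
#'
#' @param vol A [label_volume()].
#' @param path Output path (`.mhd` or `.nii`/`.nii.gz`).
#' @param dialect `"metaimage"` or `"nifti"`; default guesses from extension.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path, dialect = c("auto", "metaimage", "nifti")) {
  stopifnot(inherits(vol, "label_volume"))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.mhd$", path, ignore.case = TRUE)) "metaimage" else "nifti"
  }
  if (!dir.exists(dirname(path))) {
    stop_cartthick(paste0("directory does not exist: ", dirname(path)),
                   "cartthick_io_error")
  }
  if (dialect == "metaimage") {
    write_mhd(vol, path)
  } else {
    img <- RNifti::asNifti(vol$grid)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

# --- MetaImage dialect ------------------------------------------------------
# Minimal key = value header per the MetaImage spec; only the fields needed for
# label volumes are handled (uncompressed, little-endian).

mhd_types <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_USHORT = 2L, MET_SHORT = 2L,
               MET_UINT = 4L, MET_INT = 4L)

read_mhd <- function(path, label_map) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = " = "), "")
  get <- function(key) {
    hit <- which(trimws(keys) == key)
    if (length(hit) == 0) NA_character_ else trimws(vals[hit[1]])
  }
  if (is.na(get("DimSize")) || !identical(get("NDims"), "3")) {
    stop_cartthick("not a 3D MetaImage header (need NDims = 3 and DimSize).",
                   "cartthick_format_error")
  }
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  sp_txt <- get("ElementSpacing")
  if (is.na(sp_txt)) sp_txt <- get("ElementSize")
  if (is.na(sp_txt)) {
    stop_cartthick("MetaImage header lacks ElementSpacing.",
                   "cartthick_metadata_error")
  }
  spacing <- as.numeric(strsplit(sp_txt, "\\s+")[[1]])
  etype <- get("ElementType") %||% "MET_SHORT"
  if (!etype %in% names(mhd_types)) {
    stop_cartthick(paste0("unsupported MetaImage ElementType: ", etype),
                   "cartthick_format_error")
  }
  if (identical(get("CompressedData"), "True")) {
    stop_cartthick("compressed MetaImage payloads are not supported.",
                   "cartthick_format_error")
  }
  msb <- get("BinaryDataByteOrderMSB")
  if (is.na(msb)) msb <- get("ElementByteOrderMSB")
  endian <- if (identical(msb, "True")) "big" else "little"
  datafile <- get("ElementDataFile")
  if (is.na(datafile)) {
    stop_cartthick("MetaImage header lacks ElementDataFile.",
                   "cartthick_format_error")
  }
  raw_path <- if (identical(datafile, "LOCAL")) path else
    file.path(dirname(path), datafile)
  size <- mhd_types[[etype]]
  signed <- !grepl("^MET_U", etype)
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  if (identical(datafile, "LOCAL")) {
    # payload follows the header text in the same file
    hdr_bytes <- sum(nchar(lines, type = "bytes") + 1L)
    seek(con, hdr_bytes)
  }
  v <- readBin(con, "integer", n = n, size = size, signed = signed,
               endian = endian)
  if (length(v) < n) {
    stop_cartthick("MetaImage payload shorter than DimSize implies.",
                   "cartthick_format_error")
  }
  # MetaImage stores x fastest, matching R array layout with dim (nx, ny, nz)
  label_volume(array(v, dim = dims), spacing, label_map)
}

write_mhd <- function(vol, path) {
  raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dim(vol$grid), collapse = " ")),
    paste("ElementSpacing =", paste(format(vol$spacing, digits = 17),
                                    collapse = " ")),
    "ElementType = MET_INT",
    paste("ElementDataFile =", raw_name)
  )
  writeLines(header, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.integer(vol$grid), con, size = 4L, endian = "little")
  invisible(path)
}
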