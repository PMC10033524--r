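#' MRI volume container
#'
#' A 3D scalar intensity grid in `(row, col, slice)` index order (0-based
#' geometry, 1-based R indexing), with voxel spacing in mm and a case
#' identifier. The slice axis is the acquisition (axial) axis.
#'
#' @param voxels numeric 3D array `(rows, cols, slices)`.
#' @param spacing numeric length-3, voxel spacing in mm; all components > 0.
#' @param case_id character scalar.
#' @return An object of class `mri_volume`.
#' @export
mri_volume <- function(voxels, spacing = c(1, 1, 1), case_id = "case") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array (rows, cols, slices)")
  if (any(dim(voxels) < 1L)) stop("all dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive numbers")
  structure(list(voxels = voxels, spacing = spacing,
                 case_id = as.character(case_id)[1]),
            class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mri_volume '%s'> %d x %d x %d voxels, spacing %s mm\n",
              x$case_id, d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

#' Aligned wall/tumor mask pair
#'
#' Two aligned binary 3D masks for one case: the bladder wall shell and the
#' tumor. Values are coerced to 0/1 (any nonzero voxel counts as inside).
#'
#' @param wall,tumor binary 3D arrays of identical shape.
#' @param case_id character scalar.
#' @return An object of class `mask_pair`.
#' @export
mask_pair <- function(wall, tumor, case_id = "case") {
  if (!is.array(wall) || !is.array(tumor) ||
      length(dim(wall)) != 3L || length(dim(tumor)) != 3L)
    stop("masks must be 3D arrays")
  if (!identical(dim(wall), dim(tumor)))
    stop(sprintf("mask shapes disagree: wall %s vs tumor %s",
                 paste(dim(wall), collapse = "x"),
                 paste(dim(tumor), collapse = "x")))
  wall <- array(as.numeric(wall != 0), dim(wall))
  tumor <- array(as.numeric(tumor != 0), dim(tumor))
  structure(list(wall = wall, tumor = tumor,
                 case_id = as.character(case_id)[1]),
            class = "mask_pair")
}

#' @export
print.mask_pair <- function(x, ...) {
  d <- dim(x$wall)
  cat(sprintf("<mask_pair '%s'> %d x %d x %d; wall %d voxels, tumor %d voxels\n",
              x$case_id, d[1], d[2], d[3], sum(x$wall), sum(x$tumor)))
  invisible(x)
}

.nrrd_types <- list(
  "double"  = list(what = "double",  size = 8, signed = TRUE),
  "float"   = list(what = "double",  size = 4, signed = TRUE),
  "int"     = list(what = "integer", size = 4, signed = TRUE),
  "int32"   = list(what = "integer", size = 4, signed = TRUE),
  "signed int" = list(what = "integer", size = 4, signed = TRUE),
  "short"   = list(what = "integer", size = 2, signed = TRUE),
  "int16"   = list(what = "integer", size = 2, signed = TRUE),
  "signed short" = list(what = "integer", size = 2, signed = TRUE),
  "ushort"  = list(what = "integer", size = 2, signed = FALSE),
  "uint16"  = list(what = "integer", size = 2, signed = FALSE),
  "uchar"   = list(what = "integer", size = 1, signed = FALSE),
  "uint8"   = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE)
)

#' Write a 3D array as an NRRD file
#'
#' Writes an attached-header NRRD (magic `NRRD0004`) in little-endian order.
#' Axis labels `"row" "col" "slice"` are recorded so [read_nrrd()] can
#' restore the canonical axis order regardless of how the file stores its
#' axes.
#'
#' @param x numeric 3D array.
#' @param path output file path.
#' @param spacing optional numeric length-3 voxel spacing (mm), written as the
#'   `spacings` header field.
#' @param type NRRD sample type; one of `"double"`, `"float"`, `"int"`,
#'   `"short"`, `"uchar"`. Default picks `"int"` for integer-valued data in
#'   range, else `"double"`.
#' @param encoding `"raw"` (default) or `"gzip"`.
#' @param labels character length-3 axis labels, fastest axis first. The
#'   default writes rows fastest (R's native order); passing a permutation
#'   stores the data in that axis order instead.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path, spacing = NULL, type = NULL,
                       encoding = c("raw", "gzip"),
                       labels = c("row", "col", "slice")) {
  encoding <- match.arg(encoding)
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("`x` must be a 3D array")
  labels <- as.character(labels)
  if (!setequal(labels, c("row", "col", "slice")) || length(labels) != 3L)
    stop("`labels` must be a permutation of row/col/slice")
  perm <- match(labels, c("row", "col", "slice"))
  xs <- if (identical(perm, 1:3)) x else aperm(x, perm)
  if (is.null(type)) {
    v <- as.vector(x)
    type <- if (all(is.finite(v)) && all(v == round(v)) &&
                all(abs(v) < 2^31)) "int" else "double"
  }
  tinfo <- .nrrd_types[[type]]
  if (is.null(tinfo)) stop(sprintf("unsupported NRRD type '%s'", type))
  hdr <- c("NRRD0004",
           sprintf("type: %s", type),
           "dimension: 3",
           sprintf("sizes: %s", paste(dim(xs), collapse = " ")),
           sprintf("encoding: %s", encoding),
           "endian: little",
           sprintf("labels: %s", paste(sprintf('"%s"', labels), collapse = " ")))
  if (!is.null(spacing)) {
    sp <- as.numeric(spacing)[perm]
    hdr <- c(hdr, sprintf("spacings: %s", paste(format(sp, digits = 10), collapse = " ")))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeChar("\n", con, eos = NULL)  # blank line terminates the header
  payload <- if (tinfo$what == "double") {
    raw_payload(as.double(xs), tinfo$size, "double")
  } else {
    raw_payload(as.integer(round(xs)), tinfo$size, "integer")
  }
  if (encoding == "gzip") payload <- memCompress(payload, "gzip")
  writeBin(payload, con)
  invisible(path)
}

raw_payload <- function(v, size, what) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(v, con, size = size, endian = "little")
  rawConnectionValue(con)
}

#' Read a 3D NRRD file
#'
#' Parses the NRRD header (attached or detached via `data file:`), decodes
#' `raw`, `gzip`/`gz` or `ascii` payloads, and returns the voxel grid in the
#' package's canonical `(rows, cols, slices)` order. If the header carries
#' axis `labels` that permute row/col/slice, the array is re-ordered
#' accordingly; otherwise the stored order is assumed canonical.
#'
#' @param path NRRD file (or detached `.nhdr` header) path.
#' @return A list with elements `data` (3D array), `spacing` (mm triple;
#'   `(1,1,1)` with a warning when the header gives none), and `header`
#'   (named list of raw header fields).
#' @export
read_nrrd <- function(path) {
  if (!file.exists(path)) stop(sprintf("NRRD file not found: %s", path))
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 8 || rawToChar(bytes[1:4]) != "NRRD")
    stop(sprintf("malformed NRRD '%s': missing NRRD magic", path))
  # header = everything up to the first blank line
  nl <- which(bytes == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (i in nl) {
    line_len <- i - prev - 1L
    if (line_len == 0L || (line_len == 1L && bytes[prev + 1L] == as.raw(13L))) {
      hdr_end <- i
      break
    }
    prev <- i
  }
  if (is.na(hdr_end)) stop(sprintf("malformed NRRD '%s': no header terminator", path))
  hdr_txt <- strsplit(rawToChar(bytes[seq_len(hdr_end - 1L)]), "\r?\n")[[1]]
  hdr_txt <- hdr_txt[-1]  # magic
  hdr_txt <- hdr_txt[!grepl("^\\s*(#|$)", hdr_txt)]
  kv <- regmatches(hdr_txt, regexec("^([^:]+):=?\\s*(.*)$", hdr_txt))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad))
    stop(sprintf("malformed NRRD '%s': unparsable header line '%s'",
                 path, hdr_txt[bad][1]))
  header <- stats::setNames(
    lapply(kv, function(m) trimws(m[3])),
    tolower(trimws(vapply(kv, `[`, "", 2))))

  need <- function(field) {
    if (is.null(header[[field]]))
      stop(sprintf("malformed NRRD '%s': missing required field '%s'", path, field))
    header[[field]]
  }
  ndim <- as.integer(need("dimension"))
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  if (is.na(ndim) || ndim != 3L || length(sizes) != 3L)
    stop(sprintf("NRRD '%s' is %s-dimensional; only 3D volumes are supported",
                 path, need("dimension")))
  type <- tolower(need("type"))
  tinfo <- .nrrd_types[[type]]
  if (is.null(tinfo)) stop(sprintf("malformed NRRD '%s': unsupported type '%s'", path, type))
  encoding <- tolower(need("encoding"))

  if (!is.null(header[["data file"]]) || !is.null(header[["datafile"]])) {
    dfile <- header[["data file"]] %||% header[["datafile"]]
    dpath <- file.path(dirname(path), dfile)
    if (!file.exists(dpath))
      stop(sprintf("malformed NRRD '%s': detached data file '%s' not found", path, dfile))
    payload <- readBin(dpath, "raw", n = file.info(dpath)$size)
  } else {
    payload <- bytes[seq.int(hdr_end + 1L, length(bytes))]
  }

  n <- prod(sizes)
  if (encoding %in% c("gzip", "gz")) {
    payload <- memDecompress(payload, "gzip")
    encoding <- "raw"
  }
  if (encoding %in% c("ascii", "text", "txt")) {
    v <- as.numeric(strsplit(trimws(rawToChar(payload)), "\\s+")[[1]])
  } else if (encoding == "raw") {
    endian <- tolower(header[["endian"]] %||% "little")
    v <- readBin(payload, tinfo$what, n = n, size = tinfo$size,
                 signed = tinfo$signed, endian = endian)
    v <- as.numeric(v)
  } else {
    stop(sprintf("malformed NRRD '%s': unsupported encoding '%s'", path, encoding))
  }
  if (length(v) < n)
    stop(sprintf("malformed NRRD '%s': payload has %d of %d samples",
                 path, length(v), n))
  x <- array(v[seq_len(n)], dim = sizes)

  axis_names <- c("row", "col", "slice")
  if (!is.null(header[["labels"]])) {
    labs <- regmatches(header[["labels"]],
                       gregexpr('"[^"]*"', header[["labels"]]))[[1]]
    labs <- gsub('"', "", labs)
    if (length(labs) == 3L && setequal(labs, axis_names))
      x <- aperm(x, match(axis_names, labs))
    else labs <- axis_names
  } else labs <- axis_names

  spacing <- NULL
  if (!is.null(header[["spacings"]])) {
    spacing <- as.numeric(strsplit(header[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(header[["space directions"]])) {
    vecs <- regmatches(header[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", header[["space directions"]]))[[1]]
    if (length(vecs) == 3L)
      spacing <- vapply(vecs, function(s) {
        sqrt(sum(as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])^2))
      }, 0)
  }
  if (is.null(spacing) || length(spacing) != 3L || any(is.na(spacing))) {
    warning(sprintf("NRRD '%s' has no usable spacing; assuming (1, 1, 1) mm", path))
    spacing <- c(1, 1, 1)
  } else if (length(labs) == 3L && setequal(labs, axis_names)) {
    spacing <- spacing[order(match(labs, axis_names))]
  }
  list(data = x, spacing = as.numeric(spacing), header = header)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load one segmentation case from a directory
#'
#' A case directory holds three aligned NRRD volumes: the T2 intensity image
#' and the two binary masks (bladder wall, tumor). Mask voxels are coerced to
#' `{0, 1}` (any nonzero value counts as inside the mask).
#'
#' @param case_dir directory containing the three files.
#' @param files named character vector giving the file names for components
#'   `image`, `wall` and `tumor`.
#' @return A list with `image` ([mri_volume]) and `masks` ([mask_pair]).
#' @export
load_case <- function(case_dir,
                      files = c(image = "image.nrrd", wall = "wall.nrrd",
                                tumor = "tumor.nrrd")) {
  stopifnot(all(c("image", "wall", "tumor") %in% names(files)))
  paths <- file.path(case_dir, files[c("image", "wall", "tumor")])
  missing <- !file.exists(paths)
  if (any(missing))
    stop(sprintf("case '%s' is missing component(s): %s", case_dir,
                 paste(names(files)[missing], collapse = ", ")))
  img <- read_nrrd(paths[1])
  wall <- read_nrrd(paths[2])
  tumor <- read_nrrd(paths[3])
  shapes <- list(dim(img$data), dim(wall$data), dim(tumor$data))
  if (!identical(shapes[[1]], shapes[[2]]) || !identical(shapes[[1]], shapes[[3]]))
    stop(sprintf(
      "case '%s': component shapes disagree (image %s, wall %s, tumor %s)",
      case_dir,
      paste(shapes[[1]], collapse = "x"), paste(shapes[[2]], collapse = "x"),
      paste(shapes[[3]], collapse = "x")))
  id <- basename(normalizePath(case_dir, mustWork = FALSE))
  list(image = mri_volume(img$data, img$spacing, id),
       masks = mask_pair(wall$data, tumor$data, id))
}

#' Write one segmentation case to a directory
#'
#' @param case_dir target directory (created if absent).
#' @param image an [mri_volume].
#' @param masks a [mask_pair] aligned with `image`.
#' @return `case_dir`, invisibly.
#' @export
write_case <- function(case_dir, image, masks) {
  stopifnot(inherits(image, "mri_volume"), inherits(masks, "mask_pair"))
  if (!identical(dim(image$voxels), dim(masks$wall)))
    stop("image and masks have different shapes")
  dir.create(case_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(case_dir)) stop(sprintf("cannot create case dir '%s'", case_dir))
  write_nrrd(image$voxels, file.path(case_dir, "image.nrrd"),
             spacing = image$spacing, type = "double")
  write_nrrd(masks$wall, file.path(case_dir, "wall.nrrd"),
             spacing = image$spacing, type = "uchar")
  write_nrrd(masks$tumor, file.path(case_dir, "tumor.nrrd"),
             spacing = image$spacing, type = "uchar")
  invisible(case_dir)
}
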