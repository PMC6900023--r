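#' Read a volume from NIfTI or a TIFF slice stack
#'
#' Accepts a NIfTI file (`.nii` / `.nii.gz`) or a directory of equally sized
#' single-slice TIFF files; stack order follows the zero-padded numeric part
#' of the file names (plain alphabetical order otherwise). Axial slices lie
#' along the third array index.
#'
#' @param path File or directory path.
#' @param spacing Voxel spacing in mm for TIFF stacks (TIFF carries no
#'   spacing); ignored for NIfTI, whose header is authoritative.
#' @return A list with `data` (3D array) and `spacing` (length-3, mm), class
#'   `"volume_record"`.
#' @export
read_volume <- function(path, spacing = c(0.2, 0.2, 0.2)) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                        ignore.case = TRUE)
    if (length(files) == 0L) stop("no TIFF slices found in ", path)
    num <- suppressWarnings(
      as.numeric(gsub("\\D", "", basename(files))))
    files <- files[order(if (anyNA(num)) basename(files) else num)]
    slices <- lapply(files, function(f) {
      s <- tiff::readTIFF(f, as.is = FALSE)
      if (length(dim(s)) == 3L) s <- s[, , 1L] # drop extra channels
      s
    })
    dims <- unique(t(vapply(slices, dim, integer(2))))
    if (nrow(dims) != 1L)
      stop("format error: TIFF slices differ in size")
    data <- array(unlist(slices), dim = c(dims[1L, ], length(slices)))
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    return(structure(list(data = data, spacing = spacing),
                     class = "volume_record"))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)
  structure(list(data = data, spacing = as.numeric(sp[1:3])),
            class = "volume_record")
}

#' Write a volume as NIfTI or a TIFF slice stack
#'
#' NIfTI output stores the spacing in the header and the voxels as 64-bit
#' floats, so values round-trip exactly. For a directory path, one 32-bit
#' float TIFF per axial slice is written (`slice_0001.tif`, ...).
#'
#' @param record A `"volume_record"`, or a plain 3D array (then `spacing`
#'   applies).
#' @param path Output `.nii`/`.nii.gz` file, or a directory for TIFF.
#' @param spacing Spacing when `record` is a plain array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(record, path, spacing = c(0.2, 0.2, 0.2)) {
  if (!inherits(record, "volume_record")) {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    record <- structure(list(data = as_volume3d(record), spacing = spacing),
                        class = "volume_record")
  }
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- structure(record$data, pixdim = record$spacing)
    RNifti::writeNifti(RNifti::asNifti(img, internal = FALSE,
                                       datatype = "double"), path)
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- dim(record$data)[3L]
  for (k in seq_len(n))
    tiff::writeTIFF(record$data[, , k],
                    file.path(path, sprintf("slice_%04d.tif", k)),
                    bits.per.sample = 32L)
  invisible(path)
}

#' @export
print.volume_record <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1L], d[2L], d[3L],
              paste(format(x$spacing, digits = 4), collapse = " x ")))
  invisible(x)
}

#' Save MS-D parameters to a versioned checkpoint
#'
#' Writes the flat parameter vector as little-endian 64-bit floats behind a
#' magic/version preamble, plus a JSON sidecar (`<path>.json`) carrying the
#' architecture, the normalization statistics and the parameter count.
#'
#' @param fit An `"msd_fit"`, or a flat parameter vector (then `config` is
#'   required).
#' @param path Checkpoint file path.
#' @param config An [msd_config()] when `fit` is a plain vector.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path, config = NULL) {
  if (inherits(fit, "msd_fit")) {
    params <- fit$params
    config <- fit$config
    stats <- fit$stats
  } else {
    params <- as.numeric(fit)
    if (is.null(config)) stop("'config' required for a plain parameter vector")
    stats <- NULL
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MSDCKPT1"), con)
  writeBin(length(params), con, size = 4L, endian = "little")
  writeBin(params, con, size = 8L, endian = "little")
  # normalization stats ride in the binary payload so they round-trip exactly
  writeBin(as.integer(!is.null(stats)), con, size = 4L, endian = "little")
  if (!is.null(stats))
    writeBin(c(stats$mean, stats$sd), con, size = 8L, endian = "little")
  side <- list(format = "msdseg-checkpoint", version = 1L,
               depth = config$depth, dilation_cycle = config$dilation_cycle,
               cutoff = config$cutoff, n_parameters = length(params))
  side$has_normalization <- !is.null(stats)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load an MS-D checkpoint
#'
#' @param path Checkpoint written by [save_checkpoint()].
#' @return `list(params, config, stats)` (stats `NULL` when absent).
#' @export
load_checkpoint <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(side$format, "msdseg-checkpoint"))
    stop("not an msdseg checkpoint sidecar")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, raw(), 8L)
  if (!identical(magic, charToRaw("MSDCKPT1"))) stop("bad checkpoint magic")
  n <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  params <- readBin(con, numeric(), n, size = 8L, endian = "little")
  has_stats <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  stats <- NULL
  if (isTRUE(has_stats == 1L)) {
    ms <- readBin(con, numeric(), 2L, size = 8L, endian = "little")
    stats <- structure(list(mean = ms[1L], sd = ms[2L]), class = "norm_stats")
  }
  config <- msd_config(depth = side$depth,
                       dilation_cycle = side$dilation_cycle,
                       cutoff = side$cutoff)
  if (length(params) != count_parameters(config))
    stop("checkpoint parameter count does not match its config")
  list(params = params, config = config, stats = stats)
}
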