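#' @include io_tiff.R
NULL

#' Describe the on-disk layout of a projection dataset
#'
#' A dataset is a directory holding one TIFF file per frame, with
#' zero-padded numeric suffixes whose lexicographic order is the
#' acquisition order, plus a geometry file carrying the angle list. The
#' four name fields give the file-name prefixes of the projection, flat
#' (white) and dark groups, and the name of the geometry/theta file.
#'
#' @param container only \code{"tiff_sequence"} is supported; the
#'   \code{"hdf5"} container is recognized but rejected with an error.
#' @param data file-name prefix of the projection frames.
#' @param white prefix of the flat-field frames; frames named
#'   \code{<white>_before_NNNN} / \code{<white>_after_NNNN} are split into
#'   the two groups, plain \code{<white>_NNNN} frames all go to "before".
#' @param dark prefix of the dark frames.
#' @param theta name of the YAML geometry file (angle list and scalars).
#' @return a named list of class \code{"DatasetLayout"}.
#' @export
datasetLayout <- function(container = c("tiff_sequence", "hdf5"),
                          data = "tomo", white = "flat", dark = "dark",
                          theta = "geometry.yaml") {
  container <- match.arg(container)
  if (container == "hdf5")
    stop("the 'hdf5' container is not supported by this build; ",
         "use a 'tiff_sequence' dataset")
  structure(list(container = container, data = data, white = white,
                 dark = dark, theta = theta),
            class = "DatasetLayout")
}

.seqFiles <- function(dir, prefix) {
  f <- list.files(dir, pattern = paste0("^", prefix, "_[0-9]+\\.tiff?$"),
                  full.names = TRUE)
  sort(f)
}

.readStack <- function(files) {
  frames <- lapply(files, .tiffRead)
  hw <- dim(frames[[1L]])
  for (i in seq_along(frames))
    if (!identical(dim(frames[[i]]), hw))
      stop("frame shape mismatch in TIFF sequence at ", basename(files[i]))
  out <- array(0, dim = c(length(frames), hw[1L], hw[2L]))
  for (i in seq_along(frames)) out[i, , ] <- frames[[i]]
  out
}

.writeStack <- function(stack, dir, prefix, format = "float64") {
  n <- dim(stack)[1L]
  for (i in seq_len(n)) {
    f <- file.path(dir, sprintf("%s_%04d.tif", prefix, i - 1L))
    .tiffWrite(stack[i, , ], f, format = format)
  }
  invisible(n)
}

#' Read a projection dataset from disk
#'
#' @param path dataset directory.
#' @param layout a [datasetLayout()].
#' @return a [ProjectionSet-class] with all stacks as double-precision
#'   arrays; 8/16-bit unsigned input values are widened losslessly.
#' @export
readProjectionSet <- function(path, layout = datasetLayout()) {
  if (!dir.exists(path)) stop("dataset directory not found: ", path)
  gfile <- file.path(path, layout$theta)
  if (!file.exists(gfile))
    stop("missing geometry/theta file '", layout$theta, "' in ", path)
  geom <- geometryFromList(yaml::read_yaml(gfile))
  pf <- .seqFiles(path, layout$data)
  if (!length(pf)) stop("missing projection group '", layout$data, "' in ", path)
  fb <- .seqFiles(path, paste0(layout$white, "_before"))
  fa <- .seqFiles(path, paste0(layout$white, "_after"))
  if (!length(fb) && !length(fa)) fb <- .seqFiles(path, layout$white)
  if (!length(fb) && !length(fa))
    stop("missing flat (white) group '", layout$white, "' in ", path)
  dk <- .seqFiles(path, layout$dark)
  if (!length(dk)) stop("missing dark group '", layout$dark, "' in ", path)
  proj <- .readStack(pf)
  projectionSet(
    projections = proj,
    flatsBefore = if (length(fb)) .readStack(fb) else array(0, c(0, 0, 0)),
    flatsAfter = if (length(fa)) .readStack(fa) else array(0, c(0, 0, 0)),
    darks = .readStack(dk),
    geometry = geom)
}

#' Write a projection dataset to disk
#'
#' Frames are stored as uncompressed 64-bit float grayscale TIFFs so the
#' read-back reproduces every array bit-exactly; the geometry is stored in
#' the YAML theta file.
#'
#' @param ps a [ProjectionSet-class].
#' @param path dataset directory (created if needed).
#' @param layout a [datasetLayout()].
#' @return \code{path}, invisibly.
#' @export
writeProjectionSet <- function(ps, path, layout = datasetLayout()) {
  stopifnot(is(ps, "ProjectionSet"))
  validObject(ps)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  .writeStack(ps@projections, path, layout$data)
  if (length(ps@flatsBefore))
    .writeStack(ps@flatsBefore, path, paste0(layout$white, "_before"))
  if (length(ps@flatsAfter))
    .writeStack(ps@flatsAfter, path, paste0(layout$white, "_after"))
  .writeStack(ps@darks, path, layout$dark)
  yaml::write_yaml(geometryToList(ps@geometry), file.path(path, layout$theta))
  invisible(path)
}

#' Write / read a reconstructed slice as 32-bit float TIFF
#'
#' The physical quantity and pixel size are stored in the TIFF
#' ImageDescription tag and survive the round trip. Values are stored
#' unscaled (no quantization to 8/16-bit) so downstream analysis keeps
#' physical units.
#'
#' @param slice a [ReconSlice-class]; NaN/Inf pixels are rejected.
#' @param path output file.
#' @return \code{writeSlice()}: \code{path} invisibly;
#'   \code{readSlice()}: a [ReconSlice-class].
#' @export
writeSlice <- function(slice, path) {
  stopifnot(is(slice, "ReconSlice"))
  validObject(slice)
  if (any(!is.finite(slice@values)))
    stop("slice contains non-finite pixels; refusing to write")
  desc <- sprintf("quantity=%s;pixel_size=%.17g", slice@quantity, slice@pixelSize)
  .tiffWrite(slice@values, path, description = desc, format = "float")
  invisible(path)
}

#' @rdname writeSlice
#' @export
readSlice <- function(path) {
  img <- .tiffRead(path)
  if (nrow(img) != ncol(img)) stop("slice file is not square: ", path)
  desc <- attr(img, "description")
  quantity <- "attenuation_coefficient"
  pixelSize <- 1
  if (!is.null(desc)) {
    kv <- strsplit(strsplit(desc, ";")[[1L]], "=")
    for (p in kv) {
      if (p[1L] == "quantity") quantity <- p[2L]
      if (p[1L] == "pixel_size") pixelSize <- as.numeric(p[2L])
    }
  }
  reconSlice(matrix(as.numeric(img), nrow = nrow(img)), pixelSize, quantity)
}
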