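#' @include core_model.R
NULL

## Minimal single-image grayscale TIFF codec (little-endian, uncompressed,
## float32 / uint16 / uint8, optional ImageDescription tag).
##
## Rationale: physical-unit slices must round-trip without rescaling, and
## the CRAN 'tiff' writer clamps data to [0, 1] on write; reading of
## foreign (e.g. compressed) files still falls back to tiff::readTIFF.

.tiffWrite <- function(img, path, description = NULL,
                       format = c("float", "float64", "uint16", "uint8")) {
  format <- match.arg(format)
  stopifnot(is.matrix(img))
  h <- nrow(img); w <- ncol(img)
  bps <- switch(format, float = 32L, float64 = 64L, uint16 = 16L, uint8 = 8L)
  sf <- if (format %in% c("float", "float64")) 3L else 1L
  nbytes <- h * w * (bps %/% 8L)
  desc <- if (is.null(description)) NULL else c(charToRaw(description), as.raw(0L))
  data_off <- 8L
  desc_off <- data_off + nbytes
  ifd_off <- desc_off + if (is.null(desc)) 0L else length(desc)
  if (ifd_off %% 2L == 1L) ifd_off <- ifd_off + 1L  # IFD must be word-aligned
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off), con, size = 4, endian = "little")
  if (format == "float") {
    writeBin(as.numeric(t(img)), con, size = 4, endian = "little")
  } else if (format == "float64") {
    writeBin(as.numeric(t(img)), con, size = 8, endian = "little")
  } else {
    v <- as.integer(round(t(img)))
    top <- if (format == "uint16") 65535L else 255L
    if (any(v < 0L | v > top))
      stop("integer TIFF sample out of range for ", format)
    if (format == "uint16") {
      ## writeBin size=2 expects signed shorts; map [32768, 65535] down
      v <- ifelse(v > 32767L, v - 65536L, v)
      writeBin(v, con, size = 2, endian = "little")
    } else writeBin(as.raw(v), con)
  }
  if (!is.null(desc)) writeBin(desc, con)
  if (seek(con) < ifd_off) writeBin(as.raw(0L), con)
  tags <- list(
    c(256L, 3L, 1L, w), c(257L, 3L, 1L, h), c(258L, 3L, 1L, bps),
    c(259L, 3L, 1L, 1L), c(262L, 3L, 1L, 1L))
  if (!is.null(desc)) tags <- c(tags, list(c(270L, 2L, length(desc), desc_off)))
  tags <- c(tags, list(
    c(273L, 4L, 1L, data_off), c(277L, 3L, 1L, 1L), c(278L, 3L, 1L, h),
    c(279L, 4L, 1L, nbytes), c(339L, 3L, 1L, sf)))
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(as.integer(tg[1]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[2]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[3]), con, size = 4, endian = "little")
    if (tg[2] == 3L && tg[3] == 1L) {
      writeBin(as.integer(tg[4]), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(tg[4]), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")
  invisible(path)
}

.tiffReadOwn <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L || rawToChar(raw[1:2]) != "II") return(NULL)
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (u16(2L) != 42L) return(NULL)
  ifd <- u32(4L)
  n <- u16(ifd)
  tags <- list()
  for (i in seq_len(n)) {
    e <- ifd + 2L + (i - 1L) * 12L
    tag <- u16(e); typ <- u16(e + 2L); cnt <- u32(e + 4L)
    sz <- switch(as.character(typ), "1" = 1L, "2" = 1L, "3" = 2L, "4" = 4L, NA_integer_)
    if (is.na(sz)) next
    nb <- sz * cnt
    voff <- if (nb <= 4L) e + 8L else u32(e + 8L)
    vals <- if (typ == 2L) {
      rawToChar(raw[voff + seq_len(max(cnt - 1L, 0L))])
    } else if (typ == 3L) {
      vapply(seq_len(cnt), function(k) u16(voff + (k - 1L) * 2L), numeric(1))
    } else {
      vapply(seq_len(cnt), function(k) u32(voff + (k - 1L) * 4L), numeric(1))
    }
    tags[[as.character(tag)]] <- vals
  }
  g <- function(t, d = NULL) if (!is.null(tags[[t]])) tags[[t]] else d
  if (!identical(g("259", 1), 1)) return(NULL)        # compressed: not ours
  w <- g("256"); h <- g("257"); bps <- g("258", 1); sf <- g("339", 1)
  offs <- g("273"); cnts <- g("279")
  if (is.null(w) || is.null(h) || is.null(offs)) return(NULL)
  if (!identical(g("277", 1), 1)) return(NULL)
  payload <- unlist(lapply(seq_along(offs), function(i)
    raw[offs[i] + seq_len(cnts[i])]), use.names = FALSE)
  npix <- w * h
  vals <- if (sf == 3 && bps == 32) {
    readBin(as.raw(payload), "numeric", n = npix, size = 4, endian = "little")
  } else if (sf == 3 && bps == 64) {
    readBin(as.raw(payload), "numeric", n = npix, size = 8, endian = "little")
  } else if (bps == 16) {
    v <- readBin(as.raw(payload), "integer", n = npix, size = 2,
                 signed = FALSE, endian = "little")
    as.numeric(v)
  } else if (bps == 8) {
    as.numeric(as.integer(as.raw(payload)))
  } else return(NULL)
  img <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  attr(img, "description") <- g("270")
  attr(img, "sample.format") <- if (sf == 3) "float" else "uint"
  attr(img, "bits.per.sample") <- as.integer(bps)
  img
}

.tiffRead <- function(path) {
  img <- tryCatch(.tiffReadOwn(path), error = function(e) NULL)
  if (!is.null(img)) return(img)
  ## foreign dialect: delegate to the CRAN reader (values as stored)
  img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  d <- attr(img, "description")
  m <- matrix(as.numeric(img), nrow = nrow(img))
  attr(m, "description") <- d
  m
}

## round a double matrix/array through IEEE float32 storage
.float32 <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
                 n = length(x), size = 4L)
  dim(out) <- d
  out
}
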