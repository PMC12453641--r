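# Image and dataset I/O: lossless 16-bit TIFF and raw float64 array files
# (with JSON manifest), 8-bit PNG export, a minimal single-frame DICOM
# reader (rescale slope/intercept applied to Hounsfield units), and paired
# dataset read/write with a reproducibility manifest.

#' Read a grayscale image slice
#'
#' Supported formats: `"tiff16"` (lossless 16-bit TIFF), `"png"` (8- or
#' 16-bit PNG), `"array"` (raw little-endian float64 with a JSON manifest,
#' bit-exact), `"dicom"` (single-frame uncompressed little-endian DICOM;
#' rescale slope/intercept are applied so values are in Hounsfield units).
#' The format is guessed from the file extension when not given.
#'
#' @param path input file.
#' @param format format override.
#' @return an H x W numeric matrix; DICOM input carries the applied
#'   rescale/window metadata in attribute `"dicom"`.
#' @export
read_image <- function(path, format = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  format <- format %||% guess_format(path)
  switch(format,
    tiff16 = ,
    tiff = tiff::readTIFF(path),
    png = {
      img <- png::readPNG(path)
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      img
    },
    array = read_array_image(path),
    dicom = read_dicom(path),
    stop("unsupported image format: ", format, call. = FALSE))
}

#' Write a grayscale image slice
#'
#' `"tiff16"` stores 16 bits per sample (values clamped to [0, 1];
#' round-trip exact to 1/65535); `"png"` stores 8 bits; `"array"` stores
#' raw float64 and a JSON manifest and round-trips bit-exactly.
#'
#' @param image an H x W numeric matrix.
#' @param path output file.
#' @param format `"tiff16"`, `"png"` or `"array"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, format = NULL) {
  stopifnot(is.matrix(image))
  format <- format %||% guess_format(path)
  switch(format,
    tiff16 = ,
    tiff = tiff::writeTIFF(pmin(pmax(image, 0), 1), path,
                           bits.per.sample = 16L),
    png = png::writePNG(pmin(pmax(image, 0), 1), path),
    array = write_array_image(image, path),
    stop("unsupported image format for writing: ", format, call. = FALSE))
  invisible(path)
}

guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
    tif = , tiff = "tiff16",
    png = "png",
    bin = , raw = "array",
    dcm = , dicom = "dicom",
    json = "array",
    stop("cannot guess image format from extension of ", path,
         call. = FALSE))
}

read_array_image <- function(path) {
  if (grepl("[.]json$", path)) path <- sub("[.]json$", "", path)
  man <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(man$dim), size = 8L,
               endian = "little")
  matrix(v, man$dim[1L], man$dim[2L])
}

write_array_image <- function(image, path) {
  con <- file(path, "wb")
  writeBin(as.vector(image), con, size = 8L, endian = "little")
  close(con)
  jsonlite::write_json(list(format = "hybridformer-array", version = 1L,
                            dim = dim(image), dtype = "float64",
                            endian = "little"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

## ---- minimal DICOM reader -----------------------------------------------

u16 <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
u32 <- function(raw4) sum(as.numeric(raw4) * 256^(0:3))

# Single-frame, uncompressed, little-endian (explicit or implicit VR)
# grayscale DICOM.  Enough for reading CT slices; sequences and compressed
# transfer syntaxes are not supported.
read_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path, call. = FALSE)
  pos <- 133L
  n <- length(raw)
  tags <- list()
  pixel_raw <- NULL
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n) {
    grp <- u16(raw[pos:(pos + 1L)])
    ele <- u16(raw[(pos + 2L):(pos + 3L)])
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    explicit <- grepl("^[A-Z]{2}$", vr)
    if (explicit && vr %in% long_vrs) {
      len <- u32(raw[(pos + 8L):(pos + 11L)])
      hdr <- 12L
    } else if (explicit) {
      len <- u16(raw[(pos + 6L):(pos + 7L)])
      hdr <- 8L
    } else {
      len <- u32(raw[(pos + 4L):(pos + 7L)])
      hdr <- 8L
    }
    if (len > n) stop("corrupt DICOM element length", call. = FALSE)
    val <- raw[(pos + hdr):(pos + hdr + len - 1L)]
    key <- sprintf("%04x,%04x", grp, ele)
    if (grp == 0x7fe0L && ele == 0x0010L) {
      pixel_raw <- val
      break
    }
    tags[[key]] <- val
    pos <- pos + hdr + len
  }
  num_tag <- function(key, default = NA_real_) {
    v <- tags[[key]]
    if (is.null(v)) return(default)
    as.numeric(trimws(rawToChar(v)))
  }
  us_tag <- function(key, default = NA_integer_) {
    v <- tags[[key]]
    if (is.null(v)) return(default)
    u16(v[1:2])
  }
  rows <- us_tag("0028,0010")
  cols <- us_tag("0028,0011")
  bits <- us_tag("0028,0100", 16L)
  signed <- identical(us_tag("0028,0103", 0L), 1L)
  slope <- num_tag("0028,1053", 1)
  intercept <- num_tag("0028,1052", 0)
  if (is.na(rows) || is.na(cols) || is.null(pixel_raw))
    stop("DICOM misses Rows/Columns/PixelData", call. = FALSE)
  size <- bits %/% 8L
  px <- readBin(pixel_raw, "integer", n = rows * cols, size = size,
                signed = if (size <= 2L) signed else TRUE,
                endian = "little")
  img <- matrix(slope * px + intercept, rows, cols, byrow = TRUE)
  attr(img, "dicom") <- list(rescale_slope = slope,
                             rescale_intercept = intercept,
                             window_center = num_tag("0028,1050"),
                             window_width = num_tag("0028,1051"),
                             bits_allocated = bits)
  img
}

## ---- paired dataset I/O --------------------------------------------------

#' Write a paired dataset to a directory
#'
#' Stores each pair as `pair_###_{ndct,ldct}` image files plus a
#' `manifest.json` carrying the reproducibility record (seeds, photon
#' counts, simulation mode, format).
#'
#' @param pairs list of `dose_pair`s.
#' @param dir output directory (created if needed).
#' @param format `"tiff16"` (lossless 16-bit) or `"array"` (bit-exact
#'   float64).
#' @return `dir`, invisibly.
#' @export
write_pairs <- function(pairs, dir, format = c("tiff16", "array")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "tiff16") ".tif" else ".bin"
  man <- list(format = format, n_pairs = length(pairs),
              pairs = lapply(seq_along(pairs), function(i) {
                p <- pairs[[i]]
                list(index = i, seed = p$seed, I0 = p$I0, mode = p$mode,
                     height = nrow(p$ndct), width = ncol(p$ndct))
              }))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    write_image(p$ndct, file.path(dir, sprintf("pair_%03d_ndct%s", i, ext)),
                format)
    # reconstructed slices can exceed [0,1]; shift/scale lossy formats
    ld <- p$ldct
    if (format == "tiff16") ld <- pmin(pmax(ld, 0), 1)
    write_image(ld, file.path(dir, sprintf("pair_%03d_ldct%s", i, ext)),
                format)
  }
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a paired dataset written by [write_pairs()]
#'
#' @param dir dataset directory containing `manifest.json`.
#' @return list of `dose_pair`s.
#' @export
read_pairs <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    stop("no manifest.json in ", dir, call. = FALSE)
  man <- jsonlite::read_json(mf, simplifyVector = FALSE)
  ext <- if (man$format == "tiff16") ".tif" else ".bin"
  lapply(seq_along(man$pairs), function(i) {
    rec <- man$pairs[[i]]
    structure(list(
      ndct = read_image(file.path(dir, sprintf("pair_%03d_ndct%s", i, ext)),
                        man$format),
      ldct = read_image(file.path(dir, sprintf("pair_%03d_ldct%s", i, ext)),
                        man$format),
      I0 = rec$I0, mode = rec$mode, seed = rec$seed), class = "dose_pair")
  })
}
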