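# Shared fixtures, built in code at test time.

tiny_config <- function(variant = "full", ...) {
  hf_model_config(embed_dim = 16L, depths_per_stage = c(1L, 1L),
                  bottleneck_depth = 1L, variant = variant, ...)
}

# Internal helpers are not exported; reach them through the namespace.
hf <- asNamespace("hybridformer")

# memoised small phantom + clean reconstruction (several files use it)
.fixture_env <- new.env()

fixture_phantom <- function() {
  if (is.null(.fixture_env$ph)) {
    .fixture_env$ph <- generate_phantom(48L, 48L, num_ellipses = 6L,
                                        seed = 101L)
    sino <- radon_transform(.fixture_env$ph$image)
    .fixture_env$clean_rec <- fbp_reconstruct(sino, 48L, 48L)
  }
  list(ph = .fixture_env$ph, clean_rec = .fixture_env$clean_rec)
}

# Minimal synthetic single-frame DICOM writer (explicit VR little endian);
# used only to exercise the reader.
write_synthetic_dicom <- function(path, pixels, slope = 1,
                                  intercept = -1024) {
  stopifnot(is.matrix(pixels))
  u16r <- function(x) as.raw(c(x %% 256L, x %/% 256L))
  u32r <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                               (x %/% 65536) %% 256,
                               (x %/% 16777216) %% 256))
  elem_short <- function(grp, ele, vr, value_raw) {
    len <- length(value_raw)
    if (len %% 2L == 1L) value_raw <- c(value_raw, as.raw(0L))
    c(u16r(grp), u16r(ele), charToRaw(vr), u16r(length(value_raw)),
      value_raw)
  }
  elem_long <- function(grp, ele, vr, value_raw) {
    c(u16r(grp), u16r(ele), charToRaw(vr), as.raw(c(0, 0)),
      u32r(length(value_raw)), value_raw)
  }
  ds <- function(x) charToRaw(format(x))
  px <- as.integer(round(t(pixels)))   # DICOM rows are contiguous
  pxr <- writeBin(px, raw(), size = 2L, endian = "little")
  body <- c(
    elem_short(0x0028, 0x0010, "US", u16r(nrow(pixels))),
    elem_short(0x0028, 0x0011, "US", u16r(ncol(pixels))),
    elem_short(0x0028, 0x0100, "US", u16r(16L)),
    elem_short(0x0028, 0x0103, "US", u16r(0L)),
    elem_short(0x0028, 0x1052, "DS", ds(intercept)),
    elem_short(0x0028, 0x1053, "DS", ds(slope)),
    elem_long(0x7fe0, 0x0010, "OW", pxr))
  con <- file(path, "wb")
  writeBin(c(raw(128L), charToRaw("DICM"), body), con)
  close(con)
  invisible(path)
}
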