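#' Write a list of frames as a multi-page 16-bit TIFF
#'
#' One page per timepoint, in list order. Values are clipped to `[0, 1]`
#' and quantized to 16 bits.
#'
#' @param frames A matrix or list of matrices with values in `[0, 1]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  frames <- purrr::map(frames, function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a list of frames
#'
#' @param path TIFF file path.
#' @return List of numeric matrices with values in `[0, 1]`.
#' @export
read_frames <- function(path) {
  out <- tiff::readTIFF(path, all = TRUE)
  purrr::map(out, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1] # greyscale written as-is
    matrix(as.numeric(m), nrow = nrow(m))
  })
}
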