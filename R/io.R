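# Plain-text serialization of the package's array objects. Complex data
# round-trip through CSV in long format (re/im columns) at full double
# precision; images round-trip through PNG (8- or 16-bit) or CSV.

#' Write / read snapshot frames as CSV
#'
#' Long format (`element, snapshot, re, im`) with the array geometry and
#' noise variance stored in `#`-prefixed header lines; lossless at full
#' double precision.
#'
#' @param frame A [snapshot_frame()].
#' @param path File path.
#' @return `read_snapshots()` returns a [snapshot_frame()];
#'   `write_snapshots()` returns `path` invisibly.
#' @export
write_snapshots <- function(frame, path) {
  stopifnot(inherits(frame, "snapshot_frame"))
  g <- frame$geometry
  hdr <- c(
    sprintf("# num_elements=%d", g$num_elements),
    sprintf("# num_subarrays=%d", g$num_subarrays),
    sprintf("# element_pitch=%s", format(g$element_pitch, digits = 17)),
    sprintf("# noise_variance=%s", format(frame$noise_variance, digits = 17))
  )
  X <- frame$data
  idx <- expand.grid(element = seq_len(nrow(X)), snapshot = seq_len(ncol(X)))
  df <- data.frame(idx,
                   re = format(Re(X[as.matrix(idx)]), digits = 17),
                   im = format(Im(X[as.matrix(idx)]), digits = 17))
  writeLines(hdr, path)
  suppressWarnings(write.table(df, path, append = TRUE, sep = ",",
                               row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' @rdname write_snapshots
#' @export
read_snapshots <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_val <- function(key) {
    m <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(m)) stop_domain(sprintf("missing header field %s", key))
    as.numeric(sub(paste0("^# ", key, "="), "", m[1]))
  }
  df <- read.csv(text = lines[!grepl("^#", lines)])
  M <- as.integer(get_val("num_elements"))
  T_ <- max(df$snapshot)
  X <- matrix(0i, M, T_)
  X[cbind(df$element, df$snapshot)] <- complex(real = df$re, imaginary = df$im)
  g <- array_geometry(M, as.integer(get_val("num_subarrays")),
                      get_val("element_pitch"))
  snapshot_frame(X, g, noise_variance = get_val("noise_variance"))
}

#' Write an image or phantom to PNG or CSV
#'
#' PNG output rescales to the image maximum and writes 16-bit grayscale;
#' CSV output preserves the raw values. [read_image()] returns a plain
#' numeric matrix (PNG values in `[0, 1]` times `max_value`).
#'
#' @param x A [phantom()] ([make_phantom()]), [recon_image()], or numeric
#'   matrix.
#' @param path Output path; format chosen by extension (`.png` or
#'   `.csv`).
#' @param max_value PNG read scale (default 1).
#' @return The path (write) or a numeric matrix (read).
#' @export
write_image <- function(x, path) {
  img <- if (inherits(x, "phantom")) x$truth_image
         else if (inherits(x, "recon_image")) x$pixels
         else as.matrix(x)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    peak <- max(img)
    scaled <- if (peak > 0) img / peak else img
    png::writePNG(scaled, path, dpi = NULL)
  } else if (ext == "csv") {
    write.table(format(img, digits = 17), path, sep = ",",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else stop_domain("unsupported image format: use .png or .csv")
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path, max_value = 1) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]  # grayscale from channel 1
    img * max_value
  } else if (ext == "csv") {
    as.matrix(read.csv(path, header = FALSE))
  } else stop_domain("unsupported image format: use .png or .csv")
}

#' Export a covariance estimate to CSV for audit
#'
#' Complex entries are written as `re` and `im` blocks stacked with a
#' `part` column, full double precision.
#'
#' @param R A [covariance_estimate()].
#' @param path Output CSV path.
#' @export
write_covariance <- function(R, path) {
  stopifnot(inherits(R, "covariance_estimate"))
  m <- R$matrix
  df <- rbind(
    data.frame(part = "re", format(as.data.frame(Re(m)), digits = 17)),
    data.frame(part = "im", format(as.data.frame(Im(m)), digits = 17))
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
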