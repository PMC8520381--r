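#' Define a uniform linear array and its sub-array decomposition
#'
#' An M-element uniform linear array, divided into `num_subarrays`
#' overlapping sub-arrays of length `M - num_subarrays + 1` shifted by one
#' element each — the standard spatial-smoothing decomposition.
#'
#' @param num_elements Integer `M >= 2`, number of array elements.
#' @param num_subarrays Integer `q` with `1 <= q <= M`; `q = 1` means no
#'   decomposition (the sub-array is the full array).
#' @param element_pitch Element spacing in wavelengths. The default 0.5
#'   (half-wavelength) avoids grating lobes over the full visible region.
#' @return An object of class `array_geometry` with fields `num_elements`,
#'   `num_subarrays`, `subarray_length` and `element_pitch`.
#' @examples
#' g <- array_geometry(16, num_subarrays = 4)
#' g$subarray_length  # 13
#' @export
array_geometry <- function(num_elements, num_subarrays = 1, element_pitch = 0.5) {
  num_elements <- as.integer(num_elements)
  num_subarrays <- as.integer(num_subarrays)
  if (is.na(num_elements) || num_elements < 2)
    stop_domain("`num_elements` (M) must be an integer >= 2")
  if (is.na(num_subarrays) || num_subarrays < 1 || num_subarrays > num_elements)
    stop_domain("`num_subarrays` must satisfy 1 <= q <= M")
  if (!is.numeric(element_pitch) || element_pitch <= 0)
    stop_domain("`element_pitch` must be a positive length in wavelengths")
  structure(
    list(
      num_elements = num_elements,
      num_subarrays = num_subarrays,
      subarray_length = num_elements - num_subarrays + 1L,
      element_pitch = element_pitch
    ),
    class = "array_geometry"
  )
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf(
    "Uniform linear array: M = %d elements, pitch = %g wavelengths\n",
    x$num_elements, x$element_pitch
  ))
  cat(sprintf(
    "Sub-array decomposition: q = %d sub-arrays of length l = %d\n",
    x$num_subarrays, x$subarray_length
  ))
  invisible(x)
}

#' Define a set of narrowband sources
#'
#' @param angles Arrival angles in radians, each strictly inside
#'   `(-pi/2, pi/2)` (measured from broadside).
#' @param amplitudes Complex amplitude per source (recycled); scales the
#'   source signal.
#' @return An object of class `source_set` with fields `angles`,
#'   `amplitudes`, `num_sources`.
#' @export
source_set <- function(angles = numeric(0), amplitudes = 1) {
  angles <- as.numeric(angles)
  if (length(angles) && any(abs(angles) >= pi / 2))
    stop_domain("source angles must lie strictly inside (-pi/2, pi/2)")
  amplitudes <- rep_len(as.complex(amplitudes), length(angles))
  structure(
    list(angles = angles, amplitudes = amplitudes, num_sources = length(angles)),
    class = "source_set"
  )
}

#' Narrowband steering vector of a uniform linear array
#'
#' Element-wise phase response `a(theta)[n] = exp(-i 2 pi d n sin(theta))`
#' for `n = 0, ..., length - 1`, with `d` the pitch in wavelengths. The
#' first entry is always 1 and all entries have unit modulus.
#'
#' @param geometry An [array_geometry()].
#' @param angle Arrival angle in radians, strictly inside `(-pi/2, pi/2)`.
#' @param length Number of elements to steer (defaults to the full array);
#'   pass `geometry$subarray_length` for sub-array steering.
#' @return Complex vector of the requested length.
#' @examples
#' g <- array_geometry(8)
#' steering_vector(g, 0, length = 4)  # four ones: broadside
#' @export
steering_vector <- function(geometry, angle, length = geometry$num_elements) {
  stopifnot(inherits(geometry, "array_geometry"))
  if (!is.finite(angle) || abs(angle) >= pi / 2)
    stop_domain("`angle` must lie strictly inside (-pi/2, pi/2)")
  length <- as.integer(length)
  if (length < 1 || length > geometry$num_elements)
    stop_domain("`length` must satisfy 1 <= length <= M")
  n <- seq_len(length) - 1
  exp(-1i * 2 * pi * geometry$element_pitch * n * sin(angle))
}

#' Construct a snapshot frame
#'
#' Container for `T` complex echo snapshots of an M-element array (columns
#' of `data`), the raw input to covariance estimation.
#'
#' @param data Complex matrix, M rows by T columns; all entries finite.
#' @param geometry The [array_geometry()] that produced the data (row count
#'   must equal `geometry$num_elements`).
#' @param noise_variance Per-element noise variance `sigma^2 >= 0` (the
#'   diagonal of the noise covariance).
#' @return An object of class `snapshot_frame`.
#' @export
snapshot_frame <- function(data, geometry, noise_variance = 0) {
  stopifnot(inherits(geometry, "array_geometry"))
  data <- as.matrix(data)
  storage.mode(data) <- "complex"
  if (nrow(data) != geometry$num_elements)
    stop_domain("snapshot rows must equal the geometry's element count")
  if (ncol(data) < 1) stop_domain("a snapshot frame needs at least one snapshot")
  if (!all(is.finite(Re(data))) || !all(is.finite(Im(data))))
    stop_domain("snapshot data must be finite")
  if (noise_variance < 0) stop_domain("`noise_variance` must be >= 0")
  structure(
    list(
      data = data,
      geometry = geometry,
      sample_count = ncol(data),
      noise_variance = noise_variance
    ),
    class = "snapshot_frame"
  )
}

#' Simulate narrowband echo snapshots
#'
#' Realizes the array signal model `x(t) = A s(t) + n(t)`: columns of `A`
#' are full-length steering vectors at the source angles, `s(t)` is a
#' circular complex Gaussian source signal and `n(t)` circular complex
#' Gaussian noise with covariance `sigma^2 I`. With `coherent = TRUE` all
#' sources share a single Gaussian process scaled by their amplitudes —
#' the fully coherent (multipath/artifact) case that motivates spatial
#' smoothing.
#'
#' @param geometry An [array_geometry()].
#' @param sources A [source_set()]; may be empty (noise-only frame).
#' @param n_snapshots Number of snapshots `T >= 1`.
#' @param signal_power Per-source signal variance (before the amplitude
#'   scaling); `>= 0`.
#' @param noise_variance Per-element noise variance `sigma^2 >= 0`.
#' @param seed Integer seed; the call is reproducible for a fixed seed and
#'   does not disturb the caller's RNG state. Default 0.
#' @param coherent Logical; if `TRUE` the sources are fully coherent.
#' @return A [snapshot_frame()]. With no sources and zero noise the frame
#'   is all zeros (documented degenerate case, not an error).
#' @export
simulate_snapshots <- function(geometry, sources, n_snapshots,
                               signal_power = 1, noise_variance = 0,
                               seed = 0, coherent = FALSE) {
  stopifnot(inherits(geometry, "array_geometry"), inherits(sources, "source_set"))
  n_snapshots <- as.integer(n_snapshots)
  if (n_snapshots < 1) stop_domain("`n_snapshots` must be >= 1")
  if (signal_power < 0 || noise_variance < 0)
    stop_domain("variances must be >= 0")
  M <- geometry$num_elements
  K <- sources$num_sources
  X <- withr::with_seed(seed, {
    S <- if (K == 0) {
      matrix(0i, 0, n_snapshots)
    } else if (coherent) {
      common <- rcnorm(n_snapshots, var = signal_power)
      sources$amplitudes %o% common
    } else {
      matrix(rcnorm(K * n_snapshots, var = signal_power), K, n_snapshots) *
        sources$amplitudes
    }
    A <- if (K == 0) matrix(0i, M, 0) else
      vapply(sources$angles, steering_vector, complex(M), geometry = geometry)
    N <- matrix(rcnorm(M * n_snapshots, var = noise_variance), M, n_snapshots)
    A %*% S + N
  })
  snapshot_frame(X, geometry, noise_variance = noise_variance)
}

#' Generate a synthetic ground-truth phantom
#'
#' Deterministic (for a fixed seed) reflectivity maps used as ground truth
#' for the reconstruction metrics:
#' * `"points"` — isolated unit scatterers on an empty background;
#' * `"cyst"` — an anechoic disc (zero interior) surrounded by positive
#'   speckle;
#' * `"pleura_blines"` — a bright horizontal pleural line with vertical
#'   comet-tail (B-line) streaks below it, emulating the reverberation
#'   artifacts of interstitial lung disease.
#'
#' @param kind One of `"points"`, `"cyst"`, `"pleura_blines"`.
#' @param size Image size `c(rows, cols)`, each `>= 8`.
#' @param seed Integer seed (default 0).
#' @param n_points Number of scatterers for `kind = "points"`.
#' @param radius Disc radius in pixels for `kind = "cyst"` (default a
#'   quarter of the smaller dimension).
#' @param n_blines Number of B-line streaks for `kind = "pleura_blines"`.
#' @return An object of class `phantom` with fields `truth_image`
#'   (nonnegative matrix), `scatterers` (data frame of row/col/amplitude)
#'   and `kind`.
#' @export
make_phantom <- function(kind = c("points", "cyst", "pleura_blines"),
                         size = c(32L, 32L), seed = 0,
                         n_points = 2L, radius = NULL, n_blines = 4L) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (length(size) != 2 || any(size < 8))
    stop_domain("`size` must be two integers, each >= 8")
  img <- matrix(0, size[1], size[2])
  scat <- data.frame(row = integer(0), col = integer(0), amplitude = numeric(0))
  withr::with_seed(seed, {
    if (kind == "points") {
      idx <- sample.int(size[1] * size[2], n_points)
      rr <- (idx - 1) %% size[1] + 1
      cc <- (idx - 1) %/% size[1] + 1
      img[cbind(rr, cc)] <- 1
      scat <- data.frame(row = rr, col = cc, amplitude = rep(1, n_points))
    } else if (kind == "cyst") {
      if (is.null(radius)) radius <- min(size) / 4
      ctr <- (size + 1) / 2
      speckle <- matrix(abs(rnorm(size[1] * size[2])), size[1], size[2])
      d2 <- outer(seq_len(size[1]), seq_len(size[2]),
                  function(r, c) (r - ctr[1])^2 + (c - ctr[2])^2)
      speckle[d2 <= radius^2] <- 0
      img <- speckle
    } else {
      pleura_row <- max(2L, round(size[1] / 3))
      img[pleura_row, ] <- 1
      cols <- sort(sample.int(size[2], min(n_blines, size[2])))
      depth <- pleura_row:size[1]
      decay <- exp(-(depth - pleura_row) / (0.6 * length(depth)))
      for (cc in cols) img[depth, cc] <- pmax(img[depth, cc], 0.8 * decay)
      scat <- data.frame(row = pleura_row, col = cols, amplitude = 0.8)
    }
  })
  structure(list(truth_image = img, scatterers = scat, kind = kind),
            class = "phantom")
}
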