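#' Construct a covariance estimate
#'
#' Hermitian covariance matrix with a provenance tag. Validation enforces
#' Hermitian symmetry to a relative tolerance of 1e-10; positive
#' semidefiniteness follows from construction for all estimates produced
#' by the package.
#'
#' @param matrix Complex Hermitian matrix.
#' @param kind One of `"sample"`, `"forward"`, `"backward"`, `"fb"`.
#' @param source_frame_id Optional provenance token.
#' @return An object of class `covariance_estimate`.
#' @export
covariance_estimate <- function(matrix, kind = c("sample", "forward", "backward", "fb"),
                                source_frame_id = NULL) {
  kind <- match.arg(kind)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "complex"
  if (nrow(matrix) != ncol(matrix)) stop_domain("covariance must be square")
  if (hermitian_error(matrix) > 1e-10)
    stop_domain("covariance must be Hermitian (relative tolerance 1e-10)")
  # enforce exact Hermitian symmetry so downstream solves stay clean
  matrix <- (matrix + ct(matrix)) / 2
  structure(
    list(matrix = matrix, kind = kind, size = nrow(matrix),
         source_frame_id = source_frame_id),
    class = "covariance_estimate"
  )
}

#' @export
print.covariance_estimate <- function(x, ...) {
  cat(sprintf("<covariance_estimate> kind = %s, size = %d x %d\n",
              x$kind, x$size, x$size))
  invisible(x)
}

#' Sample covariance of a snapshot frame
#'
#' The maximum-likelihood estimate `R = (1/T) sum_t x(t) x(t)^H` over the
#' frame's T snapshots: Hermitian, positive semidefinite, size M.
#'
#' @param frame A [snapshot_frame()].
#' @return A [covariance_estimate()] of kind `"sample"`.
#' @export
sample_covariance <- function(frame) {
  stopifnot(inherits(frame, "snapshot_frame"))
  X <- frame$data
  R <- (X %*% ct(X)) / ncol(X)
  covariance_estimate(R, kind = "sample")
}

# Average of the q overlapping l x l principal submatrices of R taken along
# the diagonal (l = M - q + 1). Shared by forward and backward smoothing.
.block_average <- function(R, q) {
  M <- nrow(R)
  l <- M - q + 1L
  out <- matrix(0i, l, l)
  for (i in seq_len(q)) {
    idx <- i:(i + l - 1L)
    out <- out + R[idx, idx]
  }
  out / q
}

.check_smooth_args <- function(R, q) {
  stopifnot(inherits(R, "covariance_estimate"))
  if (R$kind != "sample")
    stop_domain("smoothing expects a kind = \"sample\" covariance of the full array")
  q <- as.integer(q)
  if (q < 1 || q > R$size)
    stop_domain("`q` must satisfy 1 <= q <= M")
  q
}

#' Forward spatial smoothing
#'
#' Averages the covariance matrices of the `q` overlapping, unit-shift
#' sub-arrays of length `l = M - q + 1`: equivalently, the average of the
#' `q` principal `l x l` submatrices of the full covariance along its
#' diagonal. Smoothing decorrelates coherent echoes and restores the rank
#' of the signal subspace at the cost of aperture.
#'
#' @param R A [covariance_estimate()] of kind `"sample"`, size M.
#' @param q Number of sub-arrays, `1 <= q <= M`; `q = 1` returns `R`
#'   unchanged (as kind `"forward"`).
#' @return A [covariance_estimate()] of kind `"forward"`, size
#'   `M - q + 1`.
#' @export
forward_smooth <- function(R, q) {
  q <- .check_smooth_args(R, q)
  covariance_estimate(.block_average(R$matrix, q), kind = "forward",
                      source_frame_id = R$source_frame_id)
}

#' Backward spatial smoothing
#'
#' Forward smoothing applied to the exchange-conjugated covariance
#' `J R* J` (J the anti-identity): the sub-array average seen by the
#' reversed, conjugated array.
#'
#' @inheritParams forward_smooth
#' @return A [covariance_estimate()] of kind `"backward"`.
#' @export
backward_smooth <- function(R, q) {
  q <- .check_smooth_args(R, q)
  M <- R$size
  J <- exchange_matrix(M)
  Rb <- J %*% Conj(R$matrix) %*% J
  covariance_estimate(.block_average(Rb, q), kind = "backward",
                      source_frame_id = R$source_frame_id)
}

#' Forward-backward spatial smoothing
#'
#' Arithmetic mean of the forward- and backward-smoothed covariances.
#' The result is persymmetric (`J R* J = R`), the structural signature of
#' forward-backward averaging, and positive semidefinite.
#'
#' @inheritParams forward_smooth
#' @return A [covariance_estimate()] of kind `"fb"`.
#' @export
fb_smooth <- function(R, q) {
  f <- forward_smooth(R, q)
  b <- backward_smooth(R, q)
  covariance_estimate((f$matrix + b$matrix) / 2, kind = "fb",
                      source_frame_id = R$source_frame_id)
}

#' Minimum-variance (Capon) beamformer weights
#'
#' Solves the distortionless minimum-variance problem on the (smoothed)
#' covariance: `w = (R + eps I)^{-1} a / (a^H (R + eps I)^{-1} a)`, so that
#' `w^H a = 1` exactly. Diagonal loading `eps` stabilizes the solve; the
#' solve uses a factorization (never an explicit inverse) and reports
#' singularity instead of regularizing beyond the stated loading.
#'
#' @param R A [covariance_estimate()] (any kind) of size m.
#' @param a Complex steering vector of length m.
#' @param loading Diagonal loading `eps >= 0`, in absolute units of the
#'   covariance. A common choice is `delta * trace(R) / m`.
#' @return An object of class `beamformer_weights` with fields `weights`,
#'   `loading_used`, `method = "mvdr_sdss"`.
#' @examples
#' R <- covariance_estimate(diag(c(1, 4)), kind = "fb")
#' mvdr_weights(R, c(1, 1))$weights  # 0.8, 0.2
#' @export
mvdr_weights <- function(R, a, loading = 0) {
  stopifnot(inherits(R, "covariance_estimate"))
  a <- as.complex(a)
  if (length(a) != R$size) stop_domain("steering vector length must match R")
  if (loading < 0) stop_domain("`loading` must be >= 0")
  Rl <- R$matrix + diag(loading, R$size)
  u <- tryCatch(
    solve(Rl, a),
    error = function(e) stop_domain(
      "loaded covariance is numerically singular; increase `loading`")
  )
  denom <- sum(Conj(a) * u)
  if (Mod(denom) < .Machine$double.eps * R$size)
    stop_domain("loaded covariance is numerically singular; increase `loading`")
  w <- u / denom
  structure(
    list(weights = w, loading_used = loading, method = "mvdr_sdss"),
    class = "beamformer_weights"
  )
}

#' Delay-and-sum weights
#'
#' Fixed weights `a / (a^H a)`: align phases and average. Equals the
#' minimum-variance solution when the covariance is a scaled identity.
#'
#' @param a Complex steering vector.
#' @return A `beamformer_weights` object with `method = "das"`.
#' @export
das_weights <- function(a) {
  a <- as.complex(a)
  structure(
    list(weights = a / sum(Mod(a)^2), loading_used = 0, method = "das"),
    class = "beamformer_weights"
  )
}

#' Construct a reconstructed image
#'
#' @param pixels Nonnegative numeric matrix or vector (envelope-detected
#'   intensities; for a direction scan, one value per look angle).
#' @param method Reconstruction method tag.
#' @param angles Optional look angles (radians) for direction scans.
#' @param dynamic_range_db Display dynamic range used if log-compressed.
#' @param compressed Logical; whether `pixels` are already log-compressed
#'   (in dB below peak, stored as nonnegative `dynamic_range_db + dB`).
#' @return An object of class `recon_image`.
#' @export
recon_image <- function(pixels, method = "das", angles = NULL,
                        dynamic_range_db = 60, compressed = FALSE) {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop_domain("image pixels must be finite and nonnegative")
  structure(
    list(pixels = pixels, method = method, angles = angles,
         dynamic_range_db = dynamic_range_db, compressed = compressed),
    class = "recon_image"
  )
}

#' Beamform a snapshot frame over a scan grid of directions
#'
#' For each look angle the output power is `w^H R w` with method-specific
#' weights and covariance: delay-and-sum (`"das"`) uses fixed full-array
#' weights `a/M` on the sample covariance (no inversion); `"mvdr_sdss"`
#' uses Capon weights on the forward-backward smoothed sub-array
#' covariance with diagonal loading `eps = delta * trace(R_s) / l`.
#' The envelope (square root of power) is returned, optionally
#' log-compressed to `dynamic_range_db`.
#'
#' @param frame A [snapshot_frame()].
#' @param method `"das"` or `"mvdr_sdss"`.
#' @param angles Look angles in radians (default: 181 angles over
#'   \eqn{\pm\pi/3}).
#' @param loading_delta Relative diagonal loading `delta` (default 0.01);
#'   `eps = delta * trace(R_s)/l`.
#' @param compress Logical; apply log compression for display.
#' @param dynamic_range_db Dynamic range of the compressed display (dB).
#' @return A [recon_image()] with one pixel per look angle. An all-zero
#'   frame yields an all-zero image for every method.
#' @export
beamform_image <- function(frame, method = c("das", "mvdr_sdss"),
                           angles = NULL, loading_delta = 0.01,
                           compress = FALSE, dynamic_range_db = 60) {
  stopifnot(inherits(frame, "snapshot_frame"))
  method <- match.arg(method)
  geometry <- frame$geometry
  if (is.null(angles))
    angles <- seq(-pi / 3, pi / 3, length.out = 181)
  if (!length(angles)) stop_domain("scan grid must be nonempty")
  Rhat <- sample_covariance(frame)
  power <- if (sum(Mod(diag(Rhat$matrix))) == 0) {
    rep(0, length(angles))  # silent frame: zero image by definition
  } else if (method == "das") {
    M <- geometry$num_elements
    vapply(angles, function(th) {
      w <- das_weights(steering_vector(geometry, th))$weights
      max(Re(sum(Conj(w) * (Rhat$matrix %*% w))), 0)
    }, numeric(1))
  } else {
    Rs <- fb_smooth(Rhat, geometry$num_subarrays)
    l <- geometry$subarray_length
    eps <- loading_delta * Re(sum(diag(Rs$matrix))) / l
    vapply(angles, function(th) {
      a <- steering_vector(geometry, th, length = l)
      w <- mvdr_weights(Rs, a, loading = eps)$weights
      max(Re(sum(Conj(w) * (Rs$matrix %*% w))), 0)
    }, numeric(1))
  }
  env <- sqrt(power)
  if (compress) {
    peak <- max(env)
    db <- if (peak > 0) 20 * log10(pmax(env / peak, 10^(-dynamic_range_db / 20)))
          else rep(-dynamic_range_db, length(env))
    env <- db + dynamic_range_db  # nonnegative display scale
  }
  recon_image(matrix(env, nrow = 1), method = method, angles = angles,
              dynamic_range_db = dynamic_range_db, compressed = compress)
}

#' Measure the -3 dB mainlobe width of a direction scan
#'
#' Finds the global peak of the envelope and the half-power
#' (`peak/sqrt(2)`, i.e. -3 dB in power) crossings on either side by
#' linear interpolation.
#'
#' @param image A [recon_image()] from a direction scan (uncompressed).
#' @return Width in radians, or `NA` if a crossing is not bracketed.
#' @export
beam_width_3db <- function(image) {
  stopifnot(inherits(image, "recon_image"))
  if (isTRUE(image$compressed))
    stop_domain("measure widths on the uncompressed envelope")
  env <- as.numeric(image$pixels)
  th <- image$angles
  if (is.null(th) || length(th) != length(env))
    stop_domain("image must carry its scan angles")
  ipk <- which.max(env)
  half <- env[ipk] / sqrt(2)
  cross <- function(idx) {
    for (k in seq_along(idx)[-1]) {
      i1 <- idx[k - 1]; i2 <- idx[k]
      if ((env[i1] - half) * (env[i2] - half) <= 0 && env[i1] != env[i2]) {
        f <- (half - env[i1]) / (env[i2] - env[i1])
        return(th[i1] + f * (th[i2] - th[i1]))
      }
    }
    NA_real_
  }
  left <- cross(ipk:1)
  right <- cross(ipk:length(env))
  if (is.na(left) || is.na(right)) return(NA_real_)
  abs(right - left)
}

#' Simplified Wiener post-filter
#'
#' Pixelwise gain `S/(S + N)` with the pixel value taken as the local
#' signal-power estimate `S` and `noise_power` as `N`; gain lies in
#' `[0, 1]`. A generic comparator, not a reproduction of any published
#' feature-space-fusion pipeline.
#'
#' @param image A [recon_image()] or nonnegative numeric array.
#' @param noise_power Scalar noise power `N >= 0`; `N = 0` is the identity
#'   transform.
#' @return A [recon_image()] with method `"wiener_post"`.
#' @export
wiener_postfilter <- function(image, noise_power) {
  if (noise_power < 0) stop_domain("`noise_power` must be >= 0")
  px <- if (inherits(image, "recon_image")) image$pixels else as.matrix(image)
  if (any(px < 0)) stop_domain("input image must be nonnegative")
  gain <- ifelse(px + noise_power > 0, px / (px + noise_power), 1)
  if (noise_power == 0) gain[] <- 1
  out <- px * gain
  recon_image(out, method = "wiener_post",
              angles = if (inherits(image, "recon_image")) image$angles)
}

#' Simplified SNR post-filter
#'
#' Pixelwise gain `snr/(1 + snr)` from a per-pixel signal-to-noise map;
#' gain lies in `[0, 1]`. A generic comparator (see
#' [wiener_postfilter()]).
#'
#' @param image A [recon_image()] or nonnegative numeric array.
#' @param snr_map Nonnegative SNR per pixel (scalar or array conformable
#'   with the image).
#' @return A [recon_image()] with method `"snr_post"`.
#' @export
snr_postfilter <- function(image, snr_map) {
  px <- if (inherits(image, "recon_image")) image$pixels else as.matrix(image)
  if (any(px < 0)) stop_domain("input image must be nonnegative")
  snr <- px * 0 + snr_map  # broadcast scalar or conformable array
  if (any(snr < 0)) stop_domain("`snr_map` must be nonnegative")
  out <- px * snr / (1 + snr)
  recon_image(out, method = "snr_post",
              angles = if (inherits(image, "recon_image")) image$angles)
}
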