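# Independent brute-force oracles, deliberately written with explicit
# loops and kept separate from the package's vectorized code paths.

random_hpsd <- function(m, seed) {
  withr::with_seed(seed, {
    A <- matrix(complex(real = rnorm(m * m), imaginary = rnorm(m * m)), m, m)
    (A %*% Conj(t(A))) / m
  })
}

oracle_forward <- function(R, q) {
  M <- nrow(R)
  l <- M - q + 1
  acc <- matrix(0i, l, l)
  for (i in 1:q)
    for (r in 1:l)
      for (c in 1:l)
        acc[r, c] <- acc[r, c] + R[i + r - 1, i + c - 1]
  acc / q
}

# Backward smoothing via the per-block identity: average of
# J_l Conj(B_i) J_l over the forward blocks B_i (a different route than
# the package's exchange-conjugate-then-average).
oracle_backward <- function(R, q) {
  M <- nrow(R)
  l <- M - q + 1
  Jl <- matrix(0, l, l); Jl[cbind(l:1, 1:l)] <- 1
  acc <- matrix(0i, l, l)
  for (i in 1:q) {
    B <- R[i:(i + l - 1), i:(i + l - 1), drop = FALSE]
    acc <- acc + Jl %*% Conj(B) %*% Jl
  }
  acc / q
}

max_abs <- function(x) max(Mod(x))

expect_cplx_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max_abs(a - b), tol)
}
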