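# Internal numeric helpers shared across modules.

# Round half away from zero (the convention of clinical tables, unlike
# base round()'s round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Exchange (anti-identity) matrix J of size n.
exchange_matrix <- function(n) {
  J <- matrix(0, n, n)
  J[cbind(n:1, 1:n)] <- 1
  J
}

# Hermitian transpose.
ct <- function(x) Conj(t(x))

# Relative Hermitian asymmetry ||A - A^H|| / ||A|| (Frobenius); 0 for the
# zero matrix.
hermitian_error <- function(A) {
  nrmA <- sqrt(sum(Mod(A)^2))
  if (nrmA == 0) return(0)
  sqrt(sum(Mod(A - ct(A))^2)) / nrmA
}

# Draw n iid circular complex Gaussian values with total variance `var`
# (variance var/2 in each of the real and imaginary parts).
rcnorm <- function(n, var = 1) {
  sqrt(var / 2) * complex(real = rnorm(n), imaginary = rnorm(n))
}

stop_domain <- function(...) stop(..., call. = FALSE)
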