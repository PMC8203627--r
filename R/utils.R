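# internal numerical helpers

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Fisher r-to-z with clipping so degenerate (|r| = 1) inputs stay finite
.fisherZ <- function(r, eps = 1e-7) atanh(.clip(r, -1 + eps, 1 - eps))

.stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)

# Haar-ish uniform random rotation in SO(3) via QR of a Gaussian matrix
.randomRotation3 <- function() {
    M <- matrix(stats::rnorm(9L), 3L, 3L)
    qd <- qr(M)
    Q <- qr.Q(qd)
    Q <- Q %*% diag(sign(diag(qr.R(qd))))
    if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
    Q
}

# derive a stream seed from a base seed; kept below 2^31
.deriveSeed <- function(seed, k) {
    (as.integer(seed) + 1664525L * (as.integer(k) %% 1000L)) %% 2147483647L
}

.withSeed <- function(seed, code) {
    if (is.null(seed)) return(code)
    withr::with_seed(as.integer(seed), code)
}
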