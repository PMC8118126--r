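# Small 2D image primitives shared across the pipeline. All images are
# matrices indexed [row, col], 1-based; volumes are arrays [slice, row, col].

# Zero-padded 2D convolution, output same size as `m`. Kernels here are small
# (Gabor support <= 13x13) so a shift-and-add over kernel taps is fast enough
# and has no FFT wrap-around edge cases.
conv2_same <- function(m, k, pad_mode = c("zero", "replicate")) {
  pad_mode <- match.arg(pad_mode)
  nr <- nrow(m); nc <- ncol(m)
  kr <- nrow(k); kc <- ncol(k)
  # center tap (1-based); odd-sized kernels assumed
  cr <- (kr + 1L) %/% 2L
  cc <- (kc + 1L) %/% 2L
  if (pad_mode == "replicate") {
    ri <- clip(seq(2L - cr, nr + kr - cr), 1L, nr)
    ci <- clip(seq(2L - cc, nc + kc - cc), 1L, nc)
    pad <- m[ri, ci, drop = FALSE]
  } else {
    pad <- matrix(0, nr + kr - 1L, nc + kc - 1L)
    pad[cr:(cr + nr - 1L), cc:(cc + nc - 1L)] <- m
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      w <- k[i, j]
      if (w != 0) {
        # convolution flips the kernel relative to correlation
        out <- out + w * pad[(kr - i + 1L):(kr - i + nr), (kc - j + 1L):(kc - j + nc)]
      }
    }
  }
  out
}

# Gradient magnitude by central differences with replicated edges.
grad_mag <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up    <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  left  <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  sqrt(((down - up) / 2)^2 + ((right - left) / 2)^2)
}

# Bilinear sample of matrix `m` at fractional (r, c) positions; 0 outside.
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0;   fc <- c - c0
  val <- numeric(length(r))
  at <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  val <- at(r0, c0) * (1 - fr) * (1 - fc) +
    at(r0 + 1, c0) * fr * (1 - fc) +
    at(r0, c0 + 1) * (1 - fr) * fc +
    at(r0 + 1, c0 + 1) * fr * fc
  val
}

# Lower median: for even counts return the lower of the two middle values,
# which keeps the control-point vote an actual observed column (deterministic).
lower_median <- function(x) {
  x <- x[is.finite(x)]
  sort(x)[(length(x) + 1L) %/% 2L]
}

# Evaluate a polynomial with coefficients c(p0, p1, ...) at x (p0 + p1 x + ...).
polyval0 <- function(p, x) {
  y <- rep(0, length(x))
  for (k in rev(seq_along(p))) y <- y * x + p[k]
  y
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
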