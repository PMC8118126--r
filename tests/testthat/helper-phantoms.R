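# Shared fixtures, built in code. Phantoms are small so the suite stays fast.

small_spec <- function(...) phantom_spec(shape = c(6, 96, 96), ...)

septum_spec <- function(...) {
  phantom_spec(ventricles = ventricle_layout(4:7), ...)
}

truth_hemis <- function(ph) {
  structure(list(left = ph$truth$left, right = ph$truth$right,
                 frame = "native"),
            class = "hemisphere_pair")
}

# independent brute-force mean Hausdorff (double loop)
oracle_mean_hd <- function(A, B) {
  dmin <- function(P, Q) {
    vapply(seq_len(nrow(P)), function(i) {
      min(sqrt((P[i, 1] - Q[, 1])^2 + (P[i, 2] - Q[, 2])^2))
    }, numeric(1))
  }
  mean(c(dmin(A, B), dmin(B, A)))
}

# independent per-pixel LBP loop with the same circular sampling convention
oracle_lbp <- function(m, radius = 3, neighbors = 8) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  bil <- function(r, c) {
    r0 <- floor(r); c0 <- floor(c)
    fr <- r - r0; fc <- c - c0
    m[r0, c0] * (1 - fr) * (1 - fc) +
      (if (fr > 0) m[r0 + 1, c0] * fr * (1 - fc) else 0) +
      (if (fc > 0) m[r0, c0 + 1] * (1 - fr) * fc else 0) +
      (if (fr > 0 && fc > 0) m[r0 + 1, c0 + 1] * fr * fc else 0)
  }
  for (r in (radius + 1):(nr - radius)) {
    for (c in (radius + 1):(nc - radius)) {
      code <- 0
      for (k in 0:(neighbors - 1)) {
        a <- 2 * pi * k / neighbors
        dr <- -radius * sin(a); dc <- radius * cos(a)
        if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
        if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
        if (bil(r + dr, c + dc) >= m[r, c]) code <- code + 2^k
      }
      out[r, c] <- code
    }
  }
  out
}
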