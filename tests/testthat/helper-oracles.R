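# Independent brute-force oracles for the five scene metrics. These are
# deliberately naive (explicit padding, per-pixel loops over neighborhood
# copies) and share no code with the package implementation.

# Symmetric (half-sample) padding by r pixels on every side.
pad_symmetric <- function(m, r) {
  idx <- function(n) {
    i <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
    pmin(pmax(i, 1L), n)  # guards r > n, not exercised here
  }
  ri <- c(rev(seq_len(r)), seq_len(nrow(m)), nrow(m) + 1L - seq_len(r))
  ci <- c(rev(seq_len(r)), seq_len(ncol(m)), ncol(m) + 1L - seq_len(r))
  m[ri, ci, drop = FALSE]
}

# Replicate (edge-clamp) padding by r pixels on every side.
pad_replicate <- function(m, r) {
  ri <- pmin(pmax(seq_len(nrow(m) + 2L * r) - r, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m) + 2L * r) - r, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

oracle_contrast <- function(m, tail_fraction = 0.005) {
  v <- sort(as.vector(m), decreasing = TRUE)
  k <- ceiling(tail_fraction * length(v))
  i_max <- mean(v[seq_len(k)])
  i_min <- mean(rev(v)[seq_len(k)])
  list(contrast_pct = (i_max - i_min) / 2^16 * 100, i_max = i_max,
       i_min = i_min)
}

oracle_global_entropy <- function(m, bins = 256L) {
  counts <- table(factor(as.vector(m) %/% (65536L %/% bins),
                         levels = 0:(bins - 1L)))
  p <- counts[counts > 0] / length(m)
  as.numeric(-sum(p * log2(p)) / log2(bins))
}

oracle_local_entropy <- function(m, window = 9L, bins = 256L) {
  r <- window %/% 2L
  p <- pad_symmetric(m %/% (65536L %/% bins), r)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      nb <- as.vector(p[i:(i + 2L * r), j:(j + 2L * r)])
      pr <- table(nb) / length(nb)
      out[i, j] <- -sum(pr * log2(pr))
    }
  }
  out
}

oracle_local_range <- function(m, window = 3L) {
  r <- window %/% 2L
  p <- pad_replicate(m, r)
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      nb <- p[i:(i + 2L * r), j:(j + 2L * r)]
      out[i, j] <- max(nb) - min(nb)
    }
  }
  out
}

# Direct per-pixel Sobel correlation with replicate padding, squared
# magnitude, cutoff 4 * mean.
oracle_sobel_edges <- function(m) {
  u <- m / 65535
  p <- pad_replicate(u, 1L)
  ky <- matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, 3, byrow = TRUE) / 8
  kx <- t(ky)
  g <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      nb <- p[i:(i + 2L), j:(j + 2L)]
      g[i, j] <- sum(nb * kx)^2 + sum(nb * ky)^2
    }
  }
  g > 4 * mean(g)
}

random_test_image <- function(h, w, kind = c("noise", "smooth", "blocky")) {
  kind <- match.arg(kind)
  px <- switch(kind,
    noise = matrix(sample.int(65536L, h * w, replace = TRUE) - 1L, h, w),
    smooth = {
      base <- outer(seq_len(h), seq_len(w), function(a, b)
        32768 + 15000 * sin(a / 4) * cos(b / 5))
      matrix(as.integer(pmin(pmax(round(base +
        rnorm(h * w, sd = 500)), 0), 65535)), h, w)
    },
    blocky = {
      k <- matrix(sample.int(65536L, 16, replace = TRUE) - 1L, 4, 4)
      k[pmin((seq_len(h) - 1L) %/% max(1L, h %/% 4L) + 1L, 4L),
        pmin((seq_len(w) - 1L) %/% max(1L, w %/% 4L) + 1L, 4L)]
    })
  linear_gray_image(px)
}
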