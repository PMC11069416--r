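# Daubechies-5 discrete wavelet transform with periodic boundary handling.
#
# A self-contained pyramid DWT used only by the motion-artifact correction.
# Coefficients are the standard 10-tap Daubechies filters (orthonormal, so
# the inverse transform is the transpose and reconstruction is exact to
# machine precision).

DB5_LO <- c(0.0033357252854738, -0.012580751999082, -0.0062414902127983,
            0.0775714938400457, -0.0322448695846384, -0.242294887066382,
            0.1384281459013208, 0.7243085284377729, 0.6038292697971896,
            0.1601023979741929)
DB5_HI <- c(-0.1601023979741929, 0.6038292697971896, -0.7243085284377729,
            0.1384281459013208, 0.242294887066382, -0.0322448695846384,
            -0.0775714938400457, -0.0062414902127983, 0.012580751999082,
            0.0033357252854738)

# one analysis step: even-length x -> list(approx, detail), periodic wrap
dwt_step <- function(x) {
  n <- length(x)
  L <- length(DB5_LO)
  idx <- outer(seq(1, n, by = 2) - 1, seq_len(L) - 1, "+") %% n + 1
  xm <- matrix(x[idx], nrow = n / 2)
  list(a = as.numeric(xm %*% DB5_LO), d = as.numeric(xm %*% DB5_HI))
}

idwt_step <- function(a, d) {
  n <- 2 * length(a)
  L <- length(DB5_LO)
  x <- numeric(n)
  pos <- seq(1, n, by = 2) - 1
  for (k in seq_len(L)) {
    tgt <- (pos + k - 1) %% n + 1
    x[tgt] <- x[tgt] + a * DB5_LO[k] + d * DB5_HI[k]
  }
  x
}

# full decomposition of a length-2^J block
dwt_full <- function(x, max_level = Inf) {
  details <- list()
  a <- x
  lev <- 0
  while (length(a) >= 2 * length(DB5_LO) && length(a) %% 2 == 0 && lev < max_level) {
    s <- dwt_step(a)
    lev <- lev + 1
    details[[lev]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details)
}

idwt_full <- function(dec) {
  a <- dec$approx
  for (lev in rev(seq_along(dec$details)))
    a <- idwt_step(a, dec$details[[lev]])
  a
}

# despike one series: pad to a power of two with a smooth cosine bridge from
# the last to the first sample (keeps the periodic extension continuous, so
# boundary effects do not masquerade as artifacts), decompose, zero detail
# coefficients outside the per-level IQR fence, reconstruct
dwt_despike <- function(x, iqr_factor) {
  n <- length(x)
  n2 <- 2^ceiling(log2(n))
  mu <- mean(x)
  xd <- x - mu
  m <- n2 - n
  if (m > 0) {
    w <- (1 - cos(pi * seq_len(m) / (m + 1))) / 2
    xp <- c(xd, xd[n] + (xd[1] - xd[n]) * w)
  } else xp <- xd
  dec <- dwt_full(xp)
  for (lev in seq_along(dec$details)) {
    d <- dec$details[[lev]]
    # fence statistics over data-region coefficients only: the padded tail
    # is low-amplitude and would shrink the IQR, flagging legitimate signal
    m <- min(length(d), ceiling(n / 2^lev) + 1L)
    dd <- d[seq_len(m)]
    q <- quantile(dd, c(0.25, 0.75), names = FALSE)
    # quartiles from few coefficients are noisy and narrowband signal
    # concentrates there; widen the fence at such levels so only gross
    # outliers (step shifts reach tens of sigma) are removed
    widen <- if (m < 30) 4 else 1
    fence <- q + c(-1, 1) * widen * iqr_factor * (q[2] - q[1])
    out <- dd < fence[1] | dd > fence[2]
    d[seq_len(m)][out] <- 0
    dec$details[[lev]] <- d
  }
  idwt_full(dec)[seq_len(n)] + mu
}
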