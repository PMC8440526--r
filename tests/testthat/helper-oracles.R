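# Independent oracles used across the test suite. These re-derive expected
# values by brute force or closed form; they never call the package code
# paths they are checking.

# --- ratiometric recipe: naive direct 2-D convolution implementation -------

naive_gaussian_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  k <- outer((-r):r, (-r):r, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  k / sum(k)
}

naive_reflect <- function(i, n) {
  i <- ifelse(i < 1, 1 - i, i)
  ifelse(i > n, 2 * n + 1 - i, i)
}

# direct (non-separable) 2-D convolution with reflected boundary
naive_blur <- function(x, sigma) {
  r <- ceiling(3 * sigma)
  k <- naive_gaussian_kernel(sigma)
  n <- nrow(x); p <- ncol(x)
  out <- matrix(0, n, p)
  for (a in (-r):r) {
    ia <- naive_reflect(seq_len(n) + a, n)
    for (b in (-r):r) {
      jb <- naive_reflect(seq_len(p) + b, p)
      out <- out + k[a + r + 1, b + r + 1] * x[ia, jb]
    }
  }
  out
}

naive_ratiometric <- function(stack, sigma = 1, threshold) {
  bd <- naive_blur(stack$DxDm, sigma)
  ba <- naive_blur(stack$DxAm, sigma)
  bx <- naive_blur(stack$AxAm, sigma)
  mask <- (bx > threshold) * 1
  ratio <- matrix(0, nrow(mask), ncol(mask))
  ok <- mask == 1 & bd > 0
  ratio[ok] <- ba[ok] / bd[ok]
  list(ratio = ratio, mask = mask)
}

# --- kappa: exhaustive enumeration oracle ----------------------------------

oracle_sigma <- function(ch) {
  fp <- mean(ch == 1); fm <- mean(ch == -1)
  fcr <- fp + fm
  if (fcr == 0) 0 else (fp - fm)^2 / fcr
}

oracle_delta <- function(ch, g) {
  n <- length(ch)
  sig <- oracle_sigma(ch)
  s <- vapply(seq_len(n - g + 1),
              function(i) oracle_sigma(ch[i:(i + g - 1)]), 0)
  mean((s - sig)^2)
}

# all distinct arrangements of a charge multiset c(n_pos, n_neg, n_neu)
oracle_arrangements <- function(counts) {
  res <- list()
  rec <- function(prefix, remaining) {
    if (length(remaining) == 0) {
      res[[length(res) + 1]] <<- prefix
      return(invisible())
    }
    for (v in unique(remaining)) {
      idx <- which(remaining == v)[1]
      rec(c(prefix, v), remaining[-idx])
    }
  }
  rec(integer(0), sort(rep(c(1L, -1L, 0L), counts)))
  res
}

oracle_delta_max <- function(counts, g) {
  max(vapply(oracle_arrangements(counts), oracle_delta, 0, g = g))
}

oracle_kappa <- function(ch, blob_sizes = c(5, 6)) {
  counts <- c(sum(ch == 1), sum(ch == -1), sum(ch == 0))
  mean(vapply(blob_sizes,
              function(g) oracle_delta(ch, g) / oracle_delta_max(counts, g), 0))
}

charges_of <- function(seq) {
  res <- strsplit(seq, "")[[1]]
  ifelse(res %in% c("K", "R"), 1L, ifelse(res %in% c("D", "E"), -1L, 0L))
}

# --- chain energy: plain-R re-implementation -------------------------------

r_chain_energy <- function(coords, charges, hydropathy, lambda_eff,
                           debye = 10, lB = 7.1, eps0 = 0.2, sigma = 4.5) {
  n <- nrow(coords)
  lj <- el <- contacts <- 0
  rmin <- 2^(1 / 6) * sigma
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (r < rmin) {
        sr6 <- (sigma / r)^6
        lj <- lj + 4 * (sr6^2 - sr6) + 1
      }
      eps_ij <- eps0 * (hydropathy[i] + hydropathy[j]) / 2
      if (eps_ij > 0 && r < 2.5 * sigma) {
        if (r < rmin) {
          lj <- lj - eps_ij
        } else {
          sr6 <- (sigma / r)^6
          lj <- lj + 4 * eps_ij * (sr6^2 - sr6)
        }
      }
      if (charges[i] != 0 && charges[j] != 0) {
        el <- el + charges[i] * charges[j] * lB * exp(-r / debye) / r
      }
      if (r < 1.5 * sigma) contacts <- contacts + 1
    }
  }
  list(u_lj = lj, w_el = el, w_solv = -lambda_eff * contacts,
       total = lj + el - lambda_eff * contacts, n_contacts = contacts)
}

# --- synthetic spectra from donor/acceptor emission bases ------------------

# Gaussian emission bases on a 1-nm grid; mixing fraction follows the
# transfer efficiency E (donor loses, acceptor gains).
synthetic_spectrum <- function(e, wavelengths = 460:600) {
  donor <- exp(-(wavelengths - 476)^2 / (2 * 15^2))
  acceptor <- exp(-(wavelengths - 528)^2 / (2 * 14^2))
  tibble::tibble(
    wavelength_nm = wavelengths,
    intensity = (1 - e) * donor + e * acceptor
  )
}

# small synthetic stack with one bright disk cell
disk_stack <- function(n = 64, cx = 32, cy = 32, r = 18, ratio = 1.5,
                       i0 = 100) {
  xg <- matrix(rep(seq_len(n), each = n), n, n)
  yg <- matrix(rep(seq_len(n), times = n), n, n)
  inside <- (xg - cx)^2 + (yg - cy)^2 <= r^2
  mk <- function(v) {
    m <- matrix(0, n, n)
    m[inside] <- v
    m
  }
  cell_stack(DxDm = mk(i0), DxAm = mk(i0 * ratio), AxAm = mk(i0))
}
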