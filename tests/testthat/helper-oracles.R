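# Brute-force direct evaluations of the defining formulas, written as
# plain double loops independent of the package's vectorized paths.
# Border convention everywhere: edge-inclusive symmetric reflection.

refl <- function(i, n) {
  ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
}

brute_bilateral <- function(img, sigma_s, sigma_r, radius) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      num <- 0; den <- 0
      for (dy in -radius:radius) {
        for (dx in -radius:radius) {
          v <- img[refl(y + dy, h), refl(x + dx, w)]
          wt <- exp(-(dy^2 + dx^2) / (2 * sigma_s^2)) *
            exp(-(img[y, x] - v)^2 / (2 * sigma_r^2))
          num <- num + wt * v
          den <- den + wt
        }
      }
      out[y, x] <- num / den
    }
  }
  out
}

brute_nlm <- function(img, h_par, patch_radius, search_radius) {
  h <- nrow(img); w <- ncol(img)
  gv <- function(y, x) img[refl(y, h), refl(x, w)]
  out <- matrix(0, h, w)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      num <- 0; den <- 0
      for (dy in -search_radius:search_radius) {
        for (dx in -search_radius:search_radius) {
          d2 <- 0
          for (ty in -patch_radius:patch_radius) {
            for (tx in -patch_radius:patch_radius) {
              d2 <- d2 + (gv(y + ty, x + tx) - gv(y + dy + ty, x + dx + tx))^2
            }
          }
          wt <- exp(-d2 / h_par^2)
          num <- num + wt * gv(y + dy, x + dx)
          den <- den + wt
        }
      }
      out[y, x] <- num / den
    }
  }
  out
}

brute_guided <- function(p_img, guide, radius, eps, var_floor = 1e-12) {
  h <- nrow(p_img); w <- ncol(p_img)
  gi <- function(img, y, x) img[refl(y, h), refl(x, w)]
  a_map <- matrix(0, h, w); b_map <- matrix(0, h, w)
  n_win <- (2 * radius + 1)^2
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      si <- 0; sp <- 0; sii <- 0; sip <- 0
      for (dy in -radius:radius) {
        for (dx in -radius:radius) {
          iv <- gi(guide, y + dy, x + dx)
          pv <- gi(p_img, y + dy, x + dx)
          si <- si + iv; sp <- sp + pv
          sii <- sii + iv * iv; sip <- sip + iv * pv
        }
      }
      m_i <- si / n_win; m_p <- sp / n_win
      var_i <- sii / n_win - m_i^2
      cov_ip <- sip / n_win - m_i * m_p
      a_map[y, x] <- cov_ip / (var_i + eps + var_floor)
      b_map[y, x] <- m_p - a_map[y, x] * m_i
    }
  }
  out <- matrix(0, h, w)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      sa <- 0; sb <- 0
      for (dy in -radius:radius) {
        for (dx in -radius:radius) {
          sa <- sa + gi(a_map, y + dy, x + dx)
          sb <- sb + gi(b_map, y + dy, x + dx)
        }
      }
      out[y, x] <- (sa / n_win) * guide[y, x] + sb / n_win
    }
  }
  out
}

brute_ssim <- function(ref, img, max_val = 1, radius = 5, sigma = 1.5) {
  h <- nrow(ref); w <- ncol(ref)
  g <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- outer(g, g); k <- k / sum(k)
  c1 <- (0.01 * max_val)^2; c2 <- (0.03 * max_val)^2
  total <- 0
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      mx <- 0; my <- 0; sxx <- 0; syy <- 0; sxy <- 0
      for (dy in -radius:radius) {
        for (dx in -radius:radius) {
          wk <- k[dy + radius + 1, dx + radius + 1]
          a <- ref[refl(y + dy, h), refl(x + dx, w)]
          b <- img[refl(y + dy, h), refl(x + dx, w)]
          mx <- mx + wk * a; my <- my + wk * b
          sxx <- sxx + wk * a * a; syy <- syy + wk * b * b
          sxy <- sxy + wk * a * b
        }
      }
      sxx <- sxx - mx^2; syy <- syy - my^2; sxy <- sxy - mx * my
      total <- total + ((2 * mx * my + c1) * (2 * sxy + c2)) /
        ((mx^2 + my^2 + c1) * (sxx + syy + c2))
    }
  }
  total / (h * w)
}

brute_entropy <- function(img, bins = 256) {
  counts <- numeric(bins)
  for (v in as.vector(img)) {
    b <- min(floor(v * bins), bins - 1) + 1
    counts[b] <- counts[b] + 1
  }
  p <- counts / length(img)
  e <- 0
  for (pi in p) if (pi > 0) e <- e - pi * log2(pi)
  e
}

brute_std_dev <- function(img) {
  mu <- sum(img) / length(img)
  sqrt(sum((img - mu)^2) / length(img))
}

brute_avg_gradient <- function(img) {
  m <- nrow(img); n <- ncol(img)
  total <- 0
  for (s in seq_len(m - 1)) {
    for (t in seq_len(n - 1)) {
      dx <- img[s + 1, t] - img[s, t]
      dy <- img[s, t + 1] - img[s, t]
      total <- total + sqrt((dx^2 + dy^2) / 2)
    }
  }
  total / ((m - 1) * (n - 1))
}

brute_mse <- function(ref, img) {
  total <- 0
  for (i in seq_along(ref)) total <- total + (ref[i] - img[i])^2
  total / length(ref)
}

brute_cc <- function(ref, img) {
  n <- length(ref)
  mr <- sum(ref) / n; mf <- sum(img) / n
  num <- sum((ref - mr) * (img - mf))
  num / (n * brute_std_dev(ref) * brute_std_dev(img))
}

# Truncated-Gaussian spatial convolution (the large-sigma_r limit of the
# bilateral filter), same window and padding convention.
brute_gaussian_window_blur <- function(img, sigma_s, radius) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      num <- 0; den <- 0
      for (dy in -radius:radius) {
        for (dx in -radius:radius) {
          wt <- exp(-(dy^2 + dx^2) / (2 * sigma_s^2))
          num <- num + wt * img[refl(y + dy, h), refl(x + dx, w)]
          den <- den + wt
        }
      }
      out[y, x] <- num / den
    }
  }
  out
}

# Deterministic small test images
ramp_image <- function(h, w, step = 1 / (w - 1)) {
  matrix(rep(seq(0, by = step, length.out = w), each = h), h, w)
}

seeded_image <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

seeded_rgb <- function(h, w, seed) {
  set.seed(seed)
  array(runif(h * w * 3), dim = c(h, w, 3))
}
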