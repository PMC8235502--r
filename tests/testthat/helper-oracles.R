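# Brute-force oracles, deliberately naive: direct loops and exhaustive
# enumeration, independent of the package's vectorized / library-backed
# implementations.

# Disk membership by the package's documented rule: center within radius.
oracle_disk_fraction <- function(raster, r_px) {
  nr <- nrow(raster); nc <- ncol(raster)
  R <- floor(r_px + 1e-9)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      num <- 0L; den <- 0L
      for (di in -R:R) {
        for (dj in -R:R) {
          if (di^2 + dj^2 <= r_px^2 + 1e-9) {
            ii <- i + di; jj <- j + dj
            if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
              den <- den + 1L
              if (raster[ii, jj]) num <- num + 1L
            }
          }
        }
      }
      out[i, j] <- num / den
    }
  }
  out
}

# Naive set-based dilation: pixel true iff any true pixel within r_px.
oracle_dilate <- function(raster, r_px) {
  nr <- nrow(raster); nc <- ncol(raster)
  out <- matrix(FALSE, nr, nc)
  tr <- which(raster, arr.ind = TRUE)
  if (nrow(tr) == 0L) return(out)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      d2 <- (tr[, 1] - i)^2 + (tr[, 2] - j)^2
      out[i, j] <- any(d2 <= r_px^2 + 1e-9)
    }
  }
  out
}

oracle_erode <- function(raster, r_px) {
  !oracle_dilate(!raster, r_px)
}

oracle_close_open <- function(raster, r_px) {
  closed <- oracle_erode(oracle_dilate(raster, r_px), r_px)
  oracle_dilate(oracle_erode(closed, r_px), r_px)
}

# Exhaustive nearest-true-pixel distance for snapped points (px units).
oracle_point_mask_dist <- function(x_px, y_px, raster) {
  tr <- which(raster, arr.ind = TRUE)
  vapply(seq_along(x_px), function(i) {
    r0 <- round(y_px[i]) + 1
    c0 <- round(x_px[i]) + 1
    if (nrow(tr) == 0L) return(Inf)
    min(sqrt((tr[, 1] - r0)^2 + (tr[, 2] - c0)^2))
  }, numeric(1))
}

# Product-limit estimator by explicit risk-set bookkeeping.
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (k in seq_along(ut)) {
    n_risk <- sum(times >= ut[k])
    d <- sum(times == ut[k] & events == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = ut, surv = surv)
}

# Efron partial log-likelihood for a single numeric covariate.
oracle_cox_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    D <- which(times == t & events == 1)
    R <- which(times >= t)
    d <- length(D)
    sum_r <- sum(exp(beta * x[R]))
    sum_d <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_r - l / d * sum_d)
    }
  }
  ll
}

oracle_cox_beta <- function(times, events, x, lower = -5, upper = 5) {
  stats::optimize(function(b) -oracle_cox_loglik(b, times, events, x),
                  c(lower, upper), tol = 1e-9)$minimum
}

# Spearman with average ranks, from first principles.
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

random_mask <- function(nr, nc, p, cal, seed) {
  set.seed(seed)
  binary_mask(matrix(runif(nr * nc) < p, nr, nc), cal)
}
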