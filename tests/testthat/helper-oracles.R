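# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by the most literal method available (flood fill,
# exhaustive scans, hand-written likelihoods) so they share no code with the
# implementation they check.

# flood fill over 26-neighborhoods on a logical 3D mask
bf_components <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dim = dims)
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      co <- arrayInd(v, dims)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        nb <- co + c(dx, dy, dz)
        if (any(nb < 1) || any(nb > dims)) next
        nl <- (nb[3] - 1) * dims[1] * dims[2] + (nb[2] - 1) * dims[1] + nb[1]
        if (mask[nl] && lab[nl] == 0L) {
          lab[nl] <- cur
          queue <- c(queue, nl)
        }
      }
    }
  }
  lab
}

# O(n^2) concordance by explicit double loop
bf_cindex <- function(risk, time, event) {
  n <- length(risk)
  conc <- disc <- ties <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # identify the usable shorter-event member
      if (time[i] < time[j] && event[i] == 1) {
        s <- i; l <- j
      } else if (time[j] < time[i] && event[j] == 1) {
        s <- j; l <- i
      } else if (time[i] == time[j] && event[i] + event[j] == 1) {
        s <- if (event[i] == 1) i else j
        l <- if (event[i] == 1) j else i
      } else {
        next
      }
      if (risk[s] > risk[l]) conc <- conc + 1
      else if (risk[s] < risk[l]) disc <- disc + 1
      else ties <- ties + 1
    }
  }
  (conc + 0.5 * ties) / (conc + disc + ties)
}

# brute-force max pairwise distance over rows (cm from mm)
bf_dmax_cm <- function(pos_mm) {
  n <- nrow(pos_mm)
  if (n <= 1) return(0)
  best <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    best <- max(best, sqrt(sum((pos_mm[i, ] - pos_mm[j, ])^2)))
  }
  best / 10
}

# hand-written Cox partial log-likelihood (no ties assumed) for one
# covariate, maximized on a refined 1-D grid
bf_cox_coef <- function(x, time, event, lo = -5, hi = 5, tol = 1e-6) {
  ord <- order(time)
  xs <- x[ord]
  es <- event[ord]
  pll <- function(b) {
    s <- 0
    for (i in seq_along(xs)) {
      if (es[i] == 1) {
        s <- s + b * xs[i] - log(sum(exp(b * xs[i:length(xs)])))
      }
    }
    s
  }
  while (hi - lo > tol) {
    g <- seq(lo, hi, length.out = 41)
    v <- vapply(g, pll, numeric(1))
    k <- which.max(v)
    lo <- g[max(1, k - 1)]
    hi <- g[min(length(g), k + 1)]
  }
  (lo + hi) / 2
}

# exact two-sided Mann-Whitney p by complete enumeration of group labelings
bf_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  m <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(n, m)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mu <- m * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# a tiny two-sphere phantom used by several files
two_sphere_phantom <- function(noise = 0, seed = 1) {
  phantom_spec(
    grid_shape = c(40, 40, 30), spacing_mm = c(2, 2, 2),
    background_suv = 1, background_noise_sd = noise,
    lesions = list(
      list(center_mm = c(20, 20, 30), radii_mm = 8, peak_suv = 10),
      list(center_mm = c(58, 60, 30), radii_mm = 6, peak_suv = 6)
    ),
    seed = seed
  )
}

# simple random censored sample for survival tests
sim_surv <- function(n, seed, rate = 0.05, cens = c(5, 40)) {
  set.seed(seed)
  te <- rexp(n, rate)
  tc <- runif(n, cens[1], cens[2])
  tibble::tibble(time_months = pmin(te, tc), event = as.integer(te <= tc))
}
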