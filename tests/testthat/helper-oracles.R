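# Independent brute-force oracles used across the suite.  These deliberately
# avoid the code paths of the package implementation.

# direct O(n^2) DFT low-pass: standard length-255 transform, DC + W lowest
# positive frequencies + conjugate mirror kept, direct-summation inverse
oracle_dft_smooth <- function(h, W) {
  n <- 255L
  ks <- 0:(n - 1)
  Fk <- vapply(ks, function(k) {
    sum(h * exp(-2i * pi * k * (0:(n - 1)) / n))
  }, complex(1))
  keep <- ks %in% c(0L, 1:W, (n - W):(n - 1))
  Fk[!keep] <- 0
  vapply(0:(n - 1), function(x) {
    Re(sum(Fk * exp(2i * pi * x * ks / n))) / n
  }, numeric(1))
}

# normal-equation OLS for y = a x + b
oracle_ols <- function(x, y) {
  B <- cbind(x, 1)
  ab <- solve(t(B) %*% B, t(B) %*% y)
  c(slope = ab[1L], intercept = ab[2L])
}

# set-definition erosion/dilation with background outside the frame
oracle_erode <- function(mask, se) {
  r <- (nrow(se) - 1L) %/% 2L
  offs <- which(se == 1L, arr.ind = TRUE) - r - 1L
  U <- nrow(mask); V <- ncol(mask)
  out <- matrix(0L, U, V)
  for (i in seq_len(U)) for (j in seq_len(V)) {
    ok <- TRUE
    for (k in seq_len(nrow(offs))) {
      r2 <- i + offs[k, 1L]; c2 <- j + offs[k, 2L]
      if (r2 < 1L || r2 > U || c2 < 1L || c2 > V || mask[r2, c2] == 0L) {
        ok <- FALSE; break
      }
    }
    if (ok) out[i, j] <- 1L
  }
  out
}

oracle_dilate <- function(mask, se) {
  r <- (nrow(se) - 1L) %/% 2L
  offs <- which(se == 1L, arr.ind = TRUE) - r - 1L
  U <- nrow(mask); V <- ncol(mask)
  out <- matrix(0L, U, V)
  for (i in seq_len(U)) for (j in seq_len(V)) {
    hit <- FALSE
    for (k in seq_len(nrow(offs))) {
      r2 <- i - offs[k, 1L]; c2 <- j - offs[k, 2L]
      if (r2 >= 1L && r2 <= U && c2 >= 1L && c2 <= V && mask[r2, c2] == 1L) {
        hit <- TRUE; break
      }
    }
    if (hit) out[i, j] <- 1L
  }
  out
}

# fast shift-based erosion (vectorised oracle for larger masks)
oracle_erode_shift <- function(mask, se) {
  r <- (nrow(se) - 1L) %/% 2L
  offs <- which(se == 1L, arr.ind = TRUE) - r - 1L
  U <- nrow(mask); V <- ncol(mask)
  pad <- matrix(0L, U + 2L * r, V + 2L * r)
  pad[r + seq_len(U), r + seq_len(V)] <- mask
  out <- matrix(1L, U, V)
  for (k in seq_len(nrow(offs))) {
    out <- out & pad[r + seq_len(U) + offs[k, 1L], r + seq_len(V) + offs[k, 2L]]
  }
  out * 1L
}

oracle_dilate_shift <- function(mask, se) {
  r <- (nrow(se) - 1L) %/% 2L
  offs <- which(se == 1L, arr.ind = TRUE) - r - 1L
  U <- nrow(mask); V <- ncol(mask)
  pad <- matrix(0L, U + 2L * r, V + 2L * r)
  pad[r + seq_len(U), r + seq_len(V)] <- mask
  out <- matrix(0L, U, V)
  for (k in seq_len(nrow(offs))) {
    out <- out | pad[r + seq_len(U) - offs[k, 1L], r + seq_len(V) - offs[k, 2L]]
  }
  out * 1L
}

# L1 ball of radius n (composed diamond structuring element)
oracle_diamond <- function(radius) {
  d <- outer(abs(seq.int(-radius, radius)), abs(seq.int(-radius, radius)), "+")
  (d <= radius) * 1L
}

# 8-connected labelling by BFS in plain R
oracle_label8 <- function(mask) {
  U <- nrow(mask); V <- ncol(mask)
  lab <- matrix(0L, U, V)
  nxt <- 0L
  for (i in seq_len(U)) for (j in seq_len(V)) {
    if (mask[i, j] == 1L && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j)); lab[i, j] <- nxt
      while (length(queue) > 0L) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (dr in -1:1) for (dc in -1:1) {
          r2 <- p[1L] + dr; c2 <- p[2L] + dc
          if (r2 >= 1L && r2 <= U && c2 >= 1L && c2 <= V &&
              mask[r2, c2] == 1L && lab[r2, c2] == 0L) {
            lab[r2, c2] <- nxt
            queue[[length(queue) + 1L]] <- c(r2, c2)
          }
        }
      }
    }
  }
  lab
}

# exhaustive pair-enumeration clique energy (4-neighbour)
oracle_clique_energy <- function(mask, beta = 1) {
  U <- nrow(mask); V <- ncol(mask)
  e <- 0
  for (i in seq_len(U)) for (j in seq_len(V)) {
    if (j < V) e <- e + if (mask[i, j] == mask[i, j + 1L]) -beta else beta
    if (i < U) e <- e + if (mask[i, j] == mask[i + 1L, j]) -beta else beta
  }
  e
}

# random blob mask: union of a few dilated random seeds
random_blob_mask <- function(U, V, n_seeds = 6L, radius = 3L) {
  m <- matrix(0L, U, V)
  pts <- cbind(sample(U, n_seeds, replace = TRUE), sample(V, n_seeds, replace = TRUE))
  d <- oracle_diamond(radius)
  r <- radius
  for (k in seq_len(n_seeds)) {
    for (dr in -r:r) for (dc in -r:r) {
      if (abs(dr) + abs(dc) <= r) {
        i <- pts[k, 1L] + dr; j <- pts[k, 2L] + dc
        if (i >= 1L && i <= U && j >= 1L && j <= V) m[i, j] <- 1L
      }
    }
  }
  m
}

# analytic circle contour
circle_contour <- function(radius, centre = c(100, 100), n = 720L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(centre[1L] + radius * sin(th), centre[2L] + radius * cos(th))
}
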