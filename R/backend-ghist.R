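# Built-in "ghist" descriptor backend: multi-scale difference-of-Gaussians
# keypoints, each encoded as a 4x4 grid of 8-bin gradient-orientation
# histograms (128-d), unit-normalised, clipped at 0.2, renormalised and
# quantised to 8 bits. Deterministic by construction; no random state.

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur with reflected boundaries
gaussian_blur <- function(m, sigma) {
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  reflect <- function(idx, n) {
    idx <- abs(idx - 1L) + 1L              # reflect below 1
    over <- idx > n
    idx[over] <- 2L * n - idx[over]        # reflect above n
    pmin(pmax(idx, 1L), n)
  }
  conv_rows <- function(x) {
    n <- nrow(x)
    acc <- matrix(0, n, ncol(x))
    for (t in seq_along(k)) {
      acc <- acc + k[t] * x[reflect(seq_len(n) + (t - r - 1L), n), , drop = FALSE]
    }
    acc
  }
  t(conv_rows(t(conv_rows(m))))
}

# strict 3x3 local maxima of a response matrix above a threshold,
# excluding a border margin; returns cbind(row, col)
local_maxima <- function(A, thresh, margin) {
  n <- nrow(A); m <- ncol(A)
  if (n < 2L * margin + 3L || m < 2L * margin + 3L) {
    return(matrix(integer(0), 0L, 2L))
  }
  ri <- (margin + 1L):(n - margin)
  ci <- (margin + 1L):(m - margin)
  C <- A[ri, ci, drop = FALSE]
  ok <- C > thresh
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    ok <- ok & (C > A[ri + dr, ci + dc, drop = FALSE])
  }
  w <- which(ok, arr.ind = TRUE)
  if (nrow(w) == 0L) return(matrix(integer(0), 0L, 2L))
  cbind(w[, 1L] + margin, w[, 2L] + margin)
}

# vectorised bilinear sampling of matrix M at real-valued (row, col) positions
bilinear_sample <- function(M, r, c) {
  n <- nrow(M); m <- ncol(M)
  r <- pmin(pmax(r, 1), n); c <- pmin(pmax(c, 1), m)
  r0 <- pmin(floor(r), n - 1L); c0 <- pmin(floor(c), m - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * n + r0
  M[i00] * (1 - fr) * (1 - fc) + M[i00 + 1] * fr * (1 - fc) +
    M[i00 + n] * (1 - fr) * fc + M[i00 + n + 1] * fr * fc
}

ghist_extract <- function(pixels, contrast_thresh = 0.015, max_keypoints = 400L) {
  img <- pixels / 255
  sigmas <- 1.6 * 2^((0:4) / 2)
  blurred <- lapply(sigmas, function(s) gaussian_blur(img, s))
  spacing <- sigmas[1:4] / 1.6
  margins <- as.integer(ceiling(7.5 * spacing + 2))

  kp <- NULL
  for (lev in 1:4) {
    D <- abs(blurred[[lev + 1L]] - blurred[[lev]])
    pts <- local_maxima(D, contrast_thresh, margins[lev])
    if (nrow(pts)) {
      kp <- rbind(kp, cbind(pts, lev, D[pts]))
    }
  }
  if (is.null(kp) || nrow(kp) == 0L) {
    return(list(descriptors = matrix(numeric(0), 0L, 128L),
                keypoints = matrix(numeric(0), 0L, 3L)))
  }
  # strongest responses first; deterministic tie-break by level, row, col
  ord <- order(-kp[, 4L], kp[, 3L], kp[, 1L], kp[, 2L])
  kp <- kp[ord, , drop = FALSE]
  if (nrow(kp) > max_keypoints) kp <- kp[seq_len(max_keypoints), , drop = FALSE]

  # fixed 16x16 sample lattice per keypoint, 4x4 cells of 4x4 samples
  rel <- (1:16) - 8.5
  dyv <- rep(rel, times = 16)
  dxv <- rep(rel, each = 16)
  cell <- (rep(ceiling((1:16) / 4), each = 16) - 1L) * 4L +
    rep(ceiling((1:16) / 4), times = 16)          # 1..16, column-cell major
  Cmat <- outer(cell, 1:16, `==`) * 1              # 256 x 16 indicator

  desc_all <- vector("list", 4L)
  kp_all <- vector("list", 4L)
  for (lev in 1:4) {
    sel <- kp[, 3L] == lev
    if (!any(sel)) next
    pts <- kp[sel, , drop = FALSE]
    G <- blurred[[lev]]
    n <- nrow(G); m <- ncol(G)
    gx <- matrix(0, n, m); gy <- matrix(0, n, m)
    gx[, 2:(m - 1)] <- (G[, 3:m] - G[, 1:(m - 2)]) / 2
    gy[2:(n - 1), ] <- (G[3:n, ] - G[1:(n - 2), ]) / 2

    sp <- spacing[lev]
    K <- nrow(pts)
    R <- pts[, 1L] %o% rep(1, 256) + rep(1, K) %o% (dyv * sp)
    C <- pts[, 2L] %o% rep(1, 256) + rep(1, K) %o% (dxv * sp)
    sgx <- matrix(bilinear_sample(gx, R, C), K, 256L)
    sgy <- matrix(bilinear_sample(gy, R, C), K, 256L)
    mag <- sqrt(sgx^2 + sgy^2)
    wts <- exp(-(dxv^2 + dyv^2) / (2 * 8^2))       # spatial Gaussian window
    mag <- mag * rep(wts, each = K)
    ori <- atan2(sgy, sgx) %% (2 * pi)
    bin <- floor(ori / (pi / 4))
    bin[bin > 7] <- 7

    desc <- matrix(0, K, 128L)
    for (b in 0:7) {
      desc[, (0:15) * 8L + b + 1L] <- (mag * (bin == b)) %*% Cmat
    }
    nrm <- sqrt(rowSums(desc^2))
    keep <- nrm > 1e-12
    desc <- desc[keep, , drop = FALSE] / nrm[keep]
    desc[desc > 0.2] <- 0.2
    desc <- desc / sqrt(rowSums(desc^2))
    desc <- pmin(floor(desc * 512 + 0.5), 255)
    desc_all[[lev]] <- desc
    kp_all[[lev]] <- cbind(x = pts[keep, 2L], y = pts[keep, 1L],
                           scale = rep(sigmas[lev], sum(keep)))
  }
  list(descriptors = do.call(rbind, c(desc_all[!vapply(desc_all, is.null, logical(1))],
                                      list(matrix(numeric(0), 0L, 128L)))),
       keypoints = do.call(rbind, c(kp_all[!vapply(kp_all, is.null, logical(1))],
                                    list(matrix(numeric(0), 0L, 3L)))))
}

register_default_backends <- function() {
  register_descriptor_backend("ghist", list(
    version = "1.0.0",
    extract = ghist_extract
  ))
}
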