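# Internal image/array helpers shared across modules.

# Centred moving average along the columns of a matrix, window k (odd),
# renormalized at the edges. Cumulative sums keep it fully vectorized; for
# window sums of order 1e3 against running totals of order 1e9 the
# cancellation error stays below 1e-9 relative.
.box_filter_cols <- function(m, k) {
  if (k <= 1L) return(m)
  n <- nrow(m); nc <- ncol(m)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(as.numeric(m))
  if (nc > 1L) {
    off <- cs[n * seq_len(nc - 1L)]
    cs <- matrix(cs, n, nc)
    cs[, -1L] <- cs[, -1L, drop = FALSE] -
      matrix(off, n, nc - 1L, byrow = TRUE)
  } else {
    cs <- matrix(cs, n, 1L)
  }
  hi <- pmin(seq_len(n) + h, n)
  lo <- seq_len(n) - h - 1L
  out <- cs[hi, , drop = FALSE]
  pos <- lo >= 1L
  out[pos, ] <- out[pos, , drop = FALSE] - cs[lo[pos], , drop = FALSE]
  out / (hi - pmax(lo, 0L))
}

# Centred moving average along the rows of a matrix (window k, odd), edge
# columns renormalized; operates without transposing.
.box_filter_rows <- function(mat, k) {
  if (k <= 1L) return(mat)
  h <- (k - 1L) %/% 2L
  n <- ncol(mat)
  S <- mat
  for (o in seq_len(h)) {
    S[, (1 + o):n] <- S[, (1 + o):n] + mat[, 1:(n - o), drop = FALSE]
    S[, 1:(n - o)] <- S[, 1:(n - o)] + mat[, (1 + o):n, drop = FALSE]
  }
  S <- S / k
  for (j in seq_len(min(h, n))) {
    cnt <- min(j + h, n) - max(j - h, 1L) + 1L
    S[, j] <- S[, j] * (k / cnt)
    jr <- n - j + 1L
    cnt <- min(jr + h, n) - max(jr - h, 1L) + 1L
    S[, jr] <- S[, jr] * (k / cnt)
  }
  S
}

# Normalized (edge-renormalized) box smoothing of a rows x cols x frames
# array, separable along the three axes.
box_smooth_3d <- function(arr, kernel = c(5, 5, 3)) {
  d <- dim(arr)
  stopifnot(length(d) == 3, length(kernel) == 3)
  # along rows
  out <- .box_filter_cols(matrix(arr, d[1], d[2] * d[3]), kernel[1])
  # along cols
  out <- array(out, d)
  out <- aperm(out, c(2, 1, 3))
  out <- .box_filter_cols(matrix(out, d[2], d[1] * d[3]), kernel[2])
  out <- aperm(array(out, d[c(2, 1, 3)]), c(2, 1, 3))
  # along frames
  dim(out) <- c(d[1] * d[2], d[3])
  out <- .box_filter_rows(out, kernel[3])
  array(out, d)
}

# Otsu threshold of a numeric vector (maximizes between-class variance over a
# histogram). Returns a value such that foreground is v > threshold.
otsu_threshold <- function(v, n_bins = 256L) {
  v <- v[is.finite(v)]
  if (!length(v)) stop("no finite values to threshold")
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[n_bins]
  between <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# Disc-shaped structuring element of a given pixel radius.
disc_kernel <- function(radius_px) {
  radius_px <- max(1L, as.integer(round(radius_px)))
  EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
}

# Largest connected foreground component of a logical matrix (8-connectivity).
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  if (max(lab) == 0) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

# Connected components among active voxels of a 3D array under face (6-neighbour)
# or full (26-neighbour) adjacency. `idx` holds sorted 1-based linear indices;
# returns an integer membership vector parallel to `idx`.
label_components_3d <- function(idx, dims, connectivity = c("face", "full")) {
  connectivity <- match.arg(connectivity)
  n <- length(idx)
  if (n == 0L) return(integer(0))
  ar <- arrayInd(idx, dims)
  d1 <- dims[1]; d2 <- dims[2]; d3 <- dims[3]
  if (connectivity == "face") {
    steps <- list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  } else {
    steps <- list()
    for (dr in -1:1) for (dc in -1:1) for (dt in -1:1) {
      v <- c(dr, dc, dt)
      # keep one of each +/- pair
      if (any(v != 0) && (dt > 0 || (dt == 0 && (dc > 0 || (dc == 0 && dr > 0))))) {
        steps[[length(steps) + 1L]] <- as.integer(v)
      }
    }
  }
  from <- integer(0); to <- integer(0)
  for (s in steps) {
    ok <- ar[, 1] + s[1] >= 1L & ar[, 1] + s[1] <= d1 &
          ar[, 2] + s[2] >= 1L & ar[, 2] + s[2] <= d2 &
          ar[, 3] + s[3] >= 1L & ar[, 3] + s[3] <= d3
    off <- s[1] + s[2] * d1 + s[3] * d1 * d2
    m <- rep(NA_integer_, n)
    m[ok] <- match(idx[ok] + off, idx)
    hit <- which(!is.na(m))
    from <- c(from, hit)
    to <- c(to, m[hit])
  }
  if (length(from)) {
    g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  } else {
    g <- igraph::make_empty_graph(n, directed = FALSE)
  }
  as.integer(igraph::components(g)$membership)
}

# Dice overlap coefficient of two logical masks.
dice_coefficient <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Bilinear sampling of matrix `img` at (continuous) row/col coordinates,
# 1-based pixel centres; out-of-range coordinates clamp to the border.
bilinear_sample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# Rescale a matrix by `scale` about its centre (bilinear), preserving shape:
# output pixel (r, c) samples the input at centre + (r - centre) / scale.
rescale_about_center <- function(img, scale) {
  if (scale == 1) return(img)
  nr <- nrow(img); nc <- ncol(img)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  rr <- cr + (seq_len(nr) - cr) / scale
  cc_out <- cc + (seq_len(nc) - cc) / scale
  grid_r <- rep(rr, times = nc)
  grid_c <- rep(cc_out, each = nr)
  matrix(bilinear_sample(img, grid_r, grid_c), nr, nc)
}

# Integer translation of a matrix, zero filling. shift = c(rows, cols): the
# content moves down/right for positive shifts.
shift_matrix <- function(img, shift, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(fill, nr, nc)
  sr <- shift[1]; sc <- shift[2]
  r_src <- max(1, 1 - sr):min(nr, nr - sr)
  c_src <- max(1, 1 - sc):min(nc, nc - sc)
  if (length(r_src) && length(c_src)) {
    out[r_src + sr, c_src + sc] <- img[r_src, c_src]
  }
  out
}

# 5x5-style per-frame median filter followed by a centred moving average in
# time. EBImage's constant-time median filter needs values in [0, 1].
smooth_transient_stack <- function(arr, spatial_size = 5L, temporal_k = 3L) {
  d <- dim(arr)
  lo <- min(arr); hi <- max(arr)
  scale <- if (hi > lo) hi - lo else 1
  rad <- as.integer(spatial_size %/% 2)
  out <- arr
  for (t in seq_len(d[3])) {
    f <- (arr[, , t] - lo) / scale
    out[, , t] <- EBImage::imageData(EBImage::medianFilter(f, rad)) * scale + lo
  }
  dim(out) <- c(d[1] * d[2], d[3])
  out <- .box_filter_rows(out, temporal_k)
  array(out, d)
}
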