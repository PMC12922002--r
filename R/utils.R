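# Internal helpers shared across modules. Images are plain numeric matrices
# indexed [row, col]; reported coordinates are 0-based pixel centers,
# origin top-left.

# Reflect-pad a matrix by `r` pixels on every side.
pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc)
    stop("padding radius ", r, " too large for a ", nr, "x", nc, " image")
  ri <- c(rev(seq_len(r) + 1L), seq_len(nr), nr - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(nc), nc - seq_len(r))
  m[ri, ci, drop = FALSE]
}

# Convolve with reflective boundary handling via padding + EBImage::filter2.
conv2_reflect <- function(m, kernel) {
  r <- (max(dim(kernel)) - 1L) %/% 2L
  if (r == 0L) return(m * kernel[1L, 1L])
  p <- pad_reflect(m, r)
  out <- EBImage::filter2(p, kernel, boundary = "circular")
  out[(r + 1L):(r + nrow(m)), (r + 1L):(r + ncol(m)), drop = FALSE]
}

# Sampled, normalized 2-D Gaussian kernel (radius 5 sigma keeps truncation
# error below 1e-6 of the peak).
gaussian_kernel <- function(sigma, radius = ceiling(5 * sigma)) {
  x <- (-radius):radius
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so components that
# touch only diagonally are merged with a union-find pass.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask > 0)
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  n <- max(lab)
  if (n < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs with differing positive labels
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab
  pos <- lab > 0L
  out[pos] <- remap[lab[pos]]
  out
}

# Relabel a label matrix so positive ids are contiguous 1..k, preserving the
# order of the surviving original ids.
relabel_contiguous <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(lab)
  out <- lab
  pos <- lab > 0L
  out[pos] <- match(lab[pos], ids)
  out
}

# Shoelace area of a closed polygon given as a 2-column matrix of vertices.
polygon_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

# Total edge length of a closed polygon.
polygon_perimeter <- function(v) {
  d <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE]) - v
  sum(sqrt(rowSums(d^2)))
}

# Number of lattice points on the boundary of a closed lattice polygon
# (sum of gcd(|dx|, |dy|) over edges); used with Pick's theorem.
lattice_boundary_points <- function(v) {
  d <- abs(rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE]) - v)
  sum(mapply(function(a, b) {
    a <- as.integer(round(a)); b <- as.integer(round(b))
    while (b != 0L) { t <- a %% b; a <- b; b <- t }
    a
  }, d[, 1L], d[, 2L]))
}

# Deterministic 31-bit string hash for fanning a global seed out to
# per-image RNG streams.
stable_hash <- function(s) {
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

# Evaluate f under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, f) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  f()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(name, " must be a single number in [", lo, ", ", hi, "]")
  invisible(x)
}
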