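#' Maximal information coefficient
#'
#' Maximal normalized mutual information of a pair of vectors over all
#' \eqn{n_x \times n_y} grids with \eqn{n_x n_y \le n^{\alpha}} (and
#' \eqn{n_x, n_y \ge 2}): for each grid the mutual information of the
#' induced discretization is divided by \eqn{\log_2 \min(n_x, n_y)}, and the
#' maximum over grids is returned.
#'
#' For small samples (n <= 30) the search over grid lines is exhaustive and
#' the value is exact. For larger samples the standard MINE approximation is
#' used: one axis is equipartitioned, the other optimized exactly by dynamic
#' programming over clump boundaries (at most `c` times the bin count), and
#' both axis orders are tried. The result is deterministic either way.
#'
#' @param x,y numeric vectors of equal length >= 10.
#' @param alpha grid-size exponent; default 0.6.
#' @param c clump factor of the approximate search; default 15.
#' @return MIC in [0, 1]. Constant input gives 0.
#' @export
mic <- function(x, y, alpha = 0.6, c = 15) {
  n <- length(x)
  if (length(y) != n || n < 10L)
    stop("mic: need equal lengths >= 10", call. = FALSE)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(0)
  B <- max(floor(n^alpha), 4)
  shapes <- .mic_shapes(B)
  best <- 0
  if (n <= 30L) {
    for (s in seq_len(nrow(shapes)))
      best <- max(best, .mic_exact_shape(x, y, shapes[s, 1], shapes[s, 2]))
  } else {
    # one DP per equipartitioned row count covers every column count <= B/ny
    for (ny in 2:max(2, floor(B / 2))) {
      nx <- floor(B / ny)
      if (nx < 2L) next
      best <- max(best,
                  .mic_approx_shape(x, y, nx, ny, c),   # y equipartitioned
                  .mic_approx_shape(y, x, nx, ny, c))   # x equipartitioned
    }
  }
  min(max(best, 0), 1)
}

.mic_shapes <- function(B) {
  out <- NULL
  for (ny in 2:max(2, floor(B / 2)))
    for (nx in 2:max(2, floor(B / ny)))
      if (nx * ny <= B) out <- rbind(out, c(nx, ny))
  out
}

# mutual information (bits) of a labelled grid
.grid_mi <- function(xl, yl, nx, ny) {
  n <- length(xl)
  cnt <- tabulate(xl + (yl - 1L) * nx, nbins = nx * ny)
  P <- cnt / n
  px <- rowSums(matrix(P, nx, ny)); py <- colSums(matrix(P, nx, ny))
  pij <- P[P > 0]
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hxy <- -sum(pij * log2(pij))
  hx + hy - hxy
}

# exact maximum over all grids of one shape (small-n path)
.mic_exact_shape <- function(x, y, nx, ny) {
  xl_all <- .axis_partitions(x, nx)
  yl_all <- .axis_partitions(y, ny)
  norm <- log2(min(nx, ny))
  best <- 0
  for (a in seq_len(ncol(xl_all)))
    for (b in seq_len(ncol(yl_all))) {
      v <- .grid_mi(xl_all[, a], yl_all[, b], nx, ny) / norm
      if (v > best) best <- v
    }
  best
}

# all ways to cut an axis into `nb` non-empty bins between distinct values;
# returns a matrix of per-point labels, one column per partition
.axis_partitions <- function(v, nb) {
  cuts <- sort(unique(v))
  edges <- (utils::head(cuts, -1) + utils::tail(cuts, -1)) / 2
  k <- length(edges)
  if (k < nb - 1L) return(matrix(findInterval(v, numeric(0)) + 1L, ncol = 1L))
  sel <- utils::combn(k, nb - 1L)
  apply(sel, 2L, function(s) findInterval(v, edges[s]) + 1L)
}

# MINE-style approximation: equipartition y into ny rows, optimize the x
# partition by DP over clump boundaries; returns best normalized value over
# 2..nx columns
.mic_approx_shape <- function(x, y, nx, ny, c) {
  n <- length(x)
  Q <- .equipartition(y, ny)
  ord <- order(x)
  xs <- x[ord]; Qs <- Q[ord]
  bnd <- .clump_boundaries(xs, Qs, max(floor(c * nx), nx + 1L))
  k <- length(bnd)                       # boundaries incl. 0 and n
  cnt <- bnd                             # cumulative point counts
  nyr <- max(Q)
  cumrow <- sapply(seq_len(nyr), function(q) c(0, cumsum(Qs == q))[bnd + 1L])
  if (is.null(dim(cumrow))) cumrow <- matrix(cumrow, nrow = k)

  rowtot <- cumrow[k, ]
  pq <- rowtot[rowtot > 0] / n
  HQ <- -sum(pq * log2(pq))

  # additive bin score f(s, t) for the segment (bnd[s], bnd[t]]
  xlg <- function(w) ifelse(w > 0, w * log2(w), 0)
  f <- matrix(-Inf, k, k)
  for (s in seq_len(k - 1L)) {
    t <- (s + 1L):k
    w <- (cnt[t] - cnt[s]) / n
    acc <- -xlg(w)
    for (q in seq_len(nyr))
      acc <- acc + xlg((cumrow[t, q] - cumrow[s, q]) / n)
    f[s, t] <- acc
  }

  Fcur <- f[1L, ]                        # one bin over (0, t]
  best <- -Inf
  bestval <- 0
  for (l in 2:nx) {
    if (k <= l) break
    Fnew <- rep(-Inf, k)
    for (t in (l + 1L):k) {
      s <- seq(l, t - 1L)
      Fnew[t] <- max(Fcur[s] + f[s, t])
    }
    Fcur <- Fnew
    best <- max(best, Fcur[k])
    val <- (HQ + best) / log2(min(l, ny))
    bestval <- max(bestval, val)
  }
  bestval
}

# greedy equipartition of values into `nb` groups keeping ties together
.equipartition <- function(v, nb) {
  n <- length(v)
  ord <- order(v)
  vs <- v[ord]
  if (!anyDuplicated(vs)) {              # fast path: exact equipartition
    sizes <- diff(round(seq(0, n, length.out = nb + 1)))
    Q <- integer(n)
    Q[ord] <- rep(seq_len(nb), sizes)
    return(Q)
  }
  grp_end <- which(c(vs[-1] != vs[-n], TRUE))
  Q <- integer(n)
  row <- 1L; placed <- 0L; i <- 1L; start <- 1L
  desired <- n / nb
  for (e in grp_end) {
    size <- e - start + 1L
    if (placed > 0L && row < nb &&
        abs(placed + size - desired) >= abs(placed - desired)) {
      row <- row + 1L; placed <- 0L
      desired <- (n - start + 1) / (nb - row + 1L)
    }
    Q[ord[start:e]] <- row
    placed <- placed + size
    start <- e + 1L
  }
  Q
}

# candidate cut positions: clump boundaries (x-tie groups merged with
# neighbours sharing one pure row), capped at `cap` superclumps
.clump_boundaries <- function(xs, Qs, cap) {
  n <- length(xs)
  if (!anyDuplicated(xs)) {              # fast path: clumps are row runs
    ends <- cumsum(rle(Qs)$lengths)
    return(.cap_boundaries(ends, n, cap))
  }
  gstart <- which(c(TRUE, xs[-1] != xs[-n]))
  gend <- c(gstart[-1] - 1L, n)
  purerow <- vapply(seq_along(gstart), function(i) {
    q <- Qs[gstart[i]:gend[i]]
    if (all(q == q[1L])) q[1L] else NA_integer_
  }, integer(1))
  # merge consecutive pure groups with the same row
  keep <- rep(TRUE, length(gstart))
  if (length(gstart) > 1L)
    for (i in 2:length(gstart))
      if (!is.na(purerow[i]) && !is.na(purerow[i - 1L]) &&
          purerow[i] == purerow[i - 1L]) keep[i] <- FALSE
  cid <- cumsum(keep)                        # clump id per x-group
  ends <- as.numeric(tapply(gend, cid, max)) # clump end positions
  .cap_boundaries(ends, n, cap)
}

# thin clump boundaries to ~cap superclumps by point-count equipartition
.cap_boundaries <- function(ends, n, cap) {
  if (length(ends) > cap) {
    target <- n * seq_len(cap - 1L) / cap
    pick <- vapply(target, function(tg) ends[which.min(abs(ends - tg))],
                   numeric(1))
    ends <- sort(unique(c(pick, n)))
  }
  c(0, ends)
}
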