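#' Gray-level quantization of a masked region
#'
#' Maps in-mask intensities to levels `1..n_levels` by equal-width bins over
#' the in-mask intensity range (fixed-bin-count quantization). Out-of-mask
#' pixels are coded 0. A constant region maps every pixel to level 1.
#'
#' @param roi an [ebus_image()] (grayscale) or numeric matrix of intensities.
#' @param mask a [lesion_mask()] or binary matrix.
#' @param n_levels number of gray levels (>= 2, default 32).
#' @return Integer matrix of levels in `0..n_levels` (0 = outside mask).
#' @export
quantize_gray <- function(roi, mask, n_levels = 32L) {
  x <- if (inherits(roi, "ebus_image")) to_gray(roi$pixels) else roi
  m <- if (inherits(mask, "lesion_mask")) mask$mask else matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (n_levels < 2) stop("n_levels must be >= 2")
  if (!all(dim(x) == dim(m))) stop("roi and mask shapes differ")
  if (sum(m) == 0) stop("empty mask")
  q <- matrix(0L, nrow(x), ncol(x))
  v <- x[m == 1L]
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    q[m == 1L] <- 1L
  } else {
    q[m == 1L] <- pmin(floor((v - lo) / (hi - lo) * n_levels) + 1L, n_levels)
  }
  q
}

# the four distance-1 2-D offsets (row, col): 0, 45, 90, 135 degrees
.glcm_offsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

# pairs of levels for one offset: both members in-mask (level > 0)
offset_pairs <- function(q, dr, dc) {
  n <- dim(q)
  r1 <- max(1L, 1L - dr):min(n[1], n[1] - dr)
  c1 <- max(1L, 1L - dc):min(n[2], n[2] - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  keep <- a > 0L & b > 0L
  cbind(a[keep], b[keep])
}

#' Gray-level co-occurrence matrix
#'
#' Counts level pairs at a single pixel offset; both members of a pair must
#' be in-mask. The symmetric form counts each pair in both directions (the
#' matrix equals its transpose); the normalized form sums to 1.
#'
#' @param q quantized grid from [quantize_gray()].
#' @param offset integer `(d_row, d_col)` displacement (default `(0, 1)`,
#'   i.e. 0 degrees at distance 1).
#' @param n_levels number of gray levels (defaults to `max(q)`).
#' @param symmetric count both directions (default TRUE).
#' @param normalize divide by the total count (default FALSE).
#' @return `n_levels x n_levels` matrix.
#' @export
glcm_matrix <- function(q, offset = c(0L, 1L), n_levels = max(q),
                        symmetric = TRUE, normalize = FALSE) {
  if (sum(q > 0L) < 2L) stop("mask must contain at least 2 pixels")
  pr <- offset_pairs(q, offset[1], offset[2])
  cnt <- matrix(0, n_levels, n_levels)
  if (nrow(pr) > 0) {
    t1 <- tabulate((pr[, 2] - 1L) * n_levels + pr[, 1], nbins = n_levels^2)
    cnt <- matrix(t1, n_levels, n_levels)
  }
  if (symmetric) cnt <- cnt + t(cnt)
  if (normalize && sum(cnt) > 0) cnt <- cnt / sum(cnt)
  cnt
}

.elog2 <- function(x) ifelse(x > 0, log2(x), 0)

# 24 co-occurrence features from one normalized symmetric GLCM
glcm_features_one <- function(P) {
  Ng <- nrow(P)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(Ng) * px); muy <- sum(seq_len(Ng) * py)
  sigx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))
  # diagonal (difference) and cross-diagonal (sum) distributions
  k_diff <- abs(i - j)
  p_diff <- as.vector(rowsum(as.vector(P), as.vector(k_diff)))  # k = 0..Ng-1
  kd <- sort(unique(as.vector(k_diff)))
  k_sum <- i + j
  p_sum <- as.vector(rowsum(as.vector(P), as.vector(k_sum)))    # k = 2..2Ng
  ks <- sort(unique(as.vector(k_sum)))
  da <- sum(kd * p_diff)
  HX <- -sum(px * .elog2(px)); HY <- -sum(py * .elog2(py))
  HXY <- -sum(P * .elog2(P))
  pxy <- outer(px, py)
  HXY1 <- -sum(P * .elog2(pxy))
  HXY2 <- -sum(pxy * .elog2(pxy))
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))
  corr <- if (sigx > 0 && sigy > 0) (sum(i * j * P) - mux * muy) / (sigx * sigy) else 0
  # MCC: second largest eigenvalue of Q(i,j) = sum_k p(i,k) p(j,k) / (px_i py_k)
  nz <- which(px > 0)
  mcc <- if (length(nz) >= 2) {
    Pn <- P[nz, nz, drop = FALSE]
    Qm <- (Pn / px[nz]) %*% t(Pn / matrix(py[nz], length(nz), length(nz), byrow = TRUE))
    ev <- sort(Re(eigen(Qm, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(ev[2], 0))
  } else 1
  c(Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(p_diff * .elog2(p_diff)),
    DifferenceVariance = sum((kd - da)^2 * p_diff),
    Id = sum(P / (1 + k_diff)),
    Idm = sum(P / (1 + k_diff^2)),
    Idmn = sum(P / (1 + k_diff^2 / Ng^2)),
    Idn = sum(P / (1 + k_diff / Ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(P[k_diff > 0] / k_diff[k_diff > 0]^2),
    JointAverage = sum(i * P),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(ks * p_sum),
    SumEntropy = -sum(p_sum * .elog2(p_sum)),
    SumSquares = sum((i - mux)^2 * P))
}

#' Co-occurrence texture features
#'
#' The 24 GLCM features, computed per distance-1 offset (0, 45, 90, 135
#' degrees) on the symmetrized normalized matrix and averaged over the four
#' angles. Conventions for degenerate regions: correlation on a constant
#' region is 0; information-measure features are 0 when the marginal
#' entropies vanish.
#'
#' @param q quantized grid from [quantize_gray()].
#' @param n_levels number of gray levels (defaults to `max(q)`).
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(q, n_levels = max(q)) {
  per <- vapply(.glcm_offsets, function(off) {
    P <- glcm_matrix(q, off, n_levels, symmetric = TRUE, normalize = TRUE)
    glcm_features_one(P)
  }, numeric(24))
  rowMeans(per)
}

#' Adaptive weighted-sum of the upper and lower triangular GLCM (AWS)
#'
#' A heterogeneity statistic on the *unsymmetrized* normalized GLCM:
#' `S_U = sum_{i<j} p(i,j) |i-j|` and `S_L = sum_{i>j} p(i,j) |i-j|`, with the
#' adaptive weight `w = S_U / (S_U + S_L)` (0.5 when both vanish), giving
#' `AWS = w S_U + (1-w) S_L`. It is 0 exactly when all co-occurrence mass is
#' diagonal (homogeneous texture), and equals `S_U` for a symmetric matrix.
#'
#' @param P an unsymmetrized normalized GLCM (matrix summing to 1).
#' @return Single numeric value.
#' @export
aws_feature <- function(P) {
  Ng <- nrow(P)
  i <- matrix(seq_len(Ng), Ng, Ng); j <- t(i)
  su <- sum(P[i < j] * abs(i - j)[i < j])
  sl <- sum(P[i > j] * abs(i - j)[i > j])
  w <- if (su + sl > 0) su / (su + sl) else 0.5
  w * su + (1 - w) * sl
}

# mean AWS over the four distance-1 angles
aws_feature_avg <- function(q, n_levels = max(q)) {
  mean(vapply(.glcm_offsets, function(off) {
    P <- glcm_matrix(q, off, n_levels, symmetric = FALSE, normalize = TRUE)
    aws_feature(P)
  }, numeric(1)))
}

# ---- GLRLM ------------------------------------------------------------------

# run-length counts N(gray, length) for one direction; 0-level breaks runs
glrlm_counts <- function(q, dir) {
  lines <- switch(paste(dir, collapse = ","),
    "0,1" = split(q, row(q)),
    "1,0" = split(q, col(q)),
    "1,1" = split(q, col(q) - row(q)),
    "1,-1" = split(q, col(q) + row(q)),
    stop("unsupported direction"))
  g <- integer(0); l <- integer(0)
  for (ln in lines) {
    r <- rle(as.integer(ln))
    keep <- r$values > 0L
    g <- c(g, r$values[keep]); l <- c(l, r$lengths[keep])
  }
  data.frame(g = g, l = l)
}

glrlm_features_one <- function(runs, np) {
  g <- runs$g; l <- runs$l
  nr <- nrow(runs)
  p <- rep(1 / nr, nr)
  mug <- sum(g * p); mul <- sum(l * p)
  gl_tab <- tapply(rep(1, nr), g, sum)          # runs per gray level
  rl_tab <- tapply(rep(1, nr), l, sum)          # runs per length
  # run entropy over the joint (g, l) distribution
  jt <- tapply(rep(1, nr), paste(g, l), sum) / nr
  c(ShortRunEmphasis = mean(1 / l^2),
    LongRunEmphasis = mean(l^2),
    GrayLevelNonUniformity = sum(gl_tab^2) / nr,
    GrayLevelNonUniformityNormalized = sum(gl_tab^2) / nr^2,
    RunLengthNonUniformity = sum(rl_tab^2) / nr,
    RunLengthNonUniformityNormalized = sum(rl_tab^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum(p * (g - mug)^2),
    RunVariance = sum(p * (l - mul)^2),
    RunEntropy = -sum(jt * .elog2(jt)),
    LowGrayLevelRunEmphasis = mean(1 / g^2),
    HighGrayLevelRunEmphasis = mean(g^2),
    ShortRunLowGrayLevelEmphasis = mean(1 / (g^2 * l^2)),
    ShortRunHighGrayLevelEmphasis = mean(g^2 / l^2),
    LongRunLowGrayLevelEmphasis = mean(l^2 / g^2),
    LongRunHighGrayLevelEmphasis = mean(g^2 * l^2))
}

#' Run-length texture features
#'
#' The 16 GLRLM features, computed per direction (0, 45, 90, 135 degrees)
#' and averaged. Out-of-mask pixels break runs.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(q, n_levels = max(q)) {
  np <- sum(q > 0L)
  dirs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  per <- vapply(dirs, function(d) glrlm_features_one(glrlm_counts(q, d), np),
                numeric(16))
  rowMeans(per)
}

# ---- GLDM -------------------------------------------------------------------

.neigh8 <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L), c(0L, 1L),
                c(1L, -1L), c(1L, 0L), c(1L, 1L))

shift_grid <- function(q, dr, dc, fill = 0L) {
  n <- dim(q)
  out <- matrix(fill, n[1], n[2])
  r1 <- max(1L, 1L - dr):min(n[1], n[1] - dr)
  c1 <- max(1L, 1L - dc):min(n[2], n[2] - dc)
  out[r1, c1] <- q[r1 + dr, c1 + dc]
  out
}

#' Gray-level dependence features
#'
#' For each in-mask pixel the dependence size is 1 plus the number of in-mask
#' 8-neighbours with the identical quantized level (dependence tolerance
#' alpha = 0), giving sizes 1..9. The 14 GLDM features are computed from the
#' (gray level, dependence) count table.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(q, n_levels = max(q)) {
  inm <- q > 0L
  dep <- matrix(0L, nrow(q), ncol(q))
  for (nb in .neigh8) {
    s <- shift_grid(q, nb[1], nb[2])
    dep <- dep + (s > 0L & s == q)
  }
  g <- q[inm]; d <- dep[inm] + 1L
  nz <- length(g)
  p <- rep(1 / nz, nz)
  mug <- sum(g * p); mud <- sum(d * p)
  gl_tab <- tapply(rep(1, nz), g, sum)
  dn_tab <- tapply(rep(1, nz), d, sum)
  jt <- tapply(rep(1, nz), paste(g, d), sum) / nz
  c(SmallDependenceEmphasis = mean(1 / d^2),
    LargeDependenceEmphasis = mean(d^2),
    GrayLevelNonUniformity = sum(gl_tab^2) / nz,
    DependenceNonUniformity = sum(dn_tab^2) / nz,
    DependenceNonUniformityNormalized = sum(dn_tab^2) / nz^2,
    GrayLevelVariance = sum(p * (g - mug)^2),
    DependenceVariance = sum(p * (d - mud)^2),
    DependenceEntropy = -sum(jt * .elog2(jt)),
    LowGrayLevelEmphasis = mean(1 / g^2),
    HighGrayLevelEmphasis = mean(g^2),
    SmallDependenceLowGrayLevelEmphasis = mean(1 / (g^2 * d^2)),
    SmallDependenceHighGrayLevelEmphasis = mean(g^2 / d^2),
    LargeDependenceLowGrayLevelEmphasis = mean(d^2 / g^2),
    LargeDependenceHighGrayLevelEmphasis = mean(g^2 * d^2))
}

# ---- GLSZM ------------------------------------------------------------------

# 8-connected zone sizes per gray level. EBImage::bwlabel is 4-connected, so
# labels touching diagonally are merged with a union-find pass.
glszm_zones <- function(q) {
  g <- integer(0); s <- integer(0)
  for (lev in sort(unique(q[q > 0L]))) {
    bin <- q == lev
    lab <- EBImage::bwlabel(bin)
    nl <- max(lab)
    if (nl == 0) next
    parent <- seq_len(nl)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (nb in list(c(-1L, -1L), c(-1L, 1L))) {  # diagonal adjacencies
      sh <- shift_grid(lab, nb[1], nb[2])
      pairup <- unique(cbind(lab[lab > 0 & sh > 0], sh[lab > 0 & sh > 0]))
      if (length(pairup)) for (k in seq_len(nrow(pairup))) {
        a <- find(pairup[k, 1]); b <- find(pairup[k, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
    roots <- vapply(seq_len(nl), find, integer(1))
    sizes <- tabulate(lab[lab > 0])
    zs <- tapply(sizes, roots, sum)
    g <- c(g, rep(lev, length(zs))); s <- c(s, as.integer(zs))
  }
  data.frame(g = g, s = s)
}

#' Size-zone texture features
#'
#' Zones are 8-connected components of equal quantized level inside the mask;
#' the 16 GLSZM features are computed from the (gray level, zone size) count
#' table (direction-free).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(q, n_levels = max(q)) {
  z <- glszm_zones(q)
  np <- sum(q > 0L)
  g <- z$g; s <- z$s
  nz <- nrow(z)
  p <- rep(1 / nz, nz)
  mug <- sum(g * p); mus <- sum(s * p)
  gl_tab <- tapply(rep(1, nz), g, sum)
  sz_tab <- tapply(rep(1, nz), s, sum)
  jt <- tapply(rep(1, nz), paste(g, s), sum) / nz
  c(SmallAreaEmphasis = mean(1 / s^2),
    LargeAreaEmphasis = mean(s^2),
    GrayLevelNonUniformity = sum(gl_tab^2) / nz,
    GrayLevelNonUniformityNormalized = sum(gl_tab^2) / nz^2,
    SizeZoneNonUniformity = sum(sz_tab^2) / nz,
    SizeZoneNonUniformityNormalized = sum(sz_tab^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum(p * (g - mug)^2),
    ZoneVariance = sum(p * (s - mus)^2),
    ZoneEntropy = -sum(jt * .elog2(jt)),
    LowGrayLevelZoneEmphasis = mean(1 / g^2),
    HighGrayLevelZoneEmphasis = mean(g^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (g^2 * s^2)),
    SmallAreaHighGrayLevelEmphasis = mean(g^2 / s^2),
    LargeAreaLowGrayLevelEmphasis = mean(s^2 / g^2),
    LargeAreaHighGrayLevelEmphasis = mean(g^2 * s^2))
}

# ---- NGTDM ------------------------------------------------------------------

#' Neighbouring gray-tone difference features
#'
#' For each in-mask pixel with at least one in-mask 8-neighbour, the absolute
#' difference between its level and the mean level of those neighbours is
#' accumulated per level (`s_i`); the 5 NGTDM features follow.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 features (Coarseness, Contrast,
#'   Busyness, Complexity, Strength).
#' @export
ngtdm_features <- function(q, n_levels = max(q)) {
  inm <- q > 0L
  ssum <- matrix(0, nrow(q), ncol(q))
  scnt <- matrix(0L, nrow(q), ncol(q))
  for (nb in .neigh8) {
    sh <- shift_grid(q, nb[1], nb[2])
    ssum <- ssum + sh * (sh > 0L)
    scnt <- scnt + (sh > 0L)
  }
  valid <- inm & scnt > 0L
  abar <- ssum[valid] / scnt[valid]
  g <- q[valid]
  np <- sum(valid)
  lev <- sort(unique(g))
  ni <- vapply(lev, function(L) sum(g == L), numeric(1))
  si <- vapply(lev, function(L) sum(abs(g[g == L] - abar[g == L])), numeric(1))
  pi_ <- ni / np
  ngp <- length(lev)
  coarse <- if (sum(pi_ * si) > 0) 1 / sum(pi_ * si) else 1e6
  contr <- if (ngp > 1) {
    (sum(outer(pi_, pi_) * outer(lev, lev, function(a, b) (a - b)^2)) /
       (ngp * (ngp - 1))) * (sum(si) / np)
  } else 0
  ipi <- lev * pi_
  busy_den <- sum(abs(outer(ipi, ipi, "-")))
  busy <- if (busy_den > 0) sum(pi_ * si) / busy_den else 0
  cplx <- sum(outer(seq_along(lev), seq_along(lev), Vectorize(function(a, b)
    abs(lev[a] - lev[b]) * (pi_[a] * si[a] + pi_[b] * si[b]) / (pi_[a] + pi_[b])))) / np
  strg_num <- sum(outer(pi_, pi_, "+") * outer(lev, lev, function(a, b) (a - b)^2))
  strg <- if (sum(si) > 0) strg_num / sum(si) else 0
  c(Coarseness = coarse, Contrast = contr, Busyness = busy,
    Complexity = cplx, Strength = strg)
}

#' Matrix-based texture feature bank
#'
#' The 75 matrix-family features: 24 GLCM + 14 GLDM + 16 GLRLM + 16 GLSZM +
#' 5 NGTDM, each prefixed with its family name.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of length 75.
#' @export
texture_features <- function(q, n_levels = max(q)) {
  out <- c(prefix_names(glcm_features(q, n_levels), "glcm"),
           prefix_names(gldm_features(q, n_levels), "gldm"),
           prefix_names(glrlm_features(q, n_levels), "glrlm"),
           prefix_names(glszm_features(q, n_levels), "glszm"),
           prefix_names(ngtdm_features(q, n_levels), "ngtdm"))
  stopifnot(length(out) == 75L)
  out
}

prefix_names <- function(x, prefix) {
  names(x) <- paste(prefix, names(x), sep = "_")
  x
}
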