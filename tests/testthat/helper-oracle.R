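# Independent brute-force oracles: everything here is written with explicit
# scalar loops straight from the textbook definitions, deliberately sharing no
# code with the package implementations.

oracle_glcm <- function(q, dr, dc, n_levels, symmetric = TRUE) {
  P <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(q))) for (c_ in seq_len(ncol(q))) {
    r2 <- r + dr; c2 <- c_ + dc
    if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
    a <- q[r, c_]; b <- q[r2, c2]
    if (a > 0 && b > 0) {
      P[a, b] <- P[a, b] + 1
      if (symmetric) P[b, a] <- P[b, a] + 1
    }
  }
  P
}

oracle_glcm_features <- function(P) {
  Ng <- nrow(P)
  P <- P / sum(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:Ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx2 <- 0; sy2 <- 0
  for (i in 1:Ng) { sx2 <- sx2 + (i - mux)^2 * px[i]; sy2 <- sy2 + (i - muy)^2 * py[i] }
  pdiff <- numeric(Ng); psum <- numeric(2 * Ng)   # pdiff index k+1, k=0..Ng-1
  for (i in 1:Ng) for (j in 1:Ng) {
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
    psum[i + j] <- psum[i + j] + P[i, j]
  }
  lg2 <- function(x) if (x > 0) log2(x) else 0
  f <- c(Autocorrelation = 0, ClusterProminence = 0, ClusterShade = 0,
         ClusterTendency = 0, Contrast = 0, Correlation = 0,
         DifferenceAverage = 0, DifferenceEntropy = 0, DifferenceVariance = 0,
         Id = 0, Idm = 0, Idmn = 0, Idn = 0, Imc1 = 0, Imc2 = 0,
         InverseVariance = 0, JointAverage = 0, JointEnergy = 0,
         JointEntropy = 0, MCC = 0, MaximumProbability = 0, SumAverage = 0,
         SumEntropy = 0, SumSquares = 0)
  HX <- 0; HY <- 0; HXY <- 0; HXY1 <- 0; HXY2 <- 0
  for (i in 1:Ng) { HX <- HX - px[i] * lg2(px[i]); HY <- HY - py[i] * lg2(py[i]) }
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    f["Autocorrelation"] <- f["Autocorrelation"] + i * j * p
    f["ClusterProminence"] <- f["ClusterProminence"] + (i + j - mux - muy)^4 * p
    f["ClusterShade"] <- f["ClusterShade"] + (i + j - mux - muy)^3 * p
    f["ClusterTendency"] <- f["ClusterTendency"] + (i + j - mux - muy)^2 * p
    f["Contrast"] <- f["Contrast"] + (i - j)^2 * p
    f["Id"] <- f["Id"] + p / (1 + abs(i - j))
    f["Idm"] <- f["Idm"] + p / (1 + (i - j)^2)
    f["Idmn"] <- f["Idmn"] + p / (1 + (i - j)^2 / Ng^2)
    f["Idn"] <- f["Idn"] + p / (1 + abs(i - j) / Ng)
    if (i != j) f["InverseVariance"] <- f["InverseVariance"] + p / (i - j)^2
    f["JointAverage"] <- f["JointAverage"] + i * p
    f["JointEnergy"] <- f["JointEnergy"] + p^2
    HXY <- HXY - p * lg2(P[i, j])
    HXY1 <- HXY1 - p * lg2(px[i] * py[j])
    HXY2 <- HXY2 - px[i] * py[j] * lg2(px[i] * py[j])
  }
  f["JointEntropy"] <- HXY
  f["MaximumProbability"] <- max(P)
  da <- 0
  for (k in 0:(Ng - 1)) da <- da + k * pdiff[k + 1]
  f["DifferenceAverage"] <- da
  for (k in 0:(Ng - 1)) {
    f["DifferenceEntropy"] <- f["DifferenceEntropy"] - pdiff[k + 1] * lg2(pdiff[k + 1])
    f["DifferenceVariance"] <- f["DifferenceVariance"] + (k - da)^2 * pdiff[k + 1]
  }
  for (k in 2:(2 * Ng)) {
    f["SumAverage"] <- f["SumAverage"] + k * psum[k]
    f["SumEntropy"] <- f["SumEntropy"] - psum[k] * lg2(psum[k])
  }
  for (i in 1:Ng) for (j in 1:Ng)
    f["SumSquares"] <- f["SumSquares"] + (i - mux)^2 * P[i, j]
  f["Correlation"] <- if (sx2 > 0 && sy2 > 0) {
    s <- 0
    for (i in 1:Ng) for (j in 1:Ng) s <- s + i * j * P[i, j]
    (s - mux * muy) / sqrt(sx2 * sy2)
  } else 0
  f["Imc1"] <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  f["Imc2"] <- sqrt(max(1 - exp(-2 * (HXY2 - HXY)), 0))
  nzi <- which(px > 0)
  f["MCC"] <- if (length(nzi) >= 2) {
    Q <- matrix(0, length(nzi), length(nzi))
    for (ia in seq_along(nzi)) for (ja in seq_along(nzi)) {
      s <- 0
      for (ka in seq_along(nzi))
        s <- s + P[nzi[ia], nzi[ka]] * P[nzi[ja], nzi[ka]] / (px[nzi[ia]] * py[nzi[ka]])
      Q[ia, ja] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(ev[2], 0))
  } else 1
  f
}

oracle_glcm_bank <- function(q, n_levels) {
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  acc <- NULL
  for (o in offs) {
    f <- oracle_glcm_features(oracle_glcm(q, o[1], o[2], n_levels))
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / length(offs)
}

oracle_aws <- function(P) {
  su <- 0; sl <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (i < j) su <- su + P[i, j] * abs(i - j)
    if (i > j) sl <- sl + P[i, j] * abs(i - j)
  }
  w <- if (su + sl > 0) su / (su + sl) else 0.5
  w * su + (1 - w) * sl
}

# runs along one direction, tracing each line pixel by pixel
oracle_glrlm_runs <- function(q, dr, dc) {
  nr <- nrow(q); nc <- ncol(q)
  starts <- list()
  for (r in 1:nr) for (c_ in 1:nc) {
    pr <- r - dr; pc <- c_ - dc
    if (pr < 1 || pr > nr || pc < 1 || pc > nc)
      starts[[length(starts) + 1]] <- c(r, c_)
  }
  g <- integer(0); l <- integer(0)
  for (s in starts) {
    r <- s[1]; c_ <- s[2]
    cur <- 0L; len <- 0L
    while (r >= 1 && r <= nr && c_ >= 1 && c_ <= nc) {
      v <- q[r, c_]
      if (v == cur) len <- len + 1L
      else {
        if (cur > 0L) { g <- c(g, cur); l <- c(l, len) }
        cur <- v; len <- 1L
      }
      r <- r + dr; c_ <- c_ + dc
    }
    if (cur > 0L) { g <- c(g, cur); l <- c(l, len) }
  }
  cbind(g = g, l = l)
}

oracle_glrlm_features <- function(runs, np) {
  nr <- nrow(runs)
  f <- setNames(numeric(16),
    c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
      "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
      "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
      "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
      "LongRunHighGrayLevelEmphasis"))
  for (k in 1:nr) {
    g <- runs[k, 1]; l <- runs[k, 2]
    f["ShortRunEmphasis"] <- f["ShortRunEmphasis"] + 1 / l^2
    f["LongRunEmphasis"] <- f["LongRunEmphasis"] + l^2
    f["LowGrayLevelRunEmphasis"] <- f["LowGrayLevelRunEmphasis"] + 1 / g^2
    f["HighGrayLevelRunEmphasis"] <- f["HighGrayLevelRunEmphasis"] + g^2
    f["ShortRunLowGrayLevelEmphasis"] <- f["ShortRunLowGrayLevelEmphasis"] + 1 / (g^2 * l^2)
    f["ShortRunHighGrayLevelEmphasis"] <- f["ShortRunHighGrayLevelEmphasis"] + g^2 / l^2
    f["LongRunLowGrayLevelEmphasis"] <- f["LongRunLowGrayLevelEmphasis"] + l^2 / g^2
    f["LongRunHighGrayLevelEmphasis"] <- f["LongRunHighGrayLevelEmphasis"] + g^2 * l^2
  }
  for (nm in c("ShortRunEmphasis", "LongRunEmphasis", "LowGrayLevelRunEmphasis",
               "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
               "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
               "LongRunHighGrayLevelEmphasis")) f[nm] <- f[nm] / nr
  gl <- table(runs[, 1]); rl <- table(runs[, 2])
  f["GrayLevelNonUniformity"] <- sum(gl^2) / nr
  f["GrayLevelNonUniformityNormalized"] <- sum(gl^2) / nr^2
  f["RunLengthNonUniformity"] <- sum(rl^2) / nr
  f["RunLengthNonUniformityNormalized"] <- sum(rl^2) / nr^2
  f["RunPercentage"] <- nr / np
  mug <- mean(runs[, 1]); mul <- mean(runs[, 2])
  f["GrayLevelVariance"] <- mean((runs[, 1] - mug)^2)
  f["RunVariance"] <- mean((runs[, 2] - mul)^2)
  jt <- table(paste(runs[, 1], runs[, 2])) / nr
  f["RunEntropy"] <- -sum(jt * log2(jt))
  f
}

oracle_glrlm_bank <- function(q) {
  np <- sum(q > 0)
  dirs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  acc <- NULL
  for (d in dirs) {
    f <- oracle_glrlm_features(oracle_glrlm_runs(q, d[1], d[2]), np)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / 4
}

oracle_gldm_features <- function(q) {
  nr <- nrow(q); nc <- ncol(q)
  g <- integer(0); d <- integer(0)
  for (r in 1:nr) for (c_ in 1:nc) {
    if (q[r, c_] == 0L) next
    dep <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c_ + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (q[r2, c2] > 0L && q[r2, c2] == q[r, c_]) dep <- dep + 1L
    }
    g <- c(g, q[r, c_]); d <- c(d, dep + 1L)
  }
  nz <- length(g)
  f <- setNames(numeric(14),
    c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
      "GrayLevelNonUniformity", "DependenceNonUniformity",
      "DependenceNonUniformityNormalized", "GrayLevelVariance",
      "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
      "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
      "SmallDependenceHighGrayLevelEmphasis",
      "LargeDependenceLowGrayLevelEmphasis",
      "LargeDependenceHighGrayLevelEmphasis"))
  f["SmallDependenceEmphasis"] <- mean(1 / d^2)
  f["LargeDependenceEmphasis"] <- mean(d^2)
  f["GrayLevelNonUniformity"] <- sum(table(g)^2) / nz
  f["DependenceNonUniformity"] <- sum(table(d)^2) / nz
  f["DependenceNonUniformityNormalized"] <- sum(table(d)^2) / nz^2
  f["GrayLevelVariance"] <- mean((g - mean(g))^2)
  f["DependenceVariance"] <- mean((d - mean(d))^2)
  jt <- table(paste(g, d)) / nz
  f["DependenceEntropy"] <- -sum(jt * log2(jt))
  f["LowGrayLevelEmphasis"] <- mean(1 / g^2)
  f["HighGrayLevelEmphasis"] <- mean(g^2)
  f["SmallDependenceLowGrayLevelEmphasis"] <- mean(1 / (g^2 * d^2))
  f["SmallDependenceHighGrayLevelEmphasis"] <- mean(g^2 / d^2)
  f["LargeDependenceLowGrayLevelEmphasis"] <- mean(d^2 / g^2)
  f["LargeDependenceHighGrayLevelEmphasis"] <- mean(g^2 * d^2)
  f
}

# flood-fill (8-connected) zone sizes
oracle_glszm_zones <- function(q) {
  nr <- nrow(q); nc <- ncol(q)
  seen <- matrix(FALSE, nr, nc)
  g <- integer(0); s <- integer(0)
  for (r in 1:nr) for (c_ in 1:nc) {
    if (q[r, c_] == 0L || seen[r, c_]) next
    lev <- q[r, c_]
    stack <- list(c(r, c_)); seen[r, c_] <- TRUE; size <- 0L
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (!seen[r2, c2] && q[r2, c2] == lev) {
          seen[r2, c2] <- TRUE
          stack[[length(stack) + 1]] <- c(r2, c2)
        }
      }
    }
    g <- c(g, lev); s <- c(s, size)
  }
  cbind(g = g, s = s)
}

oracle_glszm_features <- function(q) {
  z <- oracle_glszm_zones(q)
  np <- sum(q > 0)
  g <- z[, 1]; s <- z[, 2]; nz <- nrow(z)
  f <- setNames(numeric(16),
    c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
      "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
      "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
      "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
      "LargeAreaHighGrayLevelEmphasis"))
  f["SmallAreaEmphasis"] <- mean(1 / s^2)
  f["LargeAreaEmphasis"] <- mean(s^2)
  f["GrayLevelNonUniformity"] <- sum(table(g)^2) / nz
  f["GrayLevelNonUniformityNormalized"] <- sum(table(g)^2) / nz^2
  f["SizeZoneNonUniformity"] <- sum(table(s)^2) / nz
  f["SizeZoneNonUniformityNormalized"] <- sum(table(s)^2) / nz^2
  f["ZonePercentage"] <- nz / np
  f["GrayLevelVariance"] <- mean((g - mean(g))^2)
  f["ZoneVariance"] <- mean((s - mean(s))^2)
  jt <- table(paste(g, s)) / nz
  f["ZoneEntropy"] <- -sum(jt * log2(jt))
  f["LowGrayLevelZoneEmphasis"] <- mean(1 / g^2)
  f["HighGrayLevelZoneEmphasis"] <- mean(g^2)
  f["SmallAreaLowGrayLevelEmphasis"] <- mean(1 / (g^2 * s^2))
  f["SmallAreaHighGrayLevelEmphasis"] <- mean(g^2 / s^2)
  f["LargeAreaLowGrayLevelEmphasis"] <- mean(s^2 / g^2)
  f["LargeAreaHighGrayLevelEmphasis"] <- mean(g^2 * s^2)
  f
}

oracle_ngtdm_features <- function(q) {
  nr <- nrow(q); nc <- ncol(q)
  gs <- integer(0); diffs <- numeric(0)
  for (r in 1:nr) for (c_ in 1:nc) {
    if (q[r, c_] == 0L) next
    s <- 0; cnt <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c_ + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (q[r2, c2] > 0L) { s <- s + q[r2, c2]; cnt <- cnt + 1L }
    }
    if (cnt == 0L) next
    gs <- c(gs, q[r, c_]); diffs <- c(diffs, abs(q[r, c_] - s / cnt))
  }
  np <- length(gs)
  lev <- sort(unique(gs))
  ni <- sapply(lev, function(L) sum(gs == L))
  si <- sapply(lev, function(L) sum(diffs[gs == L]))
  pi_ <- ni / np
  ngp <- length(lev)
  coarse <- if (sum(pi_ * si) > 0) 1 / sum(pi_ * si) else 1e6
  contr <- 0
  if (ngp > 1) {
    for (a in seq_len(ngp)) for (b in seq_len(ngp))
      contr <- contr + pi_[a] * pi_[b] * (lev[a] - lev[b])^2
    contr <- contr / (ngp * (ngp - 1)) * sum(si) / np
  }
  bden <- 0
  for (a in seq_len(ngp)) for (b in seq_len(ngp))
    bden <- bden + abs(lev[a] * pi_[a] - lev[b] * pi_[b])
  busy <- if (bden > 0) sum(pi_ * si) / bden else 0
  cplx <- 0
  for (a in seq_len(ngp)) for (b in seq_len(ngp))
    cplx <- cplx + abs(lev[a] - lev[b]) * (pi_[a] * si[a] + pi_[b] * si[b]) / (pi_[a] + pi_[b])
  cplx <- cplx / np
  strg <- 0
  for (a in seq_len(ngp)) for (b in seq_len(ngp))
    strg <- strg + (pi_[a] + pi_[b]) * (lev[a] - lev[b])^2
  strg <- if (sum(si) > 0) strg / sum(si) else 0
  c(Coarseness = coarse, Contrast = contr, Busyness = busy,
    Complexity = cplx, Strength = strg)
}

# exhaustive greedy tiling oracle with explicit rectangle-overlap checks
oracle_tile <- function(ok, side) {
  n <- dim(ok)
  acc <- list()
  overlaps <- function(a, b)
    !(a[1] + side - 1 < b[1] || b[1] + side - 1 < a[1] ||
        a[2] + side - 1 < b[2] || b[2] + side - 1 < a[2])
  for (r in seq_len(max(0, n[1] - side + 1))) {
    for (c_ in seq_len(max(0, n[2] - side + 1))) {
      if (!(ok[r, c_] && ok[r, c_ + side - 1] && ok[r + side - 1, c_] &&
            ok[r + side - 1, c_ + side - 1])) next
      clash <- FALSE
      for (a in acc) if (overlaps(a, c(r, c_))) { clash <- TRUE; break }
      if (!clash) acc[[length(acc) + 1]] <- c(r, c_)
    }
  }
  if (length(acc) == 0) matrix(integer(0), 0, 2)
  else do.call(rbind, acc)
}

# small random blobby binary mask for tiling property tests
random_blob_mask <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  k <- EBImage::makeBrush(15, "Gaussian", sigma = 4)
  sm <- EBImage::filter2(m, k)
  matrix(as.integer(sm > quantile(sm, runif(1, 0.3, 0.7))), n, n)
}
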