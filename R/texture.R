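#' Texture features of a quantized region
#'
#' Computes the 90 texture statistics of the inventory from five gray-level
#' matrix families, all built over the masked voxel set only:
#'
#' * GLCM (39): 13 Haralick-type statistics over symmetric distance-1
#'   co-occurrence matrices for the 13 unique 3D directions, each reported
#'   under three aggregations -- the mean over directions, the range
#'   (max - min) over directions, and the statistic of the direction-merged
#'   matrix.
#' * GLRLM (16): run-length statistics on the run matrix summed over the 13
#'   directions.
#' * GLSZM (16): size-zone statistics over 26-connected equal-level zones.
#' * GLDM (14): dependence statistics with neighborhood = 26-neighbors and
#'   dependence threshold alpha = 0; the dependence size counts the center,
#'   so it ranges 1..27.
#' * NGTDM (5): coarseness, contrast, busyness, complexity, strength with a
#'   26-neighbor neighborhood.
#'
#' Degenerate regions (fewer than 2 voxels) return all features as 0 with
#' attribute `degenerate = TRUE`, so downstream selection never sees NaNs.
#'
#' @param q a `quantized_region` from [discretize()].
#' @return Named numeric vector of length 90.
#' @export
texture_features <- function(q) {
  stopifnot(inherits(q, "quantized_region"))
  nm <- texture_feature_names()
  if (q$n_voxels < 2) {
    out <- setNames(numeric(length(nm)), nm)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  dims <- dim(q$levels)
  G <- q$G
  out <- c(
    glcm_features(.glcm_counts(q$levels, dims, G), G),
    glrlm_features(.glrlm_counts(q$levels, dims, G), q$n_voxels),
    glszm_features(.glszm_zones(q$levels, dims), q$n_voxels),
    gldm_features(.gldm_counts(q$levels, dims, G)),
    ngtdm_features(.ngtdm_counts(q$levels, dims, G))
  )
  stopifnot(identical(names(out), nm))
  out
}

texture_feature_names <- function() {
  g <- glcm_stat_names()
  c(as.vector(t(outer(g, c("mean", "range", "merged"), paste, sep = "_"))),
    paste0("glrlm_", c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv",
                       "rv", "re", "lglre", "hglre", "srlgle", "srhgle",
                       "lrlgle", "lrhgle")),
    paste0("glszm_", c("sae", "lae", "gln", "glnn", "szn", "sznn", "zp", "glv",
                       "zv", "ze", "lglze", "hglze", "salgle", "sahgle",
                       "lalgle", "lahgle")),
    paste0("gldm_", c("sde", "lde", "gln", "dn", "dnn", "glv", "dv", "de",
                      "lgle", "hgle", "sdlgle", "sdhgle", "ldlgle", "ldhgle")),
    paste0("ngtdm_", c("coarseness", "contrast", "busyness", "complexity",
                       "strength")))
}

glcm_stat_names <- function() {
  paste0("glcm_", c("autocorrelation", "cluster_prominence", "cluster_shade",
                    "contrast", "correlation", "difference_entropy",
                    "dissimilarity", "joint_energy", "joint_entropy",
                    "idm", "id", "max_probability", "sum_average"))
}

# 13 statistics of one normalized symmetric co-occurrence matrix
glcm_stats <- function(P) {
  G <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(seq_len(G) * px)
  sig2 <- sum((seq_len(G) - mu)^2 * px)
  pd <- vapply(0:(G - 1), function(k) sum(P[abs(i - j) == k]), numeric(1))
  pdnz <- pd[pd > 0]
  pnz <- P[P > 0]
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 1
  c(sum(i * j * P),
    sum((i + j - 2 * mu)^4 * P),
    sum((i + j - 2 * mu)^3 * P),
    sum((i - j)^2 * P),
    corr,
    -sum(pdnz * log2(pdnz)),
    sum(abs(i - j) * P),
    sum(P^2),
    -sum(pnz * log2(pnz)),
    sum(P / (1 + (i - j)^2)),
    sum(P / (1 + abs(i - j))),
    max(P),
    sum((i + j) * P))
}

glcm_features <- function(counts, G) {
  tot <- apply(counts, 3, sum)
  keep <- which(tot > 0)
  stats_per <- vapply(keep, function(t) glcm_stats(counts[, , t] / tot[t]),
                      numeric(13))
  merged <- apply(counts[, , keep, drop = FALSE], c(1, 2), sum)
  stats_merged <- glcm_stats(merged / sum(merged))
  vals <- as.vector(rbind(rowMeans(stats_per),
                          apply(stats_per, 1, max) - apply(stats_per, 1, min),
                          stats_merged))
  nm <- as.vector(t(outer(glcm_stat_names(), c("mean", "range", "merged"),
                          paste, sep = "_")))
  setNames(vals, nm)
}

glrlm_features <- function(R, np) {
  G <- nrow(R); L <- ncol(R)
  Nr <- sum(R)
  i <- row(R); l <- col(R)
  p <- R / Nr
  ri <- rowSums(R); rl <- colSums(R)
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  pnz <- p[p > 0]
  setNames(c(
    sum(R / l^2) / Nr,
    sum(R * l^2) / Nr,
    sum(ri^2) / Nr,
    sum(ri^2) / Nr^2,
    sum(rl^2) / Nr,
    sum(rl^2) / Nr^2,
    Nr / (13 * np),
    sum(p * (i - mu_i)^2),
    sum(p * (l - mu_l)^2),
    -sum(pnz * log2(pnz)),
    sum(R / i^2) / Nr,
    sum(R * i^2) / Nr,
    sum(R / (i^2 * l^2)) / Nr,
    sum(R * i^2 / l^2) / Nr,
    sum(R * l^2 / i^2) / Nr,
    sum(R * i^2 * l^2) / Nr
  ), paste0("glrlm_", c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp",
                        "glv", "rv", "re", "lglre", "hglre", "srlgle",
                        "srhgle", "lrlgle", "lrhgle")))
}

glszm_features <- function(zones, np) {
  lev <- zones$level
  siz <- zones$size
  Nz <- length(lev)
  ci <- table(lev)
  cs <- table(siz)
  cell <- table(paste(lev, siz))
  pcell <- as.numeric(cell) / Nz
  mu_i <- mean(lev); mu_s <- mean(siz)
  setNames(c(
    mean(1 / siz^2),
    mean(siz^2),
    sum(ci^2) / Nz,
    sum(ci^2) / Nz^2,
    sum(cs^2) / Nz,
    sum(cs^2) / Nz^2,
    Nz / np,
    mean((lev - mu_i)^2),
    mean((siz - mu_s)^2),
    -sum(pcell * log2(pcell)),
    mean(1 / lev^2),
    mean(lev^2),
    mean(1 / (lev^2 * siz^2)),
    mean(lev^2 / siz^2),
    mean(siz^2 / lev^2),
    mean(lev^2 * siz^2)
  ), paste0("glszm_", c("sae", "lae", "gln", "glnn", "szn", "sznn", "zp",
                        "glv", "zv", "ze", "lglze", "hglze", "salgle",
                        "sahgle", "lalgle", "lahgle")))
}

gldm_features <- function(D) {
  G <- nrow(D)
  Nz <- sum(D)
  i <- row(D); d <- col(D)  # dependence size 1..27 (center included)
  p <- D / Nz
  di <- rowSums(D); dd <- colSums(D)
  mu_i <- sum(i * p); mu_d <- sum(d * p)
  pnz <- p[p > 0]
  setNames(c(
    sum(D / d^2) / Nz,
    sum(D * d^2) / Nz,
    sum(di^2) / Nz,
    sum(dd^2) / Nz,
    sum(dd^2) / Nz^2,
    sum(p * (i - mu_i)^2),
    sum(p * (d - mu_d)^2),
    -sum(pnz * log2(pnz)),
    sum(D / i^2) / Nz,
    sum(D * i^2) / Nz,
    sum(D / (i^2 * d^2)) / Nz,
    sum(D * i^2 / d^2) / Nz,
    sum(D * d^2 / i^2) / Nz,
    sum(D * i^2 * d^2) / Nz
  ), paste0("gldm_", c("sde", "lde", "gln", "dn", "dnn", "glv", "dv", "de",
                       "lgle", "hgle", "sdlgle", "sdhgle", "ldlgle",
                       "ldhgle")))
}

ngtdm_features <- function(acc) {
  nvec <- acc$n; svec <- acc$s
  G <- length(nvec)
  Nvp <- sum(nvec)
  nm <- paste0("ngtdm_", c("coarseness", "contrast", "busyness", "complexity",
                           "strength"))
  if (Nvp == 0) return(setNames(numeric(5), nm))
  p <- nvec / Nvp
  act <- which(p > 0)
  Ngp <- length(act)
  lev <- seq_len(G)

  coars_den <- sum(p * svec)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6

  contrast <- 0
  if (Ngp > 1) {
    dif2 <- outer(lev[act], lev[act], function(a, b) (a - b)^2)
    contrast <- sum(outer(p[act], p[act]) * dif2) / (Ngp * (Ngp - 1)) *
      sum(svec) / Nvp
  }
  ip <- lev[act] * p[act]
  bus_den <- sum(abs(outer(ip, ip, "-")))
  busyness <- if (bus_den > 0) sum(p * svec) / bus_den else 0

  dif <- abs(outer(lev[act], lev[act], "-"))
  psum <- outer(p[act], p[act], "+")
  pssum <- outer(p[act] * svec[act], p[act] * svec[act], "+")
  complexity <- sum(dif * pssum / psum) / Nvp

  s_tot <- sum(svec)
  strength <- if (s_tot > 0) sum(psum * dif^2) / s_tot else 0

  setNames(c(coarseness, contrast, busyness, complexity, strength), nm)
}
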