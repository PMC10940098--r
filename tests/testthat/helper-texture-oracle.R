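# Loop-based re-derivations of every texture statistic from the naive
# matrices, mirroring the textbook definitions entry by entry.

oracle_glcm_stats13 <- function(M) {
  P <- M / sum(M)
  G <- nrow(P)
  px <- rowSums(P)
  mu <- 0
  for (i in 1:G) mu <- mu + i * px[i]
  sig2 <- 0
  for (i in 1:G) sig2 <- sig2 + (i - mu)^2 * px[i]
  ac <- cp <- cs <- ct <- ds <- je <- jh <- idm <- id <- sa <- 0
  cor_num <- 0
  pd <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    ac <- ac + i * j * p
    cp <- cp + (i + j - 2 * mu)^4 * p
    cs <- cs + (i + j - 2 * mu)^3 * p
    ct <- ct + (i - j)^2 * p
    cor_num <- cor_num + i * j * p
    ds <- ds + abs(i - j) * p
    je <- je + p^2
    if (p > 0) jh <- jh - p * log2(p)
    idm <- idm + p / (1 + (i - j)^2)
    id <- id + p / (1 + abs(i - j))
    sa <- sa + (i + j) * p
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p
  }
  de <- 0
  for (k in seq_along(pd)) if (pd[k] > 0) de <- de - pd[k] * log2(pd[k])
  corr <- if (sig2 > 0) (cor_num - mu^2) / sig2 else 1
  c(autocorrelation = ac, cluster_prominence = cp, cluster_shade = cs,
    contrast = ct, correlation = corr, difference_entropy = de,
    dissimilarity = ds, joint_energy = je, joint_entropy = jh,
    idm = idm, id = id, max_probability = max(P), sum_average = sa)
}

oracle_glrlm_stats <- function(R, np) {
  G <- nrow(R); L <- ncol(R)
  Nr <- sum(R)
  out <- setNames(numeric(16),
                  c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv",
                    "rv", "re", "lglre", "hglre", "srlgle", "srhgle",
                    "lrlgle", "lrhgle"))
  mu_i <- mu_l <- 0
  for (i in 1:G) for (l in 1:L) {
    p <- R[i, l] / Nr
    mu_i <- mu_i + i * p; mu_l <- mu_l + l * p
  }
  for (i in 1:G) for (l in 1:L) {
    r <- R[i, l]
    if (r == 0) next
    p <- r / Nr
    out["sre"] <- out["sre"] + r / l^2
    out["lre"] <- out["lre"] + r * l^2
    out["glv"] <- out["glv"] + p * (i - mu_i)^2
    out["rv"] <- out["rv"] + p * (l - mu_l)^2
    out["re"] <- out["re"] - p * log2(p)
    out["lglre"] <- out["lglre"] + r / i^2
    out["hglre"] <- out["hglre"] + r * i^2
    out["srlgle"] <- out["srlgle"] + r / (i^2 * l^2)
    out["srhgle"] <- out["srhgle"] + r * i^2 / l^2
    out["lrlgle"] <- out["lrlgle"] + r * l^2 / i^2
    out["lrhgle"] <- out["lrhgle"] + r * i^2 * l^2
  }
  for (nm in c("sre", "lre", "lglre", "hglre", "srlgle", "srhgle",
               "lrlgle", "lrhgle"))
    out[nm] <- out[nm] / Nr
  out["gln"] <- sum(rowSums(R)^2) / Nr
  out["glnn"] <- sum(rowSums(R)^2) / Nr^2
  out["rln"] <- sum(colSums(R)^2) / Nr
  out["rlnn"] <- sum(colSums(R)^2) / Nr^2
  out["rp"] <- Nr / (13 * np)
  out
}

oracle_glszm_stats <- function(zones, np) {
  lev <- zones$level; siz <- zones$size
  Nz <- length(lev)
  pc <- table(paste(lev, siz)) / Nz
  c(sae = mean(1 / siz^2), lae = mean(siz^2),
    gln = sum(table(lev)^2) / Nz, glnn = sum(table(lev)^2) / Nz^2,
    szn = sum(table(siz)^2) / Nz, sznn = sum(table(siz)^2) / Nz^2,
    zp = Nz / np,
    glv = mean((lev - mean(lev))^2), zv = mean((siz - mean(siz))^2),
    ze = -sum(pc * log2(pc)),
    lglze = mean(1 / lev^2), hglze = mean(lev^2),
    salgle = mean(1 / (lev^2 * siz^2)), sahgle = mean(lev^2 / siz^2),
    lalgle = mean(siz^2 / lev^2), lahgle = mean(lev^2 * siz^2))
}

oracle_gldm_stats <- function(D) {
  G <- nrow(D); K <- ncol(D)
  Nz <- sum(D)
  out <- setNames(numeric(14),
                  c("sde", "lde", "gln", "dn", "dnn", "glv", "dv", "de",
                    "lgle", "hgle", "sdlgle", "sdhgle", "ldlgle", "ldhgle"))
  mu_i <- mu_d <- 0
  for (i in 1:G) for (d in 1:K) {
    p <- D[i, d] / Nz
    mu_i <- mu_i + i * p; mu_d <- mu_d + d * p
  }
  for (i in 1:G) for (d in 1:K) {
    v <- D[i, d]
    if (v == 0) next
    p <- v / Nz
    out["sde"] <- out["sde"] + v / d^2
    out["lde"] <- out["lde"] + v * d^2
    out["glv"] <- out["glv"] + p * (i - mu_i)^2
    out["dv"] <- out["dv"] + p * (d - mu_d)^2
    out["de"] <- out["de"] - p * log2(p)
    out["lgle"] <- out["lgle"] + v / i^2
    out["hgle"] <- out["hgle"] + v * i^2
    out["sdlgle"] <- out["sdlgle"] + v / (i^2 * d^2)
    out["sdhgle"] <- out["sdhgle"] + v * i^2 / d^2
    out["ldlgle"] <- out["ldlgle"] + v * d^2 / i^2
    out["ldhgle"] <- out["ldhgle"] + v * i^2 * d^2
  }
  for (nm in c("sde", "lde", "lgle", "hgle", "sdlgle", "sdhgle", "ldlgle",
               "ldhgle"))
    out[nm] <- out[nm] / Nz
  out["gln"] <- sum(rowSums(D)^2) / Nz
  out["dn"] <- sum(colSums(D)^2) / Nz
  out["dnn"] <- sum(colSums(D)^2) / Nz^2
  out
}

oracle_ngtdm_stats <- function(acc, G) {
  nvec <- acc$n; svec <- acc$s
  Nvp <- sum(nvec)
  if (Nvp == 0) return(setNames(numeric(5),
    c("coarseness", "contrast", "busyness", "complexity", "strength")))
  p <- nvec / Nvp
  act <- which(p > 0)
  Ngp <- length(act)
  den <- sum(p * svec)
  coarseness <- if (den > 0) 1 / den else 1e6
  contrast <- 0
  if (Ngp > 1) {
    s <- 0
    for (i in act) for (j in act) s <- s + p[i] * p[j] * (i - j)^2
    contrast <- s / (Ngp * (Ngp - 1)) * sum(svec) / Nvp
  }
  bden <- 0
  for (i in act) for (j in act) bden <- bden + abs(i * p[i] - j * p[j])
  busyness <- if (bden > 0) den / bden else 0
  comp <- 0
  for (i in act) for (j in act)
    comp <- comp + abs(i - j) * (p[i] * svec[i] + p[j] * svec[j]) / (p[i] + p[j])
  comp <- comp / Nvp
  st <- 0
  for (i in act) for (j in act) st <- st + (p[i] + p[j]) * (i - j)^2
  strength <- if (sum(svec) > 0) st / sum(svec) else 0
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = comp, strength = strength)
}

# full 90-statistic oracle for a quantized region
oracle_texture_features <- function(q, G, np) {
  offs <- oracle_offsets()
  mats <- lapply(offs, function(o) oracle_glcm(q, G, o))
  tot <- vapply(mats, sum, numeric(1))
  keep <- which(tot > 0)
  per <- vapply(mats[keep], oracle_glcm_stats13, numeric(13))
  merged <- Reduce(`+`, mats[keep])
  mg <- oracle_glcm_stats13(merged)
  glcm <- as.vector(rbind(rowMeans(per),
                          apply(per, 1, max) - apply(per, 1, min), mg))
  names(glcm) <- as.vector(t(outer(
    paste0("glcm_", names(mg)), c("mean", "range", "merged"), paste, sep = "_")))
  c(glcm,
    setNames(oracle_glrlm_stats(oracle_glrlm(q, G), np),
             paste0("glrlm_", names(oracle_glrlm_stats(matrix(1, 1, 1), 1)))),
    setNames(oracle_glszm_stats(oracle_zones(q), np),
             paste0("glszm_", c("sae", "lae", "gln", "glnn", "szn", "sznn",
                                "zp", "glv", "zv", "ze", "lglze", "hglze",
                                "salgle", "sahgle", "lalgle", "lahgle"))),
    setNames(oracle_gldm_stats(oracle_gldm(q, G)),
             paste0("gldm_", names(oracle_gldm_stats(matrix(1, 1, 1))))),
    setNames(oracle_ngtdm_stats(oracle_ngtdm(q, G), G),
             paste0("ngtdm_", c("coarseness", "contrast", "busyness",
                                "complexity", "strength"))))
}
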