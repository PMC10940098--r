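# Programmatic fixtures shared across test files.

random_quantized <- function(dims, G, seed, p_mask = 0.8) {
  set.seed(seed)
  m <- array(runif(prod(dims)) < p_mask, dims)
  vol <- image_volume(array(rnorm(prod(dims)), dims))
  q <- array(0L, dims)
  q[m] <- sample.int(G, sum(m), replace = TRUE)
  structure(list(levels = q, G = as.integer(G), n_voxels = sum(m),
                 spacing = c(1, 1, 1)),
            class = "quantized_region")
}

toy_volume <- function(vals, dims = NULL) {
  if (is.null(dims)) dims <- c(length(vals), 1, 1)
  image_volume(array(vals, dims))
}

full_mask <- function(dims) voxel_mask(array(TRUE, dims))

# small PH-simulated survival sample
sim_surv <- function(n, beta_x, seed, shape = 1.2, scale = 48, horizon = 60) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  u <- runif(n)
  t_ev <- scale * (-log(u) * exp(-beta_x * x))^(1 / shape)
  cens <- runif(n, 0, horizon)
  data.frame(x = x, time = pmin(t_ev, cens), event = as.integer(t_ev <= cens))
}
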