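# Small, fast phantom configurations shared across tests. Uniform
# soft-tissue background (no lungs), noise and streaks off unless a test
# turns them on, so closed-form oracles apply.
quiet_phantom_spec <- function(..., grid_shape = c(32, 48, 48),
                               radius_mm = 10, height_mm = 16,
                               center = NULL, seed = 1) {
  args <- list(
    grid_shape = grid_shape, lung_hu = NA,
    implant = list(center = center, radius_mm = radius_mm,
                   height_mm = height_mm),
    bloom_sigma = 0, noise_sd = 0, streak = list(), seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(phantom_spec, args)
}

# Modify fields of an existing spec while keeping its class.
respec <- function(spec, ...) {
  mods <- list(...)
  for (nm in names(mods)) spec[[nm]] <- mods[[nm]]
  class(spec) <- "phantom_spec"
  spec
}

# Monte-Carlo ICC(C,k) of the discretized latent reader model; independent
# cross-check of the quadrature target used by the package's validation
# battery.
mc_icc_ck <- function(sq, se, cutpoints, k, n_cases = 20000, seed = 42) {
  set.seed(seed)
  latent <- rnorm(n_cases, 0, sq)
  scores <- vapply(seq_len(k), function(j)
    1 + colSums(outer(cutpoints, latent + rnorm(n_cases, 0, se), `<`)),
    numeric(n_cases))
  v <- var(as.vector(scores))
  cv <- mean(vapply(combn(k, 2, simplify = FALSE), function(ij)
    cov(scores[, ij[1]], scores[, ij[2]]), numeric(1)))
  rho1 <- cv / v
  k * rho1 / (1 + (k - 1) * rho1)
}
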