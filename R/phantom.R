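# Run expr with a local RNG state seeded by `seed`; the caller's
# .Random.seed is untouched, so all randomness flows through explicit seeds.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Separable 3-D Gaussian blur; sigma_vox per axis in voxel units. Kernels
# are truncated at 4 sigma and renormalized at the borders (convolution
# matrix rows sum to one).
gauss_blur3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(4 * s))
    offs <- -half:half
    kern <- exp(-offs^2 / (2 * s^2))
    n <- d[ax]
    K <- matrix(0, n, n)
    for (j in seq_along(offs)) {
      idx <- seq_len(n) + offs[j]
      ok <- idx >= 1 & idx <= n
      K[cbind(which(ok), idx[ok])] <- K[cbind(which(ok), idx[ok])] + kern[j]
    }
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    dd <- dim(a)
    a <- K %*% matrix(a, dd[1], dd[2] * dd[3])
    dim(a) <- dd
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Synthetic CT phantom specification
#'
#' Parameters of the synthetic thorax-like phantom: a soft-tissue body
#' ellipse with two lung ellipses inside an air background, a cylindrical
#' metal implant aligned with the slice axis, Gaussian pre-composite blur of
#' the implant (blooming), low-angular-order sinusoidal bright/dark streak
#' modulation around the implant, and additive Gaussian voxel noise.
#'
#' @param grid_shape integer length-3, volume dimensions in voxels
#'   (slice, row, column).
#' @param spacing voxel edge lengths (mm).
#' @param background_hu soft-tissue plateau (HU).
#' @param lung_hu lung plateau (HU); set `NA` to omit the lungs.
#' @param metal_hu implant plateau (HU); must exceed the soft-tissue range.
#' @param implant list with `center` (mm, (slice, row, col) physical
#'   coordinates; default volume center), `radius_mm` and `height_mm` of the
#'   cylinder (axis = slice axis).
#' @param contrast optional list(`center` (row, col) mm, `radius_mm`, `hu`)
#'   describing a contrast-filled cylinder spanning the implant height.
#' @param bloom_sigma Gaussian blur scale (mm) applied to the implant
#'   indicator before compositing; larger values push the fixed-threshold
#'   boundary outward, i.e. more blooming.
#' @param streak list of streak components, each
#'   list(`amplitude` HU, `order` >= 1 integer angular order, `phase` rad,
#'   `decay` mm radial decay length). The component adds
#'   `A * cos(order * theta + phase) * exp(-dist / decay)` outside the
#'   implant, `theta` being the polar angle about the implant axis and
#'   `dist` the distance to the implant surface.
#' @param noise_sd additive Gaussian noise SD (HU); must be >= 0.
#' @param seed integer seed; the generator is fully deterministic given the
#'   spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40, 64, 64),
                         spacing = c(1, 1, 1),
                         background_hu = 40,
                         lung_hu = -750,
                         metal_hu = 3000,
                         implant = list(center = NULL, radius_mm = 10,
                                        height_mm = 24),
                         contrast = NULL,
                         bloom_sigma = 0.8,
                         streak = list(list(amplitude = 60, order = 2,
                                            phase = 0, decay = 40)),
                         noise_sd = 15,
                         seed = 1) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            length(spacing) == 3L, all(spacing > 0))
  if (is.null(implant$center))
    implant$center <- (grid_shape - 1) * spacing / 2
  if (metal_hu <= background_hu + 500)
    stop("`metal_hu` must clearly exceed the soft-tissue range")
  if (implant$radius_mm <= 0 || implant$height_mm <= 0)
    stop("implant radius and height must be positive")
  if (bloom_sigma < 0) stop("`bloom_sigma` must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  for (s in streak) {
    if (s$amplitude < 0 || s$order < 1 || s$decay <= 0)
      stop("streak components need amplitude >= 0, order >= 1, decay > 0")
  }
  structure(
    list(grid_shape = grid_shape, spacing = spacing,
         background_hu = background_hu, lung_hu = lung_hu,
         metal_hu = metal_hu, implant = implant, contrast = contrast,
         bloom_sigma = bloom_sigma, streak = streak, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Generate a synthetic CT phantom volume with known ground truth
#'
#' Composites the phantom described by a [phantom_spec()]: background layers
#' (air, body, lungs, optional contrast), the Gaussian-blurred metal
#' implant, the angular streak field, and voxel noise. The implant's true
#' volume is computed analytically (`pi * r^2 * h`), giving a ground truth
#' for blooming measurements.
#'
#' @param spec a [phantom_spec()].
#' @return A list: `volume` ([ct_volume()]), `implant_mask` (logical array,
#'   the unblurred cylinder), `true_volume_cm3`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$spacing
  z <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  x <- (seq_len(d[3]) - 1) * sp[3]
  ctr <- spec$implant$center
  R <- spec$implant$radius_mm
  H <- spec$implant$height_mm

  dy <- matrix(y - ctr[2], d[2], d[3])
  dx <- matrix(x - ctr[3], d[2], d[3], byrow = TRUE)
  rho <- sqrt(dy^2 + dx^2)
  theta <- atan2(dx, dy)
  to3 <- function(m) aperm(array(m, c(d[2], d[3], d[1])), c(3, 1, 2))
  rho3 <- to3(rho)
  theta3 <- to3(theta)
  az <- array(abs(z - ctr[1]), d)  # varies along axis 1

  inside_half <- az <= H / 2
  if ((ctr[2] - R) < 0 || (ctr[2] + R) > max(y) ||
      (ctr[3] - R) < 0 || (ctr[3] + R) > max(x) ||
      (ctr[1] - H / 2) < 0 || (ctr[1] + H / 2) > max(z))
    stop("implant does not fit inside the grid")
  implant_mask <- rho3 <= R & inside_half

  # Background: air outside the body ellipse, soft tissue inside, lungs as
  # two ellipses flanking the implant.
  cy <- (d[2] - 1) * sp[2] / 2
  cx <- (d[3] - 1) * sp[3] / 2
  ay <- 0.45 * (d[2] - 1) * sp[2]
  ax <- 0.47 * (d[3] - 1) * sp[3]
  body <- to3((dy + ctr[2] - cy)^2 / ay^2 + (dx + ctr[3] - cx)^2 / ax^2 <= 1)
  bg <- array(-1000, d)
  bg[body] <- spec$background_hu
  if (!is.na(spec$lung_hu)) {
    off <- 0.55 * ax
    ly <- 0.5 * ay; lx <- 0.33 * ax
    for (s_ in c(-1, 1)) {
      lung <- to3((dy + ctr[2] - cy)^2 / ly^2 +
                    (dx + ctr[3] - (cx + s_ * off))^2 / lx^2 <= 1)
      bg[lung & body] <- spec$lung_hu
    }
  }
  if (!is.null(spec$contrast)) {
    cc <- spec$contrast
    con <- to3((dy + ctr[2] - cc$center[1])^2 +
                 (dx + ctr[3] - cc$center[2])^2 <= cc$radius_mm^2) & inside_half
    bg[con] <- cc$hu
  }

  m <- implant_mask + 0
  if (spec$bloom_sigma > 0)
    m <- gauss_blur3d(m, spec$bloom_sigma / sp)

  vol <- bg * (1 - m) + spec$metal_hu * m

  if (length(spec$streak) > 0) {
    dist <- sqrt(pmax(rho3 - R, 0)^2 + pmax(az - H / 2, 0)^2)
    outside <- !implant_mask
    for (s_ in spec$streak) {
      vol <- vol + outside * s_$amplitude *
        cos(s_$order * theta3 + s_$phase) * exp(-dist / s_$decay)
    }
  }

  if (spec$noise_sd > 0) {
    vol <- vol + with_seed(spec$seed,
                           array(stats::rnorm(prod(d), 0, spec$noise_sd), d))
  }

  list(
    volume = ct_volume(vol, spacing = sp),
    implant_mask = implant_mask,
    true_volume_cm3 = pi * R^2 * H / 1000,
    spec = spec
  )
}

#' Generate a battery of phantom cases over a parameter sweep
#'
#' Expands a parameter grid over phantom parameters, generates one phantom
#' per grid point (seeded `base$seed + i` for case `i`), and records the
#' swept covariates in a per-case skeleton table ready for the artifact
#' metrics.
#'
#' @param base a [phantom_spec()] providing all unswept parameters.
#' @param sweep named list of vectors. Names may be scalar spec fields
#'   (`bloom_sigma`, `noise_sd`, `metal_hu`, `background_hu`, `lung_hu`) or
#'   `streak_amplitude`, `streak_order`, `streak_phase`, `streak_decay`
#'   (applied to the first streak component).
#' @return A list: `cases` (list of [generate_phantom()] results) and
#'   `table` (data frame: `case_id`, swept parameters, `true_volume_cm3`).
#' @export
generate_case_battery <- function(base, sweep) {
  stopifnot(inherits(base, "phantom_spec"))
  if (!is.list(sweep) || length(sweep) == 0L || any(lengths(sweep) == 0L))
    stop("`sweep` must be a non-empty named list of non-empty vectors")
  scalar_fields <- c("bloom_sigma", "noise_sd", "metal_hu",
                     "background_hu", "lung_hu")
  streak_fields <- c(streak_amplitude = "amplitude", streak_order = "order",
                     streak_phase = "phase", streak_decay = "decay")
  bad <- setdiff(names(sweep), c(scalar_fields, names(streak_fields)))
  if (length(bad) > 0)
    stop("unknown sweep parameter(s): ", paste(bad, collapse = ", "))
  grid <- expand.grid(sweep, KEEP.OUT.ATTRS = FALSE)
  cases <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec_i <- base
    for (nm in names(grid)) {
      if (nm %in% scalar_fields) {
        spec_i[[nm]] <- grid[i, nm]
      } else {
        spec_i$streak[[1]][[streak_fields[[nm]]]] <- grid[i, nm]
      }
    }
    spec_i$seed <- base$seed + i
    class(spec_i) <- "phantom_spec"
    cases[[i]] <- generate_phantom(spec_i)
  }
  tab <- cbind(
    data.frame(case_id = seq_len(nrow(grid))), grid,
    true_volume_cm3 = vapply(cases, `[[`, numeric(1), "true_volume_cm3")
  )
  list(cases = cases, table = tab)
}

#' Reader-score simulation specification
#'
#' Describes an ordinal reader-score simulation: each case carries a latent
#' quality value; each reader's reading adds Gaussian noise; the noisy
#' latent value is discretized through four ordered cutpoints into scores
#' 1-5.
#'
#' @param n_cases number of cases.
#' @param n_readers number of readers (>= 2).
#' @param latent_quality numeric length `n_cases`, or `NULL` to draw
#'   standard-normal latent qualities under `seed`.
#' @param reader_sd reader noise SD (scalar, or length `n_readers`).
#' @param cutpoints four strictly increasing thresholds mapping latent
#'   values to scores 1-5.
#' @param questions character vector of question labels; each question gets
#'   independent reader noise around the same per-case latent quality.
#' @param seed integer seed.
#' @return An object of class `reader_sim_spec`.
#' @export
reader_sim_spec <- function(n_cases, n_readers = 6, latent_quality = NULL,
                            reader_sd = 1,
                            cutpoints = c(-1.5, -0.5, 0.5, 1.5),
                            questions = "Q1", seed = 1) {
  n_cases <- as.integer(n_cases)
  n_readers <- as.integer(n_readers)
  if (n_cases < 1L) stop("`n_cases` must be >= 1")
  if (n_readers < 2L) stop("`n_readers` must be >= 2")
  if (!is.null(latent_quality) && length(latent_quality) != n_cases)
    stop("`latent_quality` must have length n_cases")
  if (length(cutpoints) != 4L || any(diff(cutpoints) <= 0))
    stop("`cutpoints` must be 4 strictly increasing thresholds")
  if (any(reader_sd < 0) || !length(reader_sd) %in% c(1L, n_readers))
    stop("`reader_sd` must be a non-negative scalar or per-reader vector")
  structure(
    list(n_cases = n_cases, n_readers = n_readers,
         latent_quality = latent_quality,
         reader_sd = rep(reader_sd, length.out = n_readers),
         cutpoints = as.numeric(cutpoints),
         questions = as.character(questions), seed = as.integer(seed)),
    class = "reader_sim_spec"
  )
}

#' Simulate ordinal reader scores
#'
#' Draws `score(case, reader, question) = 1 + #\{cutpoints below
#' latent_quality[case] + noise\}` with independent reader noise per reading.
#' Deterministic for a fixed spec.
#'
#' @param spec a [reader_sim_spec()].
#' @return A long-format data frame of class `reader_scores` with columns
#'   `case_id`, `reader_id`, `question`, `score` (integers 1-5). The latent
#'   qualities used are attached as attribute `latent_quality`.
#' @export
simulate_reader_scores <- function(spec) {
  stopifnot(inherits(spec, "reader_sim_spec"))
  with_seed(spec$seed, {
    latent <- spec$latent_quality
    if (is.null(latent)) latent <- stats::rnorm(spec$n_cases)
    grid <- expand.grid(
      reader = seq_len(spec$n_readers),
      case_id = seq_len(spec$n_cases),
      question = spec$questions,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    eps <- stats::rnorm(nrow(grid), 0, spec$reader_sd[grid$reader])
    val <- latent[grid$case_id] + eps
    score <- 1L + rowSums(outer(val, spec$cutpoints, `>`))
    out <- data.frame(
      case_id = grid$case_id,
      reader_id = paste0("R", grid$reader),
      question = grid$question,
      score = as.integer(score),
      stringsAsFactors = FALSE
    )
    attr(out, "latent_quality") <- latent
    class(out) <- c("reader_scores", "data.frame")
    out
  })
}
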