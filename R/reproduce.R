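STUDY_CORR_VARS <- c("vg_sum", paste0("q", 1:6), "diff_hu", "sd_artifact",
                     "bloom_vol", "amplitude_low_freq")

#' Recompute the study's summary statistics from the bundled tables
#'
#' Runs the deterministic statistical pipeline on both bundled study
#' fixtures: Spearman correlation matrices between visual grading and the
#' objective artifact metrics, VG_SUM and BloomVol extrema, and the
#' log-linear blooming/streak/SD regression models (numeric keV coding,
#' stepwise AIC). When `out_dir` is given, a JSON report and a short
#' human-readable summary are written; repeated invocations produce
#' byte-identical output.
#'
#' @param out_dir optional output directory.
#' @return The report, invisibly: a nested list with one entry per fixture
#'   (`correlations`, `extrema`, `regression`) keyed by stable names.
#' @export
run_study_reproduction <- function(out_dir = NULL) {
  report <- list()
  for (name in c("phantom", "patient")) {
    fx <- load_fixture(name)
    rec <- fx$records
    cm <- spearman_matrix(rec, STUDY_CORR_VARS)
    metric_vars <- c("diff_hu", "sd_artifact", "bloom_vol",
                     "amplitude_low_freq")
    corr <- list()
    for (v in c("vg_sum", "q1")) {
      for (m in metric_vars) {
        corr[[paste(v, m, sep = "_vs_")]] <- list(
          rho = round(cm$rho[v, m], 6),
          p = round(cm$p[v, m], 6),
          n = cm$n_used[v, m]
        )
      }
    }
    extrema <- list(
      vg_sum_max = max(rec$vg_sum),
      vg_sum_min = min(rec$vg_sum),
      bloom_vol_max = max(rec$bloom_vol, na.rm = TRUE),
      bloom_vol_min = min(rec$bloom_vol, na.rm = TRUE),
      bloom_vol_n = sum(!is.na(rec$bloom_vol))
    )
    terms <- intersect(
      c(if (name == "phantom") "kvp", if (name == "phantom") "iq",
        "vmi", "kernel", "imar", "slice_mm"),
      names(rec)
    )
    regression <- list()
    for (resp in c("bloom_vol", "sd_artifact", "amplitude_low_freq")) {
      fit <- fit_metric_model(rec, resp, link = "log",
                              candidate_terms = terms,
                              selection = "stepwise_aic",
                              vmi_coding = "numeric")
      regression[[resp]] <- list(
        terms = fit$terms,
        adjusted_r2 = round(fit$adjusted_r2, 6),
        aic = round(fit$aic, 4),
        n = fit$n_obs, n_dropped = fit$n_dropped
      )
    }
    report[[name]] <- list(correlations = corr, extrema = extrema,
                           regression = regression)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    writeLines(json, file.path(out_dir, "study_reproduction.json"))
    txt <- c(
      "Study reproduction summary",
      vapply(names(report), function(nm) {
        e <- report[[nm]]$extrema
        sprintf("  %s: VG_SUM max %d, BloomVol %.1f..%.1f cm^3 (n=%d)",
                nm, e$vg_sum_max, e$bloom_vol_min, e$bloom_vol_max,
                e$bloom_vol_n)
      }, character(1))
    )
    writeLines(txt, file.path(out_dir, "study_reproduction.txt"))
  }
  invisible(report)
}

#' Validate the pipeline on synthetic data with known ground truth
#'
#' Executes a compact synthetic battery and reports a pass/fail verdict per
#' property: blooming volume non-decreasing in the blur scale and converging
#' to the analytic cylinder volume; streak amplitude responding linearly to
#' the modulation amplitude; ICC recovery against the discretized latent
#' model; and exact coefficient recovery of a noiseless log-linear model.
#'
#' @param seed integer seed for every stochastic component.
#' @param out_dir optional output directory for a JSON report.
#' @param invert_bloom_labels internal negative control: reverses the blur
#'   sweep labels, which must make the monotonicity property fail.
#' @return A list of class `synthetic_validation` with per-property entries
#'   (`pass` plus the measured quantities) and attribute `ok` (all passed).
#' @export
run_synthetic_validation <- function(seed = 7, out_dir = NULL,
                                     invert_bloom_labels = FALSE) {
  checks <- list()

  base <- phantom_spec(grid_shape = c(32, 48, 48), lung_hu = NA,
                       implant = list(center = NULL, radius_mm = 10,
                                      height_mm = 16),
                       bloom_sigma = 0, noise_sd = 0,
                       streak = list(), seed = seed)

  sigmas <- c(0, 0.5, 1, 1.5, 2)
  vols <- vapply(sigmas, function(sg) {
    sp <- base; sp$bloom_sigma <- sg; class(sp) <- "phantom_spec"
    compute_bloom_vol(generate_phantom(sp)$volume, lower = 800)$volume_cm3
  }, numeric(1))
  if (invert_bloom_labels) vols <- rev(vols)
  true_vol <- pi * 10^2 * 16 / 1000
  checks$bloom_monotone <- list(
    sigmas = sigmas, volumes = vols, true_volume_cm3 = true_vol,
    pass = !is.unsorted(vols) &&
      abs(vols[1] - true_vol) / true_vol < 0.03
  )

  amps <- c(10, 25, 40, 55, 70)
  alf <- vapply(amps, function(a) {
    sp <- base
    sp$streak <- list(list(amplitude = a, order = 1, phase = 0.4,
                           decay = 1e6))
    class(sp) <- "phantom_spec"
    compute_amplitude_low_freq(generate_phantom(sp)$volume,
                               center_slice = 15)$amplitude_low_freq
  }, numeric(1))
  r2 <- suppressWarnings(summary(stats::lm(alf ~ amps))$r.squared)
  checks$streak_linear <- list(amplitudes = amps, alf = alf, r_squared = r2,
                               pass = r2 > 0.99)

  sim <- reader_sim_spec(n_cases = 100, n_readers = 6,
                         reader_sd = sqrt(1.5),
                         cutpoints = c(-1.9, -0.63, 0.63, 1.9),
                         seed = seed)
  iccs <- vapply(1:25, function(i) {
    sp <- sim; sp$seed <- seed + i; class(sp) <- "reader_sim_spec"
    icc_inter(score_matrix(simulate_reader_scores(sp), "Q1"))$icc
  }, numeric(1))
  target <- icc_ck_discretized(1, sqrt(1.5), sim$cutpoints, 6)
  checks$icc_recovery <- list(mean_icc = mean(iccs), target = target,
                              pass = abs(mean(iccs) - target) < 0.05)

  set_n <- 40
  dat <- with_seed(seed, data.frame(
    kvp = sample(c(90, 120, 140), set_n, replace = TRUE),
    kernel = sample(c("Qr36f", "Bv56f"), set_n, replace = TRUE)
  ))
  beta <- c(b1 = -1.5, bk = -0.2)
  dat$resp <- exp(2 + beta["b1"] * log(dat$kvp) +
                    beta["bk"] * (dat$kernel == "Bv56f"))
  fit <- suppressWarnings(
    fit_metric_model(dat, "resp", link = "log",
                     candidate_terms = c("kvp", "kernel")))
  est <- fit$coefficients$estimate[match(c("kvp", "kernelBv56f"),
                                         fit$coefficients$term)]
  checks$loglinear_exact <- list(
    estimates = est, truth = unname(beta),
    adjusted_r2 = fit$adjusted_r2,
    pass = max(abs(est - beta)) < 1e-8 && abs(fit$adjusted_r2 - 1) < 1e-10
  )

  ok <- all(vapply(checks, `[[`, logical(1), "pass"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(
      jsonlite::toJSON(checks, auto_unbox = TRUE, digits = 8, pretty = TRUE),
      file.path(out_dir, "synthetic_validation.json"))
  }
  structure(checks, ok = ok, class = "synthetic_validation")
}

#' @export
print.synthetic_validation <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("  %-18s %s\n", nm, if (x[[nm]]$pass) "PASS" else "FAIL"))
  cat(if (attr(x, "ok")) "all properties pass\n" else "FAILURES present\n")
  invisible(x)
}

# Population ICC(C,k) of scores obtained by discretizing latent ~ N(0, sq^2)
# plus reader noise N(0, se^2) through ordered cutpoints: moments of the
# discretized scores by Gauss-Legendre-free 1-D quadrature (integrate()).
icc_ck_discretized <- function(sq, se, cutpoints, k) {
  surv <- function(q, cp) stats::pnorm((q - cp) / se)
  e_b <- vapply(cutpoints, function(cp) {
    stats::integrate(function(q) stats::dnorm(q, 0, sq) * surv(q, cp),
                     -Inf, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
  e_bb_same <- outer(seq_along(cutpoints), seq_along(cutpoints),
                     Vectorize(function(i, j) {
                       cp <- max(cutpoints[i], cutpoints[j])
                       stats::integrate(function(q)
                         stats::dnorm(q, 0, sq) * surv(q, cp),
                         -Inf, Inf, rel.tol = 1e-10)$value
                     }))
  e_bb_diff <- outer(seq_along(cutpoints), seq_along(cutpoints),
                     Vectorize(function(i, j) {
                       stats::integrate(function(q)
                         stats::dnorm(q, 0, sq) * surv(q, cutpoints[i]) *
                           surv(q, cutpoints[j]),
                         -Inf, Inf, rel.tol = 1e-10)$value
                     }))
  es <- sum(e_b)
  var_s <- sum(e_bb_same) - es^2
  cov_s <- sum(e_bb_diff) - es^2
  rho1 <- cov_s / var_s
  k * rho1 / (1 + (k - 1) * rho1)
}
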