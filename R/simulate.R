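#' Count noise model
#'
#' Counts are drawn negative-binomially around their expected occupancy with
#' `variance = mu + nb_dispersion * mu^2` (the technical component; internal
#' control sites receive only this). Signal sites additionally carry a
#' mean-one multiplicative lognormal biological factor with coefficient of
#' variation `biological_cv`, drawn once per (site, replicate) and shared
#' across the replicate's time points: replicates are independent cultures,
#' and their scatter is the biological variance the analysis attributes to
#' them.
#'
#' @param nb_dispersion negative-binomial dispersion (>= 0). 0 disables count
#'   noise entirely (deterministic rounding, no Poisson component), giving the
#'   exact noiseless limit used for oracle tests.
#' @param biological_cv lognormal CV of the per-replicate biological factor
#'   (>= 0), applied to signal sites only.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(nb_dispersion = 0.002, biological_cv = 0.30) {
  stopifnot(is.numeric(nb_dispersion), nb_dispersion >= 0,
            is.numeric(biological_cv), biological_cv >= 0)
  structure(list(nb_dispersion = nb_dispersion, biological_cv = biological_cv),
            class = "noise_model")
}

# NB draw parameterized by dispersion d: var = mu + d*mu^2 (size = 1/d).
# d = 0 is the exact noiseless limit: counts are the rounded means.
rnbinom_disp <- function(mu, dispersion) {
  if (dispersion == 0) return(round(mu))
  rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

# mean-one lognormal draws at a given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a parallel-factor ChIP-seq time course
#'
#' Generates raw counts with the statistical structure the downstream analysis
#' assumes: every library contains both the dynamic signal factor's sites and
#' a constant internal-control factor's sites; each sample's counts are scaled
#' by a confounding immunoprecipitation-efficiency x sequencing-depth factor
#' that the normalization must remove; signal sites carry extra biological
#' replicate-to-replicate noise. Ground truth (per-site dynamics, per-sample
#' effects, the noiseless occupancy table) is returned for parameter-recovery
#' scoring.
#'
#' Within a sample, the expected count of site j is
#' `occupancy_curve(spec_j, t) * strength_j * efficiency_i * depth_i`
#' (times the biological factor for signal sites), and counts are drawn
#' negative-binomially. Re-running with the same design (same seed) reproduces
#' the matrix exactly.
#'
#' @param design a [study_design()]; its `seed` drives all randomness.
#' @param dynamics named list of per-class [dynamics_spec()] defaults, as from
#'   [default_dynamics()].
#' @param noise a [noise_model()].
#' @param efficiency,depth optional explicit per-sample effect vectors
#'   (recycled checks apply); when `NULL` they are drawn lognormally with CVs
#'   `efficiency_cv` and `depth_cv`.
#' @param efficiency_cv,depth_cv lognormal CVs of the per-sample
#'   immunoprecipitation-efficiency and depth factors.
#' @param site_strength_sdlog lognormal sdlog of the per-site strength factor
#'   multiplying each signal site's whole occupancy curve (site-to-site
#'   affinity spread).
#' @param control_meanlog,control_sdlog lognormal parameters of the
#'   control-site expected counts (median `exp(control_meanlog)`, default 500).
#' @return an object of classes `pftc_dataset` and `pftc_counts`, with an
#'   additional `truth` component (site dynamics table, per-sample effects,
#'   expected noiseless occupancy matrix, seed).
#' @examples
#' ds <- simulate_timecourse(study_design(seed = 1))
#' dim(ds$counts)
#' @export
simulate_timecourse <- function(design = study_design(),
                                dynamics = default_dynamics(),
                                noise = noise_model(),
                                efficiency = NULL,
                                depth = NULL,
                                efficiency_cv = 0.25,
                                depth_cv = 0.10,
                                site_strength_sdlog = 0.15,
                                control_meanlog = log(500),
                                control_sdlog = 0.5) {
  stopifnot(inherits(design, "study_design"), inherits(noise, "noise_model"))
  classes <- names(design$n_sites_per_class)
  missing_dyn <- setdiff(classes, names(dynamics))
  if (length(missing_dyn)) {
    stop("no dynamics_spec supplied for class(es): ",
         paste(missing_dyn, collapse = ", "))
  }
  manifest <- sample_manifest(design)
  n_samp <- nrow(manifest)
  set.seed(design$seed)

  # per-sample confounders (the quantity normalization must recover)
  if (is.null(efficiency)) efficiency <- rlnorm_cv(n_samp, efficiency_cv)
  if (is.null(depth)) depth <- rlnorm_cv(n_samp, depth_cv)
  stopifnot(length(efficiency) == n_samp, all(efficiency > 0),
            length(depth) == n_samp, all(depth > 0))
  scale_i <- efficiency * depth * design$mean_depth

  # site tables: signal sites on chr1, control sites on chr2, 400 bp peaks
  n_sig <- sum(design$n_sites_per_class)
  class_of <- rep(classes, times = design$n_sites_per_class)
  width <- 400L
  sites <- rbind(
    data.frame(chrom = "chr1",
               start = seq_len(n_sig) * 1000L,
               site_id = sprintf("signal_%04d", seq_len(n_sig)),
               role = "signal", stringsAsFactors = FALSE),
    data.frame(chrom = "chr2",
               start = seq_len(design$n_control_sites) * 1000L,
               site_id = sprintf("control_%04d",
                                 seq_len(design$n_control_sites)),
               role = "control", stringsAsFactors = FALSE)
  )
  sites$end <- sites$start + width
  sites <- sites[, c("chrom", "start", "end", "site_id", "role")]

  # noiseless occupancy (sites x time points)
  tps <- design$time_points_min
  strength <- rlnorm(n_sig, meanlog = -site_strength_sdlog^2 / 2,
                     sdlog = site_strength_sdlog)
  occ_sig <- t(vapply(seq_len(n_sig), function(j) {
    strength[j] * occupancy_curve(dynamics[[class_of[j]]], tps)
  }, numeric(length(tps))))
  ctrl_strength <- rlnorm(design$n_control_sites,
                          meanlog = control_meanlog, sdlog = control_sdlog)
  occ_ctrl <- matrix(ctrl_strength, nrow = design$n_control_sites,
                     ncol = length(tps))
  expected <- rbind(occ_sig, occ_ctrl)
  dimnames(expected) <- list(sites$site_id, tps)

  # biological factor per (signal site, replicate), shared across time points
  bio <- matrix(rlnorm_cv(n_sig * design$n_replicates, noise$biological_cv),
                nrow = n_sig)

  tp_idx <- match(manifest$time_min, tps)
  counts <- matrix(0, nrow = nrow(sites), ncol = n_samp)
  for (i in seq_len(n_samp)) {
    mu <- expected[, tp_idx[i]] * scale_i[i]
    mu[seq_len(n_sig)] <- mu[seq_len(n_sig)] * bio[, manifest$replicate[i]]
    counts[, i] <- rnbinom_disp(mu, noise$nb_dispersion)
  }

  obj <- count_matrix(counts, sites, manifest)
  obj$truth <- list(
    sites = data.frame(
      site_id = sites$site_id,
      class_label = c(class_of, rep("control", design$n_control_sites)),
      strength = c(strength, ctrl_strength),
      stringsAsFactors = FALSE),
    dynamics = dynamics[classes],
    effects = data.frame(sample_id = manifest$sample_id,
                         efficiency = efficiency,
                         depth_factor = depth,
                         stringsAsFactors = FALSE),
    expected = expected,
    noise = unclass(noise),
    seed = design$seed
  )
  class(obj) <- c("pftc_dataset", class(obj))
  obj
}

#' @export
print.pftc_dataset <- function(x, ...) {
  NextMethod()
  tab <- table(x$truth$sites$class_label)
  cat("  ground truth classes: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "; seed ", x$truth$seed, "\n", sep = "")
  invisible(x)
}
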