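#' Experimental design of a binding time course
#'
#' Describes the sample grid (time points x replicates) and the site
#' composition of a synthetic parallel-factor ChIP time course. The default
#' reproduces the study layout: 10 time points spanning 0-90 min at 10 min
#' resolution, 6 biological replicates (60 signal-target samples), 2000
#' internal-control sites and 2500 signal sites split over the dynamic
#' classes.
#'
#' @param time_points_min strictly increasing, non-negative times in minutes.
#' @param n_replicates number of biological replicates per time point.
#' @param n_control_sites number of constitutively bound internal-control
#'   sites per library.
#' @param n_sites_per_class named integer vector mapping class labels
#'   (see [dynamics_spec()]) to site counts.
#' @param mean_depth global expected-depth multiplier (arbitrary units; the
#'   per-class occupancy scales already carry the read-count magnitudes).
#' @param seed integer seed driving all randomness of the generator.
#' @return an object of class `study_design`.
#' @export
study_design <- function(time_points_min = seq(0, 90, by = 10),
                         n_replicates = 6,
                         n_control_sites = 2000,
                         n_sites_per_class = c(A = 400, C = 1200,
                                               B = 400, null = 500),
                         mean_depth = 1,
                         seed = 1L) {
  stopifnot(is.numeric(time_points_min), length(time_points_min) >= 2,
            all(time_points_min >= 0), !is.unsorted(time_points_min,
                                                    strictly = TRUE))
  if (n_replicates < 1 || n_control_sites < 1) {
    stop("design dimensions must be positive")
  }
  if (is.null(names(n_sites_per_class)) ||
      !all(names(n_sites_per_class) %in%
           c("A", "C", "B", "null", "cyclical"))) {
    stop("n_sites_per_class must be named with known class labels")
  }
  if (any(n_sites_per_class < 0) || sum(n_sites_per_class) < 1) {
    stop("design dimensions must be positive")
  }
  stopifnot(is.numeric(mean_depth), mean_depth > 0)
  structure(
    list(time_points_min = as.numeric(time_points_min),
         n_replicates = as.integer(n_replicates),
         n_control_sites = as.integer(n_control_sites),
         n_sites_per_class = n_sites_per_class,
         mean_depth = mean_depth,
         seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Sample manifest for a design
#'
#' One row per signal-target library: sample id, time point and replicate.
#'
#' @param design a [study_design()].
#' @return data.frame with columns `sample_id`, `time_min`, `replicate`.
#' @export
sample_manifest <- function(design) {
  stopifnot(inherits(design, "study_design"))
  grid <- expand.grid(replicate = seq_len(design$n_replicates),
                      time_min = design$time_points_min,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$time_min, grid$replicate), c("time_min", "replicate")]
  out <- data.frame(
    sample_id = sprintf("t%02d_r%d", grid$time_min, grid$replicate),
    time_min = grid$time_min,
    replicate = grid$replicate,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

validate_manifest <- function(manifest) {
  req <- c("sample_id", "time_min", "replicate")
  if (!all(req %in% names(manifest))) {
    stop("manifest must have columns ", paste(req, collapse = ", "))
  }
  key <- paste(manifest$time_min, manifest$replicate)
  if (anyDuplicated(key)) stop("(time_min, replicate) pairs must be unique")
  grid <- table(manifest$time_min)
  if (length(unique(grid)) != 1L) {
    stop("manifest does not cover a full time x replicate grid")
  }
  invisible(manifest)
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "<study_design> %d time points (%g-%g min) x %d replicates = %d samples\n",
    length(x$time_points_min), min(x$time_points_min), max(x$time_points_min),
    x$n_replicates, length(x$time_points_min) * x$n_replicates))
  cat(sprintf("  signal sites: %s; control sites: %d; seed %d\n",
              paste(sprintf("%s=%d", names(x$n_sites_per_class),
                            x$n_sites_per_class), collapse = ", "),
              x$n_control_sites, x$seed))
  invisible(x)
}
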