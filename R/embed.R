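#' t-SNE embedding of site binding profiles
#'
#' Embeds the replicate-averaged time profiles of the signal sites (10
#' dimensions under the default design) into two dimensions with Barnes-Hut
#' t-SNE. The embedding is for visualization and stability checks of the
#' trajectory structure; classification never uses it. Runs single-threaded
#' so a fixed seed reproduces coordinates exactly.
#'
#' @param x a `pftc_binding` (or `pftc_counts`); only signal sites are
#'   embedded.
#' @param perplexity t-SNE perplexity; must satisfy
#'   `1 < perplexity < n_sites / 3`.
#' @param seed integer seed (recorded in the result).
#' @param max_iter gradient iterations.
#' @return data.frame of class `pftc_embedding` (`site_id`, `x`, `y`) with
#'   attributes `perplexity`, `seed` and `input` (a description of the
#'   embedded matrix).
#' @export
embed_sites <- function(x, perplexity = 50, seed = 42, max_iter = 1000) {
  prof <- collapse_replicates(x)[x$sites$role == "signal", , drop = FALSE]
  n <- nrow(prof)
  if (!(perplexity > 1 && perplexity < n / 3)) {
    stop("perplexity must satisfy 1 < perplexity < n_sites/3 = ", n / 3)
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(prof, dims = 2, perplexity = perplexity,
                      pca = FALSE, check_duplicates = FALSE,
                      max_iter = max_iter, num_threads = 1)
  out <- data.frame(site_id = rownames(prof),
                    x = fit$Y[, 1], y = fit$Y[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "perplexity") <- perplexity
  attr(out, "seed") <- seed
  attr(out, "input") <- sprintf(
    "replicate-averaged occupancy profiles, %d sites x %d time points",
    n, ncol(prof))
  class(out) <- c("pftc_embedding", class(out))
  out
}

#' Perplexity stability sweep
#'
#' Runs [embed_sites()] over a list of perplexities (default the 2-200 sweep)
#' and records each embedding; used to confirm that the trajectory structure
#' is stable for moderate-to-high perplexity and degrades only at very low
#' values.
#'
#' @inheritParams embed_sites
#' @param perplexities perplexity values to test.
#' @return named list of `pftc_embedding` objects.
#' @export
perplexity_sweep <- function(x, perplexities = c(2, 5, 30, 50, 100, 200),
                             seed = 42, max_iter = 1000) {
  out <- lapply(perplexities, function(p) {
    embed_sites(x, perplexity = p, seed = seed, max_iter = max_iter)
  })
  names(out) <- as.character(perplexities)
  out
}

#' Separation score between two site groups in an embedding
#'
#' Distance between the two group centroids divided by the mean of the two
#' within-group root-mean-square spreads. Large values mean the groups occupy
#' distinct regions of the map.
#'
#' @param embedding a `pftc_embedding`.
#' @param classes named character vector (or data.frame with `site_id`,
#'   `class`) giving a group label per site.
#' @param groups the two labels to score (default `c("A", "B")`).
#' @return the separation score (a single number).
#' @export
class_separation <- function(embedding, classes, groups = c("A", "B")) {
  if (is.data.frame(classes)) {
    classes <- stats::setNames(classes$class, classes$site_id)
  }
  lab <- classes[embedding$site_id]
  xy <- cbind(embedding$x, embedding$y)
  cent <- lapply(groups, function(g) colMeans(xy[lab %in% g, , drop = FALSE]))
  spread <- vapply(groups, function(g) {
    m <- xy[lab %in% g, , drop = FALSE]
    sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
  }, numeric(1))
  sqrt(sum((cent[[1]] - cent[[2]])^2)) / mean(spread)
}

#' @export
print.pftc_embedding <- function(x, ...) {
  cat(sprintf("<pftc_embedding> %d sites, perplexity %g, seed %d\n",
              nrow(x), attr(x, "perplexity"), attr(x, "seed")))
  invisible(x)
}
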