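# sites data.frame (0-based half-open) <-> GRanges (1-based closed)
sites_to_granges <- function(sites) {
  gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end)
  )
  if (!is.null(sites$site_id)) gr$name <- sites$site_id
  gr
}

granges_to_sites <- function(gr, role = NA_character_) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  nm <- if (!is.null(gr$name)) as.character(gr$name) else
    sprintf("site_%05d", seq_along(gr))
  df$site_id <- nm
  df$role <- role
  df
}

io_fail <- function(path, what) {
  stop(what, " failed for path: ", path, call. = FALSE)
}

#' Write a simulated dataset as a plain-text fixture
#'
#' Emits the sample manifest (TSV), signal and control site intervals (BED,
#' 0-based half-open, site ids in the name column), the raw count matrix (TSV,
#' sites as rows, header row of sample ids) and the ground truth (JSON,
#' including the generator seed). The files round-trip losslessly through
#' [read_fixture()].
#'
#' @param dataset a `pftc_dataset` from [simulate_timecourse()] (or any
#'   `pftc_counts`; ground truth is written only when present).
#' @param dir output directory, created if needed.
#' @return invisibly, the named vector of paths written.
#' @export
write_fixture <- function(dataset, dir) {
  stopifnot(inherits(dataset, "pftc_counts"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    io_fail(dir, "creating fixture directory")
  }
  paths <- c(manifest = file.path(dir, "manifest.tsv"),
             counts = file.path(dir, "counts.tsv"),
             signal_bed = file.path(dir, "signal_sites.bed"),
             control_bed = file.path(dir, "control_sites.bed"),
             truth = file.path(dir, "ground_truth.json"))
  tryCatch({
    utils::write.table(dataset$manifest, paths["manifest"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cts <- data.frame(site_id = rownames(dataset$counts), dataset$counts,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(cts, paths["counts"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (role in c("signal", "control")) {
      gr <- sites_to_granges(dataset$sites[dataset$sites$role == role, ,
                                           drop = FALSE])
      rtracklayer::export(gr, paths[[paste0(role, "_bed")]], format = "BED")
    }
  }, error = function(e) {
    stop("writing fixture under ", dir, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.null(dataset$truth)) {
    truth <- dataset$truth
    truth$dynamics <- lapply(truth$dynamics, unclass)
    truth$expected <- list(site_id = rownames(truth$expected),
                           time_min = as.numeric(colnames(truth$expected)),
                           occupancy = unname(
                             split(truth$expected,
                                   row(truth$expected))))
    jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                         digits = NA, null = "null")
  } else {
    paths <- paths[names(paths) != "truth"]
  }
  invisible(paths)
}

#' Read a fixture directory back into a count container
#'
#' Counterpart of [write_fixture()]; also accepts externally produced inputs
#' in the same layout (per-sample peak calls reduced to two BED site sets, a
#' count TSV and a manifest TSV).
#'
#' @param dir fixture directory, or `NULL` to pass the four paths explicitly.
#' @param counts,manifest,signal_bed,control_bed explicit file paths
#'   (override the defaults derived from `dir`).
#' @return a `pftc_counts`; if `ground_truth.json` is present the result also
#'   carries `truth` and inherits `pftc_dataset`.
#' @export
read_fixture <- function(dir = NULL,
                         counts = file.path(dir, "counts.tsv"),
                         manifest = file.path(dir, "manifest.tsv"),
                         signal_bed = file.path(dir, "signal_sites.bed"),
                         control_bed = file.path(dir, "control_sites.bed")) {
  for (p in c(counts, manifest, signal_bed, control_bed)) {
    if (!file.exists(p)) io_fail(p, "reading fixture input")
  }
  man <- utils::read.table(manifest, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  cts <- utils::read.table(counts, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(cts[, -1, drop = FALSE])
  rownames(mat) <- cts$site_id
  sig <- granges_to_sites(rtracklayer::import(signal_bed, format = "BED"),
                          role = "signal")
  ctl <- granges_to_sites(rtracklayer::import(control_bed, format = "BED"),
                          role = "control")
  sites <- rbind(sig, ctl)
  sites <- sites[match(rownames(mat), sites$site_id), ]
  if (anyNA(sites$site_id)) {
    stop("count rows not covered by the BED site sets")
  }
  obj <- count_matrix(mat[, man$sample_id, drop = FALSE], sites, man)
  truth_path <- if (!is.null(dir)) file.path(dir, "ground_truth.json") else ""
  if (nzchar(truth_path) && file.exists(truth_path)) {
    obj$truth <- read_ground_truth(truth_path)
    class(obj) <- c("pftc_dataset", class(obj))
  }
  obj
}

#' Read a ground-truth JSON written by [write_fixture()]
#' @param path path to `ground_truth.json`.
#' @return the truth list (site classes, per-sample effects, expected
#'   occupancy matrix, noise parameters, seed).
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) io_fail(path, "reading ground truth")
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  occ <- truth$expected$occupancy
  if (is.list(occ)) occ <- do.call(rbind, occ)
  dimnames(occ) <- list(truth$expected$site_id, truth$expected$time_min)
  truth$expected <- occ
  truth
}

#' Write a normalized binding matrix (or factors table) as TSV
#'
#' @param x a `pftc_binding`, or the factor vector from [derive_factors()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_binding_tsv <- function(x, path) {
  if (inherits(x, "pftc_binding")) {
    df <- data.frame(site_id = rownames(x$values), x$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(sample_id = names(x), factor = as.numeric(x),
                     method = attr(x, "method"),
                     reference = attr(x, "reference"),
                     stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
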