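#' Write an expression data set as TSV exchange files
#'
#' Writes the standard three-file exchange used throughout the pipeline:
#' `matrix.tsv` (feature_id column plus one column per sample),
#' `samples.tsv` (sample sheet) and `features.tsv` (feature sheet).
#'
#' @param x A `phx_expr` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the three files.
#' @seealso [read_expression()]
#' @export
write_expression <- function(x, dir) {
  stopifnot(inherits(x, "phx_expr"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.tsv", "samples.tsv", "features.tsv"))
  mat <- data.frame(feature_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(mat, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$samples, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$features, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read an expression data set from TSV exchange files
#'
#' Reads and validates the three-file exchange written by
#' [write_expression()]: an intensity matrix (feature_id + one column per
#' sample), a sample sheet (`sample_id`, `time_min`, `replicate`,
#' `condition`) and a feature sheet (`feature_id`, `organism`, ...).
#' Non-positive intensities are floored to `floor_epsilon` (default: the
#' smallest positive value in the matrix) with a logged count.
#'
#' @param matrix_path,sample_sheet_path,feature_sheet_path File paths.
#' @param floor_epsilon Positive replacement value for non-positive cells;
#'   `NULL` uses the smallest positive intensity present.
#' @return A `phx_expr` object.
#' @export
read_expression <- function(matrix_path, sample_sheet_path,
                            feature_sheet_path, floor_epsilon = NULL) {
  mat <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  samples <- read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  features <- read.delim(feature_sheet_path, stringsAsFactors = FALSE)

  .phx_stopifnot_cols(mat, "feature_id", "expression matrix")
  .phx_stopifnot_cols(samples, c("sample_id", "time_min", "replicate",
                                 "condition"), "sample sheet")
  .phx_stopifnot_cols(features, c("feature_id", "organism"), "feature sheet")
  if (any(is.na(samples$time_min)) || any(is.na(samples$replicate))) {
    stop("sample sheet has missing time_min/replicate metadata")
  }
  bad_org <- setdiff(unique(features$organism), c("phage", "host"))
  if (length(bad_org)) {
    stop("unknown organism tag(s) in feature sheet: ",
         paste(bad_org, collapse = ", "))
  }
  if (anyDuplicated(mat$feature_id)) {
    stop("duplicate feature ids in expression matrix")
  }

  values <- as.matrix(mat[, setdiff(names(mat), "feature_id"), drop = FALSE])
  rownames(values) <- mat$feature_id
  if (!all(samples$sample_id %in% colnames(values))) {
    stop("sample sheet lists samples absent from the expression matrix")
  }
  values <- values[, samples$sample_id, drop = FALSE]
  if (!all(rownames(values) %in% features$feature_id)) {
    stop("expression matrix has features absent from the feature sheet")
  }
  features <- features[match(rownames(values), features$feature_id), ,
                       drop = FALSE]
  rownames(features) <- NULL

  nonpos <- !is.finite(values) | values <= 0
  if (any(nonpos)) {
    if (is.null(floor_epsilon)) {
      pos <- values[!nonpos & values > 0]
      if (!length(pos)) stop("matrix has no positive intensities")
      floor_epsilon <- min(pos)
    }
    message(sprintf("floored %d non-positive intensity cell(s) to %g",
                    sum(nonpos), floor_epsilon))
    values[nonpos] <- floor_epsilon
  }

  structure(list(values = values, samples = samples, features = features),
            class = "phx_expr")
}

#' Normalize intensities to a housekeeping reference feature
#'
#' Divides each sample's intensities by that sample's intensity of the
#' housekeeping reference feature (e.g. 16S rRNA), removing per-array
#' scaling; the reference row becomes exactly 1 everywhere. Phage and host
#' features are normalized jointly by the same per-sample divisor. The
#' operation is idempotent.
#'
#' @param x A `phx_expr` object.
#' @param reference_feature Id of the reference feature; must be present
#'   with positive intensity in every sample.
#' @return A normalized `phx_expr`.
#' @export
normalize_to_reference <- function(x, reference_feature = "16S") {
  stopifnot(inherits(x, "phx_expr"))
  if (!reference_feature %in% rownames(x$values)) {
    stop(sprintf("reference feature '%s' not found", reference_feature))
  }
  ref <- x$values[reference_feature, ]
  if (any(!is.finite(ref) | ref <= 0)) {
    stop(sprintf("reference feature '%s' must be positive in every sample",
                 reference_feature))
  }
  x$values <- sweep(x$values, 2, ref, `/`)
  x
}

#' Summarize phage probe rows to ORF rows
#'
#' Collapses multi-probe phage features to one row per ORF using the
#' per-sample median across that ORF's probes (robust to the 2-16
#' probes-per-ORF design). Host rows pass through unchanged.
#'
#' @param x A `phx_expr` whose phage features carry an `orf_id` column in
#'   the feature sheet.
#' @return A `phx_expr` with one row per phage ORF.
#' @export
summarize_probes <- function(x) {
  stopifnot(inherits(x, "phx_expr"))
  ph <- x$features$organism == "phage"
  if (!any(ph)) return(x)
  if (is.null(x$features$orf_id) || any(is.na(x$features$orf_id[ph]))) {
    stop("phage features must carry probe-to-ORF links (orf_id)")
  }
  orf_of <- x$features$orf_id[ph]
  probe_vals <- x$values[x$features$feature_id[ph], , drop = FALSE]
  orfs <- unique(orf_of)
  summarized <- t(vapply(orfs, function(o) {
    apply(probe_vals[orf_of == o, , drop = FALSE], 2, median)
  }, numeric(ncol(x$values))))
  rownames(summarized) <- orfs

  keep <- x$features[!ph, , drop = FALSE]
  first <- x$features[ph, ][match(orfs, orf_of), , drop = FALSE]
  first$feature_id <- orfs
  values <- rbind(x$values[keep$feature_id, , drop = FALSE], summarized)
  features <- rbind(keep, first)
  rownames(features) <- NULL
  structure(list(values = values, samples = x$samples, features = features),
            class = "phx_expr")
}

#' Log2 fold changes against the uninfected reference time point
#'
#' For every feature and every post-reference time point, computes
#' `log2(mean over replicates at t / mean over replicates at the reference
#' time)`, using arithmetic means of (normalized) intensities.
#'
#' @param x A `phx_expr` (normalize first for housekeeping-referenced fold
#'   changes).
#' @param reference_time Reference time in minutes (default 0, the
#'   uninfected samples).
#' @param condition Restrict to samples of this condition; `NULL` uses all.
#' @return A numeric matrix (features x post-reference time points) of
#'   class `phx_fc`, with column names the times in minutes, and the
#'   feature sheet attached as attribute `"features"`.
#' @export
log_fold_change <- function(x, reference_time = 0, condition = NULL) {
  stopifnot(inherits(x, "phx_expr"))
  samples <- x$samples
  keep <- if (is.null(condition)) rep(TRUE, nrow(samples)) else {
    samples$condition == condition
  }
  samples <- samples[keep, , drop = FALSE]
  values <- x$values[, keep, drop = FALSE]
  times <- sort(unique(samples$time_min))
  if (!reference_time %in% times) {
    stop(sprintf("reference time %g min has no samples", reference_time))
  }
  means <- vapply(times, function(t) {
    cols <- samples$time_min == t
    if (!any(cols)) stop(sprintf("no replicates at %g min", t))
    rowMeans(values[, cols, drop = FALSE])
  }, numeric(nrow(values)))
  colnames(means) <- times
  ref <- means[, as.character(reference_time)]
  post <- setdiff(times, reference_time)
  fc <- log2(means[, as.character(post), drop = FALSE] / ref)
  structure(fc, class = c("phx_fc", class(fc)),
            times = post, features = x$features)
}

#' Compute burst size from a one-step growth curve
#'
#' Detects the initial (latent) and terminal plateaus of the curve as the
#' maximal prefix and suffix whose titers stay within `tol` (default 10%)
#' of their own mean, and returns `(mean terminal plateau - mean latent
#' plateau) / infected_cells` -- progeny phage per infected cell.
#'
#' @param g A `phx_growth` object, or a list with `times`, `titers`,
#'   `infected_cells`.
#' @param tol Relative tolerance defining a plateau.
#' @return Burst size (a number). A degenerate curve whose points all lie
#'   in one plateau returns 0 with a warning.
#' @export
compute_burst_size <- function(g, tol = 0.1) {
  titers <- g$titers
  n <- length(titers)
  if (n < 2) stop("growth curve needs at least two time points")
  if (is.null(g$infected_cells) || g$infected_cells <= 0) {
    stop("infected_cells must be positive")
  }
  flat <- function(v) {
    m <- mean(v)
    m > 0 && max(abs(v - m)) <= tol * m
  }
  pre <- max(which(vapply(seq_len(n), function(k) flat(titers[1:k]), TRUE)))
  suf <- max(which(vapply(seq_len(n), function(k) flat(titers[(n - k + 1):n]),
                          TRUE)))
  if (pre >= n || suf >= n) {
    warning("degenerate growth curve: all points lie in one plateau")
    return(0)
  }
  (mean(titers[(n - suf + 1):n]) - mean(titers[1:pre])) / g$infected_cells
}
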