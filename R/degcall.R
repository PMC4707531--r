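#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts p-values by the Benjamini-Hochberg step-up procedure
#' (q_(i) = min over j >= i of p_(j) * m / j, capped at 1, returned in
#' input order), controlling the false discovery rate. Thin wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector of p-values in \\[0, 1\\].
#' @return q-values in input order; empty input returns empty output.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

# Vectorized one-way ANOVA across the rows of two replicate groups.
# With two groups this is the equal-variance F-test (the square of the
# pooled t); zero variance with equal means yields p = 1 by convention,
# zero variance with unequal means p = 0.
.phx_row_anova <- function(a, b) {
  n1 <- ncol(a)
  n0 <- ncol(b)
  if (n1 < 2 || n0 < 2) stop("need >= 2 replicates in each group")
  m1 <- rowMeans(a)
  m0 <- rowMeans(b)
  gm <- (n1 * m1 + n0 * m0) / (n1 + n0)
  ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  ssw <- rowSums((a - m1)^2) + rowSums((b - m0)^2)
  df2 <- n1 + n0 - 2
  f <- (ssb / 1) / (ssw / df2)
  p <- pf(f, 1, df2, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1
  p[ssw == 0 & ssb > 0] <- 0
  p
}

#' Call differentially expressed host genes at one time point
#'
#' For every host gene, runs a one-way ANOVA on log2 normalized replicate
#' intensities (infected at time `t` vs the uninfected reference),
#' adjusts the p-values across all host genes at this time point by
#' Benjamini-Hochberg, and emits a DEG record iff the fold change (ratio
#' of arithmetic replicate means) exceeds `fc_threshold` in either
#' direction AND the adjusted q (or, with `use_q = FALSE`, the raw p)
#' falls below `q_threshold`.
#'
#' @param x A normalized `phx_expr`.
#' @param t Time point in minutes (must have >= 2 replicates, as must the
#'   reference).
#' @param fc_threshold Fold-change threshold (default 2; the test is
#'   strict: `fold change > fc_threshold`).
#' @param q_threshold Significance threshold on q (default 0.05).
#' @param use_q If `FALSE`, threshold the raw ANOVA p instead of q.
#' @param reference_time Reference time (default 0 min).
#' @return Data frame of DEG records (`gene_id`, `time_min`, `log2fc`,
#'   `p`, `q`, `direction`), with the tested host gene universe attached
#'   as attribute `"universe"`.
#' @export
call_degs_at_timepoint <- function(x, t, fc_threshold = 2,
                                   q_threshold = 0.05, use_q = TRUE,
                                   reference_time = 0) {
  stopifnot(inherits(x, "phx_expr"))
  host <- x$features$organism == "host" & !x$features$is_reference
  genes <- x$features$feature_id[host]
  cols1 <- x$samples$time_min == t
  cols0 <- x$samples$time_min == reference_time
  if (sum(cols1) < 2 || sum(cols0) < 2) {
    stop(sprintf("need >= 2 replicates at %g and %g min", t, reference_time))
  }
  v1 <- x$values[genes, cols1, drop = FALSE]
  v0 <- x$values[genes, cols0, drop = FALSE]

  p <- .phx_row_anova(log2(v1), log2(v0))
  q <- bh_adjust(p)
  log2fc <- log2(rowMeans(v1) / rowMeans(v0))
  stat <- if (use_q) q else p
  called <- abs(log2fc) > log2(fc_threshold) & stat < q_threshold
  out <- data.frame(
    gene_id = genes[called],
    time_min = rep(t, sum(called)),
    log2fc = unname(log2fc[called]),
    p = unname(p[called]),
    q = unname(q[called]),
    direction = ifelse(log2fc[called] > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
  attr(out, "universe") <- genes
  out
}

#' Call DEGs at every post-reference time point
#'
#' Convenience wrapper running [call_degs_at_timepoint()] at each
#' post-reference time of the sample sheet and binding the records.
#'
#' @inheritParams call_degs_at_timepoint
#' @param times Time points to test; defaults to all post-reference times.
#' @return Combined DEG record data frame (attribute `"universe"` kept).
#' @export
call_degs <- function(x, times = NULL, fc_threshold = 2, q_threshold = 0.05,
                      use_q = TRUE, reference_time = 0) {
  if (is.null(times)) {
    times <- setdiff(sort(unique(x$samples$time_min)), reference_time)
  }
  recs <- lapply(times, call_degs_at_timepoint, x = x,
                 fc_threshold = fc_threshold, q_threshold = q_threshold,
                 use_q = use_q, reference_time = reference_time)
  out <- do.call(rbind, recs)
  attr(out, "universe") <- attr(recs[[1]], "universe")
  out
}

#' Aggregate per-timepoint DEG records into a summary
#'
#' Builds the aggregated DEG summary: per-timepoint up/down counts, the
#' unique up/down/overall union sets (a gene affected at several time
#' points counts once in the union but once per time point in the
#' per-timepoint sum), the full intersection structure (per-gene
#' time-point membership patterns with counts, the Venn diagram of the
#' time course), and a per-gene infection-stage label from the earliest
#' affected time (early 5-10, middle 10-30, late 30-80 min). Genes called
#' up at one time and down at another are kept in both direction sets and
#' flagged.
#'
#' @param records DEG record data frame from [call_degs()] /
#'   [call_degs_at_timepoint()] (possibly rbind-ed across time points).
#' @return A `phx_deg_summary` list: `per_time` (time_min, n_down, n_up),
#'   `down_genes`, `up_genes`, `all_genes`, `counts` (n_unique,
#'   n_down_unique, n_up_unique, per_time_sum), `patterns` (per-gene
#'   direction and time-point membership with per-pattern counts),
#'   `stages` (gene_id, first_time, stage), `conflicts`, and the tested
#'   `universe` when present on the records.
#' @export
aggregate_degs <- function(records) {
  empty <- !nrow(records)
  times <- if (empty) numeric() else sort(unique(records$time_min))
  per_time <- data.frame(
    time_min = times,
    n_down = vapply(times, function(t) {
      sum(records$time_min == t & records$direction == "down")
    }, 0L),
    n_up = vapply(times, function(t) {
      sum(records$time_min == t & records$direction == "up")
    }, 0L)
  )
  down_genes <- sort(unique(records$gene_id[records$direction == "down"]))
  up_genes <- sort(unique(records$gene_id[records$direction == "up"]))
  all_genes <- sort(unique(records$gene_id))
  conflicts <- intersect(down_genes, up_genes)
  if (length(conflicts)) {
    warning(sprintf(
      "%d gene(s) called up at one time point and down at another (kept in both sets)",
      length(conflicts)))
  }

  patterns <- if (empty) {
    data.frame(gene_id = character(), direction = character(),
               pattern = character(), stringsAsFactors = FALSE)
  } else {
    key <- split(records$time_min, list(records$gene_id, records$direction),
                 drop = TRUE)
    ids <- strsplit(names(key), "\\.(?=[^.]*$)", perl = TRUE)
    data.frame(
      gene_id = vapply(ids, `[`, "", 1),
      direction = vapply(ids, `[`, "", 2),
      pattern = vapply(key, function(t) paste(sort(t), collapse = "+"), ""),
      stringsAsFactors = FALSE
    )
  }
  pattern_counts <- if (nrow(patterns)) {
    pc <- as.data.frame(table(direction = patterns$direction,
                              pattern = patterns$pattern),
                        stringsAsFactors = FALSE)
    pc <- pc[pc$Freq > 0, , drop = FALSE]
    names(pc)[3] <- "n_genes"
    rownames(pc) <- NULL
    pc
  } else {
    data.frame(direction = character(), pattern = character(),
               n_genes = integer(), stringsAsFactors = FALSE)
  }

  stages <- if (empty) {
    data.frame(gene_id = character(), first_time = numeric(),
               stage = character(), stringsAsFactors = FALSE)
  } else {
    first <- vapply(split(records$time_min, records$gene_id), min, 0)
    data.frame(gene_id = names(first), first_time = unname(first),
               stage = unname(.phx_stage_of_peak(first)),
               stringsAsFactors = FALSE)
  }

  structure(list(
    per_time = per_time,
    down_genes = down_genes,
    up_genes = up_genes,
    all_genes = all_genes,
    counts = list(n_unique = length(all_genes),
                  n_down_unique = length(down_genes),
                  n_up_unique = length(up_genes),
                  per_time_sum = nrow(records)),
    patterns = patterns,
    pattern_counts = pattern_counts,
    stages = stages,
    conflicts = conflicts,
    universe = attr(records, "universe")
  ), class = "phx_deg_summary")
}

#' @export
print.phx_deg_summary <- function(x, ...) {
  cat(sprintf(
    "DEG summary: %d unique genes (%d down, %d up); per-timepoint sum %d\n",
    x$counts$n_unique, x$counts$n_down_unique, x$counts$n_up_unique,
    x$counts$per_time_sum))
  print(x$per_time, row.names = FALSE)
  invisible(x)
}
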