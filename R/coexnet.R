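#' Pearson correlation with t-transform significance
#'
#' Standard Pearson correlation of two sample vectors, with the two-sided
#' p-value of `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 degrees of
#' freedom; `r = +/-1` yields p = 0.
#'
#' @param x,y Numeric vectors of equal length n >= 3, neither constant.
#' @return List with `cor`, `p` and `n`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 samples")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  r <- cor(x, y)
  p <- if (1 - r^2 <= 8 * .Machine$double.eps) 0 else {
    2 * pt(-abs(r) * sqrt(n - 2) / sqrt(1 - r^2), n - 2)
  }
  list(cor = r, p = p, n = n)
}

#' Screen all phage x host pairs for strong signed correlations
#'
#' Computes the Pearson correlation of every phage feature against every
#' host feature over the replicate-level samples of a time window (on log2
#' normalized intensities) and retains only the strongest correlations:
#' edges with `p < alpha` AND `|cor| > cor_min` (defaults 0.01 and 0.99).
#' Constant features are skipped with a log entry.
#'
#' @param x A normalized `phx_expr`.
#' @param times Time points (minutes) of the screening window; must select
#'   at least 3 replicate-level samples.
#' @param cor_min Hard threshold on |cor| (strict).
#' @param alpha Significance threshold on the raw t-transform p (strict);
#'   no multiple-testing correction is applied, matching the hard-filter
#'   screen, unless `adjust = TRUE`.
#' @param adjust If `TRUE`, Benjamini-Hochberg-adjust the p-values across
#'   all evaluated pairs before thresholding.
#' @param positive_only Keep only positive correlations.
#' @param phage_ids,host_ids Restrict either side (defaults: all phage
#'   features; all non-reference host features).
#' @param unit `"replicate"` (default) correlates over replicate-level
#'   samples; `"timepoint_mean"` first averages replicates per time point.
#' @param stage Label stored on the returned edges (e.g. `"middle"`,
#'   `"merged"`).
#' @return Data frame of edges (`phage_id`, `host_id`, `cor`, `p`, `sign`,
#'   `stage`, `n`), sorted by p.
#' @export
screen_pairs <- function(x, times, cor_min = 0.99, alpha = 0.01,
                         adjust = FALSE, positive_only = FALSE,
                         phage_ids = NULL, host_ids = NULL,
                         unit = c("replicate", "timepoint_mean"),
                         stage = NA_character_) {
  stopifnot(inherits(x, "phx_expr"))
  unit <- match.arg(unit)
  if (is.null(phage_ids)) {
    phage_ids <- x$features$feature_id[x$features$organism == "phage"]
  }
  if (is.null(host_ids)) {
    host_ids <- x$features$feature_id[x$features$organism == "host" &
                                        !x$features$is_reference]
  }
  if (!length(phage_ids) || !length(host_ids)) {
    stop("need at least one phage and one host feature to screen")
  }
  cols <- x$samples$time_min %in% times
  L <- log2(x$values[, cols, drop = FALSE])
  tmin <- x$samples$time_min[cols]
  if (unit == "timepoint_mean") {
    ut <- sort(unique(tmin))
    L <- vapply(ut, function(t) rowMeans(L[, tmin == t, drop = FALSE]),
                numeric(nrow(L)))
    colnames(L) <- ut
  }
  n <- ncol(L)
  if (n < 3) {
    stop(sprintf("screening window selects %d sample(s); at least 3 required", n))
  }

  P <- t(L[phage_ids, , drop = FALSE])
  H <- t(L[host_ids, , drop = FALSE])
  const_p <- apply(P, 2, sd) == 0
  const_h <- apply(H, 2, sd) == 0
  if (any(const_p) || any(const_h)) {
    message(sprintf("skipping %d constant feature(s) in the screening window",
                    sum(const_p) + sum(const_h)))
    P <- P[, !const_p, drop = FALSE]
    H <- H[, !const_h, drop = FALSE]
  }
  if (!ncol(P) || !ncol(H)) {
    return(.phx_empty_edges())
  }
  C <- cor(P, H)
  r2 <- pmin(C^2, 1)
  tt <- abs(C) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  pv <- 2 * pt(-tt, n - 2)
  pv[r2 >= 1] <- 0
  if (adjust) pv[] <- bh_adjust(as.vector(pv))

  keep <- pv < alpha & abs(C) > cor_min
  if (positive_only) keep <- keep & C > 0
  idx <- which(keep, arr.ind = TRUE)
  if (!nrow(idx)) return(.phx_empty_edges())
  edges <- data.frame(
    phage_id = rownames(C)[idx[, 1]],
    host_id = colnames(C)[idx[, 2]],
    cor = C[idx],
    p = pv[idx],
    sign = ifelse(C[idx] > 0, "+", "-"),
    stage = stage,
    n = n,
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$p, edges$phage_id, edges$host_id), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

.phx_empty_edges <- function() {
  data.frame(phage_id = character(), host_id = character(), cor = numeric(),
             p = numeric(), sign = character(), stage = character(),
             n = integer(), stringsAsFactors = FALSE)
}

#' Build a stage co-expression network from screened edges
#'
#' Keeps the positive edges of one stage (the stage networks display
#' positively co-expressed, putatively co-functional genes), attaches a
#' K-score -- the node's degree, its number of links -- to every node, and
#' excludes isolated nodes. The network is bipartite: edges join a phage
#' gene and a host gene only.
#'
#' @param edges Edge data frame from [screen_pairs()].
#' @param stage Stage label to keep (`NULL`: all rows).
#' @param classes Optional named vector mapping node ids to temporal
#'   classes/annotation flags, stored on the nodes.
#' @return A `phx_network`: list with `nodes` (`id`, `organism`, `class`,
#'   `k_score`) and `edges`.
#' @export
stage_network <- function(edges, stage = NULL, classes = NULL) {
  if (!is.null(stage)) edges <- edges[edges$stage %in% stage, , drop = FALSE]
  edges <- edges[edges$sign == "+", , drop = FALSE]
  nodes <- data.frame(
    id = c(unique(edges$phage_id), unique(edges$host_id)),
    organism = c(rep("phage", length(unique(edges$phage_id))),
                 rep("host", length(unique(edges$host_id)))),
    stringsAsFactors = FALSE
  )
  deg <- table(c(edges$phage_id, edges$host_id))
  nodes$k_score <- if (nrow(nodes)) as.integer(deg[nodes$id]) else integer()
  nodes$class <- if (is.null(classes)) rep(NA_character_, nrow(nodes)) else {
    unname(classes[nodes$id])
  }
  structure(list(nodes = nodes, edges = edges,
                 stage = if (is.null(stage)) unique(edges$stage) else stage),
            class = "phx_network")
}

#' Middle-stage screen of phage genes against host transcriptional regulators
#'
#' Runs the hard-threshold correlation screen restricted to the host
#' transcriptional-regulator (TR) subset over the middle-infection-stage
#' window, and splits the surviving pairs into negative and positive
#' lists. Negative pairs indicate inhibitory phage-TR action; positive
#' pairs shared function.
#'
#' @param x A normalized `phx_expr` whose feature sheet flags TRs
#'   (`is_tr`).
#' @param times Screening window (default the middle-stage samples of the
#'   grid, 10-30 min).
#' @inheritParams screen_pairs
#' @return List with `negative`, `positive` (edge data frames),
#'   `n_negative`, `n_positive`.
#' @export
tr_screen <- function(x, times = NULL, cor_min = 0.99, alpha = 0.01,
                      unit = c("replicate", "timepoint_mean")) {
  stopifnot(inherits(x, "phx_expr"))
  if (is.null(x$features$is_tr) || !any(x$features$is_tr)) {
    stop("feature sheet declares no transcriptional regulators (is_tr)")
  }
  if (is.null(times)) {
    times <- stage_sample_times("middle", sort(unique(x$samples$time_min)))
  }
  tr_ids <- x$features$feature_id[x$features$is_tr &
                                    x$features$organism == "host"]
  edges <- screen_pairs(x, times, cor_min = cor_min, alpha = alpha,
                        host_ids = tr_ids, unit = match.arg(unit),
                        stage = "middle")
  list(negative = edges[edges$sign == "-", , drop = FALSE],
       positive = edges[edges$sign == "+", , drop = FALSE],
       n_negative = sum(edges$sign == "-"),
       n_positive = sum(edges$sign == "+"))
}

#' Merged all-timepoint co-expression network
#'
#' Screens every phage x host pair over the replicate-level samples of all
#' post-infection time points jointly (positive edges only, same hard
#' thresholds), builds the merged network with K-scores, and -- when an
#' annotation map is supplied -- tabulates the number of host target genes
#' of each phage gene in each functional term (the ribbon-plot input).
#' The summary also reports which temporal classes of phage genes carry
#' edges.
#'
#' @param x A normalized `phx_expr`.
#' @param times The post-infection time points; all must be present in the
#'   sample sheet (missing ones are a hard error).
#' @param annotation Optional `phx_annotation` of host functional terms.
#' @param classes Optional named vector ORF id -> temporal class; defaults
#'   to the feature sheet's `class_truth` when available.
#' @inheritParams screen_pairs
#' @return List with `network` (`phx_network`), `edges`,
#'   `function_targets` (data frame `phage_id`, `term_id`, `n_targets`),
#'   `classes_present`.
#' @export
merged_network <- function(x, times = NULL, annotation = NULL,
                           classes = NULL, cor_min = 0.99, alpha = 0.01,
                           unit = c("replicate", "timepoint_mean")) {
  stopifnot(inherits(x, "phx_expr"))
  have <- sort(unique(x$samples$time_min))
  if (is.null(times)) times <- setdiff(have, 0)
  missing <- setdiff(times, have)
  if (length(missing)) {
    stop("missing time point(s): ", paste(missing, collapse = ", "))
  }
  if (is.null(classes) && !is.null(x$features$class_truth)) {
    ph <- x$features$organism == "phage"
    classes <- setNames(x$features$class_truth[ph], x$features$feature_id[ph])
  }
  edges <- screen_pairs(x, times, cor_min = cor_min, alpha = alpha,
                        positive_only = TRUE, unit = match.arg(unit),
                        stage = "merged")
  net <- stage_network(edges, classes = classes)

  function_targets <- NULL
  if (!is.null(annotation)) {
    mapping <- if (inherits(annotation, "phx_annotation")) {
      annotation$mapping
    } else annotation
    hits <- merge(edges[, c("phage_id", "host_id")], mapping,
                  by.x = "host_id", by.y = "gene_id")
    function_targets <- if (nrow(hits)) {
      agg <- aggregate(list(n_targets = hits$host_id),
                       by = list(phage_id = hits$phage_id,
                                 term_id = hits$term_id), FUN = length)
      agg[order(agg$phage_id, agg$term_id), , drop = FALSE]
    } else {
      data.frame(phage_id = character(), term_id = character(),
                 n_targets = integer(), stringsAsFactors = FALSE)
    }
  }
  phage_nodes <- net$nodes$id[net$nodes$organism == "phage"]
  classes_present <- if (is.null(classes)) character() else {
    sort(unique(unname(classes[phage_nodes])))
  }
  list(network = net, edges = edges, function_targets = function_targets,
       classes_present = classes_present)
}

#' Genomic-adjacency report of network components
#'
#' For each connected component of a co-expression network, lists its
#' phage ORF members and whether they are contiguous along the phage
#' genome (consecutive ORF numbers; single-ORF components are contiguous
#' by convention), plus the overall contiguity fraction.
#'
#' @param network A `phx_network`.
#' @param orf_order Optional named integer vector giving each phage node's
#'   genomic rank; by default the number embedded in the ORF id is used.
#' @return List with `components` (data frame `component`, `orfs`,
#'   `n_orfs`, `contiguous`) and `contiguity_fraction`.
#' @export
adjacency_cluster_report <- function(network, orf_order = NULL) {
  stopifnot(inherits(network, "phx_network"))
  if (!nrow(network$edges)) {
    return(list(components = data.frame(component = integer(),
                                        orfs = character(), n_orfs = integer(),
                                        contiguous = logical()),
                contiguity_fraction = NA_real_))
  }
  g <- igraph::graph_from_data_frame(
    network$edges[, c("phage_id", "host_id")], directed = FALSE,
    vertices = network$nodes$id)
  comp <- igraph::components(g)$membership
  phage_ids <- network$nodes$id[network$nodes$organism == "phage"]
  rank_of <- if (is.null(orf_order)) {
    r <- as.integer(gsub("\\D", "", phage_ids))
    if (any(is.na(r))) stop("cannot parse genomic order from ORF ids; supply orf_order")
    setNames(r, phage_ids)
  } else orf_order

  per_comp <- split(phage_ids, comp[phage_ids])
  per_comp <- per_comp[vapply(per_comp, length, 0L) > 0]
  components <- data.frame(
    component = as.integer(names(per_comp)),
    orfs = vapply(per_comp, function(o) {
      paste(o[order(rank_of[o])], collapse = ",")
    }, "", USE.NAMES = FALSE),
    n_orfs = vapply(per_comp, length, 0L),
    contiguous = vapply(per_comp, function(o) {
      r <- sort(rank_of[o])
      length(r) == 1 || all(diff(r) == 1)
    }, TRUE),
    stringsAsFactors = FALSE
  )
  rownames(components) <- NULL
  list(components = components,
       contiguity_fraction = mean(components$contiguous))
}

#' @export
print.phx_network <- function(x, ...) {
  cat(sprintf("phx co-expression network: %d nodes (%d phage, %d host), %d edges\n",
              nrow(x$nodes), sum(x$nodes$organism == "phage"),
              sum(x$nodes$organism == "host"), nrow(x$edges)))
  invisible(x)
}

#' Write network exchange tables
#'
#' Writes a Cytoscape-style interaction table (`edges.tsv`: phage_id,
#' host_id, cor, p, sign, stage, n) and a node attribute table
#' (`nodes.tsv`: id, organism, class, k_score) to a directory.
#'
#' @param network A `phx_network`.
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_network <- function(network, dir) {
  stopifnot(inherits(network, "phx_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("edges.tsv", "nodes.tsv"))
  write.table(network$edges, paths[1], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(network$nodes, paths[2], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
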