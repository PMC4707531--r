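#' Fisher exact over-representation of annotation terms
#'
#' For each term of an annotation map, forms the 2x2 table (a = DEGs in
#' the term, b = DEGs outside it, c = non-DEG term members, d = the rest
#' of the background) and computes the one-sided over-representation
#' p-value, the hypergeometric upper tail P(X >= a). Terms with no member
#' in the background are skipped with a log entry. Rows are sorted by p.
#'
#' @param deg_set Character vector of DEG gene ids (subset of
#'   `background`).
#' @param background Character vector: all probed host genes.
#' @param map A `phx_annotation` (or data frame `gene_id`, `term_id`).
#' @param time_min Optional time annotation carried onto the rows.
#' @param alpha Significance threshold for the `significant` flag
#'   (default 0.01, uncorrected, as the screen is a hard filter).
#' @param adjust If `TRUE`, additionally Benjamini-Hochberg-adjust across
#'   terms into a `q` column (the `significant` flag then uses `q`).
#' @return Data frame (`term_id`, `time_min`, `a`, `b`, `c`, `d`, `p`,
#'   `significant`, and `q` when `adjust`).
#' @export
fisher_enrichment <- function(deg_set, background, map, time_min = NA,
                              alpha = 0.01, adjust = FALSE) {
  mapping <- if (inherits(map, "phx_annotation")) map$mapping else map
  .phx_stopifnot_cols(mapping, c("gene_id", "term_id"), "annotation map")
  if (!all(deg_set %in% background)) {
    stop("deg_set must be a subset of the background")
  }
  deg_set <- unique(deg_set)
  background <- unique(background)
  N <- length(background)
  n_deg <- length(deg_set)

  members <- split(mapping$gene_id, mapping$term_id)
  members <- lapply(members, function(g) intersect(unique(g), background))
  empty <- vapply(members, length, 0L) == 0
  if (any(empty)) {
    message(sprintf("skipping %d term(s) with no member in the background",
                    sum(empty)))
    members <- members[!empty]
  }
  if (!length(members)) {
    return(data.frame(term_id = character(), time_min = numeric(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  K <- vapply(members, length, 0L)
  a <- vapply(members, function(g) length(intersect(g, deg_set)), 0L)
  b <- n_deg - a
  cc <- K - a
  d <- N - n_deg - cc
  p <- phyper(a - 1, K, N - K, n_deg, lower.tail = FALSE)
  out <- data.frame(term_id = names(members), time_min = time_min,
                    a = a, b = b, c = cc, d = d, p = p,
                    stringsAsFactors = FALSE)
  if (adjust) {
    out$q <- bh_adjust(out$p)
    out$significant <- out$q < alpha
  } else {
    out$significant <- out$p < alpha
  }
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster pathway significance profiles across the time course
#'
#' Builds the term x time matrix of -log10(p) (missing term/time
#' combinations count as p = 1; values capped at `cap`), then clusters
#' terms hierarchically under Euclidean distance with average linkage and
#' cuts at `k` clusters, grouping pathways by the infection stage at
#' which they respond.
#'
#' @param rows Enrichment rows across time points (rbind-ed
#'   [fisher_enrichment()] outputs; needs `term_id`, `time_min`, `p`).
#' @param k Number of clusters (default 4).
#' @param cap Cap on -log10(p) before clustering (default 16).
#' @return List with `labels` (term -> cluster), `order` (dendrogram leaf
#'   order as term ids), `profile` (the clustered matrix) and `hclust`.
#' @export
cluster_pathway_profiles <- function(rows, k = 4, cap = 16) {
  .phx_stopifnot_cols(rows, c("term_id", "time_min", "p"), "enrichment rows")
  terms <- sort(unique(rows$term_id))
  times <- sort(unique(rows$time_min))
  if (length(terms) < k) stop("fewer terms than clusters requested")
  m <- matrix(0, length(terms), length(times),
              dimnames = list(terms, times))
  m[cbind(match(rows$term_id, terms), match(rows$time_min, times))] <-
    pmin(-log10(rows$p), cap)
  tree <- hclust(dist(m), method = "average")
  labels <- cutree(tree, k = k)
  list(labels = labels, order = terms[tree$order], profile = m, hclust = tree)
}

#' Percentage-of-functional-class DEG ratio table
#'
#' For each functional term, time point and direction, the percentage of
#' the term's background members that are DEGs of that direction at that
#' time: `100 * |DEGs of direction at time in term| / |term members in
#' background|`. Terms whose percentage exceeds `flag_threshold` (default
#' 40%) are flagged as strongly affected. Empty terms are skipped.
#'
#' @param summary A `phx_deg_summary` from [aggregate_degs()]; the tested
#'   gene universe recorded on it is the background.
#' @param map A `phx_annotation` (typically `vocabulary = "function"`) or
#'   data frame `gene_id`, `term_id`.
#' @param records The DEG records the summary was built from (needed for
#'   per-timepoint membership).
#' @param flag_threshold Percentage above which a cell is flagged.
#' @param denominator `"term"` (default: percent of the functional class)
#'   or `"degs"` (percent of that time point's DEG list).
#' @return Data frame (`term_id`, `time_min`, `direction`, `n`,
#'   `term_size`, `percentage`, `flagged`).
#' @export
function_ratio_table <- function(summary, map, records,
                                 flag_threshold = 40,
                                 denominator = c("term", "degs")) {
  stopifnot(inherits(summary, "phx_deg_summary"))
  denominator <- match.arg(denominator)
  mapping <- if (inherits(map, "phx_annotation")) map$mapping else map
  .phx_stopifnot_cols(mapping, c("gene_id", "term_id"), "annotation map")
  background <- summary$universe
  if (is.null(background)) background <- unique(mapping$gene_id)
  members <- split(mapping$gene_id, mapping$term_id)
  members <- lapply(members, function(g) intersect(unique(g), background))
  members <- members[vapply(members, length, 0L) > 0]

  times <- summary$per_time$time_min
  grid <- expand.grid(term_id = names(members), time_min = times,
                      direction = c("down", "up"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$term_size <- vapply(members[grid$term_id], length, 0L)
  grid$n <- mapply(function(term, t, dir) {
    degs <- records$gene_id[records$time_min == t & records$direction == dir]
    length(intersect(members[[term]], degs))
  }, grid$term_id, grid$time_min, grid$direction)
  denom <- if (denominator == "term") grid$term_size else {
    vapply(seq_len(nrow(grid)), function(i) {
      max(1L, sum(records$time_min == grid$time_min[i] &
                    records$direction == grid$direction[i]))
    }, 0L)
  }
  grid$percentage <- 100 * grid$n / denom
  grid$flagged <- grid$percentage > flag_threshold
  grid[order(grid$term_id, grid$time_min, grid$direction), , drop = FALSE]
}

#' Read a gene-to-term annotation map
#'
#' Reads either a two-column TSV (`gene_id`, `term`/`term_id`) or a GMT
#' file (term, description, member genes per line).
#'
#' @param path File path; format guessed from the `.gmt` extension unless
#'   given.
#' @param format `"tsv"` or `"gmt"`.
#' @param vocabulary Vocabulary tag stored on the terms.
#' @return A `phx_annotation`.
#' @export
read_annotation_map <- function(path, format = c("auto", "tsv", "gmt"),
                                vocabulary = "pathway") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (format == "gmt") {
    lines <- strsplit(readLines(path), "\t", fixed = TRUE)
    mapping <- do.call(rbind, lapply(lines, function(f) {
      if (length(f) < 3) return(NULL)
      data.frame(gene_id = f[-(1:2)], term_id = f[1], stringsAsFactors = FALSE)
    }))
    terms <- data.frame(
      term_id = vapply(lines, `[`, "", 1),
      name = vapply(lines, function(f) if (length(f) > 1) f[2] else f[1], ""),
      vocabulary = vocabulary, stringsAsFactors = FALSE)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!"term_id" %in% names(df) && "term" %in% names(df)) {
      names(df)[names(df) == "term"] <- "term_id"
    }
    .phx_stopifnot_cols(df, c("gene_id", "term_id"), "annotation map")
    mapping <- df[, c("gene_id", "term_id")]
    terms <- data.frame(term_id = unique(df$term_id),
                        name = unique(df$term_id),
                        vocabulary = vocabulary, stringsAsFactors = FALSE)
  }
  structure(list(mapping = mapping, terms = terms), class = "phx_annotation")
}
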