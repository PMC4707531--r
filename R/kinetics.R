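#' Infection stage windows
#'
#' The three temporal windows of the infection cycle used to class phage
#' ORFs by peak time: early up to 10 min (5-min expression counts as
#' early), middle (10, 30] min, late (30, 80] min. The windows partition
#' the post-infection clock, so every peak time maps to exactly one class.
#'
#' @return Data frame with columns `class`, `lower`, `upper` (upper
#'   inclusive).
#' @export
stage_windows <- function() {
  data.frame(class = c("early", "middle", "late"),
             lower = c(0, 10, 30), upper = c(10, 30, 80),
             stringsAsFactors = FALSE)
}

#' Sample times belonging to an infection stage
#'
#' Stage sample windows for correlation screens are boundary-inclusive
#' (early 5-10 min, middle 10-30 min, late 30-80 min), matching how the
#' stages are described on the infection clock; boundary time points (10,
#' 30 min) belong to both adjacent stages.
#'
#' @param stage `"early"`, `"middle"` or `"late"`.
#' @param time_points The full sampling grid in minutes.
#' @return The post-infection times of the grid falling in the stage.
#' @export
stage_sample_times <- function(stage = c("early", "middle", "late"),
                               time_points) {
  stage <- match.arg(stage)
  lim <- switch(stage, early = c(5, 10), middle = c(10, 30), late = c(30, 80))
  time_points[time_points >= lim[1] & time_points <= lim[2] & time_points > 0]
}

#' Assign a temporal class from a single expression profile
#'
#' Classes a profile by the window containing its peak (argmax over time);
#' ties are broken toward the earlier time point (a gene already maximal
#' early is early). The result is invariant to any strictly increasing
#' transform of the profile.
#'
#' @param profile Numeric vector of expression (or fold-change) values.
#' @param times Matching time points in minutes.
#' @return A list with `class` (`"early"`, `"middle"`, `"late"`, or `NA`
#'   for an all-equal, unclassifiable profile) and `peak_time`.
#' @export
assign_peak_class <- function(profile, times) {
  stopifnot(length(profile) == length(times))
  if (length(unique(profile)) == 1) {
    return(list(class = NA_character_, peak_time = NA_real_))
  }
  ord <- order(times)
  profile <- profile[ord]
  times <- times[ord]
  peak <- times[which.max(profile)]
  list(class = .phx_stage_of_peak(peak), peak_time = peak)
}

#' Class all phage ORFs of a fold-change matrix by peak time
#'
#' Applies [assign_peak_class()] to every phage row of a fold-change
#' matrix, returning a temporal class map with per-ORF peak times and
#' z-scored profiles.
#'
#' @param fc A `phx_fc` matrix from [log_fold_change()], or any numeric
#'   matrix with time-named columns.
#' @param orf_ids Rows to class; defaults to the phage features recorded on
#'   the matrix, or all rows if no feature sheet is attached.
#' @return Data frame (`orf_id`, `peak_time`, `class`) of class
#'   `phx_class_map`, with the z-scored profile matrix attached as
#'   attribute `"profiles"`.
#' @export
classify_peaks <- function(fc, orf_ids = NULL) {
  times <- .phx_fc_times(fc)
  if (is.null(orf_ids)) {
    feats <- attr(fc, "features")
    orf_ids <- if (!is.null(feats)) {
      feats$feature_id[feats$organism == "phage"]
    } else rownames(fc)
  }
  m <- unclass(fc)[orf_ids, , drop = FALSE]
  res <- lapply(orf_ids, function(o) assign_peak_class(m[o, ], times))
  z <- t(apply(m, 1, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  out <- data.frame(orf_id = orf_ids,
                    peak_time = vapply(res, `[[`, 0, "peak_time"),
                    class = vapply(res, `[[`, "", "class"),
                    stringsAsFactors = FALSE)
  structure(out, class = c("phx_class_map", "data.frame"), profiles = z)
}

.phx_fc_times <- function(fc) {
  times <- attr(fc, "times")
  if (is.null(times)) times <- as.numeric(colnames(fc))
  if (any(is.na(times))) stop("fold-change matrix must have time-named columns")
  times
}

#' Hierarchically cluster temporal profiles
#'
#' Agglomerative clustering of z-scored profiles under correlation
#' distance (1 - Pearson) with average linkage, cut at `k` clusters. Each
#' cluster is labeled by the majority peak class of its members.
#'
#' @param fc Fold-change matrix (`phx_fc` or plain matrix with time-named
#'   columns); rows are profiles.
#' @param k Number of clusters, between 1 and the number of profiles.
#' @param orf_ids Rows to cluster (defaults as in [classify_peaks()]).
#' @return List with `labels` (named cluster ids), `class_of_cluster`
#'   (majority peak class per cluster), `order` (dendrogram leaf order)
#'   and `hclust` (the tree).
#' @export
cluster_profiles <- function(fc, k = 3, orf_ids = NULL) {
  cmap <- classify_peaks(fc, orf_ids)
  z <- attr(cmap, "profiles")
  n <- nrow(z)
  if (k < 1 || k > n) stop(sprintf("k must be between 1 and %d", n))
  cc <- suppressWarnings(cor(t(z)))
  cc[!is.finite(cc)] <- 0
  d <- as.dist(1 - cc)
  tree <- hclust(d, method = "average")
  labels <- cutree(tree, k = k)
  class_of_cluster <- vapply(split(cmap$class, labels[cmap$orf_id]),
                             function(cl) {
                               cl <- cl[!is.na(cl)]
                               if (!length(cl)) NA_character_ else
                                 names(sort(table(cl), decreasing = TRUE))[1]
                             }, "")
  list(labels = labels, class_of_cluster = class_of_cluster,
       order = tree$order, hclust = tree)
}

#' Class phage ORFs from drug-condition expression
#'
#' Cross-validates temporal classes with the two inhibitor conditions:
#' chloramphenicol (Cm, blocks de novo protein synthesis, so only early
#' genes are expressed) and phosphonoacetic acid (PAA, blocks the phage
#' DNA polymerase, so late genes are not expressed). An ORF counts as
#' "expressed" in a condition when its mean intensity at the assay time is
#' at least `fc_threshold`-fold its own 0-min baseline. Decision table:
#' expressed under Cm -> early; otherwise expressed under PAA -> middle;
#' otherwise expressed in the untreated infection -> late; expressed
#' nowhere -> unclassifiable (`NA`, flagged).
#'
#' @param control,cm,paa `phx_expr` matrices for the untreated infection
#'   and the two drug conditions (sharing phage ORFs).
#' @param fc_threshold Fold threshold for "expressed" (default 2).
#' @param cm_time,paa_time Assay times in minutes (30 for Cm, 80 for PAA).
#' @return Data frame (`orf_id`, `expressed_cm`, `expressed_paa`,
#'   `expressed_control`, `class`).
#' @export
classify_by_drug_response <- function(control, cm, paa, fc_threshold = 2,
                                      cm_time = 30, paa_time = 80) {
  orfs <- control$features$feature_id[control$features$organism == "phage"]
  for (m in list(cm, paa)) {
    if (!all(orfs %in% rownames(m$values))) {
      stop("drug-condition matrices must share the control's phage ORFs")
    }
  }
  ratio_at <- function(x, ids, t) {
    base <- rowMeans(x$values[ids, x$samples$time_min == 0, drop = FALSE])
    at <- rowMeans(x$values[ids, x$samples$time_min == t, drop = FALSE])
    at / base
  }
  expressed_cm <- ratio_at(cm, orfs, cm_time) >= fc_threshold
  expressed_paa <- ratio_at(paa, orfs, paa_time) >= fc_threshold
  post <- setdiff(unique(control$samples$time_min), 0)
  ctrl_ratio <- do.call(pmax, lapply(post, function(t) ratio_at(control, orfs, t)))
  expressed_control <- ctrl_ratio >= fc_threshold
  class <- ifelse(expressed_cm, "early",
                  ifelse(expressed_paa, "middle",
                         ifelse(expressed_control, "late", NA_character_)))
  if (any(is.na(class))) {
    message(sprintf("%d ORF(s) expressed under neither drug nor control: unclassifiable",
                    sum(is.na(class))))
  }
  data.frame(orf_id = orfs, expressed_cm = unname(expressed_cm),
             expressed_paa = unname(expressed_paa),
             expressed_control = unname(expressed_control),
             class = unname(class), stringsAsFactors = FALSE)
}

#' Reconcile peak-based and drug-based class assignments
#'
#' Joins the two classifications over their common ORF universe and
#' reports per-ORF agreement and the overall concordance fraction. The
#' peak-based class is retained as primary.
#'
#' @param classes_peak A `phx_class_map` from [classify_peaks()] (or any
#'   data frame with `orf_id`, `class`).
#' @param classes_drug Data frame with `orf_id`, `class` from
#'   [classify_by_drug_response()].
#' @return List with `table` (orf_id, class_peak, class_drug, agree),
#'   `concordance` (fraction agreeing among ORFs classified by both) and
#'   `disagreements`.
#' @export
reconcile_classes <- function(classes_peak, classes_drug) {
  tab <- merge(
    data.frame(orf_id = classes_peak$orf_id, class_peak = classes_peak$class,
               stringsAsFactors = FALSE),
    data.frame(orf_id = classes_drug$orf_id, class_drug = classes_drug$class,
               stringsAsFactors = FALSE),
    by = "orf_id")
  tab$agree <- tab$class_peak == tab$class_drug
  both <- !is.na(tab$agree)
  concordance <- if (any(both)) mean(tab$agree[both]) else NA_real_
  list(table = tab, concordance = concordance,
       disagreements = tab[both & !tab$agree, , drop = FALSE])
}
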