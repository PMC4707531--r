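#' Build a synthetic dual-organism time-series configuration
#'
#' Describes everything the generator plants into a synthetic phage + host
#' expression data set: the infection time grid, replicate count, the
#' per-ORF temporal class map, per-timepoint differential-expression plans
#' for the host, and phage-host correlation pair plans, plus noise and
#' baseline parameters. [generate_expression()] turns a configuration into
#' an intensity matrix; [paper_mirror_config()] returns the configuration
#' whose planted structure reproduces the study-scale printed counts.
#'
#' @param time_points Sampling times in minutes post-infection, strictly
#'   increasing; the first must be 0 (the uninfected reference).
#' @param replicates Number of biological replicates per time point.
#' @param phage_class_map Named character vector mapping phage ORF ids to
#'   temporal classes (`"early"`, `"middle"`, `"late"`). May be empty for a
#'   host-only data set.
#' @param host_gene_count Number of host genes; ids are `PA0001`,
#'   `PA0002`, ... in genome order.
#' @param tr_genes Host gene ids flagged as transcriptional regulators in
#'   the feature sheet (the TR screen universe).
#' @param deg_plan Data frame (`gene_id`, `time_min`, `direction`,
#'   `log2fc`) of planted host differential expression: at each listed time
#'   point the gene's log2 intensity is shifted by `log2fc` upward
#'   (`direction == "up"`) or downward (`"down"`). `log2fc` is a positive
#'   magnitude.
#' @param tr_pair_plan,merged_pair_plan Data frames (`phage_id`, `host_id`,
#'   `sign`, `target`) of planted phage-host correlation pairs. The host
#'   partner's profile is constructed so that its sample Pearson
#'   correlation with the phage partner over the pair's screening window
#'   (middle-stage samples for `tr_pair_plan`, all post-infection samples
#'   for `merged_pair_plan`) equals `sign * target` exactly. Each host gene
#'   may appear in at most one pair and must not be in `deg_plan`;
#'   `tr_pair_plan` hosts must be in `tr_genes`.
#' @param noise_sigma Standard deviation, on the log2 scale, of the
#'   multiplicative noise applied to every non-reference feature.
#' @param sample_scale_sigma Standard deviation (log2) of a per-sample
#'   scaling factor applied to all features including the reference; 0
#'   (default) keeps the reference identical across samples. Setting it
#'   positive emulates per-array intensity scaling that
#'   [normalize_to_reference()] removes.
#' @param reference_feature Id of the noise-free housekeeping feature.
#' @param reference_level Constant log2 intensity of the reference feature.
#' @param pair_amp Log2-scale standard deviation, over the screening
#'   window, of a planted pair host's profile. Kept below 0.35 so planted
#'   pair hosts never cross the 2-fold DEG threshold.
#' @param baseline List of baseline log2 intensity distributions:
#'   `phage_mean`, `phage_sd` (background level of phage features before
#'   induction) and `host_mean`, `host_sd`.
#' @param profile List of phage kinetic-profile parameters: `amplitude`
#'   (range of peak log2 fold induction), `width` (range of log-time bump
#'   widths), `peak_ranges` (per-class peak-time ranges in minutes),
#'   `wiggle_sigma` (sd of per-ORF per-timepoint kinetic deviations from
#'   the class archetype), `margin` (required log2 excess of the in-window
#'   maximum over the out-of-window maximum), `shape_cor_max` (maximum
#'   tolerated |correlation| between an ORF's temporal shape and any
#'   planted DEG step pattern), `max_tries` (rejection-sampling budget),
#'   and the planted-pair partner rules: `partner_amplitude`,
#'   `partner_width`, `partner_peak`, `partner_wiggle`, `partner_margin`
#'   (wide, nearly window-flat bumps for TR-pair partners),
#'   `merged_early_peak` / `immediate_early_peak` /
#'   `immediate_early_width` (peak-time separation of merged-plan early
#'   partners from non-plan immediate-early ORFs), and `partner_sep` /
#'   `max_sep_tries` (the kinetic-separation invariant: a pair partner's
#'   realized window correlation against every rival ORF is kept at or
#'   below `partner_sep` by redrawing its kinetic deviations and noise).
#'   See the package vignette for why these rules are needed to recover
#'   planted pair counts exactly under a hard `|cor| > 0.99` screen.
#' @param seed Integer seed; all randomness is derived from it through
#'   stable per-feature substreams, so identical configurations generate
#'   bit-identical matrices and adding features does not reshuffle others.
#'
#' @return An object of class `phx_config`.
#' @seealso [paper_mirror_config()], [generate_expression()]
#' @export
synthetic_config <- function(time_points = c(0, 5, 10, 20, 30, 80),
                             replicates = 3,
                             phage_class_map = character(),
                             host_gene_count = 100,
                             tr_genes = character(),
                             deg_plan = NULL,
                             tr_pair_plan = NULL,
                             merged_pair_plan = NULL,
                             noise_sigma = 0.1,
                             sample_scale_sigma = 0,
                             reference_feature = "16S",
                             reference_level = 14,
                             pair_amp = 0.3,
                             baseline = list(phage_mean = 6, phage_sd = 0.5,
                                             host_mean = 9, host_sd = 1.2),
                             profile = list(),
                             seed = 1) {
  profile_defaults <- list(
    amplitude = c(3, 4.5),
    width = c(0.55, 0.75),
    peak_ranges = list(early = c(5, 10), middle = c(16, 30), late = c(60, 80)),
    partner_amplitude = c(2.2, 2.8),
    partner_width = c(1.7, 1.9),
    partner_peak = c(24, 28),
    partner_wiggle = 0.1,
    partner_margin = 0.45,
    partner_sep = 0.97,
    max_sep_tries = 50,
    merged_early_peak = c(7, 10),
    immediate_early_peak = c(5, 6),
    immediate_early_width = c(0.4, 0.55),
    wiggle_sigma = 0.3,
    margin = 0.5,
    shape_cor_max = 0.96,
    max_tries = 200
  )
  profile <- utils::modifyList(profile_defaults, profile)
  empty_deg <- data.frame(gene_id = character(), time_min = numeric(),
                          direction = character(), log2fc = numeric(),
                          stringsAsFactors = FALSE)
  empty_pairs <- data.frame(phage_id = character(), host_id = character(),
                            sign = numeric(), target = numeric(),
                            stringsAsFactors = FALSE)
  cfg <- structure(list(
    time_points = as.numeric(time_points),
    replicates = as.integer(replicates),
    phage_class_map = phage_class_map,
    host_gene_count = as.integer(host_gene_count),
    host_ids = sprintf("PA%04d", seq_len(host_gene_count)),
    tr_genes = tr_genes,
    deg_plan = if (is.null(deg_plan)) empty_deg else deg_plan,
    tr_pair_plan = if (is.null(tr_pair_plan)) empty_pairs else tr_pair_plan,
    merged_pair_plan = if (is.null(merged_pair_plan)) empty_pairs else merged_pair_plan,
    noise_sigma = noise_sigma,
    sample_scale_sigma = sample_scale_sigma,
    reference_feature = reference_feature,
    reference_level = reference_level,
    pair_amp = pair_amp,
    baseline = baseline,
    profile = profile,
    seed = as.integer(seed)
  ), class = "phx_config")
  validate_config(cfg)
  cfg
}

#' Validate a synthetic configuration
#'
#' Checks the structural invariants of a [synthetic_config()]: a strictly
#' increasing time grid anchored at the uninfected 0-minute reference, a
#' class map assigning each declared ORF exactly one temporal class, and
#' plan tables whose gene ids exist in the generated feature universe
#' (with pair hosts unique, outside the DEG plan, and TR pair hosts drawn
#' from the declared TR set).
#'
#' @param config A `phx_config` object.
#' @return `config`, invisibly; errors describe the first violated
#'   invariant.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "phx_config"))
  tp <- config$time_points
  if (length(tp) < 2 || any(diff(tp) <= 0)) {
    stop("time_points must be strictly increasing with at least two points")
  }
  if (tp[1] != 0) stop("the first time point must be the uninfected reference (0 min)")
  if (config$replicates < 1) stop("replicates must be >= 1")
  cm <- config$phage_class_map
  if (length(cm)) {
    if (is.null(names(cm)) || anyDuplicated(names(cm))) {
      stop("phage_class_map must be named with unique ORF ids")
    }
    bad <- setdiff(unique(cm), c("early", "middle", "late"))
    if (length(bad)) stop("unknown temporal class(es): ", paste(bad, collapse = ", "))
  }
  dp <- config$deg_plan
  .phx_stopifnot_cols(dp, c("gene_id", "time_min", "direction", "log2fc"), "deg_plan")
  if (nrow(dp)) {
    if (!all(dp$gene_id %in% config$host_ids)) {
      stop("deg_plan contains gene ids outside the generated host gene set")
    }
    if (!all(dp$time_min %in% tp[-1])) {
      stop("deg_plan contains time points outside the post-infection grid")
    }
    if (!all(dp$direction %in% c("up", "down"))) stop("deg_plan direction must be 'up' or 'down'")
    if (any(dp$log2fc <= 0)) stop("deg_plan log2fc must be positive magnitudes")
    key <- paste(dp$gene_id, dp$time_min)
    if (anyDuplicated(key)) stop("deg_plan assigns a gene twice at one time point")
  }
  pairs <- rbind(config$tr_pair_plan, config$merged_pair_plan)
  .phx_stopifnot_cols(pairs, c("phage_id", "host_id", "sign", "target"), "pair plan")
  if (nrow(pairs)) {
    if (!all(pairs$phage_id %in% names(cm))) {
      stop("pair plan contains phage ids outside the declared ORF set")
    }
    if (!all(pairs$host_id %in% config$host_ids)) {
      stop("pair plan contains host ids outside the generated host gene set")
    }
    if (anyDuplicated(pairs$host_id)) {
      stop("each host gene may be the partner of at most one planted pair")
    }
    if (any(pairs$host_id %in% dp$gene_id)) {
      stop("planted pair hosts must not also be in the deg_plan")
    }
    if (!all(pairs$sign %in% c(-1, 1))) stop("pair sign must be -1 or +1")
    if (any(pairs$target <= 0 | pairs$target >= 1)) stop("pair target |cor| must be in (0, 1)")
  }
  if (nrow(config$tr_pair_plan) &&
      !all(config$tr_pair_plan$host_id %in% config$tr_genes)) {
    stop("tr_pair_plan hosts must be declared transcriptional regulators (tr_genes)")
  }
  if (!all(config$tr_genes %in% config$host_ids)) {
    stop("tr_genes must be a subset of the generated host gene set")
  }
  if (config$noise_sigma < 0) stop("noise_sigma must be >= 0")
  invisible(config)
}

#' Study-scale mirror configuration
#'
#' Returns the [synthetic_config()] whose planted structure reproduces, at
#' full scale, the printed counts of the PaP3 / *P. aeruginosa* infection
#' study design: 71 phage ORFs with temporal classes early = ORF57-71 (15),
#' middle = ORF22-56 (35), late = ORF1-21 (21); 5,633 host genes sampled at
#' 0, 5, 10, 20, 30 and 80 min in three replicates; a host DEG plan with
#' 2,160 unique DEGs (2,120 down, 40 up; 1,852 down and 28 up at 30 min; no
#' up-regulated genes at 5 min; per-timepoint memberships summing to
#' 4,129); a middle-window TR pair plan of 24 negative and 1 positive
#' (ORF52-PA0163) planted correlations over 19 distinct middle-class phage
#' genes; and a merged-window pair plan linking 14 early ORFs (ORF58-71)
#' to 110 distinct host genes, all positively.
#'
#' Per-timepoint DEG set sizes other than at 30 min, and the overlap
#' structure between time points, are not individually printed in the
#' source study; the plan uses nested interval memberships (down:
#' 150/450/1200/1852/407, up: 0/8/20/28/14 at 5/10/20/30/80 min) satisfying
#' every printed constraint. Planted effects are strong
#' (`|log2FC|` in [2.5, 3.5]) and noise low (sigma 0.1) so the planted
#' structure is recoverable by the screening thresholds the pipeline uses.
#'
#' @param seed Integer seed forwarded to [synthetic_config()].
#' @return A `phx_config` object.
#' @export
paper_mirror_config <- function(seed = 1) {
  orf <- function(i) sprintf("ORF%d", i)
  class_map <- c(
    setNames(rep("late", 21), orf(1:21)),
    setNames(rep("middle", 35), orf(22:56)),
    setNames(rep("early", 15), orf(57:71))
  )

  host_id <- function(i) sprintf("PA%04d", i)
  # Planted DEG memberships as index ranges into the down (D1..D2120,
  # ids PA2000..PA4119) and up (U1..U40, ids PA4120..PA4159) gene lists.
  down_sets <- list(`5` = 1:150, `10` = 1671:2120, `20` = 653:1852,
                    `30` = 1:1852, `80` = 1500:1906)
  up_sets <- list(`10` = 1:8, `20` = 5:24, `30` = 1:28, `80` = 27:40)
  down_id <- function(i) host_id(1999 + i)
  up_id <- function(i) host_id(4119 + i)
  # Deterministic per-gene effect magnitudes in [2.5, 3.5].
  mag <- function(i) 2.5 + ((i * 7) %% 11) / 10
  deg_plan <- rbind(
    do.call(rbind, lapply(names(down_sets), function(t) {
      i <- down_sets[[t]]
      data.frame(gene_id = down_id(i), time_min = as.numeric(t),
                 direction = "down", log2fc = mag(i), stringsAsFactors = FALSE)
    })),
    do.call(rbind, lapply(names(up_sets), function(t) {
      i <- up_sets[[t]]
      data.frame(gene_id = up_id(i), time_min = as.numeric(t),
                 direction = "up", log2fc = mag(i), stringsAsFactors = FALSE)
    }))
  )

  # Middle-stage TR pairs: 24 negative + 1 positive (ORF52-PA0163) over
  # 19 distinct middle-class phage genes, 25 distinct TR hosts.
  neg_phage <- c(rep("ORF53", 3), rep("ORF32", 2), rep("ORF39", 2),
                 rep("ORF40", 2), rep("ORF33", 2),
                 orf(c(34:38, 41:48)))
  stopifnot(length(neg_phage) == 24)
  neg_hosts <- host_id(setdiff(150:174, 163))
  tr_pair_plan <- rbind(
    data.frame(phage_id = neg_phage, host_id = neg_hosts, sign = -1,
               target = 0.997, stringsAsFactors = FALSE),
    data.frame(phage_id = "ORF52", host_id = host_id(163), sign = 1,
               target = 0.997, stringsAsFactors = FALSE)
  )

  # Merged-window pairs: 14 early ORFs (ORF58-71) x 110 distinct hosts.
  merged_orfs <- orf(58:71)
  per_orf <- c(rep(8, 12), 7, 7)
  merged_pair_plan <- data.frame(
    phage_id = rep(merged_orfs, per_orf),
    host_id = host_id(4499 + seq_len(sum(per_orf))),
    sign = 1, target = 0.997, stringsAsFactors = FALSE
  )

  synthetic_config(
    time_points = c(0, 5, 10, 20, 30, 80),
    replicates = 3,
    phage_class_map = class_map,
    host_gene_count = 5633,
    tr_genes = host_id(1:476),
    deg_plan = deg_plan,
    tr_pair_plan = tr_pair_plan,
    merged_pair_plan = merged_pair_plan,
    noise_sigma = 0.1,
    seed = seed
  )
}

# Temporal class of a peak time on the infection clock: early up to 10 min
# (5-min expression counts as early), middle (10, 30], late beyond 30.
.phx_stage_of_peak <- function(t) {
  ifelse(t <= 10, "early", ifelse(t <= 30, "middle", "late"))
}

# Normalized, centered indicator directions of the distinct planted DEG
# step patterns over the post-infection grid; used to keep phage kinetic
# shapes separated from host step responses.
.phx_pattern_directions <- function(deg_plan, post_times) {
  if (!nrow(deg_plan)) return(list())
  pats <- unique(lapply(split(deg_plan$time_min, deg_plan$gene_id),
                        function(t) sort(unique(t))))
  dirs <- lapply(pats, function(p) {
    v <- as.numeric(post_times %in% p)
    v <- v - mean(v)
    n <- sqrt(sum(v^2))
    if (n > 0) v / n else NULL
  })
  Filter(Negate(is.null), dirs)
}

# Draw one ORF's kinetic signal over the post-infection grid: a log-normal
# bump in time peaking inside the class window, plus per-timepoint kinetic
# deviations, rejection-sampled so that (a) the in-window maximum dominates
# every out-of-window value by `margin` and (b) the centered temporal shape
# is not collinear with any planted DEG step pattern.
#
# A planted pair rides on its phage partner's realized window vector, so a
# partner that shares the steep temporal contrast of its class would drag
# its exactly calibrated host across the |cor| > 0.99 screening threshold
# against every kinetically similar ORF. Two generator design rules keep
# planted counts exact:
#   * TR-pair partners (middle class) get wide, nearly window-flat bumps
#     with small kinetic deviations: their middle-window between-timepoint
#     variance is comparable to the replicate noise variance, so replicate
#     noise attenuates any transitive correlation well below threshold
#     while the peak classer still sees the (enforced) in-window margin.
#   * Merged-plan partners (early class) peak late in the early window
#     (7-10 min), while early ORFs outside the plan are sharp
#     immediate-early genes peaking at 5-6 min, keeping their full-course
#     shapes well separated from the partners'.
.phx_phage_signal <- function(config, orf_id, klass, post_times, pattern_dirs,
                              role = c("none", "tr", "merged"), salt = 0) {
  pr <- config$profile
  role <- match.arg(role)
  set.seed(.phx_substream(config$seed, orf_id, "profile"))
  amp <- runif(1, pr$amplitude[1], pr$amplitude[2])
  wiggle_sd <- pr$wiggle_sigma
  margin <- pr$margin
  if (role == "tr" && klass == "middle") {
    amp <- runif(1, pr$partner_amplitude[1], pr$partner_amplitude[2])
    width <- runif(1, pr$partner_width[1], pr$partner_width[2])
    peak <- runif(1, pr$partner_peak[1], pr$partner_peak[2])
    wiggle_sd <- pr$partner_wiggle
    margin <- pr$partner_margin
  } else if (role == "merged" && klass == "early") {
    width <- runif(1, pr$width[1], pr$width[2])
    peak <- runif(1, pr$merged_early_peak[1], pr$merged_early_peak[2])
  } else if (role == "none" && klass == "early" &&
             nrow(config$merged_pair_plan)) {
    width <- runif(1, pr$immediate_early_width[1], pr$immediate_early_width[2])
    peak <- runif(1, pr$immediate_early_peak[1], pr$immediate_early_peak[2])
  } else {
    width <- runif(1, pr$width[1], pr$width[2])
    rng <- pr$peak_ranges[[klass]]
    peak <- runif(1, rng[1], rng[2])
  }
  bump <- amp * exp(-(log(post_times / peak))^2 / (2 * width^2))
  in_win <- .phx_stage_of_peak(post_times) == klass
  if (!any(in_win)) {
    stop(sprintf("no post-infection time point falls in the %s window", klass))
  }
  best <- bump
  best_viol <- Inf
  set.seed(.phx_substream(config$seed, orf_id, "wiggle", salt))
  for (i in seq_len(pr$max_tries)) {
    sig <- bump + rnorm(length(post_times), 0, wiggle_sd)
    viol <- if (all(in_win)) 0 else {
      max(0, max(sig[!in_win]) + margin - max(sig[in_win]))
    }
    if (length(pattern_dirs)) {
      sc <- sig - mean(sig)
      nsc <- sqrt(sum(sc^2))
      if (nsc > 0) {
        shape_cor <- max(abs(vapply(pattern_dirs,
                                    function(d) sum(sc * d), 0))) / nsc
        viol <- viol + max(0, shape_cor - pr$shape_cor_max)
      }
    }
    if (viol < best_viol) {
      best_viol <- viol
      best <- sig
    }
    if (viol <= 0) break
  }
  best
}

# Calibrated planted-pair host profile over the window samples: an affine
# transform of the phage partner's realized log2 values plus a Gaussian
# perturbation orthogonalized and rescaled so the sample Pearson
# correlation over the window equals sign * target exactly.
.phx_pair_values <- function(config, host_id, z, sign, target) {
  n <- length(z)
  zc <- z - mean(z)
  nz <- sqrt(sum(zc^2))
  if (n < 3 || nz == 0) {
    warning(sprintf(
      "planted pair for host %s cannot reach |cor| = %.3f (window too small or constant phage profile); leaving host at baseline",
      host_id, target), call. = FALSE)
    return(NULL)
  }
  zh <- zc / nz
  set.seed(.phx_substream(config$seed, host_id, "pair"))
  repeat {
    e <- rnorm(n)
    e <- e - mean(e)
    e <- e - sum(e * zh) * zh
    ne <- sqrt(sum(e^2))
    if (ne > 1e-8) break
  }
  u <- sign * target * zh + sqrt(1 - target^2) * e / ne
  config$pair_amp * sqrt(n - 1) * u
}

#' Generate a synthetic dual-organism expression matrix
#'
#' Realizes a [synthetic_config()] as a positive intensity matrix over all
#' phage and host features and all (time, replicate) samples of one
#' experimental condition. Phage features follow unimodal class-dependent
#' kinetics peaking inside their stage window; planted host DEGs are
#' shifted by their planned log2 effects at their planned time points;
#' planted pair hosts are constructed to meet their target window
#' correlation and sign exactly; multiplicative log-normal noise is applied
#' to everything except the constant, noise-free reference feature. Under
#' `infected+Cm` (protein-synthesis block) middle and late phage features
#' stay at baseline and early features hold their peak; under
#' `infected+PAA` (phage DNA-polymerase block) only late features stay at
#' baseline. Host DEG and pair plans apply to the plain `infected`
#' condition only. The same configuration and seed produce bit-identical
#' output.
#'
#' @param config A `phx_config`.
#' @param condition One of `"infected"`, `"infected+Cm"`, `"infected+PAA"`.
#' @return A `phx_expr` object: a list with `values` (features x samples
#'   intensity matrix), `samples` (sample sheet: `sample_id`, `time_min`,
#'   `replicate`, `condition`) and `features` (feature sheet: `feature_id`,
#'   `organism`, `orf_id`, `class_truth`, `is_tr`, `is_reference`).
#' @export
generate_expression <- function(config,
                                condition = c("infected", "infected+Cm",
                                              "infected+PAA")) {
  validate_config(config)
  condition <- match.arg(condition)
  restore <- .phx_push_rng()
  on.exit(restore())

  tp <- config$time_points
  post <- tp[-1]
  reps <- seq_len(config$replicates)
  samples <- data.frame(
    sample_id = sprintf("t%03d_r%d", rep(tp, each = length(reps)),
                        rep(reps, times = length(tp))),
    time_min = rep(tp, each = length(reps)),
    replicate = rep(reps, times = length(tp)),
    condition = condition,
    stringsAsFactors = FALSE
  )
  ns <- nrow(samples)
  t_index <- match(samples$time_min, tp)

  orfs <- names(config$phage_class_map)
  hosts <- config$host_ids
  features <- data.frame(
    feature_id = c(config$reference_feature, orfs, hosts),
    organism = c("host", rep("phage", length(orfs)), rep("host", length(hosts))),
    orf_id = c(NA_character_, orfs, rep(NA_character_, length(hosts))),
    class_truth = c(NA_character_, unname(config$phage_class_map),
                    rep(NA_character_, length(hosts))),
    is_tr = c(FALSE, rep(FALSE, length(orfs)), hosts %in% config$tr_genes),
    is_reference = c(TRUE, rep(FALSE, length(orfs) + length(hosts))),
    stringsAsFactors = FALSE
  )

  L <- matrix(0, nrow(features), ns,
              dimnames = list(features$feature_id, samples$sample_id))
  L[config$reference_feature, ] <- config$reference_level

  pattern_dirs <- .phx_pattern_directions(config$deg_plan, post)
  bl <- config$baseline
  sigma <- config$noise_sigma

  tr_partners <- unique(config$tr_pair_plan$phage_id)
  merged_partners <- unique(config$merged_pair_plan$phage_id)
  role_of <- function(o) {
    if (o %in% tr_partners) "tr" else {
      if (o %in% merged_partners) "merged" else "none"
    }
  }
  phage_bg <- vapply(orfs, function(o) {
    set.seed(.phx_substream(config$seed, o, "baseline"))
    rnorm(1, bl$phage_mean, bl$phage_sd)
  }, 0)
  phage_row <- function(o, salt) {
    klass <- config$phage_class_map[[o]]
    sig <- .phx_phage_signal(config, o, klass, post, pattern_dirs,
                             role = role_of(o), salt = salt)
    if (condition == "infected+Cm") {
      sig <- if (klass == "early") cummax(sig) else sig * 0
    } else if (condition == "infected+PAA") {
      sig <- if (klass == "late") sig * 0 else cummax(sig)
    }
    profile_t <- c(0, sig)   # zero induction in the uninfected reference
    set.seed(.phx_substream(config$seed, o, "noise", condition, salt))
    phage_bg[[o]] + profile_t[t_index] + rnorm(ns, 0, sigma)
  }
  for (o in orfs) L[o, ] <- phage_row(o, salt = 0)

  # Kinetic-separation invariant for planted-pair partners: over its
  # screening window, a partner's realized profile must not correlate
  # beyond partner_sep with any rival ORF. At |rho| <= 0.97 the exactly
  # calibrated host partner is mathematically unable to cross the
  # |cor| > 0.99 edge threshold against a rival, so planted pair counts
  # are recovered exactly. Violating partners get their kinetic
  # deviations and noise redrawn (deterministically, from salted
  # substreams). Merged-plan partners are checked only against ORFs
  # outside the plan: extra edges among planted nodes do not change the
  # planted node sets.
  if (condition == "infected" && (length(tr_partners) || length(merged_partners))) {
    pr <- config$profile
    salts <- setNames(rep(0L, length(orfs)), orfs)
    checks <- list(
      list(partners = tr_partners,
           times = stage_sample_times("middle", tp),
           exempt = character()),
      list(partners = merged_partners, times = post,
           exempt = merged_partners)
    )
    for (round in 1:3) {
      changed <- FALSE
      for (ck in checks) {
        cols <- samples$time_min %in% ck$times
        if (sum(cols) < 3) next
        for (a in ck$partners) {
          rivals <- setdiff(orfs, union(a, ck$exempt))
          if (!length(rivals)) next
          B <- t(L[rivals, cols, drop = FALSE])
          repeat {
            r <- suppressWarnings(cor(L[a, cols], B))
            r[is.na(r)] <- 0
            if (max(abs(r)) <= pr$partner_sep ||
                salts[[a]] >= pr$max_sep_tries) break
            salts[[a]] <- salts[[a]] + 1L
            L[a, ] <- phage_row(a, salt = salts[[a]])
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }

  host_bg <- numeric(length(hosts))
  names(host_bg) <- hosts
  for (g in hosts) {
    set.seed(.phx_substream(config$seed, g, "baseline"))
    host_bg[[g]] <- rnorm(1, bl$host_mean, bl$host_sd)
    set.seed(.phx_substream(config$seed, g, "noise", condition))
    L[g, ] <- host_bg[[g]] + rnorm(ns, 0, sigma)
  }

  if (condition == "infected") {
    dp <- config$deg_plan
    if (nrow(dp)) {
      shift <- ifelse(dp$direction == "up", dp$log2fc, -dp$log2fc)
      for (t in unique(dp$time_min)) {
        rows <- dp$time_min == t
        cols <- samples$time_min == t
        L[dp$gene_id[rows], cols] <- L[dp$gene_id[rows], cols] + shift[rows]
      }
    }
    plant_pairs <- function(plan, window_times) {
      cols <- which(samples$time_min %in% window_times)
      for (k in seq_len(nrow(plan))) {
        p <- plan[k, ]
        dev <- .phx_pair_values(config, p$host_id, L[p$phage_id, cols],
                                p$sign, p$target)
        if (!is.null(dev)) L[p$host_id, cols] <<- host_bg[[p$host_id]] + dev
      }
    }
    plant_pairs(config$tr_pair_plan, stage_sample_times("middle", tp))
    plant_pairs(config$merged_pair_plan, post)
  }

  if (config$sample_scale_sigma > 0) {
    set.seed(.phx_substream(config$seed, "__sample_scale__", condition))
    L <- sweep(L, 2, rnorm(ns, 0, config$sample_scale_sigma), `+`)
  }

  structure(list(values = 2^L, samples = samples, features = features),
            class = "phx_expr")
}

#' Generate a synthetic gene-to-term annotation map
#'
#' Assigns every host gene of a configuration to `terms_per_gene` terms
#' drawn uniformly (without replacement) from `n_terms` terms, emulating a
#' pathway or functional-class table. An optional `spike` concentrates a
#' chosen gene set inside one designated term so that downstream
#' over-representation analysis has a planted true positive: the spiked
#' term's membership is replaced by the given genes plus deterministic
#' filler up to `size`.
#'
#' @param config A `phx_config` (supplies the host gene universe and seed).
#' @param terms_per_gene Number of terms assigned to each host gene; 0
#'   returns an empty map.
#' @param n_terms Number of terms, at least 1.
#' @param spike Optional list with elements `term` (term id to spike),
#'   `genes` (character vector of member genes) and optionally `size`
#'   (total membership; defaults to `length(genes)`).
#' @param vocabulary `"pathway"` or `"function"`; stored on each term.
#' @return A `phx_annotation` object: list with `mapping` (data frame
#'   `gene_id`, `term_id`) and `terms` (data frame `term_id`, `name`,
#'   `vocabulary`).
#' @export
generate_annotations <- function(config, terms_per_gene = 2, n_terms,
                                 spike = NULL,
                                 vocabulary = c("pathway", "function")) {
  validate_config(config)
  vocabulary <- match.arg(vocabulary)
  if (n_terms < 1) stop("n_terms must be >= 1")
  if (terms_per_gene > n_terms) stop("terms_per_gene cannot exceed n_terms")
  restore <- .phx_push_rng()
  on.exit(restore())

  prefix <- if (vocabulary == "pathway") "PWY" else "FUN"
  term_ids <- sprintf("%s%03d", prefix, seq_len(n_terms))
  terms <- data.frame(term_id = term_ids,
                      name = sprintf("%s term %d", vocabulary, seq_len(n_terms)),
                      vocabulary = vocabulary, stringsAsFactors = FALSE)

  hosts <- config$host_ids
  if (terms_per_gene == 0) {
    mapping <- data.frame(gene_id = character(), term_id = character(),
                          stringsAsFactors = FALSE)
  } else {
    set.seed(.phx_substream(config$seed, "__annotations__", vocabulary,
                            n_terms, terms_per_gene))
    picks <- lapply(hosts, function(g) sample(term_ids, terms_per_gene))
    mapping <- data.frame(gene_id = rep(hosts, each = terms_per_gene),
                          term_id = unlist(picks), stringsAsFactors = FALSE)
  }

  if (!is.null(spike)) {
    stopifnot(is.list(spike), !is.null(spike$term), !is.null(spike$genes))
    if (!all(spike$genes %in% hosts)) {
      stop("spike genes must belong to the host gene universe")
    }
    size <- if (is.null(spike$size)) length(spike$genes) else spike$size
    if (size < length(spike$genes)) stop("spike size smaller than its gene set")
    filler <- setdiff(hosts, spike$genes)[seq_len(size - length(spike$genes))]
    members <- c(spike$genes, filler)
    mapping <- mapping[mapping$term_id != spike$term, ]
    mapping <- rbind(mapping,
                     data.frame(gene_id = members, term_id = spike$term,
                                stringsAsFactors = FALSE))
    if (!spike$term %in% terms$term_id) {
      terms <- rbind(terms, data.frame(term_id = spike$term,
                                       name = spike$term,
                                       vocabulary = vocabulary,
                                       stringsAsFactors = FALSE))
    }
  }
  rownames(mapping) <- NULL
  structure(list(mapping = mapping, terms = terms), class = "phx_annotation")
}

#' Generate a one-step growth curve
#'
#' Produces an idealized phage one-step growth curve: the titer stays flat
#' at the number of initially infected cells (infective centers) through
#' the latent period, rises smoothly (a smoothstep ramp) during the release
#' phase, and plateaus at `infected_cells * (1 + burst_size)` from
#' `rise_min` onward, so that [compute_burst_size()] recovers `burst_size`.
#'
#' @param burst_size Progeny phage released per infected cell (>= 0).
#' @param latent_min End of the latent (flat) phase, minutes.
#' @param rise_min Time at which the final plateau is reached; must exceed
#'   `latent_min`.
#' @param infected_cells Number of initially infected cells.
#' @param by Sampling interval in minutes (default 10, the bench protocol).
#' @return A `phx_growth` object: list with `times`, `titers`,
#'   `infected_cells`.
#' @export
generate_growth_curve <- function(burst_size, latent_min, rise_min,
                                  infected_cells, by = 10) {
  if (burst_size < 0) stop("burst_size must be >= 0")
  if (rise_min <= latent_min) stop("rise_min must exceed latent_min")
  times <- seq(0, rise_min + 2 * by, by = by)
  s <- pmin(pmax((times - latent_min) / (rise_min - latent_min), 0), 1)
  ramp <- s^2 * (3 - 2 * s)
  titers <- infected_cells * (1 + burst_size * ramp)
  structure(list(times = times, titers = titers,
                 infected_cells = infected_cells),
            class = "phx_growth")
}

#' @export
print.phx_config <- function(x, ...) {
  cat(sprintf(
    "phx synthetic config: %d phage ORFs, %d host genes, %d time points x %d replicates\n",
    length(x$phage_class_map), x$host_gene_count, length(x$time_points),
    x$replicates))
  cat(sprintf("  deg_plan: %d planted gene-timepoint effects; pairs: %d TR + %d merged; sigma = %g; seed = %d\n",
              nrow(x$deg_plan), nrow(x$tr_pair_plan), nrow(x$merged_pair_plan),
              x$noise_sigma, x$seed))
  invisible(x)
}

#' @export
print.phx_expr <- function(x, ...) {
  cat(sprintf("phx expression matrix: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$condition), collapse = ", ")))
  invisible(x)
}
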