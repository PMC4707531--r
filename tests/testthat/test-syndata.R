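test_that("paper-mirror configuration plants the study-scale structure", {
  cfg <- paper_mirror_config(seed = 1)
  expect_length(cfg$phage_class_map, 71)
  expect_identical(as.integer(table(cfg$phage_class_map)[c("early", "middle", "late")]),
                   c(15L, 35L, 21L))
  expect_identical(unname(cfg$phage_class_map[sprintf("ORF%d", 57:71)]),
                   rep("early", 15))
  expect_identical(cfg$host_gene_count, 5633L)
  expect_length(cfg$tr_genes, 476)

  # TR pair plan: 24 negative, 1 positive (ORF52-PA0163), distinct TR hosts
  tp <- cfg$tr_pair_plan
  expect_identical(nrow(tp), 25L)
  expect_identical(sum(tp$sign == -1), 24L)
  pos <- tp[tp$sign == 1, ]
  expect_identical(pos$phage_id, "ORF52")
  expect_identical(pos$host_id, "PA0163")
  expect_false(anyDuplicated(tp$host_id) > 0)
  expect_true(all(tp$host_id %in% cfg$tr_genes))

  # merged plan: 14 early ORFs, 110 distinct hosts, all positive
  mp <- cfg$merged_pair_plan
  expect_identical(nrow(mp), 110L)
  expect_length(unique(mp$phage_id), 14)
  expect_true(all(cfg$phage_class_map[unique(mp$phage_id)] == "early"))
  expect_true(all(mp$sign == 1))

  # DEG plan reproduces the printed per-timepoint and union counts
  dp <- cfg$deg_plan
  down <- dp[dp$direction == "down", ]
  up <- dp[dp$direction == "up", ]
  expect_identical(nrow(dp), 4129L)
  expect_length(unique(dp$gene_id), 2160)
  expect_length(unique(down$gene_id), 2120)
  expect_length(unique(up$gene_id), 40)
  expect_identical(sum(down$time_min == 30), 1852L)
  expect_identical(sum(up$time_min == 30), 28L)
  expect_identical(sum(up$time_min == 5), 0L)
  expect_true(all(dp$log2fc >= 2.5))
  expect_true(cfg$noise_sigma <= 0.1)
})

test_that("configuration invariants are validated", {
  expect_error(synthetic_config(time_points = c(5, 10)), "reference")
  expect_error(synthetic_config(time_points = c(0, 10, 10)), "increasing")
  expect_error(synthetic_config(phage_class_map = c(ORF1 = "dawn")), "class")
  expect_error(
    synthetic_config(host_gene_count = 5,
                     deg_plan = data.frame(gene_id = "PA9999", time_min = 5,
                                           direction = "down", log2fc = 3)),
    "host gene set")
  expect_error(
    synthetic_config(phage_class_map = c(ORF1 = "middle"), host_gene_count = 5,
                     tr_pair_plan = data.frame(phage_id = "ORF1",
                                               host_id = "PA0001",
                                               sign = -1, target = 0.997)),
    "tr_genes")
  # a host may be partner of at most one pair
  expect_error(
    synthetic_config(phage_class_map = c(ORF1 = "middle", ORF2 = "middle"),
                     host_gene_count = 5, tr_genes = "PA0001",
                     tr_pair_plan = data.frame(phage_id = c("ORF1", "ORF2"),
                                               host_id = "PA0001",
                                               sign = -1, target = 0.997)),
    "at most one")
})

test_that("generation is deterministic and insensitive to added features", {
  cfg <- synthetic_config(phage_class_map = c(ORF1 = "early", ORF2 = "late"),
                          host_gene_count = 20, seed = 11)
  x1 <- generate_expression(cfg)
  x2 <- generate_expression(cfg)
  expect_identical(x1$values, x2$values)

  # enlarging the host set leaves the shared features' draws untouched
  cfg_big <- synthetic_config(phage_class_map = cfg$phage_class_map,
                              host_gene_count = 40, seed = 11)
  x3 <- generate_expression(cfg_big)
  shared <- rownames(x1$values)
  expect_identical(x1$values[shared, ], x3$values[shared, ])
})

test_that("zero noise and empty plans give constant host baselines", {
  cfg <- synthetic_config(host_gene_count = 15, noise_sigma = 0, seed = 3)
  x <- generate_expression(cfg)
  host_rows <- x$values[x$features$feature_id[!x$features$is_reference], ]
  expect_true(all(apply(host_rows, 1, function(v) diff(range(v)) == 0)))
})

test_that("the reference feature is noise-free and identical in all samples", {
  x <- generate_expression(paper_mirror_config(seed = 2))
  ref <- x$values["16S", ]
  expect_identical(unname(diff(range(ref))), 0)
})

test_that("phage kinetics peak inside their class stage window", {
  x <- mirror_data(1)$norm
  fc <- log_fold_change(x)
  phage <- x$features[x$features$organism == "phage", ]
  times <- as.numeric(colnames(fc))
  peak <- times[apply(unclass(fc)[phage$feature_id, ], 1, which.max)]
  win <- list(early = c(5, 10), middle = c(20, 30), late = c(80, 80))
  ok <- mapply(function(p, cl) p >= win[[cl]][1] && p <= win[[cl]][2],
               peak, phage$class_truth)
  expect_true(all(ok))
  # early example: an early ORF attains its maximum at 5 or 10 min
  expect_true(peak[phage$feature_id == "ORF60"] %in% c(5, 10))
})

test_that("drug conditions silence the blocked classes and spare the rest", {
  cfg <- paper_mirror_config(seed = 4)
  inf <- generate_expression(cfg, "infected")
  cm <- generate_expression(cfg, "infected+Cm")
  paa <- generate_expression(cfg, "infected+PAA")
  ph <- cm$features[cm$features$organism == "phage", ]
  base <- function(x, ids) rowMeans(x$values[ids, x$samples$time_min == 0])
  peak_ratio <- function(x, ids) {
    post <- setdiff(unique(x$samples$time_min), 0)
    peaks <- do.call(pmax, lapply(post, function(t) {
      rowMeans(x$values[ids, x$samples$time_min == t, drop = FALSE])
    }))
    peaks / base(x, ids)
  }
  mean_ratio <- function(x, ids) {
    rowMeans(x$values[ids, x$samples$time_min > 0]) / base(x, ids)
  }
  early <- ph$feature_id[ph$class_truth == "early"]
  silenced_cm <- ph$feature_id[ph$class_truth %in% c("middle", "late")]
  late <- ph$feature_id[ph$class_truth == "late"]

  expect_true(all(peak_ratio(cm, early) > 2))
  expect_true(all(mean_ratio(cm, silenced_cm) > 1 / 1.5 &
                    mean_ratio(cm, silenced_cm) < 1.5))
  expect_true(all(peak_ratio(paa, setdiff(ph$feature_id, late)) > 2))
  expect_true(all(mean_ratio(paa, late) > 1 / 1.5 &
                    mean_ratio(paa, late) < 1.5))
  expect_error(generate_expression(cfg, "infected+Rif"))
  # under the inhibitors the infection-specific host plans do not apply
  expect_true(all(abs(log2(mean_ratio(cm, cfg$deg_plan$gene_id[1:5]))) < 0.5))
})

test_that("planted pairs hit their target correlation over their window", {
  for (s in 1:20) {
    d <- mirror_data(s)
    L <- log2(d$norm$values)
    mid <- d$norm$samples$time_min %in% c(10, 20, 30)
    post <- d$norm$samples$time_min > 0
    tp <- d$config$tr_pair_plan
    r_tr <- mapply(function(p, h) cor(L[p, mid], L[h, mid]),
                   tp$phage_id, tp$host_id)
    expect_equal(unname(r_tr), tp$sign * tp$target, tolerance = 1e-12)
    mp <- d$config$merged_pair_plan
    r_m <- mapply(function(p, h) cor(L[p, post], L[h, post]),
                  mp$phage_id, mp$host_id)
    expect_equal(unname(r_m), mp$sign * mp$target, tolerance = 1e-12)
  }
})

test_that("annotation generation covers terms and supports spiking", {
  cfg <- paper_mirror_config(seed = 1)
  ann <- generate_annotations(cfg, terms_per_gene = 2, n_terms = 27,
                              vocabulary = "function")
  expect_s3_class(ann, "phx_annotation")
  members <- table(ann$mapping$term_id)
  expect_length(members, 27)
  expect_true(all(members > 0))
  expect_true(all(ann$mapping$gene_id %in% cfg$host_ids))

  spiked <- generate_annotations(cfg, terms_per_gene = 1, n_terms = 10,
                                 spike = list(term = "PWY001",
                                              genes = cfg$host_ids[1:50],
                                              size = 60))
  got <- spiked$mapping$gene_id[spiked$mapping$term_id == "PWY001"]
  expect_length(got, 60)
  expect_true(all(cfg$host_ids[1:50] %in% got))

  none <- generate_annotations(cfg, terms_per_gene = 0, n_terms = 5)
  expect_identical(nrow(none$mapping), 0L)
})

test_that("growth curves plateau at the planted burst size", {
  g <- generate_growth_curve(31, 30, 80, 1e8)
  expect_true(all(g$titers >= 0))
  expect_identical(g$titers[g$times <= 30], rep(1e8, 4))
  expect_equal(max(g$titers), 1e8 * 32)
  expect_error(generate_growth_curve(10, 50, 40, 1e6), "exceed")
  flat <- generate_growth_curve(0, 30, 80, 1e8)
  expect_true(diff(range(flat$titers)) == 0)
})
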