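test_that("pearson_with_p matches the covariance-formula oracle", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1.1, 1.9, 3.2, 3.9, 5.0)
  got <- pearson_with_p(x, y)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$cor, r_manual, tolerance = 1e-12)
  expect_equal(got$p, stats::cor.test(x, y)$p.value, tolerance = 1e-12)
  # perfect anticorrelation: r = -1, p = 0
  anti <- pearson_with_p(x, -x)
  expect_equal(anti$cor, -1, tolerance = 1e-12)
  expect_identical(anti$p, 0)
  expect_error(pearson_with_p(x, rep(1, 5)), "constant")
  expect_error(pearson_with_p(1:2, 1:2), "3 samples")
})

test_that("null correlations have uniform p-values", {
  set.seed(31)
  p <- replicate(400, pearson_with_p(rnorm(30), rnorm(30))$p)
  expect_equal(mean(p), 0.5, tolerance = 0.05)
  expect_equal(mean(p < 0.1), 0.1, tolerance = 0.05)
})

test_that("screen_pairs equals the naive all-pairs oracle", {
  cfg <- synthetic_config(
    phage_class_map = setNames(rep(c("early", "middle", "late"), c(6, 8, 6)),
                               sprintf("ORF%d", 1:20)),
    host_gene_count = 20, seed = 17)
  x <- normalize_to_reference(generate_expression(cfg))
  # loose thresholds so the comparison exercises non-trivial edge sets
  got <- screen_pairs(x, times = c(5, 10, 20, 30, 80), cor_min = 0.3,
                      alpha = 0.2)
  want <- screen_oracle(x, times = c(5, 10, 20, 30, 80), cor_min = 0.3,
                        alpha = 0.2)
  key <- function(d) sort(paste(d$phage_id, d$host_id))
  expect_identical(key(got), key(want))
  m <- merge(got, want, by = c("phage_id", "host_id"))
  expect_equal(m$cor.x, m$cor.y, tolerance = 1e-10)
  expect_equal(m$p.x, m$p.y, tolerance = 1e-10)
  expect_true(all(got$sign == ifelse(got$cor > 0, "+", "-")))
})

test_that("screen thresholds are strict and monotone", {
  cfg <- synthetic_config(
    phage_class_map = setNames(rep("middle", 10), sprintf("ORF%d", 1:10)),
    host_gene_count = 30, seed = 23)
  x <- normalize_to_reference(generate_expression(cfg))
  base <- screen_pairs(x, times = c(10, 20, 30), cor_min = 0.2, alpha = 0.3)
  # raising cor_min or lowering alpha never adds an edge
  for (cm in c(0.4, 0.6, 0.9)) {
    sub <- screen_pairs(x, times = c(10, 20, 30), cor_min = cm, alpha = 0.3)
    expect_true(all(paste(sub$phage_id, sub$host_id) %in%
                      paste(base$phage_id, base$host_id)))
    expect_true(all(abs(sub$cor) > cm))
  }
  for (al in c(0.1, 0.01)) {
    sub <- screen_pairs(x, times = c(10, 20, 30), cor_min = 0.2, alpha = al)
    expect_true(all(paste(sub$phage_id, sub$host_id) %in%
                      paste(base$phage_id, base$host_id)))
    expect_true(all(sub$p < al))
  }
  # a window below three samples is a hard error naming the minimum
  one_rep <- synthetic_config(phage_class_map = c(ORF1 = "middle"),
                              host_gene_count = 3, replicates = 1, seed = 2)
  x1 <- normalize_to_reference(generate_expression(one_rep))
  expect_error(screen_pairs(x1, times = 20), "at least 3")
})

test_that("networks are bipartite with degree K-scores conserved", {
  set.seed(91)
  for (i in 1:20) {
    n_edge <- sample(3:40, 1)
    edges <- data.frame(
      phage_id = sample(sprintf("ORF%d", 1:8), n_edge, replace = TRUE),
      host_id = sample(sprintf("PA%04d", 1:12), n_edge, replace = TRUE),
      cor = runif(n_edge, 0.991, 0.999), p = 1e-6, sign = "+",
      stage = "early", n = 6)
    edges <- edges[!duplicated(edges[, 1:2]), ]
    net <- stage_network(edges)
    expect_identical(sum(net$nodes$k_score), 2L * nrow(net$edges))
    expect_true(all(net$edges$phage_id %in%
                      net$nodes$id[net$nodes$organism == "phage"]))
    expect_true(all(net$edges$host_id %in%
                      net$nodes$id[net$nodes$organism == "host"]))
    expect_true(all(net$nodes$k_score >= 1))   # no isolated nodes
  }
})

test_that("stage networks keep positive edges only; stars score correctly", {
  star <- data.frame(phage_id = "ORF60", host_id = sprintf("PA%04d", 1:5),
                     cor = 0.995, p = 1e-7, sign = "+", stage = "early", n = 6)
  net <- stage_network(star)
  expect_identical(net$nodes$k_score[net$nodes$id == "ORF60"], 5L)
  expect_true(all(net$nodes$k_score[net$nodes$organism == "host"] == 1L))
  single <- stage_network(star[1, ])
  expect_true(all(single$nodes$k_score == 1L))
  neg <- star
  neg$sign <- "-"; neg$cor <- -0.995
  expect_identical(nrow(stage_network(neg)$edges), 0L)
})

test_that("the middle-stage TR screen recovers the planted pair table", {
  for (s in 1:20) {
    d <- mirror_data(s)
    ts <- tr_screen(d$norm)
    plan <- d$config$tr_pair_plan
    expect_identical(ts$n_negative, 24L)
    expect_identical(ts$n_positive, 1L)
    got <- rbind(ts$negative, ts$positive)
    expect_setequal_chr(paste(got$phage_id, got$host_id, got$sign),
                        paste(plan$phage_id, plan$host_id,
                              ifelse(plan$sign > 0, "+", "-")))
  }
  # screening restricted to TRs requires a declared TR set
  cfg <- synthetic_config(phage_class_map = c(ORF1 = "middle"),
                          host_gene_count = 3, seed = 1)
  x <- normalize_to_reference(generate_expression(cfg))
  expect_error(tr_screen(x), "no transcriptional regulators")
})

test_that("null data yields no edges at the hard thresholds", {
  n_edges <- vapply(1:50, function(s) {
    cfg <- synthetic_config(
      phage_class_map = setNames(rep(c("early", "middle", "late"), c(3, 4, 3)),
                                 sprintf("ORF%d", 1:10)),
      host_gene_count = 100,
      tr_genes = sprintf("PA%04d", 1:100), seed = 5000 + s)
    x <- normalize_to_reference(generate_expression(cfg))
    tr_screen(x)$n_negative + tr_screen(x)$n_positive
  }, 0L)
  expect_gte(sum(n_edges == 0), 45)
})

test_that("the merged network contains only planted early genes and hosts", {
  for (s in 1:20) {
    d <- mirror_data(s)
    mn <- merged_network(d$norm)
    plan <- d$config$merged_pair_plan
    hosts <- mn$network$nodes$id[mn$network$nodes$organism == "host"]
    phage <- mn$network$nodes$id[mn$network$nodes$organism == "phage"]
    expect_setequal_chr(hosts, plan$host_id)
    expect_setequal_chr(phage, unique(plan$phage_id))
    expect_identical(mn$classes_present, "early")
    expect_true(all(mn$edges$cor > 0))
    # every planted pair is recovered
    expect_true(all(paste(plan$phage_id, plan$host_id) %in%
                      paste(mn$edges$phage_id, mn$edges$host_id)))
  }
})

test_that("merged networks tabulate function targets and enforce time points", {
  d <- mirror_data(1)
  ann <- generate_annotations(d$config, terms_per_gene = 1, n_terms = 20,
                              vocabulary = "function")
  mn <- merged_network(d$norm, annotation = ann)
  ft <- mn$function_targets
  expect_true(all(ft$n_targets >= 1))
  # per-ORF totals equal per-ORF distinct host target counts
  per_orf <- tapply(ft$n_targets, ft$phage_id, sum)
  deg <- table(mn$edges$phage_id)
  expect_equal(as.integer(per_orf[names(deg)]), as.integer(deg))

  sub <- d$norm
  keep <- sub$samples$time_min != 80
  sub$values <- sub$values[, keep]
  sub$samples <- sub$samples[keep, ]
  expect_error(merged_network(sub, times = c(5, 10, 20, 30, 80)),
               "missing time point")
})

test_that("adjacency report flags genomically contiguous components", {
  edges <- data.frame(
    phage_id = c("ORF64", "ORF65", "ORF60", "ORF70"),
    host_id = c("PA0001", "PA0001", "PA0002", "PA0002"),
    cor = 0.995, p = 1e-8, sign = "+", stage = "merged", n = 15)
  net <- stage_network(edges)
  rep <- adjacency_cluster_report(net)
  comp <- rep$components
  contiguous <- comp$contiguous[grepl("ORF64", comp$orfs)]
  split_comp <- comp$contiguous[grepl("ORF60", comp$orfs)]
  expect_true(contiguous)        # ORF64-65 are adjacent on the genome
  expect_false(split_comp)       # ORF60 and ORF70 are not
  expect_equal(rep$contiguity_fraction, 0.5)
  # single-ORF components are contiguous by convention
  solo <- stage_network(edges[1, ])
  expect_true(all(adjacency_cluster_report(solo)$components$contiguous))
})
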