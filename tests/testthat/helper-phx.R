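# Shared fixtures: small configurations and a memoised cache of
# full-scale mirror data sets (several multi-seed recovery tests reuse
# the same generated matrices).

.phx_cache <- new.env(parent = emptyenv())

mirror_data <- function(seed, condition = "infected") {
  key <- paste0("mirror-", seed, "-", condition)
  if (is.null(.phx_cache[[key]])) {
    cfg <- paper_mirror_config(seed = seed)
    .phx_cache[[key]] <- list(
      config = cfg,
      norm = normalize_to_reference(generate_expression(cfg, condition))
    )
  }
  .phx_cache[[key]]
}

# 71-ORF mirror kinetics without the host-side plans: fast generation for
# phage-only classing / clustering tests.
phage_only_config <- function(seed) {
  full <- paper_mirror_config(seed = 1)
  synthetic_config(phage_class_map = full$phage_class_map,
                   host_gene_count = 1, seed = seed)
}

# A small host-only configuration with a planted DEG plan.
small_deg_config <- function(seed, n_genes = 300, plan = NULL) {
  synthetic_config(host_gene_count = n_genes, deg_plan = plan, seed = seed)
}

expect_setequal_chr <- function(a, b) {
  expect_identical(sort(unique(a)), sort(unique(b)))
}

# Naive screening oracle: loop all phage x host pairs with cor.test.
screen_oracle <- function(x, times, cor_min = 0.99, alpha = 0.01) {
  cols <- x$samples$time_min %in% times
  L <- log2(x$values[, cols, drop = FALSE])
  ph <- x$features$feature_id[x$features$organism == "phage"]
  ho <- x$features$feature_id[x$features$organism == "host" &
                                !x$features$is_reference]
  out <- NULL
  for (p in ph) {
    for (h in ho) {
      if (sd(L[p, ]) == 0 || sd(L[h, ]) == 0) next
      ct <- stats::cor.test(L[p, ], L[h, ])
      if (ct$p.value < alpha && abs(ct$estimate) > cor_min) {
        out <- rbind(out, data.frame(phage_id = p, host_id = h,
                                     cor = unname(ct$estimate),
                                     p = ct$p.value))
      }
    }
  }
  out
}
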