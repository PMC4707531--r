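#' Write / read a synthetic configuration as YAML
#'
#' Serializes a [synthetic_config()] to YAML (plan tables become lists of
#' column vectors) and reads it back. Round-tripping a configuration
#' through YAML preserves the generated data exactly, since all
#' randomness derives from the stored seed.
#'
#' @param config A `phx_config`.
#' @param path YAML file path.
#' @return `write_config` invisibly returns `path`; `read_config` returns
#'   the `phx_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "phx_config"))
  x <- unclass(config)
  x$host_ids <- NULL  # derived from host_gene_count
  x$phage_class_map <- as.list(x$phage_class_map)
  for (f in c("deg_plan", "tr_pair_plan", "merged_pair_plan")) {
    x[[f]] <- as.list(x[[f]])
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  plan <- function(p, cols) {
    if (is.null(p) || !length(p$gene_id %||% p$phage_id)) NULL else {
      as.data.frame(lapply(p[cols], unlist), stringsAsFactors = FALSE)
    }
  }
  synthetic_config(
    time_points = unlist(x$time_points),
    replicates = x$replicates,
    phage_class_map = unlist(x$phage_class_map),
    host_gene_count = x$host_gene_count,
    tr_genes = as.character(unlist(x$tr_genes)),
    deg_plan = plan(x$deg_plan, c("gene_id", "time_min", "direction", "log2fc")),
    tr_pair_plan = plan(x$tr_pair_plan, c("phage_id", "host_id", "sign", "target")),
    merged_pair_plan = plan(x$merged_pair_plan,
                            c("phage_id", "host_id", "sign", "target")),
    noise_sigma = x$noise_sigma,
    sample_scale_sigma = x$sample_scale_sigma,
    reference_feature = x$reference_feature,
    reference_level = x$reference_level,
    pair_amp = x$pair_amp,
    baseline = lapply(x$baseline, unlist),
    profile = local({
      pr <- x$profile
      scalar <- setdiff(names(pr), "peak_ranges")
      pr[scalar] <- lapply(pr[scalar], unlist)
      if (!is.null(pr$peak_ranges)) {
        pr$peak_ranges <- lapply(pr$peak_ranges, unlist)
      }
      pr
    }),
    seed = x$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
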