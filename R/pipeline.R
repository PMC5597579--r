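write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Default pipeline configuration
#'
#' The run configuration consumed by [run_pipeline()]; fields may be
#' overridden from a YAML file or a named list. A seed is mandatory —
#' stochastic stages refuse to run unseeded.
#'
#' @param overrides named list (or path to a YAML file) of fields to
#'   override.
#' @return Named list of configuration values.
#' @export
default_config <- function(overrides = NULL) {
  cfg <- list(
    seed = NULL,
    bin_width = 50,
    n_genes = 200,
    n_bound = 60,
    h3_fold = 1.5,
    mix_ratio = 1 / 8,
    total_ip_reads = 1e6,
    total_input_reads = 1e6,
    pseudocount = 1,
    upstream = 500,
    downstream = 500,
    body_bins = 100,
    control_region = list(chrom = "chrI", start = 2000, end = 4000),
    loss = list(strains = list(wt = 0.002, mutant = 0.02),
                generations = 11, colonies = 3, n_cells = 2000))
  if (is.character(overrides) && length(overrides) == 1)
    overrides <- yaml::read_yaml(overrides)
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

#' Run the full synthetic analysis pipeline
#'
#' Wires every stage end-to-end on the demonstration occupancy model:
#' simulate dual-genome ChIP libraries (wild type and mutant H3 with
#' spike-in; CENP-A and the remodeler subunit without), compute spike-in
#' normalization factors, build normalized ratio and mutant-vs-wild-type
#' tracks, score region fold enrichment of the centromeric central core,
#' extract metagene matrices, classify genes high/low by exact two-means and
#' test the overlap of the two high sets, and estimate per-strain
#' minichromosome loss rates. All outputs are plain text files under
#' \code{out_dir}; a manifest with an MD5 checksum per file makes
#' determinism checkable.
#'
#' @param config a list from [default_config()], a named list of overrides,
#'   or a YAML path. Must carry a \code{seed}.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the manifest data.frame and the key
#'   computed quantities (normalization results, fold-change summaries,
#'   region enrichment, overlap, loss rates).
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- if (is.list(config) && !is.null(config$loss)) config
         else default_config(config)
  if (is.null(cfg$seed)) stop("pipeline configuration must provide a seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(path) { files[[length(files) + 1]] <<- path; path }

  model <- example_model(n_genes = cfg$n_genes, n_bound = cfg$n_bound,
                         h3_fold = cfg$h3_fold, bin_width = cfg$bin_width)
  layout <- model$layout
  write_layout(layout,
               domains_path = emit(file.path(out_dir, "domains.bed")),
               genes_path = emit(file.path(out_dir, "genes.bed")))

  mk_cfg <- function(off) sim_config(seed = cfg$seed + off,
                                     total_ip_reads = cfg$total_ip_reads,
                                     total_input_reads = cfg$total_input_reads,
                                     mix_ratio = cfg$mix_ratio)
  ## --- simulate ---------------------------------------------------------
  sims <- list(
    h3_wt = simulate_chip(model, mk_cfg(1), "wt", "H3"),
    h3_mut = simulate_chip(model, mk_cfg(2), "mutant", "H3"),
    cenpa = simulate_chip(model, mk_cfg(3), "wt", "CENP-A"),
    ies6 = simulate_chip(model, mk_cfg(4), "wt", "Ies6"))
  for (nm in names(sims)) {
    write_track(sims[[nm]]$ip_exp,
                emit(file.path(out_dir, paste0(nm, "_ip.bedgraph"))))
    write_track(sims[[nm]]$input_exp,
                emit(file.path(out_dir, paste0(nm, "_input.bedgraph"))))
  }
  counts_df <- do.call(rbind, lapply(names(sims), function(nm) {
    cc <- sims[[nm]]$counts
    data.frame(sample = nm, ip_exp = cc$ip_exp, input_exp = cc$input_exp,
               ip_spike = cc$ip_spike, input_spike = cc$input_spike)
  }))
  write_tsv(counts_df, emit(file.path(out_dir, "spike_counts.tsv")))

  ## --- normalize --------------------------------------------------------
  nr_wt <- n_factor_ip_vs_input(sims$h3_wt$counts)
  nr_mut <- n_factor_ip_vs_input(sims$h3_mut$counts)
  nr_mw <- n_factor_mut_vs_wt(sims$h3_mut$counts, sims$h3_wt$counts)
  norm_df <- data.frame(
    contrast = c("h3_wt_ip_vs_input", "h3_mut_ip_vs_input", "h3_mut_vs_wt"),
    mode = c(nr_wt$mode, nr_mut$mode, nr_mw$mode),
    e_ip = c(nr_wt$e_ip, nr_mut$e_ip, nr_mw$e_ip),
    n_factor = c(nr_wt$n_factor, nr_mut$n_factor, nr_mw$n_factor))
  write_tsv(norm_df, emit(file.path(out_dir, "normalization.tsv")))

  ## --- tracks -----------------------------------------------------------
  mw_track <- mutant_vs_wt_track(sims$h3_mut$ip_exp, sims$h3_wt$ip_exp,
                                 n_factor = nr_mw$n_factor,
                                 pseudocount = cfg$pseudocount)
  write_track(mw_track, emit(file.path(out_dir, "h3_mut_vs_wt.bedgraph")))

  ses_ies6 <- ses_scale(sims$ies6$ip_exp, sims$ies6$input_exp)
  n_ses <- (sims$ies6$counts$input_exp / sims$ies6$counts$ip_exp) /
    as.numeric(ses_ies6)
  ies6_ratio <- ratio_track(sims$ies6$ip_exp, sims$ies6$input_exp,
                            n_factor = n_ses, pseudocount = cfg$pseudocount)
  write_track(ies6_ratio, emit(file.path(out_dir, "ies6_enrichment.bedgraph")))

  d <- layout$domains
  cnt_region <- list(chrom = "chrI",
                     start = d$start[d$label == "cnt"][1],
                     end = d$end[d$label == "cnt"][1])
  fe <- region_fold_enrichment(sims$cenpa$ip_exp, sims$cenpa$input_exp,
                               target = cnt_region,
                               control = cfg$control_region)
  write_tsv(data.frame(target = "cnt", control = "control_locus",
                       fold_enrichment = fe$fold_enrichment),
            emit(file.path(out_dir, "region_enrichment.tsv")))

  ## --- metagene ---------------------------------------------------------
  m_ies6 <- metagene_matrix(ies6_ratio, layout, upstream = cfg$upstream,
                            downstream = cfg$downstream,
                            body_bins = cfg$body_bins)
  m_h3 <- metagene_matrix(mw_track, layout, upstream = cfg$upstream,
                          downstream = cfg$downstream,
                          body_bins = cfg$body_bins)
  write_tsv(data.frame(gene_id = m_ies6$gene_ids,
                       round(m_ies6$matrix, 6), check.names = FALSE),
            emit(file.path(out_dir, "ies6_metagene_matrix.tsv")))
  write_tsv(data.frame(position = seq_along(average_profile(m_ies6)),
                       ies6 = round(average_profile(m_ies6), 6),
                       h3_mut_vs_wt = round(average_profile(m_h3), 6)),
            emit(file.path(out_dir, "average_profiles.tsv")))
  write_tsv(data.frame(gene_id = heatmap_order(m_ies6)),
            emit(file.path(out_dir, "ies6_heatmap_order.tsv")))

  ## --- overlap ----------------------------------------------------------
  cl_ies6 <- kmeans_high_low(m_ies6$summary)
  cl_h3 <- kmeans_high_low(m_h3$summary)
  ov <- hypergeom_overlap(layout$genes$gene_id, cl_ies6$high, cl_h3$high)
  write_tsv(data.frame(universe = ov$universe_size,
                       high_enrichment = ov$set_a_size,
                       high_h3_increase = ov$set_b_size,
                       overlap = ov$overlap,
                       expected = ov$expected_overlap,
                       p_value = ov$p_value),
            emit(file.path(out_dir, "overlap.tsv")))

  ## --- lossrate ---------------------------------------------------------
  strains <- cfg$loss$strains
  loss_rows <- list()
  loss_results <- list()
  for (i in seq_along(strains)) {
    nm <- names(strains)[i]
    obs <- simulate_loss_assay(p_loss = strains[[i]],
                               N = cfg$loss$generations, I = 100,
                               colonies = cfg$loss$colonies,
                               n_cells = cfg$loss$n_cells,
                               seed = cfg$seed + 100 + i)
    res <- aggregate_loss(obs)
    loss_results[[nm]] <- res
    loss_rows[[nm]] <- data.frame(strain = nm, mean_rate = res$mean_rate,
                                  sd_rate = res$sd_rate,
                                  n_colonies = res$n_colonies)
  }
  write_tsv(do.call(rbind, loss_rows),
            emit(file.path(out_dir, "loss_rates.tsv")))

  ## --- manifest ---------------------------------------------------------
  manifest <- data.frame(file = basename(unlist(files)),
                         md5 = unname(tools::md5sum(unlist(files))))
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  bound <- model$bound_bins
  mw_vals <- track_concat(mw_track)
  invisible(list(
    manifest = manifest,
    model = model,
    normalization = norm_df,
    fold_change_bound = mean(mw_vals[bound]),
    fold_change_unbound = mean(mw_vals[-c(bound, model$cnt_bins)]),
    region_enrichment = fe,
    overlap = ov,
    loss = loss_results))
}
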