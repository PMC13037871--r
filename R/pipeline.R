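# End-to-end orchestration of the synthetic demonstration pipeline.

#' Default pipeline configuration
#'
#' Nested list of stage toggles and thresholds for [run_pipeline()]. All
#' stages run on synthetic data generated from `seed`, so the pipeline is
#' fully reproducible offline. The configuration round-trips losslessly
#' through JSON.
#'
#' @param seed global RNG seed.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, consensus = TRUE, curate = TRUE,
                  place = TRUE, diversity = TRUE, tempsignal = TRUE,
                  spatial = TRUE),
    simulate = list(n_tips = 12L, tip_age_range = c(40000, 120000),
                    pop_size = 50000, genome_length = 16569L,
                    clock = list(rate = 1.57e-8, model = "TN93",
                                 invariant_fraction = 0, kappa1 = 20,
                                 kappa2 = 40),
                    damage = list(p_ct_5p = 0.30, decay = 0.5,
                                  coverage = 20, contamination_frac = 0.05)),
    consensus = list(min_depth = 3L, min_agreement = 0.65,
                     damage_window = 3L, trim_quality = 20L, trim_max = 3L,
                     contamination_threshold = 0.10),
    curate = list(max_n = 2600L, deletion_mode = "partial", deletion_p = 0.90),
    spatial = list(max_range_ky = 30, window_ky = 10, rarefy_n = 60L,
                   rarefy_reps = 1000L, bin_width = 2, hotspot_reps = 99L)
  ), class = "pipeline_config")
}

checksum_files <- function(paths) {
  sums <- tools::md5sum(paths)
  data.frame(file = basename(names(sums)), md5 = unname(sums),
             stringsAsFactors = FALSE)
}

#' Run the full synthetic demonstration pipeline
#'
#' Executes the stages in dependency order (simulate, consensus, curate,
#' place, diversity, tempsignal, spatial), writing every artefact to
#' `out_dir` and a JSON run report (parameters, per-stage summaries and
#' MD5 checksums of all outputs) to `out_dir/report.json`. With a fixed
#' seed two runs produce identical reports. Existing output directories
#' are not overwritten unless `force = TRUE`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param force overwrite an existing non-empty `out_dir`.
#' @return The run report, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop_invalid("'", out_dir, "' exists and is not empty; use force = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  report <- list(package_version = as.character(utils::packageVersion("archaeomt")),
                 seed = config$seed, config = unclass(config), stages = list())
  paths <- character(0)
  sim <- NULL

  if (isTRUE(st$simulate)) {
    sc <- config$simulate
    clock <- do.call(clock_model, sc$clock)
    tree <- simulate_tree(sc$n_tips, sc$tip_age_range, sc$pop_size,
                          seed = config$seed)
    aln <- evolve_sequences(tree, clock, sc$genome_length,
                            return_internal = TRUE, seed = config$seed + 1L)
    root_seq <- attr(aln, "internal")[1, ]
    genome <- aln[1, ]
    profile <- do.call(damage_profile, sc$damage)
    contaminant <- aln[nrow(aln), ]
    frags <- fragment_and_damage(genome, profile, contaminant,
                                 seed = config$seed + 2L)
    scenario <- spread_scenario(
      slice_start_ka = c(80, 70, 60, 50), slice_end_ka = c(70, 60, 50, 40),
      n = c(70, 90, 110, 120), lon_width = c(32, 40, 46, 50))
    loc <- simulate_localities(scenario, seed = config$seed + 3L)
    p_tree <- file.path(out_dir, "tree.nwk")
    ape::write.tree(tree, file = p_tree)
    p_aln <- file.path(out_dir, "alignment.fasta"); write_fasta(aln, p_aln)
    p_fr <- file.path(out_dir, "fragments.tsv"); write_fragments(frags, p_fr)
    p_loc <- file.path(out_dir, "localities.csv"); write_localities(loc, p_loc)
    paths <- c(paths, p_tree, p_aln, p_fr, p_loc)
    sim <- list(tree = tree, aln = aln, root_seq = root_seq, genome = genome,
                frags = frags, loc = loc, clock = clock)
    report$stages$simulate <- list(
      n_tips = sc$n_tips, alignment_length = ncol(aln),
      n_fragments = nrow(frags),
      n_localities = nrow(loc))
  }
  if (is.null(sim)) stop_invalid("pipeline currently requires the simulate stage")

  consensus <- NULL
  if (isTRUE(st$consensus)) {
    cc <- config$consensus
    policy <- consensus_policy(cc$min_depth, cc$min_agreement,
                               cc$damage_window, cc$trim_quality, cc$trim_max)
    est <- contamination_estimate(config$simulate$damage$contamination_frac)
    gate <- contamination_gate(sim$frags, est, sim$genome,
                               threshold = cc$contamination_threshold,
                               window = cc$damage_window)
    masked <- mask_and_trim(gate$fragments, sim$genome, policy)
    consensus <- call_consensus(masked, policy,
                                genome_length = length(sim$genome))
    p_cons <- file.path(out_dir, "consensus.fasta")
    write_fasta(stats::setNames(list(consensus$calls), "consensus"), p_cons)
    p_depth <- file.path(out_dir, "depth.csv")
    utils::write.csv(data.frame(position = seq_along(consensus$depth),
                                depth = consensus$depth),
                     p_depth, row.names = FALSE)
    qc <- list(decision = gate$decision,
               deaminated_fraction =
                 mean(classify_deaminated(sim$frags, sim$genome,
                                          cc$damage_window)),
               n_count = consensus$n_count,
               completeness = consensus$completeness)
    p_qc <- file.path(out_dir, "consensus_qc.json")
    jsonlite::write_json(qc, p_qc, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p_cons, p_depth, p_qc)
    report$stages$consensus <- qc
  }

  if (isTRUE(st$curate)) {
    cu <- config$curate
    cf <- completeness_filter(sim$aln, cu$max_n)
    filtered <- site_deletion(cf$retained, cu$deletion_mode, cu$deletion_p)
    p_cur <- file.path(out_dir, "curated.fasta"); write_fasta(filtered, p_cur)
    p_log <- file.path(out_dir, "curation_log.csv")
    utils::write.csv(cf$log, p_log, row.names = FALSE)
    paths <- c(paths, p_cur, p_log)
    report$stages$curate <- list(n_in = nrow(sim$aln),
                                 n_retained = nrow(cf$retained),
                                 n_columns = ncol(filtered))
  }

  if (isTRUE(st$place) && !is.null(consensus)) {
    ages <- attr(sim$tree, "tip_ages")
    outgroup <- names(which.max(ages))
    snps <- node_defining_snps(sim$aln, sim$tree, outgroup)
    placement <- place_sequence(consensus, snps, sim$tree, omit_damage = TRUE)
    p_snp <- file.path(out_dir, "diagnostic_snps.csv")
    utils::write.csv(as.data.frame(snps), p_snp, row.names = FALSE)
    p_place <- file.path(out_dir, "placement.json")
    jsonlite::write_json(
      list(assigned_node = placement$assigned_node,
           confidence = placement$confidence_note,
           sites_omitted_damage = placement$sites_omitted_damage,
           path_support = placement$path_support),
      p_place, auto_unbox = TRUE, digits = NA)
    p_ptree <- file.path(out_dir, "placement.nwk")
    write_placement_tree(sim$tree, placement, p_ptree)
    paths <- c(paths, p_snp, p_place, p_ptree)
    report$stages$place <- list(n_snps = nrow(snps),
                                assigned_node = placement$assigned_node,
                                confidence = placement$confidence_note)
  }

  if (isTRUE(st$diversity)) {
    half <- nrow(sim$aln) %/% 2
    groups <- list(siteA = sim$aln[seq_len(half), , drop = FALSE],
                   siteB = sim$aln[(half + 1):nrow(sim$aln), , drop = FALSE])
    comp <- compare_site_diversity(groups, sim$aln)
    p_div <- file.path(out_dir, "diversity.csv")
    utils::write.csv(comp, p_div, row.names = FALSE)
    paths <- c(paths, p_div)
    report$stages$diversity <- comp[, c("site", "W", "p_raw", "p_adjusted")]
  }

  if (isTRUE(st$tempsignal)) {
    ages <- attr(sim$tree, "tip_ages")
    L <- ncol(sim$aln)
    dists <- vapply(rownames(sim$aln), function(id) {
      pd <- pairwise_distance(sim$aln[id, ], sim$root_seq)
      pd$d / pd$n_compared
    }, numeric(1))
    reg <- fit_temporal_regression(dists, ages)
    p_reg <- file.path(out_dir, "temporal_regression.json")
    jsonlite::write_json(list(slope = reg$slope, intercept = reg$intercept,
                              r_squared = reg$r_squared,
                              root_age_estimate = reg$root_age_estimate),
                         p_reg, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p_reg)
    report$stages$tempsignal <- list(slope = reg$slope,
                                     r_squared = reg$r_squared)
  }

  if (isTRUE(st$spatial)) {
    sp <- config$spatial
    sliced <- filter_and_slice(sim$loc, sp$max_range_ky, sp$window_ky)
    p_slice <- file.path(out_dir, "slices.csv")
    utils::write.csv(sliced, p_slice, row.names = FALSE)
    dens <- kde_density(sliced$longitude, sliced$latitude)
    p_dens <- file.path(out_dir, "density.csv")
    utils::write.csv(data.frame(lon = rep(dens$lon, length(dens$lat)),
                                lat = rep(dens$lat, each = length(dens$lon)),
                                density = as.vector(dens$z)),
                     p_dens, row.names = FALSE)
    hot <- hotspot_permutation_test(sliced, reps = sp$hotspot_reps,
                                    seed = config$seed + 4L)
    p_hot <- file.path(out_dir, "hotspots.csv")
    utils::write.csv(hot, p_hot, row.names = FALSE)
    slices <- unique(sliced$slice[order(sliced$slice_start_ka,
                                        decreasing = TRUE)])
    sizes <- vapply(slices, function(s)
      length(unique(sliced$site_id[sliced$slice == s])), integer(1))
    base_lab <- slices[1]                       # oldest slice as baseline
    young <- rev(slices[-1])
    targ_lab <- young[which(sizes[young] >= min(sp$rarefy_n, max(sizes)))[1]]
    n_rar <- min(sp$rarefy_n, sizes[targ_lab])
    rar <- rarefy_spread(sliced[sliced$slice == base_lab, ],
                         sliced[sliced$slice == targ_lab, ],
                         n = n_rar, reps = sp$rarefy_reps,
                         bin_width = sp$bin_width, seed = config$seed + 5L)
    p_rar <- file.path(out_dir, "rarefaction.json")
    jsonlite::write_json(list(baseline = base_lab, target = targ_lab,
                              baseline_metrics = as.list(rar$baseline),
                              rarefied_medians = as.list(rar$medians),
                              p_perm = as.list(rar$p_perm)),
                         p_rar, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p_slice, p_dens, p_hot, p_rar)
    report$stages$spatial <- list(
      n_sliced = nrow(sliced), slices = slices,
      hotspot_p = stats::setNames(hot$p, hot$slice),
      rarefaction = list(baseline = as.list(rar$baseline),
                         medians = as.list(rar$medians),
                         p_perm = as.list(rar$p_perm)))
  }

  report$outputs <- checksum_files(paths)
  p_report <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, p_report, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(report)
}
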