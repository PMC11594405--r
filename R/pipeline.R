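# End-to-end orchestration: ingest -> align/extract -> curate -> metrics ->
# group -> census -> downstream, over a dataset directory of the layout
# written by emit_dataset() (structures/, predicted/, domain_definitions.tsv,
# sequences.fasta, annotations.tsv, optional structure_proteins.tsv).

#' Pipeline configuration
#'
#' @param input_dir dataset directory.
#' @param out_dir optional directory for output tables (TSV + JSON manifest);
#'   `NULL` keeps results in memory only.
#' @param curation a [curation_config()].
#' @param alignment an [alignment_params()].
#' @param identity_threshold sequence-identity clustering threshold,
#'   default 0.95.
#' @param window_agreement sub-cluster window-overlap fraction, default 0.9.
#' @param tier_cutoffs census RMSD cutoffs in Angstrom, default `c(2.5, 5)`.
#' @param regions optional list of two [region_spec()] objects for the
#'   region-wise analysis.
#' @param region_protein protein accession the region analysis applies to.
#' @param compute_geometry,compute_sse toggles for the geometry and
#'   secondary-structure metric blocks.
#' @param terminus_filter apply the extended-terminus curation rule
#'   (default `TRUE`). Disable when terminal segments are genuine mobile
#'   structure rather than construct artifacts — e.g. hinge-bearing
#'   ensembles — since the rule cannot distinguish the two.
#' @param het_cutoff,decile protein-set selection parameters (see
#'   [select_protein_sets()]).
#' @param seed integer seed recorded in the manifest.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir = NULL,
                            curation = curation_config(),
                            alignment = alignment_params(),
                            identity_threshold = 0.95,
                            window_agreement = 0.9,
                            tier_cutoffs = c(2.5, 5),
                            regions = NULL, region_protein = NULL,
                            compute_geometry = TRUE, compute_sse = TRUE,
                            terminus_filter = TRUE,
                            het_cutoff = 2.5, decile = 0.1, seed = 1) {
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 curation = curation, alignment = alignment,
                 identity_threshold = identity_threshold,
                 window_agreement = window_agreement,
                 tier_cutoffs = tier_cutoffs, regions = regions,
                 region_protein = region_protein,
                 compute_geometry = compute_geometry,
                 compute_sse = compute_sse, terminus_filter = terminus_filter,
                 het_cutoff = het_cutoff,
                 decile = decile, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass_deep(cfg), auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Run the census pipeline end to end
#'
#' Executes the stages in order — ingest, align and extract predicted
#' counterparts, curation, per-instance metrics, two-level grouping, census
#' aggregation, and the downstream analyses — logging per-stage instance
#' counts to stderr. Reruns with the same configuration and inputs are
#' deterministic.
#'
#' @param cfg a [pipeline_config()].
#' @return list with the per-instance metric table, rejection table, group
#'   membership, census tables at sub-cluster / topology / class level, tier
#'   summaries, SSE-difference distribution, geometry trend, protein sets,
#'   enrichment results, optional region analysis, and the run manifest.
#' @export
run_pipeline <- function(cfg) {
  t0 <- Sys.time()
  paths <- list(defs = file.path(cfg$input_dir, "domain_definitions.tsv"),
                fasta = file.path(cfg$input_dir, "sequences.fasta"),
                structures = file.path(cfg$input_dir, "structures"),
                predicted = file.path(cfg$input_dir, "predicted"),
                annotations = file.path(cfg$input_dir, "annotations.tsv"))
  missing <- !vapply(paths, file.exists, TRUE)
  if (any(missing))
    stop_fc(paste0("missing input path(s): ",
                   paste(unlist(paths[missing]), collapse = ", ")),
            "fc_config_error")
  hash <- config_hash(cfg)
  log_stage <- function(...) message("[foldcensus] ", ...)

  # ingest ------------------------------------------------------------
  defs <- read_domain_definitions(paths$defs)
  ref_seqs <- Biostrings::readAAStringSet(paths$fasta)
  ref_seqs <- setNames(as.character(ref_seqs),
                       sub("\\s.*", "", names(ref_seqs)))
  pred_files <- list.files(paths$predicted, pattern = "\\.(pdb|cif)$",
                           full.names = TRUE)
  pred_models <- lapply(pred_files, read_structure)
  names(pred_models) <- vapply(pred_models, function(m) m$source_id, "")
  struct_files <- list.files(paths$structures, pattern = "\\.(pdb|cif)$",
                             full.names = TRUE)
  structures <- lapply(struct_files, read_structure)
  names(structures) <- vapply(structures, function(s) s$source_id, "")
  src_map_path <- file.path(cfg$input_dir, "structure_proteins.tsv")
  src_map <- if (file.exists(src_map_path))
    read.delim(src_map_path, stringsAsFactors = FALSE) else NULL
  log_stage("ingest: ", length(structures), " structures, ",
            length(defs), " definitions, ", length(pred_models),
            " predicted models")

  # extract experimental domain instances ------------------------------
  defs_by_acc <- split(defs, vapply(defs, function(d) d$protein_acc, ""))
  instances <- list()
  for (s in structures) {
    cand <- if (!is.null(src_map)) {
      accs <- src_map$protein_acc[src_map$source_id == s$source_id]
      unlist(defs_by_acc[accs], recursive = FALSE)
    } else defs
    for (d in cand) {
      inst <- tryCatch(extract_domain_instance(s, d), error = function(e) NULL)
      if (!is.null(inst)) instances[[length(instances) + 1]] <- inst
    }
  }
  log_stage("extract: ", length(instances), " domain instances")

  # align to reference, map onto predicted model, extract counterpart --
  pred_cache <- new.env()
  mapped <- list(); maps <- list(); pred_of <- character()
  for (inst in instances) {
    acc <- inst$protein_acc
    rs <- ref_seqs[[acc]]
    model <- pred_models[[acc]]
    if (is.null(rs) || is.null(model)) next
    aln <- align_glocal(inst$seq, rs, cfg$alignment)
    map <- tryCatch(suppressWarnings(build_residue_map(inst, model, aln)),
                    error = function(e) NULL)
    if (is.null(map)) next
    inst$pid <- attr(map, "pid")
    inst$window <- range(map$ref_pos)
    pd_key <- paste(acc, inst$domain_id, paste(range(map$ref_pos), collapse = "-"),
                    sep = "|")
    if (is.null(pred_cache[[pd_key]]))
      pred_cache[[pd_key]] <- extract_predicted_domain(model, map, like = inst)
    pred <- pred_cache[[pd_key]]
    inst$extended_termini <- if (isTRUE(cfg$terminus_filter)) tryCatch(
      suppressWarnings(detect_extended_termini(inst, pred, map, cfg$curation)),
      error = function(e) NA) else FALSE
    mapped[[length(mapped) + 1]] <- inst
    maps[[length(mapped)]] <- map
    pred_of[length(mapped)] <- pd_key
  }
  log_stage("map: ", length(mapped), " instances aligned to references")

  # curation ------------------------------------------------------------
  cur <- apply_curation(mapped, cfg$curation)
  kept_idx <- match(vapply(cur$kept, function(x) x$instance_id, ""),
                    vapply(mapped, function(x) x$instance_id, ""))
  log_stage("curate: ", length(cur$kept), " kept, ", nrow(cur$rejected),
            " rejected")

  # per-instance metrics -------------------------------------------------
  sse_cache <- new.env()
  rows <- list(); insts <- cur$kept
  for (i in seq_along(insts)) {
    inst <- insts[[i]]
    map <- maps[[kept_idx[i]]]
    pd_key <- pred_of[kept_idx[i]]
    pred <- pred_cache[[pd_key]]
    sup <- superpose_instances(inst, pred,
                               map_between(map, inst, pred))
    row <- data.frame(instance_id = inst$instance_id,
                      protein_acc = inst$protein_acc,
                      domain_id = inst$domain_id,
                      topology_code = inst$topology_code,
                      cath_class = sub("\\..*", "", inst$cath_code),
                      source = inst$source, n_res = inst$n_res,
                      pid = inst$pid, rmsd = sup$rmsd, rmsd100 = sup$rmsd100,
                      stringsAsFactors = FALSE)
    if (cfg$compute_geometry) {
      sasa <- shrake_rupley_sasa(inst)
      vol <- estimate_volume(inst)
      rt <- residue_table(inst)
      be <- classify_buried_exposed(
        sasa$residue_area[rt$key], paste(rt$aa, collapse = ""))
      src_het <- structures[[inst$source]]$het_atoms
      cc <- contact_counts(inst, src_het)
      row$av_ratio <- if (vol > 0) sasa$total / vol else NA_real_
      row$be_ratio <- be$be_ratio
      row$n_met <- cc$n_met
      row$n_lig <- cc$n_lig
    }
    if (cfg$compute_sse) {
      prof_i <- suppressWarnings(assign_sse(inst))
      if (is.null(sse_cache[[pd_key]]))
        sse_cache[[pd_key]] <- suppressWarnings(assign_sse(pred))
      prof_p <- sse_cache[[pd_key]]
      rt <- residue_table(inst)
      common_i <- match(map$inst_key, rt$key)
      rtp <- residue_table(pred)
      common_p <- match(map$model_key, rtp$key)
      ok <- !is.na(common_i) & !is.na(common_p)
      row$frac_helix <- prof_i$frac_helix
      row$frac_sheet <- prof_i$frac_sheet
      row$sse_diff <- sse_count_difference(
        subset_sse(prof_p, common_p[ok]), subset_sse(prof_i, common_i[ok]))
    }
    rows[[i]] <- row
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else
    stop_fc("no instances survived curation", "fc_pipeline_error")
  log_stage("metrics: ", nrow(metrics), " instances scored")

  # confidence filter over predicted counterparts -----------------------
  conf <- vapply(ls(pred_cache), function(k)
    confidence_filter(pred_cache[[k]], cfg$curation), TRUE)
  conf_ok_prot <- unique(vapply(strsplit(names(conf)[conf], "\\|"),
                                `[`, "", 1))

  # grouping -------------------------------------------------------------
  membership <- group_instances(insts, cfg$identity_threshold,
                                cfg$window_agreement)
  metrics <- merge(metrics, membership[, c("instance_id", "cluster_id",
                                           "subcluster_id")],
                   by = "instance_id", sort = TRUE)
  log_stage("group: ", length(unique(metrics$cluster_id)), " clusters, ",
            length(unique(metrics$subcluster_id)), " sub-clusters")

  # census ---------------------------------------------------------------
  census_sub <- aggregate_groups(metrics, "subcluster_id", "subcluster",
                                 cutoffs = cfg$tier_cutoffs)
  census_topo <- aggregate_groups(metrics, "topology_code", "topology",
                                  cutoffs = cfg$tier_cutoffs)
  census_class <- aggregate_groups(metrics, "cath_class", "class",
                                   cutoffs = cfg$tier_cutoffs)
  census_sub <- spectrum_order(census_sub)
  census_topo <- spectrum_order(census_topo)
  tiers <- lapply(cfg$tier_cutoffs, function(ct) tier_census(census_topo, ct))
  sse_dist <- if (cfg$compute_sse) {
    sel <- metrics$protein_acc %in% conf_ok_prot
    sse_diff_distribution(metrics$sse_diff[sel])
  } else NULL
  trend <- if (cfg$compute_geometry) geometry_trend(census_sub) else NULL

  # downstream -----------------------------------------------------------
  gp <- unique(metrics[, c("subcluster_id", "protein_acc")])
  names(gp) <- c("group_id", "protein_acc")
  sets <- select_protein_sets(census_sub, gp, cfg$het_cutoff, cfg$decile)
  ann <- read.delim(paths$annotations, stringsAsFactors = FALSE)
  enrichment <- hypergeom_enrich(sets$het, sets$con, ann)
  regions_out <- NULL
  if (!is.null(cfg$regions)) {
    accs <- cfg$region_protein %||% unique(metrics$protein_acc)
    sel <- vapply(insts, function(x) x$protein_acc %in% accs, TRUE)
    sel_maps <- maps[kept_idx[sel]]
    sel_insts <- insts[sel]
    pk <- pred_of[kept_idx[sel]]
    tabs <- two_region_rmsd(sel_insts, pred_cache[[pk[1]]], cfg$regions,
                            lapply(seq_along(sel_insts), function(i)
                              map_between(sel_maps[[i]], sel_insts[[i]],
                                          pred_cache[[pk[i]]])))
    log_stage("regions: ", sum(tabs$complete), " of ", nrow(tabs),
              " instances complete in both regions")
    regions_out <- list(table = tabs,
                        clusters = cluster_conformations(tabs),
                        fractions = threshold_fractions(tabs))
  }
  manifest <- list(config_hash = hash, seed = cfg$seed,
                   n_structures = length(structures),
                   n_instances = length(instances),
                   n_kept = nrow(metrics),
                   elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  out <- list(metrics = metrics, rejected = cur$rejected,
              membership = membership, census_subcluster = census_sub,
              census_topology = census_topo, census_class = census_class,
              tiers = tiers, sse_distribution = sse_dist,
              geometry_trend = trend, protein_sets = sets,
              enrichment = enrichment, regions = regions_out,
              manifest = manifest)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir, hash)
  out
}

# instance -> predicted-domain residue map (the predicted domain was built
# from the same model residues, so keys carry over directly)
map_between <- function(map, inst, pred) {
  structure(data.frame(inst_key = map$inst_key, model_key = map$model_key,
                       inst_pos = map$inst_pos, ref_pos = map$ref_pos,
                       stringsAsFactors = FALSE),
            class = c("residue_map", "data.frame"), pid = attr(map, "pid"))
}

write_pipeline_outputs <- function(out, out_dir, hash) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df) || !nrow(df)) return(invisible())
    df$config_hash <- hash
    write.table(df, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  wt(out$metrics, "instance_metrics")
  wt(out$rejected, "curation_rejections")
  wt(out$membership, "cluster_membership")
  wt(out$census_subcluster, "census_subcluster")
  wt(out$census_topology, "census_topology")
  wt(out$census_class, "census_class")
  wt(out$enrichment, "enrichment")
  if (!is.null(out$geometry_trend)) wt(out$geometry_trend, "geometry_trend")
  summary <- list(config_hash = hash, tiers = out$tiers,
                  sse_distribution = if (!is.null(out$sse_distribution))
                    unclass(out$sse_distribution) else NULL,
                  manifest = out$manifest)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible()
}
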