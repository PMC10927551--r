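#' Default analysis thresholds
#'
#' The thresholds used throughout the pipeline: strict OR > 0.15 for calling
#' ohnologous chromosome pairs, at least 20 retained genes per descendant
#' chromosome, q < 0.05 for chromosome-pair enrichment, e-value <= 1e-6 for
#' accepted hits, at least 5 distinct ingroup homologues for rule-2 outgroup
#' anchoring, TPM > 5 for the expressed state and a 40% narrow/broad
#' fraction separating strong from mild specialization.
#'
#' @return named list of thresholds.
#' @export
analysis_thresholds <- function() {
  list(or_ohnolog_min = 0.15, min_retained = 20L, q_max = 0.05,
       rbh_evalue_max = 1e-6, anchor_min_multi = 5L, tpm_min = 5,
       strong_spec_frac = 0.40)
}

#' Reconstruct ancestral chromosomes from simulated or loaded genomes
#'
#' The reconstruction stage: emits (or accepts) hit tables, derives
#' reciprocal best hits between the ingroup genomes and unidirectional best
#' hits from the outgroup, tests chromosome-pair enrichment, builds the
#' homology graph, ties ingroup chromosomes to outgroup linkage groups,
#' groups ingroup chromosomes into AC sets and anchors outgroup genes to
#' them.
#'
#' @param ingroups list of two (or more) ingroup `genome_map`s.
#' @param outgroup outgroup `genome_map`.
#' @param thresholds list from [analysis_thresholds()].
#' @param score_noise_sd,offtarget_rate hit-table noise settings.
#' @param seed RNG seed for hit-table emission.
#' @param hits optional pre-computed list with `ingroup` (hit table across
#'   the ingroup pair) and `outgroup` (outgroup-vs-ingroup tables); when
#'   NULL both are emitted from the genomes.
#' @return list with `acs` (anchored `ac_set`), `stats`, `graph`, `linkage`,
#'   `rbh_pairs` and `hits`.
#' @export
reconstruct_ac <- function(ingroups, outgroup, thresholds = analysis_thresholds(),
                           score_noise_sd = 10, offtarget_rate = 0.01,
                           seed = NULL, hits = NULL) {
  stopifnot(length(ingroups) >= 2L)
  seeds <- derive_seeds(seed, 1L + length(ingroups))
  if (is.null(hits)) {
    ing_hits <- emit_hit_table(ingroups, score_noise_sd = score_noise_sd,
                               offtarget_rate = offtarget_rate,
                               seed = seeds[[1L]])
    out_hits <- lapply(seq_along(ingroups), function(i)
      emit_hit_table(list(outgroup, ingroups[[i]]),
                     score_noise_sd = score_noise_sd,
                     offtarget_rate = offtarget_rate, seed = seeds[[i + 1L]]))
    hits <- list(ingroup = ing_hits, outgroup = out_hits)
  }
  rbh <- reciprocal_best_hits(hits$ingroup, thresholds$rbh_evalue_max)
  stats <- pair_enrichment(rbh, ingroups, q_max = thresholds$q_max)
  graph <- homologous_chromosome_graph(stats, q_max = thresholds$q_max)

  ## outgroup genes as reference queries
  og_ids <- outgroup$genes$gene_id
  out_tab <- do.call(rbind, hits$outgroup)
  out_tab <- out_tab[out_tab$qseqid %in% og_ids, , drop = FALSE]
  best_out <- best_hits_unidirectional(out_tab, thresholds$rbh_evalue_max)
  linkage <- outgroup_linkage_map(best_out, outgroup, ingroups,
                                  q_max = thresholds$q_max)
  acs <- group_ancestral_chromosomes(graph, outgroup_linkage = linkage,
    ingroup_species = vapply(ingroups, `[[`, "", "species"))
  acs <- anchor_outgroup_genes(acs, outgroup, ingroups, out_tab,
                               min_multi = thresholds$anchor_min_multi,
                               evalue_max = thresholds$rbh_evalue_max)
  list(acs = acs, stats = stats, graph = graph, linkage = linkage,
       rbh_pairs = rbh, hits = hits)
}

#' Retention-profile / overlapping-ratio analysis over AC gene lists
#'
#' Computes, for every AC, the retention profile of every chromosome of
#' every supplied genome, the filtered OR matrix, the ohnolog calls within
#' each species and the cross-species ortholog assignment.
#'
#' @param genomes named list of `genome_map`s.
#' @param ac_families named list AC -> family-id vector.
#' @param thresholds list from [analysis_thresholds()].
#' @return list with per-AC `matrices`, per-AC per-species `calls`,
#'   `multiplicity` (AC x species matrix) and per-AC `orthologs`
#'   (cross-species assignments, first two genomes, NULL when either side
#'   has no qualifying chromosome).
#' @export
or_analysis <- function(genomes, ac_families,
                        thresholds = analysis_thresholds()) {
  stopifnot(length(genomes) >= 1L, length(ac_families) >= 1L)
  spp <- vapply(genomes, `[[`, "", "species")
  matrices <- list(); calls <- list()
  multiplicity <- matrix(0L, nrow = length(ac_families), ncol = length(spp),
                         dimnames = list(names(ac_families), spp))
  orthologs <- list()
  for (ac in names(ac_families)) {
    fams <- ac_families[[ac]]
    profs <- list()
    for (g in genomes) {
      fam_by_chr <- split(g$genes$family_id, g$genes$chromosome)
      for (ch in names(fam_by_chr)) {
        profs[[length(profs) + 1L]] <-
          retention_profile(fams, fam_by_chr[[ch]], ac_id = ac,
                            species = g$species, chromosome = ch)
      }
    }
    m_all <- or_matrix(profs, min_retained = thresholds$min_retained)
    matrices[[ac]] <- m_all
    prof_sp <- vapply(profs, `[[`, "", "species")
    for (sp in spp) {
      m_sp <- or_matrix(profs[prof_sp == sp],
                        min_retained = thresholds$min_retained)
      cl <- call_ohnologues(m_sp, or_min = thresholds$or_ohnolog_min)
      calls[[ac]][[sp]] <- cl
      multiplicity[ac, sp] <- multiplicity_per_ac(list(cl))
    }
    if (length(spp) >= 2L && !m_all$empty) {
      sp_of <- sub(":.*$", "", m_all$labels)
      ra <- which(sp_of == spp[1L]); cb <- which(sp_of == spp[2L])
      if (length(ra) && length(cb)) {
        cross <- m_all$values[ra, cb, drop = FALSE]
        orthologs[[ac]] <- assign_orthologs(cross,
          or_min = thresholds$or_ohnolog_min)
      }
    }
  }
  list(matrices = matrices, calls = calls, multiplicity = multiplicity,
       orthologs = orthologs)
}

#' Run the full simulation-to-report pipeline
#'
#' Executes scenario simulation, AC reconstruction and OR analysis, writes
#' every stage table as TSV plus a machine-readable JSON summary into
#' `outdir`, and returns the summary. Rerunning with the same configuration
#' and seed reproduces the outputs exactly. The scenario must declare an
#' outgroup and a speciation into at least two genomes.
#'
#' @param scenario an [evolution_scenario()] with an `outgroup`.
#' @param thresholds list from [analysis_thresholds()].
#' @param outdir output directory (created; NULL skips writing).
#' @param seed master seed overriding `scenario$seed` when non-NULL.
#' @return summary list: `seed`, `thresholds`, `n_ac_simulated`,
#'   `n_ac_recovered`, `n_anchored_genes`, `multiplicity` (per AC x
#'   species), `or_median_ohnolog`, `or_median_ortholog`,
#'   `ortholog_classes`.
#' @export
run_pipeline <- function(scenario, thresholds = analysis_thresholds(),
                         outdir = NULL, seed = NULL) {
  stopifnot(inherits(scenario, "evolution_scenario"))
  if (!is.null(seed)) scenario$seed <- seed
  if (is.null(scenario$outgroup))
    stop("pipeline scenario must declare an outgroup", call. = FALSE)
  seeds <- derive_seeds(scenario$seed, 2L)

  sim <- run_scenario(scenario)
  if (length(sim$genomes) < 2L)
    stop("pipeline scenario must speciate into >= 2 genomes", call. = FALSE)
  rec <- reconstruct_ac(sim$genomes, sim$outgroup, thresholds,
                        seed = seeds[[2L]])
  fams <- ac_family_lists(rec$acs)
  ors <- or_analysis(sim$genomes, fams, thresholds)

  ohn_or <- unlist(lapply(names(ors$calls), function(ac)
    unlist(lapply(ors$calls[[ac]], function(cl) cl$edges$or))))
  ort_or <- unlist(lapply(ors$orthologs, function(o)
    if (!is.null(o)) o$best_or[o$class == "1:1"]))
  ort_classes <- table(unlist(lapply(ors$orthologs, function(o)
    if (!is.null(o)) o$class)))

  summary <- list(
    seed = scenario$seed, thresholds = thresholds,
    n_ac_simulated = scenario$n_ancestral_chromosomes,
    n_ac_recovered = length(unique(rec$acs$membership$ac)),
    n_anchored_genes = nrow(rec$acs$anchored),
    multiplicity = as.data.frame(ors$multiplicity),
    or_median_ohnolog = if (length(ohn_or)) stats::median(ohn_or) else NA,
    or_median_ortholog = if (length(ort_or)) stats::median(ort_or) else NA,
    ortholog_classes = as.list(ort_classes))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (g in sim$genomes)
      write_gene_map(g, file.path(outdir, paste0("genes_", g$species, ".tsv")))
    write_gene_map(sim$outgroup, file.path(outdir, "genes_outgroup.tsv"))
    data.table::fwrite(sim$truth, file.path(outdir, "truth_chromosomes.tsv"),
                       sep = "\t")
    data.table::fwrite(as.data.frame(rec$stats),
                       file.path(outdir, "pair_enrichment.tsv"), sep = "\t")
    data.table::fwrite(rec$acs$membership,
                       file.path(outdir, "ac_membership.tsv"), sep = "\t")
    data.table::fwrite(rec$acs$anchored,
                       file.path(outdir, "ac_anchored_genes.tsv"), sep = "\t")
    mult <- data.frame(ac = rownames(ors$multiplicity), ors$multiplicity,
                       check.names = FALSE)
    data.table::fwrite(mult, file.path(outdir, "multiplicity.tsv"), sep = "\t")
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  summary
}
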