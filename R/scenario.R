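#' Define a karyotype-evolution scenario
#'
#' A scenario is the declarative description of one simulated history: an
#' ancestral karyotype, an ordered event list (whole-genome duplications or
#' triplications, fusions, fissions, attrition, speciation) and default
#' attrition rates. [run_scenario()] executes it reproducibly from a single
#' seed.
#'
#' Events are lists with a `type` field:
#' * `wgd`: `multiplicity` (2 or 3), optional `mode` (`"auto"`/`"allo"`).
#' * `fusion`: either explicit `chr_a`/`chr_b`, or `n` random fusions (two
#'   distinct chromosomes drawn uniformly per fusion; products may fuse again).
#' * `fission`: explicit `chr`/`breakpoint`, or `n` random midpoint fissions.
#' * `attrition`: optional `loss_rate`/`transloc_rate`/`ssd_rate` overriding
#'   the scenario defaults.
#' * `speciate`: `names` (>= 2), optional per-split rates; terminal event.
#'
#' @param n_ancestral_chromosomes,genes_per_chromosome ancestral karyotype.
#' @param events ordered list of event specifications.
#' @param loss_rate,transloc_rate,ssd_rate default attrition rates used by
#'   `attrition`/`speciate` events that do not override them.
#' @param outgroup optional list `list(name=, loss_rate=, transloc_rate=,
#'   ssd_rate=)`: an unduplicated genome split from the ancestor before any
#'   event, used as the linkage reference for reconstruction.
#' @param seed integer master seed.
#' @return an `evolution_scenario` object.
#' @export
evolution_scenario <- function(n_ancestral_chromosomes, genes_per_chromosome,
                               events = list(), loss_rate = 0,
                               transloc_rate = 0, ssd_rate = 0,
                               outgroup = NULL, seed = NULL) {
  check_count(n_ancestral_chromosomes, "n_ancestral_chromosomes")
  check_count(genes_per_chromosome, "genes_per_chromosome")
  check_prob(loss_rate, "loss_rate")
  check_prob(transloc_rate, "transloc_rate")
  check_prob(ssd_rate, "ssd_rate")
  for (ev in events) {
    if (is.null(ev$type) ||
        !ev$type %in% c("wgd", "fusion", "fission", "attrition", "speciate"))
      stop("unknown event type: ", ev$type %||% "<missing>", call. = FALSE)
    if (identical(ev$type, "wgd") && !is.null(ev$multiplicity) &&
        !ev$multiplicity %in% c(2, 3))
      stop("wgd multiplicity must be 2 or 3", call. = FALSE)
  }
  structure(list(
    n_ancestral_chromosomes = as.integer(n_ancestral_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    events = events, loss_rate = loss_rate, transloc_rate = transloc_rate,
    ssd_rate = ssd_rate, outgroup = outgroup, seed = seed
  ), class = "evolution_scenario")
}

#' Read a scenario from a YAML file
#' @param path YAML file following the [evolution_scenario()] field names.
#' @return an `evolution_scenario`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("n_ancestral_chromosomes", "genes_per_chromosome", "events",
             "loss_rate", "transloc_rate", "ssd_rate", "outgroup", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown scenario keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(evolution_scenario, y)
}

#' Execute a karyotype-evolution scenario
#'
#' Applies the event list in order, deriving one sub-seed per stochastic step
#' from the scenario seed so the whole history is byte-reproducible. The
#' outgroup genome, if requested, is split from the ancestor before any event
#' and only undergoes its own attrition.
#'
#' @param scenario an [evolution_scenario()].
#' @return list with elements `ancestor` (pre-event `genome_map`), `genomes`
#'   (named list of terminal genomes; the speciation products if a `speciate`
#'   event ran, otherwise the single evolved genome), `outgroup` (or `NULL`)
#'   and `truth` (per-chromosome descent table across terminal genomes).
#' @export
run_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "evolution_scenario"))
  sc <- scenario
  seeds <- derive_seeds(sc$seed, length(sc$events) + 2L)
  anc <- make_ancestral_genome(sc$n_ancestral_chromosomes,
                               sc$genes_per_chromosome)

  outg <- NULL
  if (!is.null(sc$outgroup)) {
    og <- sc$outgroup
    outg <- anc
    outg$species <- og$name %||% "outgroup"
    outg$genes$gene_id <- paste(outg$species, outg$genes$gene_id, sep = "@")
    outg <- apply_attrition(outg,
                            loss_rate = og$loss_rate %||% 0,
                            transloc_rate = og$transloc_rate %||% 0,
                            ssd_rate = og$ssd_rate %||% 0,
                            seed = seeds[[length(seeds)]])
  }

  g <- anc
  genomes <- NULL
  for (i in seq_along(sc$events)) {
    ev <- sc$events[[i]]
    s <- seeds[[i]]
    g <- switch(ev$type,
      wgd = apply_wgd(g, ev$multiplicity %||% 2, ev$mode %||% "auto", seed = s),
      fusion = {
        if (!is.null(ev$chr_a)) apply_fusion(g, ev$chr_a, ev$chr_b)
        else with_seed(s, {
          for (k in seq_len(ev$n %||% 1L)) {
            pick <- sample(g$chrom$chromosome, 2L)
            g <- apply_fusion(g, pick[1L], pick[2L])
          }
          g
        })
      },
      fission = {
        if (!is.null(ev$chr)) apply_fission(g, ev$chr, ev$breakpoint)
        else with_seed(s, {
          for (k in seq_len(ev$n %||% 1L)) {
            lens <- chrom_lengths(g)
            cand <- names(lens)[lens >= 2L]
            ch <- sample(cand, 1L)
            g <- apply_fission(g, ch, lens[[ch]] %/% 2L)
          }
          g
        })
      },
      attrition = apply_attrition(g,
        loss_rate = ev$loss_rate %||% sc$loss_rate,
        transloc_rate = ev$transloc_rate %||% sc$transloc_rate,
        ssd_rate = ev$ssd_rate %||% sc$ssd_rate, seed = s),
      speciate = {
        genomes <- speciate(g, unlist(ev$names),
          loss_rate = ev$loss_rate %||% sc$loss_rate,
          transloc_rate = ev$transloc_rate %||% sc$transloc_rate,
          ssd_rate = ev$ssd_rate %||% sc$ssd_rate, seed = s)
        g
      })
  }
  if (is.null(genomes)) genomes <- stats::setNames(list(g), g$species)

  truth <- do.call(rbind, lapply(genomes, function(gg) {
    data.frame(species = gg$species, chromosome = gg$chrom$chromosome,
               copy_path = gg$chrom$copy_path,
               acs = vapply(gg$chrom$acs, paste, "", collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  list(ancestor = anc, genomes = genomes, outgroup = outg, truth = truth)
}
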