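#' Tie ingroup chromosomes to outgroup linkage groups
#'
#' From unidirectional best hits with the outgroup as reference, tallies
#' shared homologues per (ingroup chromosome, outgroup chromosome) and runs
#' the same enrichment test as the within-ingroup analysis. Each ingroup
#' chromosome is tied to the enriched outgroup linkage group sharing the most
#' homologues with it (ties broken by linkage-group name); chromosomes with
#' no enriched linkage group get `NA`.
#'
#' @param best_pairs data frame `query` (outgroup gene), `subject` (ingroup
#'   gene) from [best_hits_unidirectional()].
#' @param outgroup_map `genome_map` of the outgroup.
#' @param ingroup_maps list of ingroup `genome_map`s.
#' @param q_max FDR threshold.
#' @return named character vector: `species:chromosome` -> outgroup
#'   chromosome (linkage group), NA when untied.
#' @export
outgroup_linkage_map <- function(best_pairs, outgroup_map, ingroup_maps,
                                 q_max = 0.05) {
  st <- pair_enrichment(best_pairs, c(list(outgroup_map), ingroup_maps),
                        q_max = q_max)
  st <- st[st$enriched, , drop = FALSE]
  ## query side is the outgroup; strip its species prefix to recover the LG
  st$lg <- sub("^[^:]*:", "", st$chrom_a)
  st <- st[order(st$chrom_b, -st$n_ab, st$lg), , drop = FALSE]
  best <- st[!duplicated(st$chrom_b), , drop = FALSE]
  nodes <- unlist(lapply(ingroup_maps, function(g)
    paste(g$species, g$chrom$chromosome, sep = ":")))
  out <- stats::setNames(best$lg[match(nodes, best$chrom_b)], nodes)
  out
}

#' Group chromosomes into ancestral-chromosome (AC) sets
#'
#' AC groups are the connected components of the homology graph restricted to
#' the ingroup genomes, optionally validated against an outgroup linkage map:
#' components mixing several outgroup linkage groups are split, each member
#' following its own linkage tie (members without a tie follow the subgroup
#' they share most graph edges with, then the largest subgroup). Every split
#' is logged in the `splits` attribute. Group identifiers are assigned
#' deterministically by sorted linkage-group / member order.
#'
#' @param graph homology graph from [homologous_chromosome_graph()].
#' @param outgroup_linkage optional named vector from
#'   [outgroup_linkage_map()].
#' @param ingroup_species optional character vector restricting the grouped
#'   nodes to these species.
#' @return an `ac_set`: list with `membership` (data frame `node`, `species`,
#'   `chromosome`, `ac`), `linkage` (named AC -> linkage group, NA when no
#'   outgroup was used) and `anchored` (NULL until
#'   [anchor_outgroup_genes()]).
#' @export
group_ancestral_chromosomes <- function(graph, outgroup_linkage = NULL,
                                        ingroup_species = NULL) {
  g <- graph
  if (!is.null(ingroup_species)) {
    keep <- igraph::V(g)$species %in% ingroup_species
    g <- igraph::induced_subgraph(g, igraph::V(g)[keep])
  }
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)

  splits <- list()
  groups <- list()
  for (cm in members) {
    cm <- sort(cm)
    if (is.null(outgroup_linkage)) {
      groups[[length(groups) + 1L]] <- list(nodes = cm, lg = NA_character_)
      next
    }
    lgs <- outgroup_linkage[cm]
    u <- sort(unique(lgs[!is.na(lgs)]))
    if (length(u) <= 1L) {
      groups[[length(groups) + 1L]] <-
        list(nodes = cm, lg = if (length(u)) u else NA_character_)
      next
    }
    ## split the component by linkage group
    sub <- lapply(u, function(l) cm[!is.na(lgs) & lgs == l])
    names(sub) <- u
    loose <- cm[is.na(lgs)]
    for (nd in loose) {
      nb <- names(igraph::neighbors(g, nd))
      deg <- vapply(sub, function(s) sum(nb %in% s), 0L)
      pick <- if (any(deg > 0L)) names(deg)[which.max(deg)]
              else names(which.max(vapply(sub, length, 0L)))
      sub[[pick]] <- sort(c(sub[[pick]], nd))
    }
    splits[[length(splits) + 1L]] <- list(component = cm, into = u)
    for (l in u) groups[[length(groups) + 1L]] <- list(nodes = sub[[l]], lg = l)
  }

  ord <- order(vapply(groups, function(x) x$lg %||% NA_character_, ""),
               vapply(groups, function(x) x$nodes[1L], ""), na.last = TRUE)
  groups <- groups[ord]
  w <- max(2L, nchar(as.character(length(groups))))
  ids <- sprintf(paste0("AC%0", w, "d"), seq_along(groups))

  membership <- do.call(rbind, lapply(seq_along(groups), function(i)
    data.frame(node = groups[[i]]$nodes, ac = ids[i], stringsAsFactors = FALSE)))
  membership$species <- sub(":.*$", "", membership$node)
  membership$chromosome <- sub("^[^:]*:", "", membership$node)
  membership <- membership[, c("node", "species", "chromosome", "ac")]
  linkage <- stats::setNames(vapply(groups, function(x) x$lg, ""), ids)

  structure(list(membership = membership, linkage = linkage,
                 anchored = NULL, splits = splits),
            class = "ac_set")
}

#' @export
print.ac_set <- function(x, ...) {
  cat(sprintf("<ac_set> %d AC groups over %d chromosomes",
              length(unique(x$membership$ac)), nrow(x$membership)))
  if (!is.null(x$anchored))
    cat(sprintf("; %d anchored outgroup genes", nrow(x$anchored)))
  cat("\n")
  invisible(x)
}

#' Anchor outgroup genes to ancestral chromosomes
#'
#' Reconstructs AC gene content from an outgroup genome. A gene is anchored
#' to AC X if either
#' (rule 1) its own chromosome is the linkage group tied to X *and* it has at
#' least one homologue among X's ingroup genes; or
#' (rule 2) at least `min_multi` of its distinct ingroup homologues lie on
#' chromosomes of X and no other AC also reaches that threshold.
#' Genes satisfying neither rule, or whose rules point at different ACs, are
#' left unanchored (recorded in the `unanchored` attribute).
#'
#' @param acs an `ac_set` from [group_ancestral_chromosomes()].
#' @param outgroup_map outgroup `genome_map`.
#' @param ingroup_maps list of ingroup `genome_map`s.
#' @param hits hit table(s) with outgroup genes as queries against the
#'   ingroup genomes (data frame or list of them, rbind-ed).
#' @param min_multi rule-2 threshold on distinct ingroup homologues
#'   (default 5).
#' @param evalue_max e-value cutoff applied to `hits`.
#' @return the `ac_set` with `anchored` filled: data frame `gene_id`,
#'   `family_id`, `ac`, `rule`.
#' @export
anchor_outgroup_genes <- function(acs, outgroup_map, ingroup_maps, hits,
                                  min_multi = 5, evalue_max = 1e-6) {
  stopifnot(inherits(acs, "ac_set"))
  min_multi <- check_count(min_multi, "min_multi")
  if (is.list(hits) && !is.data.frame(hits)) hits <- do.call(rbind, hits)
  h <- hits[hits$evalue <= evalue_max, c("qseqid", "sseqid"), drop = FALSE]

  og <- outgroup_map$genes
  loc <- locate_genes(ingroup_maps)
  loc$node <- paste(loc$species, loc$chromosome, sep = ":")
  loc$ac <- acs$membership$ac[match(loc$node, acs$membership$node)]

  h <- h[h$qseqid %in% og$gene_id, , drop = FALSE]
  h$ac <- loc$ac[match(h$sseqid, loc$gene_id)]
  h <- h[!is.na(h$ac), , drop = FALSE]
  h <- unique(h)

  ## rule 2: at least min_multi distinct ingroup homologues, all on the
  ## chromosomes of a single AC; two ACs both reaching the threshold is an
  ## ambiguity and anchors nowhere
  per_ac <- tapply(h$sseqid, list(h$qseqid, h$ac),
                   function(x) length(unique(x)))
  ac_by_gene <- tapply(h$ac, h$qseqid, function(x) unique(x))
  rule2 <- vapply(names(ac_by_gene), function(gid) {
    cnt <- per_ac[gid, ]
    cand <- colnames(per_ac)[!is.na(cnt) & cnt >= min_multi]
    if (length(cand) == 1L) cand else NA_character_
  }, "")

  ## rule 1: own linkage group tied to an AC + >=1 homologue in that AC
  lg_to_ac <- stats::setNames(names(acs$linkage), acs$linkage)
  og_chr <- og$chromosome[match(names(ac_by_gene), og$gene_id)]
  ac1_cand <- lg_to_ac[og_chr]
  rule1 <- vapply(seq_along(ac_by_gene), function(i) {
    a <- ac1_cand[[i]]
    if (!is.na(a) && a %in% ac_by_gene[[i]]) a else NA_character_
  }, "")
  names(rule1) <- names(ac_by_gene)

  decide <- function(r1, r2) {
    if (!is.na(r1) && !is.na(r2)) {
      if (r1 == r2) c(r1, "both") else c(NA_character_, "conflict")
    } else if (!is.na(r1)) c(r1, "rule1")
    else if (!is.na(r2)) c(r2, "rule2")
    else c(NA_character_, "none")
  }
  dec <- t(mapply(decide, rule1, rule2[names(rule1)]))
  res <- data.frame(gene_id = names(ac_by_gene), ac = dec[, 1L],
                    rule = dec[, 2L], stringsAsFactors = FALSE)
  res$family_id <- og$family_id[match(res$gene_id, og$gene_id)]

  anchored <- res[!is.na(res$ac), c("gene_id", "family_id", "ac", "rule")]
  anchored <- anchored[order(anchored$ac, anchored$gene_id), , drop = FALSE]
  rownames(anchored) <- NULL
  acs$anchored <- anchored
  attr(acs, "unanchored") <- res[is.na(res$ac), c("gene_id", "rule")]
  acs
}

#' Anchored gene families per AC
#'
#' @param acs an anchored `ac_set`.
#' @return named list: AC id -> character vector of family ids in fixed
#'   (sorted gene id) order, ready for [retention_profile()].
#' @export
ac_family_lists <- function(acs) {
  stopifnot(inherits(acs, "ac_set"), !is.null(acs$anchored))
  lapply(split(acs$anchored$family_id, acs$anchored$ac), unname)
}
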