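## locate genes across a list of genome maps: gene -> species, chromosome
locate_genes <- function(maps) {
  if (inherits(maps, "genome_map")) maps <- list(maps)
  loc <- do.call(rbind, lapply(maps, function(g)
    data.frame(gene_id = g$genes$gene_id, species = g$species,
               chromosome = g$genes$chromosome, stringsAsFactors = FALSE)))
  rownames(loc) <- NULL
  loc
}

#' Chromosome-pair homologue enrichment
#'
#' For every chromosome pair linked by at least one homologous gene pair,
#' tests whether the pair shares significantly more homologues than expected
#' from its marginal totals. The 2x2 table for chromosomes A, B is
#' `[[n_ab, n_a - n_ab], [n_b - n_ab, N - n_a - n_b + n_ab]]` where margins
#' count homologue pairs within the same genome-pair comparison. The Pearson
#' chi-squared test (no continuity correction) is used unless any expected
#' cell falls below 5, in which case Fisher's exact test supplies the
#' p-value; p-values are Benjamini-Hochberg corrected across all tested pairs
#' in one family. A pair is `enriched` when observed > expected and q < `q_max`.
#'
#' @param pairs data frame of homologous gene pairs (`gene_a`, `gene_b`),
#'   e.g. from [reciprocal_best_hits()] (or `query`/`subject` from
#'   [best_hits_unidirectional()]).
#' @param maps list of `genome_map`s locating every paired gene.
#' @param q_max FDR threshold for the `enriched` flag.
#' @return data frame of class `chrom_pair_stats`: one row per chromosome
#'   pair with margins, `chi2`, `p`, `q`, `method` and `enriched`. Chromosome
#'   labels are `species:chromosome`.
#' @export
pair_enrichment <- function(pairs, maps, q_max = 0.05) {
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0)
  nm <- names(pairs)
  ga <- pairs[[if ("gene_a" %in% nm) "gene_a" else "query"]]
  gb <- pairs[[if ("gene_b" %in% nm) "gene_b" else "subject"]]
  loc <- locate_genes(maps)
  ia <- match(ga, loc$gene_id)
  ib <- match(gb, loc$gene_id)
  if (anyNA(ia) || anyNA(ib)) {
    missing <- unique(c(ga[is.na(ia)], gb[is.na(ib)]))
    stop("gene(s) absent from maps: ", paste(utils::head(missing, 5L),
         collapse = ", "), call. = FALSE)
  }
  d <- data.frame(
    sp_a = loc$species[ia], chr_a = paste(loc$species[ia], loc$chromosome[ia], sep = ":"),
    sp_b = loc$species[ib], chr_b = paste(loc$species[ib], loc$chromosome[ib], sep = ":"),
    stringsAsFactors = FALSE)

  out <- do.call(rbind, lapply(split(d, paste(d$sp_a, d$sp_b)), function(dd) {
    N <- nrow(dd)
    tab <- as.data.frame(table(chr_a = dd$chr_a, chr_b = dd$chr_b),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0L, , drop = FALSE]
    na <- table(dd$chr_a); nb <- table(dd$chr_b)
    data.frame(
      species_a = dd$sp_a[1L], species_b = dd$sp_b[1L],
      chrom_a = tab$chr_a, chrom_b = tab$chr_b,
      n_ab = tab$Freq,
      n_a = as.integer(na[tab$chr_a]), n_b = as.integer(nb[tab$chr_b]),
      N = N, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL

  ## Pearson chi-squared on the 2x2, vectorised; Fisher fallback per row
  o11 <- out$n_ab; o12 <- out$n_a - o11
  o21 <- out$n_b - o11; o22 <- out$N - out$n_a - out$n_b + o11
  r1 <- out$n_a; r2 <- out$N - out$n_a
  c1 <- out$n_b; c2 <- out$N - out$n_b
  out$expected <- r1 * c1 / out$N
  out$chi2 <- out$N * (o11 * o22 - o12 * o21)^2 /
    pmax(as.numeric(r1) * r2 * c1 * c2, .Machine$double.eps)
  e_min <- pmin(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / out$N
  out$method <- ifelse(e_min < 5, "fisher", "chisq")
  out$p <- stats::pchisq(out$chi2, df = 1L, lower.tail = FALSE)
  for (i in which(out$method == "fisher")) {
    m <- matrix(c(o11[i], o21[i], o12[i], o22[i]), 2L)
    out$p[i] <- stats::fisher.test(m, alternative = "two.sided")$p.value
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$n_ab > out$expected & out$q < q_max
  attr(out, "q_max") <- q_max
  class(out) <- c("chrom_pair_stats", "data.frame")
  out
}

#' Homologous-chromosome graph
#'
#' Undirected graph over chromosomes with an edge for every enriched pair at
#' `q_max`. Vertices carry `species` and `chromosome` attributes; both
#' within-genome and cross-genome edges are representable.
#'
#' @param stats a `chrom_pair_stats` table from [pair_enrichment()].
#' @param q_max FDR threshold for drawing an edge.
#' @return an `igraph` graph.
#' @export
homologous_chromosome_graph <- function(stats, q_max = 0.05) {
  stopifnot(inherits(stats, "data.frame"))
  nodes <- unique(data.frame(
    name = c(stats$chrom_a, stats$chrom_b),
    species = c(stats$species_a, stats$species_b),
    stringsAsFactors = FALSE))
  nodes$chromosome <- sub("^[^:]*:", "", nodes$name)
  keep <- stats$n_ab > stats$expected & stats$q < q_max
  edges <- stats[keep, c("chrom_a", "chrom_b"), drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}
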