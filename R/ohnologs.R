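#' Call ohnologous chromosomes from an OR matrix
#'
#' Two chromosomes are called ohnologous when their overlapping ratio
#' strictly exceeds `or_min`. "Mutually ohnologous" sets are reported two
#' ways: as connected components of the resulting graph (the headline view,
#' robust to single edges lost to stochastic gene loss) and as maximal
#' cliques; components that are not cliques are flagged in `discrepancies`.
#'
#' @param m an `or_matrix`.
#' @param or_min strict OR threshold (default 0.15; a pair at exactly
#'   `or_min` is *not* called).
#' @return an `ohnolog_calls` list: `edges` (data frame `chrom_a`, `chrom_b`,
#'   `or`), `components`, `cliques` (lists of label vectors), `or_min`,
#'   `n_chromosomes`, `discrepancies`.
#' @export
call_ohnologues <- function(m, or_min = 0.15) {
  stopifnot(inherits(m, "or_matrix"))
  if (m$empty || !length(m$labels)) {
    return(structure(list(
      edges = data.frame(chrom_a = character(), chrom_b = character(),
                         or = numeric(), stringsAsFactors = FALSE),
      components = list(), cliques = list(), or_min = or_min,
      n_chromosomes = length(m$labels), discrepancies = list()),
      class = "ohnolog_calls"))
  }
  adj <- m$values > or_min
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  components <- lapply(split(names(comp$membership), comp$membership), sort)
  names(components) <- NULL
  cliques <- lapply(igraph::max_cliques(g), function(v) sort(names(v)))
  cliques <- cliques[order(-vapply(cliques, length, 0L),
                           vapply(cliques, `[`, "", 1L))]

  ut <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- data.frame(chrom_a = m$labels[ut[, 1L]],
                      chrom_b = m$labels[ut[, 2L]],
                      or = m$values[ut], stringsAsFactors = FALSE)
  discrepancies <- Filter(function(cm) {
    k <- length(cm)
    k > 1L && sum(adj[cm, cm]) < k * (k - 1L)
  }, components)

  structure(list(edges = edges, components = components, cliques = cliques,
                 or_min = or_min, n_chromosomes = length(m$labels),
                 discrepancies = discrepancies),
            class = "ohnolog_calls")
}

#' @export
print.ohnolog_calls <- function(x, ...) {
  cat(sprintf("<ohnolog_calls> %d chromosomes, %d edges (OR > %g), %d set(s)\n",
              x$n_chromosomes, nrow(x$edges), x$or_min, length(x$components)))
  invisible(x)
}

#' Per-AC multiplicity of mutually ohnologous chromosomes
#'
#' The size of the largest mutually-ohnologous set per AC (component view).
#' An AC whose matrix held at least one qualifying chromosome but no edges
#' counts 1 (a lone surviving descendant); an AC with no qualifying
#' chromosome counts 0.
#'
#' @param calls named list of `ohnolog_calls`, one per AC.
#' @return named integer vector AC -> multiplicity.
#' @export
multiplicity_per_ac <- function(calls) {
  vapply(calls, function(cl) {
    if (!inherits(cl, "ohnolog_calls")) stop("expected ohnolog_calls")
    if (length(cl$components)) max(vapply(cl$components, length, 0L))
    else if (cl$n_chromosomes >= 1L) 1L
    else 0L
  }, 0L)
}

#' Assign orthologous chromosomes across two species
#'
#' From the cross-species block of an OR matrix. A chromosome whose two best
#' partners both exceed `or_min` and sit within `rel_tol` relative OR of
#' each other cannot be resolved and is an ambiguous 1:2 (rows) or 2:1
#' (columns) case — typically a secondary independent chromosome loss in one
#' lineage. Among the remaining chromosomes, mutual best partners with OR
#' above `or_min` are 1:1 orthologues; everything else is unassigned.
#'
#' @param cross numeric matrix of OR values, rows = species-A chromosomes,
#'   columns = species-B chromosomes (dimnames required).
#' @param or_min OR threshold (strict).
#' @param rel_tol relative tolerance for calling the two best partners tied.
#' @return data frame `chromosome`, `side` ("row"/"col"), `class`
#'   (`1:1`, `1:2`, `2:1`, `unassigned`), `partners`, `best_or`.
#' @export
assign_orthologs <- function(cross, or_min = 0.15, rel_tol = 0.10) {
  stopifnot(is.matrix(cross), !is.null(rownames(cross)),
            !is.null(colnames(cross)))
  rn <- rownames(cross); cn <- colnames(cross)
  top2 <- function(vals, labels) {
    o <- order(vals, decreasing = TRUE)
    v1 <- vals[o[1L]]; v2 <- if (length(vals) > 1L) vals[o[2L]] else -Inf
    list(v1 = v1, v2 = v2, l1 = labels[o[1L]],
         l12 = paste(labels[o[seq_len(min(2L, length(labels)))]],
                     collapse = ","),
         ambiguous = v1 > or_min && v2 > or_min &&
           (v1 - v2) / v1 <= rel_tol)
  }
  row_info <- lapply(seq_along(rn), function(i) top2(cross[i, ], cn))
  col_info <- lapply(seq_along(cn), function(j) top2(cross[, j], rn))
  amb_r <- vapply(row_info, `[[`, TRUE, "ambiguous")
  amb_c <- vapply(col_info, `[[`, TRUE, "ambiguous")
  rbest <- apply(cross, 1L, which.max)
  cbest <- apply(cross, 2L, which.max)

  res <- list()
  one2one_r <- logical(length(rn)); one2one_c <- logical(length(cn))
  for (i in seq_along(rn)) {
    j <- rbest[i]
    if (!amb_r[i] && !amb_c[j] && cbest[j] == i && cross[i, j] > or_min) {
      one2one_r[i] <- TRUE; one2one_c[j] <- TRUE
      res[[length(res) + 1L]] <- data.frame(
        chromosome = rn[i], side = "row", class = "1:1",
        partners = cn[j], best_or = cross[i, j], stringsAsFactors = FALSE)
    }
  }
  leftover <- function(info, amb, label, side, cls) {
    cls_out <- if (amb) cls else "unassigned"
    partners <- if (amb) info$l12
                else if (info$v1 > or_min) info$l1 else ""
    data.frame(chromosome = label, side = side, class = cls_out,
               partners = partners, best_or = info$v1,
               stringsAsFactors = FALSE)
  }
  for (i in seq_along(rn)) if (!one2one_r[i])
    res[[length(res) + 1L]] <- leftover(row_info[[i]], amb_r[i], rn[i],
                                        "row", "1:2")
  for (j in seq_along(cn)) if (!one2one_c[j])
    res[[length(res) + 1L]] <- leftover(col_info[[j]], amb_c[j], cn[j],
                                        "col", "2:1")
  out <- do.call(rbind, res)
  out <- out[order(out$side, out$chromosome), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-retention asymmetry of ohnologous chromosome pairs
#'
#' Per-pair asymmetry ratio `max(nA, nB) / min(nA, nB)` of retained-gene
#' counts, with an optional two-sided Wilcoxon rank-sum comparison between
#' two groups of pairs (e.g. pairs generated by different WGD rounds, where
#' allopolyploidy predicts stronger asymmetry). Pairs with a zero count are
#' excluded and logged.
#'
#' @param pairs data frame with numeric columns `n_a`, `n_b` and optionally a
#'   `group` column with exactly two levels.
#' @return list with `pairs` (ratio column added), `medians` (per group, or
#'   overall) and `test` (an `htest`, or NULL without groups).
#' @export
retention_asymmetry <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("n_a", "n_b") %in% names(pairs)))
  bad <- pairs$n_a == 0 | pairs$n_b == 0
  excluded <- pairs[bad, , drop = FALSE]
  pairs <- pairs[!bad, , drop = FALSE]
  if (!nrow(pairs)) stop("no pairs with both counts > 0", call. = FALSE)
  pairs$ratio <- pmax(pairs$n_a, pairs$n_b) / pmin(pairs$n_a, pairs$n_b)
  test <- NULL
  if ("group" %in% names(pairs) && length(unique(pairs$group)) == 2L) {
    test <- stats::wilcox.test(ratio ~ group, data = pairs, exact = FALSE)
    medians <- tapply(pairs$ratio, pairs$group, stats::median)
  } else {
    medians <- c(all = stats::median(pairs$ratio))
  }
  list(pairs = pairs, medians = medians, test = test, excluded = excluded)
}

#' Count AC-composition of every chromosome
#'
#' Tallies, for each chromosome of a genome, how many of its genes belong to
#' each AC's anchored family list — the input for [detect_fusions()].
#'
#' @param g a `genome_map`.
#' @param ac_families named list AC -> family-id vector
#'   (see [ac_family_lists()]).
#' @return data frame `species`, `chromosome`, `ac`, `n_genes` (zero rows
#'   omitted).
#' @export
ac_composition <- function(g, ac_families) {
  stopifnot(inherits(g, "genome_map"), length(ac_families) > 0)
  out <- do.call(rbind, lapply(names(ac_families), function(ac) {
    hit <- g$genes$family_id %in% ac_families[[ac]]
    if (!any(hit)) return(NULL)
    tab <- table(g$genes$chromosome[hit])
    data.frame(species = g$species, chromosome = names(tab), ac = ac,
               n_genes = as.integer(tab), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Detect fusion products from AC composition
#'
#' A chromosome is called a fusion product of k ACs when at least `min_frag`
#' of its genes anchor to each of k >= 2 different ACs; it then contributes
#' k - 1 fusions to its genome's total.
#'
#' @param composition data frame from [ac_composition()] (possibly several
#'   genomes rbind-ed).
#' @param min_frag minimum anchored genes per contributing AC (default 10).
#' @return list with `per_chromosome` (data frame `species`, `chromosome`,
#'   `k`, `fusions`, `acs`) and `per_genome` (named fusion totals).
#' @export
detect_fusions <- function(composition, min_frag = 10) {
  stopifnot(is.data.frame(composition))
  comp <- composition[composition$n_genes >= min_frag, , drop = FALSE]
  key <- paste(comp$species, comp$chromosome, sep = ":")
  per <- do.call(rbind, lapply(split(comp, key), function(dd) {
    k <- length(unique(dd$ac))
    data.frame(species = dd$species[1L], chromosome = dd$chromosome[1L],
               k = k, fusions = max(k - 1L, 0L),
               acs = paste(sort(unique(dd$ac)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  per_genome <- tapply(per$fusions, per$species, sum)
  list(per_chromosome = per,
       per_genome = stats::setNames(as.integer(per_genome), names(per_genome)))
}
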