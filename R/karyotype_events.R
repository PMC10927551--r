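#' Whole-genome duplication or triplication
#'
#' Multiplies every chromosome (and hence every gene family's copy number) by
#' `multiplicity`. Copies are tagged with a subgenome letter appended to both
#' chromosome names and gene ids, and to the chromosome's copy path, so the
#' true ohnology structure stays recoverable. `mode = "allo"` models an
#' allopolyploid origin phenomenologically: the last subgenome immediately
#' suffers an extra round of gene loss (`allo_loss`), producing the retention
#' asymmetry allopolyploids show relative to autopolyploids.
#'
#' @param g a `genome_map` with at least one gene.
#' @param multiplicity 2 (duplication) or 3 (triplication).
#' @param mode `"auto"` or `"allo"`.
#' @param seed RNG seed (only consumed by `mode = "allo"`).
#' @param allo_loss extra per-gene loss probability on the disfavoured
#'   subgenome under `mode = "allo"`.
#' @return the post-WGD `genome_map`.
#' @export
apply_wgd <- function(g, multiplicity = 2, mode = c("auto", "allo"),
                      seed = NULL, allo_loss = 0.15) {
  stopifnot(inherits(g, "genome_map"))
  mode <- match.arg(mode)
  if (!multiplicity %in% c(2, 3))
    stop("`multiplicity` must be 2 or 3", call. = FALSE)
  if (!nrow(g$genes)) stop("cannot duplicate an empty genome", call. = FALSE)
  check_prob(allo_loss, "allo_loss")
  m <- as.integer(multiplicity)
  labs <- letters[seq_len(m)]

  genes <- do.call(rbind, lapply(labs, function(l) {
    gg <- g$genes
    gg$gene_id <- paste0(gg$gene_id, ".", l)
    gg$chromosome <- paste0(gg$chromosome, ".", l)
    gg
  }))
  ## keep the m copies of each chromosome adjacent in karyotype order
  chrom <- g$chrom[rep(seq_len(nrow(g$chrom)), each = m), , drop = FALSE]
  l_rep <- rep(labs, times = nrow(g$chrom))
  chrom$chromosome <- paste0(chrom$chromosome, ".", l_rep)
  chrom$copy_path <- paste0(chrom$copy_path, l_rep)
  rownames(chrom) <- NULL

  out <- new_genome_map(g$species, genes, chrom, g$dup_counter)
  out <- recompute_indices(out)
  if (mode == "allo" && allo_loss > 0) {
    out <- with_seed(seed, {
      tgt <- out$genes$chromosome %in%
        chrom$chromosome[l_rep == labs[m]]
      drop <- tgt & stats::runif(nrow(out$genes)) < allo_loss
      out$genes <- out$genes[!drop, , drop = FALSE]
      recompute_indices(out)
    })
  }
  out
}

#' Fuse two chromosomes
#'
#' Concatenates `chr_b` after `chr_a` into a single chromosome. Gene content
#' and order are preserved; the descent record of the product is the union of
#' the two parents' ancestral-chromosome sets.
#'
#' @param g a `genome_map`.
#' @param chr_a,chr_b distinct chromosome names present in `g`.
#' @param new_name name of the fusion product.
#' @return the post-fusion `genome_map` (one chromosome fewer).
#' @export
apply_fusion <- function(g, chr_a, chr_b,
                         new_name = paste(chr_a, chr_b, sep = "+")) {
  stopifnot(inherits(g, "genome_map"))
  for (ch in c(chr_a, chr_b))
    if (!ch %in% g$chrom$chromosome) stop("unknown chromosome: ", ch, call. = FALSE)
  if (identical(chr_a, chr_b))
    stop("cannot fuse a chromosome with itself", call. = FALSE)

  len_a <- sum(g$genes$chromosome == chr_a)
  ib <- g$genes$chromosome == chr_b
  g$genes$index[ib] <- g$genes$index[ib] + len_a
  g$genes$chromosome[g$genes$chromosome %in% c(chr_a, chr_b)] <- new_name

  ia <- match(chr_a, g$chrom$chromosome)
  jb <- match(chr_b, g$chrom$chromosome)
  g$chrom$chromosome[ia] <- new_name
  g$chrom$copy_path[ia] <- paste(g$chrom$copy_path[ia], g$chrom$copy_path[jb],
                                 sep = "+")
  g$chrom$acs[[ia]] <- unique(c(g$chrom$acs[[ia]], g$chrom$acs[[jb]]))
  g$chrom <- g$chrom[-jb, , drop = FALSE]
  rownames(g$chrom) <- NULL
  recompute_indices(g)
}

#' Split a chromosome at a breakpoint
#'
#' @param g a `genome_map`.
#' @param chr chromosome to split.
#' @param breakpoint number of genes kept on the first product; must satisfy
#'   `0 < breakpoint < length(chr)`.
#' @param new_names names of the two products.
#' @return the post-fission `genome_map` (one chromosome more).
#' @export
apply_fission <- function(g, chr, breakpoint,
                          new_names = paste0(chr, c(".p", ".q"))) {
  stopifnot(inherits(g, "genome_map"))
  if (!chr %in% g$chrom$chromosome) stop("unknown chromosome: ", chr, call. = FALSE)
  len <- sum(g$genes$chromosome == chr)
  if (!is.numeric(breakpoint) || breakpoint <= 0 || breakpoint >= len)
    stop("`breakpoint` must satisfy 0 < breakpoint < ", len, call. = FALSE)

  on_chr <- g$genes$chromosome == chr
  second <- on_chr & g$genes$index >= breakpoint
  g$genes$chromosome[on_chr & !second] <- new_names[1L]
  g$genes$chromosome[second] <- new_names[2L]

  i <- match(chr, g$chrom$chromosome)
  row <- g$chrom[i, , drop = FALSE]
  rows <- row[c(1L, 1L), , drop = FALSE]
  rows$chromosome <- new_names
  rows$copy_path <- paste0(row$copy_path, c(":p", ":q"))
  top <- if (i > 1L) g$chrom[seq_len(i - 1L), , drop = FALSE] else g$chrom[0L, ]
  bot <- if (i < nrow(g$chrom)) g$chrom[(i + 1L):nrow(g$chrom), , drop = FALSE]
         else g$chrom[0L, ]
  g$chrom <- rbind(top, rows, bot)
  rownames(g$chrom) <- NULL
  recompute_indices(g)
}

#' Apply gene loss, translocation and small-scale duplication
#'
#' The three attrition processes that degrade retention profiles after a WGD.
#' Each gene is independently deleted with probability `loss_rate`; each
#' survivor is independently moved to a uniformly chosen *other* chromosome
#' with probability `transloc_rate` (appended at the end of its destination);
#' and independently copied (new `gene_id`, same `family_id`) with probability
#' `ssd_rate`, the copy landing on the same chromosome half the time and on a
#' uniformly chosen other chromosome otherwise — tandem-biased small-scale
#' duplication. Chromosomes emptied by loss are retained and flagged.
#'
#' @param g a `genome_map`.
#' @param loss_rate,transloc_rate,ssd_rate per-gene probabilities in \[0, 1\].
#' @param seed RNG seed.
#' @return the post-attrition `genome_map`.
#' @export
apply_attrition <- function(g, loss_rate = 0, transloc_rate = 0, ssd_rate = 0,
                            seed = NULL) {
  stopifnot(inherits(g, "genome_map"))
  check_prob(loss_rate, "loss_rate")
  check_prob(transloc_rate, "transloc_rate")
  check_prob(ssd_rate, "ssd_rate")
  if (!nrow(g$genes)) return(g)
  chrs <- g$chrom$chromosome
  K <- length(chrs)

  with_seed(seed, {
    genes <- g$genes
    ## sort key preserving order; moved/copied genes are appended at the end
    key <- genes$index

    if (loss_rate > 0) {
      keep <- stats::runif(nrow(genes)) >= loss_rate
      genes <- genes[keep, , drop = FALSE]
      key <- key[keep]
    }

    if (transloc_rate > 0 && K > 1L && nrow(genes)) {
      mv <- stats::runif(nrow(genes)) < transloc_rate
      if (any(mv)) {
        cur <- match(genes$chromosome[mv], chrs)
        pick <- sample.int(K - 1L, sum(mv), replace = TRUE)
        pick <- ifelse(pick >= cur, pick + 1L, pick)
        genes$chromosome[mv] <- chrs[pick]
        key[mv] <- 1e9 + seq_len(sum(mv))
      }
    }

    dup_counter <- g$dup_counter
    if (ssd_rate > 0 && nrow(genes)) {
      cp <- stats::runif(nrow(genes)) < ssd_rate
      if (any(cp)) {
        copies <- genes[cp, , drop = FALSE]
        n_cp <- nrow(copies)
        copies$gene_id <- sprintf("%s_s%d", copies$gene_id,
                                  dup_counter + seq_len(n_cp))
        dup_counter <- dup_counter + n_cp
        same <- stats::runif(n_cp) < 0.5
        if (K > 1L && any(!same)) {
          cur <- match(copies$chromosome[!same], chrs)
          pick <- sample.int(K - 1L, sum(!same), replace = TRUE)
          pick <- ifelse(pick >= cur, pick + 1L, pick)
          copies$chromosome[!same] <- chrs[pick]
        }
        genes <- rbind(genes, copies)
        key <- c(key, 2e9 + seq_len(n_cp))
      }
    }

    ord <- order(match(genes$chromosome, chrs), key)
    genes <- genes[ord, , drop = FALSE]
    out <- new_genome_map(g$species, genes, g$chrom, dup_counter)
    recompute_indices(out)
  })
}

#' Speciation with independent post-split attrition
#'
#' Copies the genome into one descendant per name and subjects each to an
#' independent round of [apply_attrition()]. Chromosome names are carried
#' over unchanged, so the true orthologous chromosome pairing across the
#' descendants is "same chromosome name" (see [true_ortholog_pairs()]).
#'
#' @param g a `genome_map`.
#' @param names two or more species names.
#' @param loss_rate,transloc_rate,ssd_rate attrition rates applied
#'   independently in every descendant.
#' @param seed RNG seed (per-species sub-seeds are derived from it).
#' @return named list of `genome_map`s.
#' @export
speciate <- function(g, names, loss_rate = 0, transloc_rate = 0, ssd_rate = 0,
                     seed = NULL) {
  stopifnot(inherits(g, "genome_map"))
  if (length(names) < 2L)
    stop("speciation requires at least 2 descendant names", call. = FALSE)
  seeds <- derive_seeds(seed, length(names))
  out <- lapply(seq_along(names), function(i) {
    gi <- g
    gi$species <- names[[i]]
    ## gene ids must stay unique across the descendant genomes so that hit
    ## tables and homology pairs are unambiguous
    gi$genes$gene_id <- paste(names[[i]], gi$genes$gene_id, sep = "@")
    apply_attrition(gi, loss_rate, transloc_rate, ssd_rate, seed = seeds[[i]])
  })
  stats::setNames(out, names)
}

#' Midpoint split of a chromosome (fission control)
#'
#' Returns the two halves of a floor/ceiling midpoint split as query gene
#' lists *without* mutating the genome. Used as the negative control for
#' ohnolog calling: halves of one chromosome share no retained ancestral genes
#' beyond what small-scale duplication and translocation re-introduce, so
#' their overlapping ratio bounds the fission-derived background.
#'
#' @param g a `genome_map`.
#' @param chr chromosome with at least 2 genes.
#' @param seed unused; accepted for interface symmetry.
#' @return list with data frames `left` (floor(n/2) genes) and `right`.
#' @export
artificial_split <- function(g, chr, seed = NULL) {
  genes <- chrom_genes(g, chr)
  n <- nrow(genes)
  if (n < 2L) stop("chromosome ", chr, " has fewer than 2 genes", call. = FALSE)
  k <- n %/% 2L
  list(left = genes[seq_len(k), c("gene_id", "family_id")],
       right = genes[(k + 1L):n, c("gene_id", "family_id")])
}

#' True ohnologous chromosome pairs of a genome
#'
#' Pairs of chromosomes of the same genome whose descent records share at
#' least one ancestral chromosome but whose copy paths differ, i.e. true
#' WGD-derived duplicates.
#'
#' @param g a `genome_map`.
#' @return data frame with `chrom_a`, `chrom_b`, `ac` (first shared AC).
#' @export
true_ohnolog_pairs <- function(g) {
  ch <- g$chrom
  n <- nrow(ch)
  out <- list()
  for (i in seq_len(max(n - 1L, 0L))) for (j in (i + 1L):n) {
    shared <- intersect(ch$acs[[i]], ch$acs[[j]])
    if (length(shared) && ch$copy_path[i] != ch$copy_path[j])
      out[[length(out) + 1L]] <- data.frame(
        chrom_a = ch$chromosome[i], chrom_b = ch$chromosome[j],
        ac = shared[1L], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom_a = character(), chrom_b = character(),
                      ac = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' True orthologous chromosome pairs across speciated genomes
#'
#' @param genomes list of `genome_map`s produced by [speciate()] from one
#'   parent genome.
#' @return data frame with `species_a`, `species_b`, `chromosome`.
#' @export
true_ortholog_pairs <- function(genomes) {
  stopifnot(length(genomes) >= 2L)
  combs <- utils::combn(length(genomes), 2L)
  out <- lapply(seq_len(ncol(combs)), function(k) {
    a <- genomes[[combs[1L, k]]]; b <- genomes[[combs[2L, k]]]
    shared <- intersect(a$chrom$chromosome, b$chrom$chromosome)
    data.frame(species_a = a$species, species_b = b$species,
               chromosome = shared, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
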