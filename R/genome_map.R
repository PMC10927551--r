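#' Genome maps
#'
#' A `genome_map` is the package's per-species karyotype container: an ordered
#' set of chromosomes, each carrying an ordered list of genes. Every gene is
#' tagged with the identifier of the ancestral gene family it descends from,
#' which is what all downstream homology and retention analyses consume (the
#' framework is content-based, not sequence-based). Each chromosome also
#' carries a descent record: the ancestral chromosome(s) it derives from and a
#' copy-path string accumulating one letter per whole-genome duplication, so
#' simulations retain full ground truth.
#'
#' @name genome_map
#' @section Structure:
#' * `species`: species name.
#' * `genes`: data frame with columns `gene_id`, `family_id`, `chromosome`,
#'   `index` (0-based position on the chromosome).
#' * `chrom`: per-chromosome metadata: `chromosome`, `copy_path` and the
#'   list-column `acs` of ancestral-chromosome identifiers. Chromosomes
#'   emptied by gene loss are retained here (flagged via [chrom_lengths()]).
NULL

new_genome_map <- function(species, genes, chrom, dup_counter = 0L) {
  structure(
    list(species = species, genes = genes, chrom = chrom,
         dup_counter = as.integer(dup_counter)),
    class = "genome_map"
  )
}

## stable re-ordering: rows grouped by chromosome (in chrom table order),
## existing row order preserved within chromosome; 0-based indices rebuilt.
recompute_indices <- function(g) {
  if (nrow(g$genes)) {
    ord <- order(match(g$genes$chromosome, g$chrom$chromosome))
    g$genes <- g$genes[ord, , drop = FALSE]
    idx <- stats::ave(seq_len(nrow(g$genes)), g$genes$chromosome,
                      FUN = seq_along)
    g$genes$index <- as.integer(idx) - 1L
    rownames(g$genes) <- NULL
  }
  g
}

#' Validate a genome map's invariants
#'
#' Checks gene-id uniqueness, chromosome membership and that per-chromosome
#' indices run 0..len-1 without gaps.
#'
#' @param g a `genome_map`.
#' @return `g`, invisibly; errors describe the first violated invariant.
#' @export
validate_genome_map <- function(g) {
  stopifnot(inherits(g, "genome_map"))
  if (anyDuplicated(g$genes$gene_id))
    stop("duplicate gene_id in genome map: ",
         g$genes$gene_id[duplicated(g$genes$gene_id)][1L])
  if (!all(g$genes$chromosome %in% g$chrom$chromosome))
    stop("gene assigned to unknown chromosome")
  for (ch in unique(g$genes$chromosome)) {
    ix <- sort(g$genes$index[g$genes$chromosome == ch])
    if (!identical(ix, seq_along(ix) - 1L))
      stop("indices on chromosome ", ch, " are not 0..len-1")
  }
  invisible(g)
}

#' @export
print.genome_map <- function(x, ...) {
  lens <- chrom_lengths(x)
  cat(sprintf("<genome_map> species '%s': %d chromosomes (%d empty), %d genes, %d families\n",
              x$species, nrow(x$chrom), sum(lens == 0L), nrow(x$genes),
              length(unique(x$genes$family_id))))
  invisible(x)
}

#' Chromosome names of a genome map
#' @param g a `genome_map`.
#' @return character vector in karyotype order.
#' @export
chrom_names <- function(g) g$chrom$chromosome

#' Gene counts per chromosome
#'
#' Empty chromosomes (all genes lost) are reported with length 0 rather than
#' dropped, so descent records remain addressable.
#'
#' @param g a `genome_map`.
#' @return named integer vector over all chromosomes.
#' @export
chrom_lengths <- function(g) {
  n <- table(factor(g$genes$chromosome, levels = g$chrom$chromosome))
  stats::setNames(as.integer(n), g$chrom$chromosome)
}

#' Genes on one chromosome
#' @param g a `genome_map`.
#' @param chr chromosome name.
#' @return data frame of genes in positional order.
#' @export
chrom_genes <- function(g, chr) {
  if (!chr %in% g$chrom$chromosome)
    stop("unknown chromosome: ", chr, call. = FALSE)
  out <- g$genes[g$genes$chromosome == chr, , drop = FALSE]
  out[order(out$index), , drop = FALSE]
}

#' Create an ancestral (pre-duplication) genome
#'
#' Builds the proto-karyotype all simulations start from: `n_chr` chromosomes
#' of `genes_per_chr` genes each, every gene founding its own singleton family
#' (`family_id == gene_id`). Chromosome names double as ancestral-chromosome
#' (AC) identifiers in descent records.
#'
#' @param n_chr number of ancestral chromosomes (>= 1).
#' @param genes_per_chr genes per chromosome (>= 1).
#' @param seed unused (the construction is deterministic); accepted for
#'   interface symmetry with the other generators.
#' @return a `genome_map` for species `"ancestor"`.
#' @examples
#' g <- make_ancestral_genome(3, 10)
#' chrom_lengths(g)
#' @export
make_ancestral_genome <- function(n_chr, genes_per_chr, seed = NULL) {
  n_chr <- check_count(n_chr, "n_chr")
  genes_per_chr <- check_count(genes_per_chr, "genes_per_chr")
  wc <- max(2L, nchar(as.character(n_chr)))
  wg <- max(3L, nchar(as.character(genes_per_chr)))
  chrs <- sprintf(paste0("AC%0", wc, "d"), seq_len(n_chr))
  genes <- data.frame(
    gene_id = sprintf(paste0("%s_g%0", wg, "d"),
                      rep(chrs, each = genes_per_chr),
                      rep(seq_len(genes_per_chr), times = n_chr)),
    chromosome = rep(chrs, each = genes_per_chr),
    index = rep(seq_len(genes_per_chr) - 1L, times = n_chr),
    stringsAsFactors = FALSE
  )
  genes$family_id <- genes$gene_id
  genes <- genes[, c("gene_id", "family_id", "chromosome", "index")]
  chrom <- data.frame(chromosome = chrs, copy_path = "",
                      stringsAsFactors = FALSE)
  chrom$acs <- as.list(chrs)
  new_genome_map("ancestor", genes, chrom)
}

#' Copy-number of every gene family
#' @param g a `genome_map`.
#' @return named integer vector, one entry per family.
#' @export
family_sizes <- function(g) {
  tab <- table(g$genes$family_id)
  stats::setNames(as.integer(tab), names(tab))
}
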