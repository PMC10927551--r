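#' Classify accessible chromatin regions by genomic context
#'
#' Assigns each ACR to exactly one category with the precedence
#' promoter > proximal > exonic > distal:
#' * promoter: overlaps (>= 1 bp) the strand-aware window from
#'   `promoter_up` bp upstream to `promoter_down` bp downstream of a TSS
#'   (defaults 1 kb / 0.5 kb);
#' * proximal: overlaps the `proximal_up`/`proximal_down` window (defaults
#'   5 kb / 1 kb) but no promoter;
#' * exonic: overlaps an exon of a protein-coding gene but no proximal
#'   window;
#' * distal: none of the above.
#' Windows are clipped at position 1. Each ACR is also assigned the gene
#' with the nearest TSS (distance measured from the ACR midpoint; ties go to
#' the lower TSS coordinate) together with the strand-aware signed distance
#' (positive = downstream of the TSS).
#'
#' @param acrs data frame of intervals with columns `chrom`, `start`, `end`
#'   (0-based half-open, BED convention) and optionally `name`.
#' @param genes gene models as returned by [read_gff3_genes()] or
#'   [simulate_regulatory_landscape()]: list with data frames `genes`
#'   (`gene_id`, `chrom`, `start`, `end` 1-based closed, `strand`,
#'   `biotype`) and `exons` (`gene_id`, `chrom`, `start`, `end`).
#' @param promoter_up,promoter_down,proximal_up,proximal_down window sizes
#'   in bp.
#' @return data frame of class `acr_annotation`: `chrom`, `start`, `end`,
#'   `name`, `category`, `gene_id`, `tss_dist`.
#' @export
classify_acr_context <- function(acrs, genes, promoter_up = 1000,
                                 promoter_down = 500, proximal_up = 5000,
                                 proximal_down = 1000) {
  stopifnot(is.data.frame(acrs), all(c("chrom", "start", "end") %in% names(acrs)))
  gm <- genes$genes
  ex <- genes$exons
  stopifnot(is.data.frame(gm), nrow(gm) > 0)
  if (any(acrs$end <= acrs$start))
    stop("ACR with end <= start (BED is half-open)", call. = FALSE)
  name <- if ("name" %in% names(acrs)) acrs$name
          else sprintf("acr%05d", seq_len(nrow(acrs)))

  acr_gr <- GenomicRanges::GRanges(acrs$chrom,
    IRanges::IRanges(acrs$start + 1L, acrs$end))
  tss <- ifelse(gm$strand == "+", gm$start, gm$end)
  tss_gr <- GenomicRanges::GRanges(gm$chrom, IRanges::IRanges(tss, tss),
                                   strand = gm$strand)
  clip1 <- function(gr) {
    GenomicRanges::start(gr) <- pmax(GenomicRanges::start(gr), 1L)
    gr
  }
  prom <- clip1(GenomicRanges::promoters(tss_gr, upstream = promoter_up,
                                         downstream = promoter_down + 1L))
  prox <- clip1(GenomicRanges::promoters(tss_gr, upstream = proximal_up,
                                         downstream = proximal_down + 1L))
  pc <- gm$gene_id[gm$biotype == "protein_coding"]
  exc <- ex[ex$gene_id %in% pc, , drop = FALSE]
  ex_gr <- GenomicRanges::GRanges(exc$chrom,
    IRanges::IRanges(exc$start, exc$end))

  ov <- function(win) IRanges::overlapsAny(acr_gr, win, ignore.strand = TRUE)
  in_prom <- ov(prom)
  in_prox <- ov(prox)
  in_exon <- if (nrow(exc)) ov(ex_gr) else rep(FALSE, nrow(acrs))
  category <- ifelse(in_prom, "promoter",
              ifelse(in_prox, "proximal",
              ifelse(in_exon, "exonic", "distal")))

  ## nearest TSS by ACR midpoint, per chromosome, deterministic ties
  mid <- acrs$start + (acrs$end - acrs$start - 1L) %/% 2L + 1L  # 1-based
  gene_id <- rep(NA_character_, nrow(acrs))
  tss_dist <- rep(NA_real_, nrow(acrs))
  for (ch in unique(acrs$chrom)) {
    gi <- which(gm$chrom == ch)
    ai <- which(acrs$chrom == ch)
    if (!length(gi) || !length(ai)) next
    o <- gi[order(tss[gi], gm$gene_id[gi])]
    ts <- tss[o]
    pos <- findInterval(mid[ai], ts)
    lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(ts))
    d_lo <- abs(mid[ai] - ts[lo]); d_hi <- abs(mid[ai] - ts[hi])
    take <- ifelse(d_hi < d_lo, hi, lo)  # tie -> lower TSS coordinate
    gsel <- o[take]
    gene_id[ai] <- gm$gene_id[gsel]
    d <- mid[ai] - tss[gsel]
    tss_dist[ai] <- ifelse(gm$strand[gsel] == "-", -d, d)
  }

  out <- data.frame(chrom = acrs$chrom, start = acrs$start, end = acrs$end,
                    name = name, category = category, gene_id = gene_id,
                    tss_dist = tss_dist, stringsAsFactors = FALSE)
  class(out) <- c("acr_annotation", "data.frame")
  out
}

#' ACR counts per gene
#'
#' Counts the ACRs assigned (by nearest TSS, all categories) to each gene,
#' including zeros, with a distribution summary. When a gene classification
#' is supplied (e.g. developmental ohnologue / other ohnologue / singleton),
#' all pairwise two-sided Wilcoxon rank-sum comparisons of the per-class
#' count distributions are reported with Bonferroni adjustment.
#'
#' @param annots an `acr_annotation` from [classify_acr_context()].
#' @param gene_ids full gene universe (genes without ACRs get count 0);
#'   defaults to the genes present in `annots`.
#' @param classes optional named vector gene -> class label.
#' @return list with `counts` (data frame `gene_id`, `n_acr`, and `class` if
#'   given), `summary` (median and quartiles, per class if given) and
#'   `tests` (`pairwise.htest` or NULL).
#' @export
acr_counts_per_gene <- function(annots, gene_ids = NULL, classes = NULL) {
  stopifnot(is.data.frame(annots))
  if (is.null(gene_ids)) gene_ids <- sort(unique(annots$gene_id))
  n <- table(factor(annots$gene_id, levels = gene_ids))
  counts <- data.frame(gene_id = gene_ids, n_acr = as.integer(n),
                       stringsAsFactors = FALSE)
  tests <- NULL
  if (!is.null(classes)) {
    counts$class <- classes[counts$gene_id]
    summ <- do.call(rbind, lapply(split(counts$n_acr, counts$class),
      function(x) data.frame(n = length(x), q1 = stats::quantile(x, .25),
                             median = stats::median(x),
                             q3 = stats::quantile(x, .75))))
    if (length(unique(counts$class)) > 1L)
      tests <- stats::pairwise.wilcox.test(counts$n_acr, counts$class,
                                           p.adjust.method = "bonferroni",
                                           exact = FALSE)
  } else {
    x <- counts$n_acr
    summ <- data.frame(n = length(x), q1 = stats::quantile(x, .25),
                       median = stats::median(x),
                       q3 = stats::quantile(x, .75))
  }
  rownames(summ) <- NULL
  list(counts = counts, summary = summ, tests = tests)
}

#' Cumulative distribution of ACR-to-TSS distances
#'
#' Empirical CDF of the absolute distance from each ACR to its nearest TSS,
#' optionally rescaled by a genome-level mean intergenic length so species
#' with very different genome sizes become comparable.
#'
#' @param annots an `acr_annotation`.
#' @param scale_by `NULL`, or a positive number (e.g. from
#'   [mean_intergenic_length()]) dividing all distances.
#' @return data frame `distance`, `cumprop` (non-decreasing, ending at 1).
#' @export
tss_distance_cdf <- function(annots, scale_by = NULL) {
  d <- sort(abs(annots$tss_dist))
  if (!is.null(scale_by)) {
    stopifnot(is.numeric(scale_by), scale_by > 0)
    d <- d / scale_by
  }
  data.frame(distance = d, cumprop = seq_along(d) / length(d))
}

#' Mean intergenic length of a gene annotation
#'
#' Mean gap between consecutive gene bodies per chromosome (negative gaps
#' from overlapping genes are ignored).
#'
#' @param genes gene-model list (see [classify_acr_context()]).
#' @return mean intergenic length in bp.
#' @export
mean_intergenic_length <- function(genes) {
  gm <- genes$genes
  gaps <- unlist(lapply(split(gm, gm$chrom), function(dd) {
    dd <- dd[order(dd$start), , drop = FALSE]
    if (nrow(dd) < 2L) return(numeric())
    dd$start[-1L] - dd$end[-nrow(dd)] - 1L
  }))
  gaps <- gaps[gaps > 0]
  if (!length(gaps)) stop("no intergenic gaps found", call. = FALSE)
  mean(gaps)
}
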