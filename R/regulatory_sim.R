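#' Simulate a regulatory landscape with known ACR categories
#'
#' Generates gene models (TSS, strand, three exons each) on a synthetic
#' coordinate system — genes of 5 kb spaced every 30 kb, random strand — and
#' plants accessible chromatin regions of 200 bp in known genomic-context
#' categories. Each gene receives `Poisson(acr_rate_per_gene)` ACRs; a
#' planted ACR is distal with probability `distal_fraction` and otherwise
#' uniformly promoter / proximal / exonic. Placement offsets are drawn
#' inside strand-aware windows chosen so the planted category is
#' unambiguous: promoter ACRs sit fully inside the promoter window, proximal
#' ACRs inside the upstream proximal window clear of the promoter, exonic
#' ACRs inside the second exon beyond the proximal window, and distal ACRs
#' in mid-intergenic space more than 5 kb from every TSS. The recorded truth
#' labels are therefore exactly recoverable by [classify_acr_context()].
#'
#' @param genes_per_chr number of genes on the simulated chromosome.
#' @param acr_rate_per_gene expected ACRs per gene (Poisson rate, >= 0).
#' @param distal_fraction probability a planted ACR is distal.
#' @param seed RNG seed.
#' @return list with `acrs` (data frame `chrom`, `start`, `end` 0-based
#'   half-open, `name`, `truth` category) and `genes` (gene-model list as
#'   consumed by [classify_acr_context()]).
#' @export
simulate_regulatory_landscape <- function(genes_per_chr = 100,
                                          acr_rate_per_gene = 3,
                                          distal_fraction = 0.3,
                                          seed = NULL) {
  genes_per_chr <- check_count(genes_per_chr, "genes_per_chr")
  if (acr_rate_per_gene < 0) stop("`acr_rate_per_gene` must be >= 0", call. = FALSE)
  check_prob(distal_fraction, "distal_fraction")
  chrom <- "simChr"
  spacing <- 30000L; body <- 5000L; w <- 200L

  with_seed(seed, {
    gid <- sprintf("g%04d", seq_len(genes_per_chr))
    gstart <- 10000L + (seq_len(genes_per_chr) - 1L) * spacing
    gend <- gstart + body - 1L
    strand <- sample(c("+", "-"), genes_per_chr, replace = TRUE)
    tss <- ifelse(strand == "+", gstart, gend)
    dir <- ifelse(strand == "+", 1L, -1L)
    gm <- data.frame(gene_id = gid, chrom = chrom, start = gstart, end = gend,
                     strand = strand, biotype = "protein_coding",
                     stringsAsFactors = FALSE)
    ## exons in transcript orientation: 0-300, 1500-2500, 4000-4999 from TSS
    exon_off <- list(c(0L, 300L), c(1500L, 2500L), c(4000L, 4999L))
    exons <- do.call(rbind, lapply(exon_off, function(e) {
      a <- tss + dir * e[1L]; b <- tss + dir * e[2L]
      data.frame(gene_id = gid, chrom = chrom, start = pmin(a, b),
                 end = pmax(a, b), stringsAsFactors = FALSE)
    }))
    exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
    rownames(exons) <- NULL

    n_acr <- stats::rpois(genes_per_chr, acr_rate_per_gene)
    p_other <- (1 - distal_fraction) / 3
    cats <- sample(c("distal", "promoter", "proximal", "exonic"),
                   sum(n_acr), replace = TRUE,
                   prob = c(distal_fraction, rep(p_other, 3L)))
    host <- rep(seq_len(genes_per_chr), n_acr)
    ## transcript-orientation offset windows for the ACR start (width 200):
    ## negative = upstream of the TSS
    win <- list(promoter = c(-900L, -300L), proximal = c(-4800L, -1500L),
                exonic = c(1550L, 2300L), distal = c(8000L, 14000L))
    off <- vapply(cats, function(cc) {
      r <- win[[cc]]
      sample(r[1L]:r[2L], 1L)
    }, 0L)
    a <- tss[host] + dir[host] * off
    b <- tss[host] + dir[host] * (off + (w - 1L))
    s1 <- pmin(a, b); e1 <- pmax(a, b)
    acrs <- data.frame(chrom = chrom, start = s1 - 1L, end = e1,
                       name = sprintf("acr%05d", seq_along(host)),
                       truth = cats, stringsAsFactors = FALSE)
    acrs <- acrs[order(acrs$start), , drop = FALSE]
    rownames(acrs) <- NULL
    list(acrs = acrs, genes = list(genes = gm, exons = exons))
  })
}
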