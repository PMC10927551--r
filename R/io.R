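#' Write a genome map as 4-column TSV
#'
#' Columns `species`, `chromosome`, `gene_id`, `family_id` with a header
#' line; rows in chromosome/positional order, so gene order round-trips.
#'
#' @param g a `genome_map`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(g, path) {
  stopifnot(inherits(g, "genome_map"))
  gg <- recompute_indices(g)$genes
  out <- data.frame(species = g$species, chromosome = gg$chromosome,
                    gene_id = gg$gene_id, family_id = gg$family_id,
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a genome map
#'
#' TSV input requires the exact 4-column header `species`, `chromosome`,
#' `gene_id`, `family_id`; gene indices are rebuilt from row order.
#' GFF3 input reads `gene` features (via `rtracklayer`), taking the gene id
#' from the `ID` attribute and the family from a `family_id` attribute when
#' present (falling back to the gene id); genes are ordered by coordinate
#' within each sequence. Duplicate gene ids are an error.
#'
#' @param path input file.
#' @param format `"tsv"` or `"gff3"`.
#' @param species species name for GFF3 input (TSV carries its own).
#' @return a `genome_map` (descent records unknown: `acs` are NA).
#' @export
read_gene_map <- function(path, format = c("tsv", "gff3"),
                          species = "unknown") {
  format <- match.arg(format)
  if (format == "gff3") {
    mods <- read_gff3_genes(path)
    gm <- mods$genes
    gm <- gm[order(gm$chrom, gm$start, gm$gene_id), , drop = FALSE]
    fam <- if ("family_id" %in% names(gm)) gm$family_id else gm$gene_id
    genes <- data.frame(gene_id = gm$gene_id, family_id = fam,
                        chromosome = gm$chrom, index = 0L,
                        stringsAsFactors = FALSE)
    sp <- species
  } else {
    need <- c("species", "chromosome", "gene_id", "family_id")
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = "character")
    if (!identical(names(dt), need))
      stop("gene map ", path, " line 1: expected header ",
           paste(need, collapse = "\t"), call. = FALSE)
    if (anyNA(dt) || any(dt == ""))
      stop("gene map ", path, " line ",
           which(apply(is.na(dt) | dt == "", 1L, any))[1L] + 1L,
           ": missing field", call. = FALSE)
    sp <- unique(dt$species)
    if (length(sp) != 1L)
      stop("gene map ", path, " mixes species: ",
           paste(sp, collapse = ", "), call. = FALSE)
    genes <- data.frame(gene_id = dt$gene_id, family_id = dt$family_id,
                        chromosome = dt$chromosome, index = 0L,
                        stringsAsFactors = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    i <- which(duplicated(genes$gene_id))[1L]
    stop("gene map ", path, if (format == "tsv") paste0(" line ", i + 1L) else "",
         ": duplicate gene_id ", genes$gene_id[i], call. = FALSE)
  }
  chrs <- unique(genes$chromosome)
  chrom <- data.frame(chromosome = chrs, copy_path = NA_character_,
                      stringsAsFactors = FALSE)
  chrom$acs <- rep(list(NA_character_), length(chrs))
  recompute_indices(new_genome_map(sp, genes, chrom))
}

#' Write a hit table (12-column tabular)
#' @param hits a `hit_table`.
#' @param path output file (no header, tab-separated — the standard dialect).
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(is.data.frame(hits), identical(names(hits), HIT_COLS))
  data.table::fwrite(hits, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 12-column tabular hit table
#'
#' Rows with a wrong column count raise a parse error naming the line.
#' Duplicate (query, subject) rows are deduplicated keeping the best
#' bit-score; the kept/dropped counts are recorded in the `dedup` attribute.
#'
#' @param path input file.
#' @return a `hit_table` data frame.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf != 12L))
    stop("hit table ", path, " line ", which(nf != 12L)[1L],
         ": expected 12 columns, found ", nf[nf != 12L][1L], call. = FALSE)
  dt <- data.table::fread(text = lines, sep = "\t", header = FALSE,
                          col.names = HIT_COLS)
  n0 <- nrow(dt)
  data.table::setorder(dt, qseqid, sseqid, -bitscore, evalue)
  dt <- dt[!duplicated(dt, by = c("qseqid", "sseqid"))]
  out <- as.data.frame(dt)
  attr(out, "dedup") <- c(read = n0, kept = nrow(out))
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Read newick trees from a directory
#'
#' Every regular file is parsed as newick; unparseable files are collected
#' into the `errors` attribute instead of aborting the batch.
#'
#' @param dir directory of newick files.
#' @param pattern filename filter (default all files).
#' @return named list of `phylo` objects with an `errors` attribute
#'   (data frame `file`, `message`).
#' @export
read_trees <- function(dir, pattern = NULL) {
  stopifnot(dir.exists(dir))
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (!length(files)) {
    warning("no tree files found in ", dir)
    out <- list()
    attr(out, "errors") <- data.frame(file = character(),
                                      message = character())
    return(out)
  }
  trees <- list(); errs <- list()
  for (f in files) {
    t <- tryCatch(ape::read.tree(f), error = function(e) e,
                  warning = function(w) w)
    if (inherits(t, "phylo")) trees[[basename(f)]] <- t
    else errs[[length(errs) + 1L]] <-
      data.frame(file = basename(f),
                 message = conditionMessage(t), stringsAsFactors = FALSE)
  }
  attr(trees, "errors") <- if (length(errs)) do.call(rbind, errs)
    else data.frame(file = character(), message = character())
  trees
}

#' Write newick trees to a directory
#' @param trees named character vector of newick strings or list of `phylo`.
#' @param dir output directory (created if needed).
#' @return the written paths, invisibly.
#' @export
write_trees <- function(trees, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(trees))
  for (i in seq_along(trees)) {
    nm <- names(trees)[i] %||% sprintf("tree%04d", i)
    paths[i] <- file.path(dir, paste0(nm, ".nwk"))
    t <- trees[[i]]
    if (inherits(t, "phylo")) ape::write.tree(t, paths[i])
    else writeLines(t, paths[i])
  }
  invisible(paths)
}

#' Read BED intervals (0-based half-open)
#'
#' @param path BED file (>= 3 columns; column 4 becomes `name`).
#' @return data frame `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf < 3L))
    stop("BED ", path, " line ", which(nf < 3L)[1L],
         ": fewer than 3 columns", call. = FALSE)
  dt <- data.table::fread(text = lines, sep = "\t", header = FALSE)
  out <- data.frame(chrom = as.character(dt[[1L]]),
                    start = as.integer(dt[[2L]]), end = as.integer(dt[[3L]]),
                    name = if (ncol(dt) >= 4L) as.character(dt[[4L]])
                           else sprintf("iv%05d", seq_len(nrow(dt))),
                    stringsAsFactors = FALSE)
  bad <- which(out$end <= out$start)
  if (length(bad))
    stop("BED ", path, " line ", bad[1L], ": end <= start", call. = FALSE)
  out
}

#' Write BED intervals (0-based half-open)
#' @param intervals data frame `chrom`, `start`, `end` and optionally `name`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  data.table::fwrite(intervals[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3 (1-based closed)
#'
#' Parses `gene` and `exon` features via `rtracklayer`, linking exons to
#' genes through the `Parent`/`ID` attributes (transcript level collapsed).
#'
#' @param path GFF3 file.
#' @return list with data frames `genes` (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `biotype`, and `family_id` if annotated) and `exons`
#'   (`gene_id`, `chrom`, `start`, `end`).
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  is_gene <- type == "gene"
  if (!any(is_gene)) stop("no gene features in ", path, call. = FALSE)
  gid <- as.character(md$ID[is_gene])
  genes <- data.frame(
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    biotype = if ("biotype" %in% names(md))
      as.character(md$biotype[is_gene]) else "protein_coding",
    stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  if ("family_id" %in% names(md))
    genes$family_id <- as.character(md$family_id[is_gene])

  ## map transcript/mRNA IDs back to their gene
  parent_of <- function(x) vapply(x, function(p)
    if (length(p)) as.character(p[1L]) else NA_character_, "")
  id_all <- as.character(md$ID)
  par_all <- parent_of(md$Parent)
  owner <- stats::setNames(par_all, id_all)
  resolve_gene <- function(id) {
    seen <- character()
    while (!is.na(id) && !id %in% gid && !id %in% seen) {
      seen <- c(seen, id); id <- owner[[id]] %||% NA_character_
      if (is.null(id)) id <- NA_character_
    }
    if (!is.na(id) && id %in% gid) id else NA_character_
  }
  is_exon <- type == "exon"
  exons <- if (any(is_exon)) {
    eg <- vapply(par_all[is_exon], resolve_gene, "")
    data.frame(gene_id = eg,
               chrom = as.character(GenomicRanges::seqnames(gr)[is_exon]),
               start = GenomicRanges::start(gr)[is_exon],
               end = GenomicRanges::end(gr)[is_exon],
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), chrom = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  }
  exons <- exons[!is.na(exons$gene_id), , drop = FALSE]
  rownames(genes) <- rownames(exons) <- NULL
  list(genes = genes, exons = exons)
}

#' Write gene models as GFF3 (1-based closed)
#' @param genes gene-model list (see [read_gff3_genes()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  gm <- genes$genes; ex <- genes$exons
  g_gr <- GenomicRanges::GRanges(gm$chrom, IRanges::IRanges(gm$start, gm$end),
                                 strand = gm$strand)
  S4Vectors::mcols(g_gr)$type <- "gene"
  S4Vectors::mcols(g_gr)$ID <- gm$gene_id
  S4Vectors::mcols(g_gr)$biotype <- gm$biotype
  if ("family_id" %in% names(gm))
    S4Vectors::mcols(g_gr)$family_id <- gm$family_id
  out <- g_gr
  if (nrow(ex)) {
    e_gr <- GenomicRanges::GRanges(ex$chrom,
      IRanges::IRanges(ex$start, ex$end),
      strand = gm$strand[match(ex$gene_id, gm$gene_id)])
    S4Vectors::mcols(e_gr)$type <- "exon"
    S4Vectors::mcols(e_gr)$ID <- sprintf("%s.exon%d", ex$gene_id,
      stats::ave(seq_len(nrow(ex)), ex$gene_id, FUN = seq_along))
    S4Vectors::mcols(e_gr)$Parent <- ex$gene_id
    suppressWarnings(out <- c(g_gr, e_gr))
  }
  rtracklayer::export(out, path, format = "GFF3")
  invisible(path)
}

#' Export an hclust dendrogram as newick
#' @param hc an `hclust` (e.g. from [ward_cluster()]).
#' @return newick string.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
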