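#' Reciprocal best hits
#'
#' Returns the gene pairs (a, b) such that b is a's best-scoring subject and
#' a is b's best-scoring subject, considering only rows with
#' `evalue <= evalue_max`. Ties on bit-score are broken by lower e-value,
#' then lexicographic subject id, so the result is deterministic.
#'
#' @param hits a `hit_table` (see [emit_hit_table()] / [read_hit_table()])
#'   covering one genome pair.
#' @param evalue_max e-value cutoff (default the conventional 1e-6).
#' @return data frame with columns `gene_a`, `gene_b` (lexicographically
#'   ordered within each pair, one row per unordered pair).
#' @export
reciprocal_best_hits <- function(hits, evalue_max = 1e-6) {
  stopifnot(is.data.frame(hits))
  if (!is.numeric(evalue_max) || evalue_max <= 0)
    stop("`evalue_max` must be > 0", call. = FALSE)
  h <- data.table::as.data.table(hits)[evalue <= evalue_max]
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(h)) return(empty)
  data.table::setorder(h, qseqid, -bitscore, evalue, sseqid)
  best <- h[!duplicated(qseqid), c("qseqid", "sseqid")]
  m <- merge(best, best, by.x = c("qseqid", "sseqid"),
             by.y = c("sseqid", "qseqid"))
  if (!nrow(m)) return(empty)
  a <- pmin(m$qseqid, m$sseqid)
  b <- pmax(m$qseqid, m$sseqid)
  out <- unique(data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE))
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Unidirectional best hits
#'
#' Best-scoring subject per query at an e-value cutoff, with the same
#' deterministic tie-breaking as [reciprocal_best_hits()]. Used when homology
#' to a reference genome (e.g. a pre-duplication outgroup) is established
#' with the reference genes as queries, without requiring reciprocity.
#'
#' @inheritParams reciprocal_best_hits
#' @return data frame with columns `query`, `subject`.
#' @export
best_hits_unidirectional <- function(hits, evalue_max = 1e-6) {
  stopifnot(is.data.frame(hits))
  h <- data.table::as.data.table(hits)[evalue <= evalue_max]
  if (!nrow(h))
    return(data.frame(query = character(), subject = character(),
                      stringsAsFactors = FALSE))
  data.table::setorder(h, qseqid, -bitscore, evalue, sseqid)
  best <- h[!duplicated(qseqid)]
  out <- data.frame(query = best$qseqid, subject = best$sseqid,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
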