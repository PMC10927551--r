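HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Simulate a protein-similarity hit table
#'
#' Emits a 12-column tabular hit table (the standard `outfmt 6` dialect) for
#' every cross-genome gene pair belonging to the same ancestral family, plus
#' spurious off-target hits. Each true pair gets one bit-score drawn from
#' `Normal(score_mu, score_noise_sd)` reported reciprocally (both directions,
#' equal score); the e-value is the deterministic monotone map
#' `min(exp(-score/2), 1)`, so only score ordering matters downstream.
#' Spurious hits join random non-family pairs, are emitted in one direction
#' only and draw from a halved score distribution; their count is
#' `Binomial(n_true_pairs, offtarget_rate)`.
#'
#' @param genomes list of two or more `genome_map`s; every unordered genome
#'   pair is compared.
#' @param score_mu mean bit-score of true homologue pairs.
#' @param score_noise_sd bit-score standard deviation (>= 0).
#' @param offtarget_rate spurious-hit probability per true pair.
#' @param seed RNG seed.
#' @return data frame of class `hit_table` with the 12 standard columns.
#' @export
emit_hit_table <- function(genomes, score_mu = 200, score_noise_sd = 10,
                           offtarget_rate = 0, seed = NULL) {
  if (length(genomes) < 2L)
    stop("need at least 2 genomes to compare", call. = FALSE)
  if (score_noise_sd < 0) stop("`score_noise_sd` must be >= 0", call. = FALSE)
  check_prob(offtarget_rate, "offtarget_rate")

  with_seed(seed, {
    combs <- utils::combn(length(genomes), 2L)
    chunks <- lapply(seq_len(ncol(combs)), function(k) {
      a <- genomes[[combs[1L, k]]]$genes
      b <- genomes[[combs[2L, k]]]$genes
      m <- merge(a[, c("gene_id", "family_id")], b[, c("gene_id", "family_id")],
                 by = "family_id")
      rows <- list()
      if (nrow(m)) {
        ## deterministic pair order so a fixed seed fixes the table
        m <- m[order(m$gene_id.x, m$gene_id.y), , drop = FALSE]
        sc <- stats::rnorm(nrow(m), score_mu, score_noise_sd)
        rows$fwd <- hit_rows(m$gene_id.x, m$gene_id.y, sc)
        rows$rev <- hit_rows(m$gene_id.y, m$gene_id.x, sc)
      }
      n_sp <- if (nrow(m) && offtarget_rate > 0)
        stats::rbinom(1L, nrow(m), offtarget_rate) else 0L
      if (n_sp > 0L) {
        qi <- sample.int(nrow(a), n_sp, replace = TRUE)
        si <- sample.int(nrow(b), n_sp, replace = TRUE)
        ok <- a$family_id[qi] != b$family_id[si]
        if (any(ok)) {
          sc <- stats::rnorm(sum(ok), score_mu / 2, score_noise_sd)
          rows$spur <- hit_rows(a$gene_id[qi[ok]], b$gene_id[si[ok]], sc)
        }
      }
      do.call(rbind, rows)
    })
    out <- do.call(rbind, chunks)
    rownames(out) <- NULL
    class(out) <- c("hit_table", "data.frame")
    out
  })
}

hit_rows <- function(q, s, score) {
  bs <- round(score, 1)
  data.frame(
    qseqid = q, sseqid = s,
    pident = round(pmin(99.9, pmax(35, 35 + score / 4)), 1),
    length = 200L, mismatch = 10L, gapopen = 1L,
    qstart = 1L, qend = 200L, sstart = 1L, send = 200L,
    ## deterministic monotone map of the reported bit-score
    evalue = pmin(exp(-bs / 2), 1),
    bitscore = bs,
    stringsAsFactors = FALSE
  )
}
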