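#' The nine adult tissues profiled by default
#' @return character vector of tissue names.
#' @export
default_tissues <- function() {
  c("brain", "gills", "liver", "intestine", "heart", "muscle", "kidney",
    "testis", "blood")
}

#' Quantile-normalize an expression matrix
#'
#' Makes the distribution of every tissue column identical by replacing each
#' column with the mean-of-sorted-columns reference distribution at its
#' ranks, averaging over ties (via `limma::normalizeQuantiles`). A
#' single-column matrix is returned unchanged with a warning.
#'
#' @param m numeric genes x tissues matrix of TPM values (non-negative).
#' @return normalized matrix with the same dimnames.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("TPM values must be non-negative", call. = FALSE)
  if (ncol(m) < 2L) {
    warning("fewer than 2 tissues: quantile normalization is the identity")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Binarize expression into per-gene tissue domains
#'
#' A gene is "expressed" in a tissue when its (normalized) TPM strictly
#' exceeds `tpm_min`; the set of such tissues is its expression domain.
#'
#' @param m genes x tissues matrix with dimnames.
#' @param tpm_min strict TPM threshold (default 5).
#' @return named list: gene -> character vector of tissues (possibly empty).
#' @export
expression_domains <- function(m, tpm_min = 5) {
  m <- as.matrix(m)
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  tiss <- colnames(m)
  out <- lapply(seq_len(nrow(m)), function(i) tiss[m[i, ] > tpm_min])
  stats::setNames(out, rownames(m))
}

#' Classify the expression fate of an ohnologue pair
#'
#' From two non-empty tissue-domain sets:
#' * equal sets -> `redundancy`;
#' * strict containment of one set in the other -> `specialization`, graded
#'   `strong` when the narrow copy covers < `strong_frac` of the broad
#'   copy's domains, else `mild`;
#' * otherwise (each copy has at least one exclusive tissue) ->
#'   `subfunctionalization`.
#' The three fates are exhaustive and mutually exclusive over non-empty
#' pairs. Pairs where either copy is expressed nowhere must be excluded
#' upstream (this function errors on them).
#'
#' @param dom_a,dom_b character vectors of tissues (non-empty).
#' @param strong_frac strict fraction below which specialization is strong
#'   (default 0.40).
#' @return list `fate`, `grade` (`"strong"`/`"mild"`/NA), `domains_a`,
#'   `domains_b`.
#' @export
classify_fate <- function(dom_a, dom_b, strong_frac = 0.40) {
  dom_a <- unique(dom_a); dom_b <- unique(dom_b)
  if (!length(dom_a) || !length(dom_b))
    stop("both ohnologues must be expressed in at least one tissue",
         call. = FALSE)
  if (setequal(dom_a, dom_b)) {
    fate <- "redundancy"; grade <- NA_character_
  } else if (all(dom_a %in% dom_b) || all(dom_b %in% dom_a)) {
    fate <- "specialization"
    narrow <- min(length(dom_a), length(dom_b))
    broad <- max(length(dom_a), length(dom_b))
    grade <- if (narrow / broad < strong_frac) "strong" else "mild"
  } else {
    fate <- "subfunctionalization"; grade <- NA_character_
  }
  list(fate = fate, grade = grade, domains_a = dom_a, domains_b = dom_b)
}

#' Classify fates for a table of ohnologue pairs
#'
#' @param domains named list gene -> tissue set (from
#'   [expression_domains()]).
#' @param pairs data frame with columns `pair_id`, `gene_a`, `gene_b`.
#' @param strong_frac passed to [classify_fate()].
#' @return data frame with `pair_id`, `gene_a`, `gene_b`, `fate`, `grade`,
#'   list-columns `domains_a`/`domains_b`, and an `excluded` attribute
#'   listing pairs dropped because one copy is expressed nowhere.
#' @export
classify_fates <- function(domains, pairs, strong_frac = 0.40) {
  stopifnot(all(c("pair_id", "gene_a", "gene_b") %in% names(pairs)))
  da <- domains[pairs$gene_a]; db <- domains[pairs$gene_b]
  ok <- lengths(da) > 0L & lengths(db) > 0L
  excluded <- pairs[!ok, , drop = FALSE]
  pairs <- pairs[ok, , drop = FALSE]
  da <- da[ok]; db <- db[ok]
  calls <- mapply(classify_fate, da, db,
                  MoreArgs = list(strong_frac = strong_frac), SIMPLIFY = FALSE)
  out <- data.frame(pair_id = pairs$pair_id, gene_a = pairs$gene_a,
                    gene_b = pairs$gene_b,
                    fate = vapply(calls, `[[`, "", "fate"),
                    grade = vapply(calls, `[[`, "", "grade"),
                    stringsAsFactors = FALSE)
  out$domains_a <- lapply(calls, `[[`, "domains_a")
  out$domains_b <- lapply(calls, `[[`, "domains_b")
  attr(out, "excluded") <- excluded
  rownames(out) <- NULL
  out
}

#' Tissue profile of strongly specialized ohnologues
#'
#' Among strong-specialization pairs whose narrow copy retains at most
#' `strong_max_domains` expression domains, counts in how many pairs each
#' tissue hosts the narrow copy's expression (a multi-domain narrow copy
#' counts once per tissue).
#'
#' @param calls output of [classify_fates()].
#' @param tissues tissue universe for the (possibly zero) counts.
#' @param strong_max_domains maximum narrow-copy domain count (default 2).
#' @return named integer vector tissue -> count.
#' @export
specialization_tissue_profile <- function(calls, tissues = default_tissues(),
                                          strong_max_domains = 2) {
  counts <- stats::setNames(integer(length(tissues)), tissues)
  sel <- which(calls$fate == "specialization" &
                 !is.na(calls$grade) & calls$grade == "strong")
  for (i in sel) {
    a <- calls$domains_a[[i]]; b <- calls$domains_b[[i]]
    narrow <- if (length(a) <= length(b)) a else b
    if (length(narrow) > strong_max_domains) next
    narrow <- intersect(narrow, tissues)
    counts[narrow] <- counts[narrow] + 1L
  }
  counts
}
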