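#' Gene retention profile of a chromosome against an AC gene list
#'
#' A retention profile is a binary vector over an ancestral chromosome's
#' anchored gene list, in fixed order: position i is 1 if at least one gene
#' on the query chromosome belongs to the family of AC gene i, else 0.
#' Multiplicity is ignored (two surviving copies still give a 1), so the
#' profile depends only on chromosome gene *content*, never on gene order.
#'
#' @param ac_families character vector of ancestral family ids in fixed order
#'   (e.g. one element of [ac_family_lists()]).
#' @param chrom_families family ids of the genes on the query chromosome
#'   (any order, duplicates allowed).
#' @param ac_id,species,chromosome labels carried into the result.
#' @return a `retention_profile`: list with `ac_id`, `species`, `chromosome`,
#'   `vector` (integer 0/1) and `n_retained`.
#' @export
retention_profile <- function(ac_families, chrom_families, ac_id = "AC",
                              species = NA_character_,
                              chromosome = NA_character_) {
  if (!length(ac_families)) stop("empty AC gene list", call. = FALSE)
  v <- as.integer(ac_families %in% chrom_families)
  structure(list(ac_id = ac_id, species = species, chromosome = chromosome,
                 vector = v, n_retained = sum(v)),
            class = "retention_profile")
}

#' Overlapping ratio (OR) of two retention profiles
#'
#' The number of ancestral genes retained on both chromosomes divided by the
#' smaller of the two retained totals. Ranges over \[0, 1\], is symmetric,
#' and is insensitive both to gene order and to the size difference between
#' the two query chromosomes. Chromosomes descending from one duplication
#' share much of their retained complement (high OR); chromosomes derived
#' from a fission plus translocation background do not (low OR).
#'
#' @param a,b `retention_profile`s over the same AC gene list.
#' @return numeric OR in \[0, 1\].
#' @export
overlapping_ratio <- function(a, b) {
  stopifnot(inherits(a, "retention_profile"), inherits(b, "retention_profile"))
  if (!identical(a$ac_id, b$ac_id))
    stop("profiles refer to different ACs", call. = FALSE)
  if (length(a$vector) != length(b$vector))
    stop("profile lengths differ", call. = FALSE)
  lo <- min(a$n_retained, b$n_retained)
  if (lo == 0L)
    stop("OR undefined: a profile retains zero genes", call. = FALSE)
  sum(a$vector & b$vector) / lo
}

#' Pairwise OR matrix for one AC
#'
#' Profiles retaining fewer than `min_retained` ancestral genes are excluded
#' (logged in `excluded`) before all pairwise overlapping ratios are
#' computed. Fewer than two surviving profiles yield an empty, flagged
#' matrix rather than an error.
#'
#' @param profiles list of `retention_profile`s sharing one `ac_id`.
#' @param min_retained minimum retained genes per chromosome (default 20).
#' @return an `or_matrix`: list with `ac_id`, `labels`
#'   (`species:chromosome`), `n_retained`, symmetric `values`, `excluded`
#'   and the `empty` flag.
#' @export
or_matrix <- function(profiles, min_retained = 20) {
  stopifnot(length(profiles) >= 1L)
  acs <- unique(vapply(profiles, `[[`, "", "ac_id"))
  if (length(acs) != 1L) stop("profiles span several ACs", call. = FALSE)
  lab <- vapply(profiles, function(p)
    if (is.na(p$species)) p$chromosome else paste(p$species, p$chromosome, sep = ":"), "")
  n_ret <- vapply(profiles, `[[`, 0L, "n_retained")
  keep <- n_ret >= min_retained
  excluded <- data.frame(label = lab[!keep], n_retained = n_ret[!keep],
                         stringsAsFactors = FALSE)
  profiles <- profiles[keep]; lab <- lab[keep]; n_ret <- n_ret[keep]
  if (length(profiles) < 2L) {
    return(structure(list(ac_id = acs, labels = lab, n_retained = n_ret,
                          values = matrix(numeric(), 0L, 0L),
                          excluded = excluded, empty = TRUE),
                     class = "or_matrix"))
  }
  V <- do.call(rbind, lapply(profiles, `[[`, "vector"))
  shared <- V %*% t(V)
  mins <- outer(n_ret, n_ret, pmin)
  vals <- shared / mins
  dimnames(vals) <- list(lab, lab)
  structure(list(ac_id = acs, labels = lab,
                 n_retained = stats::setNames(n_ret, lab),
                 values = vals, excluded = excluded, empty = FALSE),
            class = "or_matrix")
}

#' @export
print.or_matrix <- function(x, ...) {
  cat(sprintf("<or_matrix> %s: %d chromosomes%s\n", x$ac_id, length(x$labels),
              if (x$empty) " (empty: <2 qualifying chromosomes)" else ""))
  invisible(x)
}

#' Ward hierarchical clustering of retention profiles
#'
#' Agglomerative clustering of the chromosomes of one OR matrix using
#' `1 - OR` as the pairwise dissimilarity and the classical Ward
#' Lance-Williams update applied to the raw (unsquared) dissimilarities
#' (`stats::hclust(method = "ward.D")`). `1 - OR` is not guaranteed
#' Euclidean, so merge-height inversions are possible; they are reported via
#' the `inversions` attribute, never silently repaired.
#'
#' @param m an `or_matrix`, or a symmetric similarity matrix in \[0, 1\].
#' @return an `hclust` object (labels are chromosome labels).
#' @export
ward_cluster <- function(m) {
  vals <- if (inherits(m, "or_matrix")) m$values else as.matrix(m)
  if (nrow(vals) < 2L) stop("need at least 2 chromosomes to cluster", call. = FALSE)
  d <- stats::as.dist(1 - vals)
  hc <- stats::hclust(d, method = "ward.D")
  attr(hc, "inversions") <- any(diff(hc$height) < 0)
  hc
}
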