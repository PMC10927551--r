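#' Monte-Carlo null for mirrored post-1R fusion pairs
#'
#' After a 1R duplication, each of `n_ac` pre-duplication chromosomes exists
#' in two copies (2*`n_ac` chromosomes). This routine estimates how often
#' `n_fusions` random fusions produce, purely by chance, at least one
#' "mirror pair": two fusion events joining the two 1R copies of the same
#' two pre-duplication chromosomes — a configuration that would mimic a
#' single pre-1R fusion. Replicate procedure (the documented default): each
#' fusion draws two distinct current chromosomes uniformly at random;
#' fusion products remain in the pool and may fuse again; an event joining
#' chromosomes X and Y contributes every cross pair of copies
#' ((i, copy), (j, copy')) with i != j carried by X and Y, and a mirror
#' exists when two distinct events contribute copy-disjoint pairs for the
#' same unordered {i, j}.
#'
#' @param n_ac number of pre-1R chromosomes (>= 2).
#' @param n_fusions number of fusions per replicate (<= n_ac).
#' @param reps Monte-Carlo replicates (>= 1).
#' @param seed RNG seed.
#' @return fraction of replicates containing at least one mirror pair.
#' @export
simulate_post1R_fusion_null <- function(n_ac, n_fusions, reps = 10000,
                                        seed = NULL) {
  n_ac <- check_count(n_ac, "n_ac", min = 2L)
  check_count(n_fusions, "n_fusions", min = 0L)
  check_count(reps, "reps", min = 1L)
  if (n_fusions > n_ac)
    stop("`n_fusions` must not exceed `n_ac`", call. = FALSE)
  if (n_fusions < 2L) return(0)

  with_seed(seed, {
    hits <- vapply(seq_len(reps), function(r) {
      ## pool of chromosomes; each is a list of (ac, copy) pairs
      pool <- c(lapply(seq_len(n_ac), function(i) cbind(i, 1L)),
                lapply(seq_len(n_ac), function(i) cbind(i, 2L)))
      events <- vector("list", n_fusions)
      for (f in seq_len(n_fusions)) {
        pick <- sample.int(length(pool), 2L)
        x <- pool[[pick[1L]]]; y <- pool[[pick[2L]]]
        ## cross pairs between distinct ACs contributed by this event
        ev <- list()
        for (a in seq_len(nrow(x))) for (b in seq_len(nrow(y))) {
          if (x[a, 1L] != y[b, 1L]) {
            i <- x[a, 1L]; j <- y[b, 1L]
            ci <- x[a, 2L]; cj <- y[b, 2L]
            if (i > j) { tmp <- i; i <- j; j <- tmp
                         tmp <- ci; ci <- cj; cj <- tmp }
            ev[[length(ev) + 1L]] <- c(i, j, ci, cj)
          }
        }
        events[[f]] <- ev
        pool[[pick[1L]]] <- rbind(x, y)
        pool <- pool[-pick[2L]]
      }
      ## mirror: two events with copy-disjoint pairs on the same {i, j}
      for (f1 in seq_len(n_fusions - 1L)) for (f2 in (f1 + 1L):n_fusions) {
        for (p1 in events[[f1]]) for (p2 in events[[f2]]) {
          if (p1[1L] == p2[1L] && p1[2L] == p2[2L] &&
              p1[3L] != p2[3L] && p1[4L] != p2[4L]) return(1L)
        }
      }
      0L
    }, 0L)
    mean(hits)
  })
}
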