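#' Simulate ohnologue-pair expression with known fates
#'
#' For each pair a fate is drawn from `fate_mix`, a pair of tissue-domain
#' sets realizing exactly that fate is constructed, and TPM values are
#' emitted: `tpm_hi` inside a domain, `tpm_lo` outside, times multiplicative
#' noise drawn uniformly from `noise_range`. The noise is required to be
#' unable to cross the binarization threshold (`tpm_hi * min(noise) >
#' tpm_min` and `tpm_lo * max(noise) < tpm_min`), so at the default settings
#' the fate classifier recovers every planted fate; `noise_range = c(1, 1)`
#' gives noiseless data.
#'
#' Domain construction: `redundancy` uses one shared random non-empty set;
#' `subfunctionalization` gives each copy at least one exclusive tissue plus
#' a random shared core; `strong_spec`/`mild_spec` nest a narrow set inside
#' a broad one with narrow/broad strictly below / at-or-above
#' `strong_frac`.
#'
#' @param n_pairs number of ohnologue pairs.
#' @param fate_mix named proportions over `redundancy`,
#'   `subfunctionalization`, `strong_spec`, `mild_spec` (must sum to 1).
#' @param tissues tissue names (>= 2; strong_spec requires >= 3).
#' @param tpm_hi,tpm_lo in-domain / out-of-domain TPM levels.
#' @param tpm_min binarization threshold the noise may not cross.
#' @param noise_range multiplicative noise bounds.
#' @param strong_frac specialization grading fraction (default 0.40).
#' @param seed RNG seed.
#' @return list with `tpm` (2*n_pairs x tissues matrix), `pairs` (data frame
#'   `pair_id`, `gene_a`, `gene_b`, `fate`, `grade`) and `tissues`.
#' @export
simulate_expression <- function(n_pairs,
                                fate_mix = c(redundancy = 0.25,
                                             subfunctionalization = 0.25,
                                             strong_spec = 0.25,
                                             mild_spec = 0.25),
                                tissues = default_tissues(),
                                tpm_hi = 50, tpm_lo = 1, tpm_min = 5,
                                noise_range = c(0.7, 1.3),
                                strong_frac = 0.40, seed = NULL) {
  n_pairs <- check_count(n_pairs, "n_pairs")
  if (length(tissues) < 2L) stop("need at least 2 tissues", call. = FALSE)
  if (abs(sum(fate_mix) - 1) > 1e-8)
    stop("`fate_mix` proportions must sum to 1", call. = FALSE)
  if (!all(names(fate_mix) %in% c("redundancy", "subfunctionalization",
                                  "strong_spec", "mild_spec")))
    stop("unknown fate in `fate_mix`", call. = FALSE)
  if (tpm_lo >= tpm_min || tpm_hi <= tpm_min)
    stop("need tpm_lo < tpm_min < tpm_hi", call. = FALSE)
  if (tpm_hi * noise_range[1L] <= tpm_min ||
      tpm_lo * noise_range[2L] >= tpm_min)
    stop("noise range allows TPM to cross the threshold", call. = FALSE)
  T <- length(tissues)
  if ("strong_spec" %in% names(fate_mix) && fate_mix[["strong_spec"]] > 0 &&
      T < 3L)
    stop("strong specialization requires at least 3 tissues", call. = FALSE)

  pick <- function(n) sample(tissues, n)
  with_seed(seed, {
    fates <- sample(names(fate_mix), n_pairs, replace = TRUE, prob = fate_mix)
    doms <- lapply(fates, function(f) {
      switch(f,
        redundancy = {
          d <- pick(sample.int(T, 1L))
          list(a = d, b = d, grade = NA_character_,
               fate = "redundancy")
        },
        subfunctionalization = {
          ea <- sample.int(T - 1L, 1L)
          eb <- sample.int(T - ea, 1L)
          sh <- sample.int(T - ea - eb + 1L, 1L) - 1L
          tt <- pick(ea + eb + sh)
          list(a = tt[c(seq_len(ea), if (sh) ea + eb + seq_len(sh))],
               b = tt[c(ea + seq_len(eb), if (sh) ea + eb + seq_len(sh))],
               grade = NA_character_, fate = "subfunctionalization")
        },
        strong_spec = {
          b <- sample(3:T, 1L)
          n_max <- ceiling(strong_frac * b - 1e-9) - 1L
          n <- sample.int(n_max, 1L)
          broad <- pick(b)
          list(a = broad[seq_len(n)], b = broad, grade = "strong",
               fate = "specialization")
        },
        mild_spec = {
          repeat {
            b <- sample(2:T, 1L)
            lo <- ceiling(strong_frac * b - 1e-9)
            if (lo <= b - 1L) break
          }
          n <- if (lo == b - 1L) lo else sample(lo:(b - 1L), 1L)
          broad <- pick(b)
          list(a = broad[seq_len(n)], b = broad, grade = "mild",
               fate = "specialization")
        })
    })
    ids <- sprintf("pair%04d", seq_len(n_pairs))
    genes <- as.vector(rbind(paste0(ids, "_a"), paste0(ids, "_b")))
    tpm <- matrix(0, nrow = 2L * n_pairs, ncol = T,
                  dimnames = list(genes, tissues))
    for (i in seq_len(n_pairs)) {
      for (g in c("a", "b")) {
        d <- doms[[i]][[g]]
        base <- ifelse(tissues %in% d, tpm_hi, tpm_lo)
        noise <- stats::runif(T, noise_range[1L], noise_range[2L])
        tpm[paste0(ids[i], "_", g), ] <- base * noise
      }
    }
    pairs <- data.frame(pair_id = ids, gene_a = paste0(ids, "_a"),
                        gene_b = paste0(ids, "_b"),
                        fate = vapply(doms, `[[`, "", "fate"),
                        grade = vapply(doms, `[[`, "", "grade"),
                        stringsAsFactors = FALSE)
    list(tpm = tpm, pairs = pairs, tissues = tissues)
  })
}
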