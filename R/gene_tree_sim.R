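#' Simulate gene-family trees under a declared WGD history
#'
#' Transcribes the true duplication/speciation history of a gene family into
#' a rooted newick topology, with leaves labeled `species|gene|chromosome`.
#' The backbone is the four post-2R reference clades `((A,B),(C,D))`, each
#' containing both reference species, plus one pre-WGD outgroup leaf. The
#' test lineage branches according to `timing`:
#' * `"post2R"`: inside one (uniformly chosen) post-2R clade — the position
#'   of a species sharing both rounds;
#' * `"post1R"`: sister to one (uniformly chosen) 1R pair clade — sharing
#'   only the first round;
#' * `"pre1R"`: sister to the whole reference ingroup — sharing neither.
#' With probability `nni_error` a tree undergoes one random
#' nearest-neighbour-interchange move, emulating gene-tree estimation error.
#'
#' @param n_families number of families (trees) to generate.
#' @param timing test-lineage divergence timing (see above).
#' @param ref_species two reference (backbone) species names.
#' @param test_species test species name.
#' @param outgroup_species outgroup species name.
#' @param chromosomes named character vector mapping the clade labels
#'   `A`, `B`, `C`, `D` to reference chromosome names.
#' @param test_chromosome chromosome name used on test leaves.
#' @param nni_error probability of one random NNI move per tree.
#' @param seed RNG seed.
#' @return named character vector of newick strings (one per family).
#' @export
simulate_gene_trees <- function(n_families,
                                timing = c("post2R", "post1R", "pre1R"),
                                ref_species = c("chicken", "gar"),
                                test_species = "hagfish",
                                outgroup_species = "amphioxus",
                                chromosomes = c(A = "cA", B = "cB",
                                                C = "cC", D = "cD"),
                                test_chromosome = "t1",
                                nni_error = 0, seed = NULL) {
  n_families <- check_count(n_families, "n_families")
  timing <- match.arg(timing)
  check_prob(nni_error, "nni_error")
  stopifnot(length(ref_species) == 2L,
            all(c("A", "B", "C", "D") %in% names(chromosomes)))

  leaf <- function(sp, fam, chr) sprintf("%s|%s|%s", sp, fam, chr)
  with_seed(seed, {
    fams <- sprintf("f%04d", seq_len(n_families))
    out <- vapply(fams, function(f) {
      clade <- function(x) sprintf("(%s,%s)",
        leaf(ref_species[1L], paste0(f, ".", tolower(x)), chromosomes[[x]]),
        leaf(ref_species[2L], paste0(f, ".", tolower(x)), chromosomes[[x]]))
      tl <- leaf(test_species, paste0(f, ".t"), test_chromosome)
      cl <- stats::setNames(lapply(c("A", "B", "C", "D"), clade),
                            c("A", "B", "C", "D"))
      if (timing == "post2R") {
        x <- sample(c("A", "B", "C", "D"), 1L)
        cl[[x]] <- sprintf("(%s,%s)", tl, cl[[x]])
        ing <- sprintf("((%s,%s),(%s,%s))", cl$A, cl$B, cl$C, cl$D)
      } else if (timing == "post1R") {
        pAB <- sprintf("(%s,%s)", cl$A, cl$B)
        pCD <- sprintf("(%s,%s)", cl$C, cl$D)
        if (sample(c(TRUE, FALSE), 1L)) pAB <- sprintf("(%s,%s)", tl, pAB)
        else pCD <- sprintf("(%s,%s)", tl, pCD)
        ing <- sprintf("(%s,%s)", pAB, pCD)
      } else {
        ing <- sprintf("(%s,((%s,%s),(%s,%s)))", tl, cl$A, cl$B, cl$C, cl$D)
      }
      nw <- sprintf("(%s,%s);", leaf(outgroup_species, paste0(f, ".o"), "c0"),
                    ing)
      if (nni_error > 0 && stats::runif(1L) < nni_error) {
        tr <- ape::read.tree(text = nw)
        tr <- phangorn::rNNI(tr, 1L)
        nw <- ape::write.tree(tr)
      }
      nw
    }, "")
    stats::setNames(out, fams)
  })
}
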