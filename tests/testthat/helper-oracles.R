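## Independent oracles used across the suite. These deliberately re-derive
## results by the most literal route available (set operations, explicit
## Lance-Williams recursion, exhaustive enumeration) so they share no code
## with the implementation they check.

## overlapping ratio by explicit set intersection over retained gene names
or_set_oracle <- function(ac_genes, fams_a, fams_b) {
  ra <- ac_genes[ac_genes %in% fams_a]
  rb <- ac_genes[ac_genes %in% fams_b]
  length(intersect(ra, rb)) / min(length(ra), length(rb))
}

## Ward ("ward.D") agglomeration by the Lance-Williams update on raw
## dissimilarities; returns merge heights in merge order
ward_lw_oracle <- function(D) {
  n <- nrow(D)
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  repeat {
    k <- length(active)
    if (k < 2) break
    best <- c(NA, NA); bd <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      d <- D[active[i], active[j]]
      if (d < bd) { bd <- d; best <- c(active[i], active[j]) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bd)
    others <- setdiff(active, c(i, j))
    for (m in others) {
      D[i, m] <- D[m, i] <-
        ((size[i] + size[m]) * D[i, m] + (size[j] + size[m]) * D[j, m] -
           size[m] * D[i, j]) / (size[i] + size[j] + size[m])
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  heights
}

## Benjamini-Hochberg by the textbook sort / cummin route
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q, 1)
}

## Exhaustive mirror-pair fraction for 2 pre-1R chromosomes and 2 sequential
## uniform fusions (all 6 x 3 equally likely outcomes enumerated)
fusion_null_enumeration_2x2 <- function() {
  units <- list(c("1a"), c("1b"), c("2a"), c("2b"))
  mirror_frac <- 0; total <- 0
  first <- utils::combn(4, 2)
  for (f1 in seq_len(ncol(first))) {
    i <- first[1, f1]; j <- first[2, f1]
    pool <- c(list(c(units[[i]], units[[j]])), units[-c(i, j)])
    second <- utils::combn(length(pool), 2)
    for (f2 in seq_len(ncol(second))) {
      total <- total + 1
      ev1 <- list(a = units[[i]], b = units[[j]])
      ev2 <- list(a = pool[[second[1, f2]]], b = pool[[second[2, f2]]])
      cross <- function(ev) {
        out <- list()
        for (x in ev$a) for (y in ev$b) {
          if (substr(x, 1, 1) != substr(y, 1, 1)) {
            p <- sort(c(x, y))
            out[[length(out) + 1]] <- p
          }
        }
        out
      }
      mirror <- FALSE
      for (p1 in cross(ev1)) for (p2 in cross(ev2)) {
        if (substr(p1[1], 1, 1) == substr(p2[1], 1, 1) &&
            substr(p1[2], 1, 1) == substr(p2[2], 1, 1) &&
            substr(p1[1], 2, 2) != substr(p2[1], 2, 2) &&
            substr(p1[2], 2, 2) != substr(p2[2], 2, 2)) mirror <- TRUE
      }
      if (mirror) mirror_frac <- mirror_frac + 1
    }
  }
  mirror_frac / total
}

## small synthetic pair set realizing a given 2x2 homologue table, for
## exercising pair_enrichment on arbitrary margins
make_pair_fixture <- function(n_ab, n_a, n_b, N) {
  stopifnot(n_ab <= min(n_a, n_b), n_a + n_b - n_ab <= N)
  n10 <- n_a - n_ab; n01 <- n_b - n_ab; n00 <- N - n_a - n_b + n_ab
  chr_a <- c(rep("A", n_ab + n10), rep("A2", n01 + n00))
  chr_b <- c(rep("B", n_ab), rep("B2", n10), rep("B", n01), rep("B2", n00))
  ga <- sprintf("x%03d", seq_len(N))
  gb <- sprintf("y%03d", seq_len(N))
  mk <- function(sp, ids, chrs) {
    genes <- data.frame(gene_id = ids, family_id = ids, chromosome = chrs,
                        index = 0L, stringsAsFactors = FALSE)
    chrom <- data.frame(chromosome = unique(chrs), copy_path = "",
                        stringsAsFactors = FALSE)
    chrom$acs <- as.list(unique(chrs))
    m <- paleokaryo:::new_genome_map(sp, genes, chrom)
    paleokaryo:::recompute_indices(m)
  }
  list(pairs = data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE),
       maps = list(mk("spA", ga, chr_a), mk("spB", gb, chr_b)))
}

## default backbone pairing used by the tree tests
test_pairing <- function() list(A = "cA", B = "cB", C = "cC", D = "cD")

classify_newick <- function(nw, test_species = "hagfish") {
  lt <- label_backbone(nw, test_pairing(), c("chicken", "gar"), "amphioxus")
  if (!lt$usable) return(NULL)
  classify_test_genes(lt, test_species)
}
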