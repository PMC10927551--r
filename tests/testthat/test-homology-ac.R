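mk_hits <- function(q, s, score, evalue = exp(-score / 2)) {
  data.frame(qseqid = q, sseqid = s, pident = 90, length = 100L,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
             sstart = 1L, send = 100L, evalue = evalue, bitscore = score,
             stringsAsFactors = FALSE)
}

test_that("reciprocal best hits require mutual bests under the e-value cap", {
  h <- mk_hits(c("a1", "b1"), c("b1", "a1"), c(100, 100))
  expect_equal(reciprocal_best_hits(h),
               data.frame(gene_a = "a1", gene_b = "b1",
                          stringsAsFactors = FALSE))
  ## reciprocity broken: b1's best is a2
  h2 <- rbind(mk_hits("a1", "b1", 100), mk_hits("b1", "a2", 120),
              mk_hits("b1", "a1", 100), mk_hits("a2", "b1", 120))
  expect_equal(nrow(reciprocal_best_hits(h2)), 1L)
  expect_equal(reciprocal_best_hits(h2)$gene_a, "a2")
  ## rows above the e-value threshold are invisible
  h3 <- mk_hits(c("a1", "b1"), c("b1", "a1"), c(100, 100), evalue = 1e-3)
  expect_equal(nrow(reciprocal_best_hits(h3, evalue_max = 1e-6)), 0L)
  expect_equal(nrow(reciprocal_best_hits(h3, evalue_max = 1e-2)), 1L)
})

test_that("RBH ties break deterministically and symmetrically", {
  ## a1 ties b1/b2 on bitscore; lower e-value wins, then lexicographic id
  h <- rbind(mk_hits("a1", "b2", 100, 1e-30), mk_hits("a1", "b1", 100, 1e-20),
             mk_hits("b2", "a1", 100, 1e-30), mk_hits("b1", "a1", 100, 1e-20))
  r <- reciprocal_best_hits(h)
  expect_equal(r$gene_b, "b2")
  ## symmetry: swapping query/subject roles wholesale yields the same pairs
  hs <- h; hs$qseqid <- h$sseqid; hs$sseqid <- h$qseqid
  expect_identical(reciprocal_best_hits(hs), r)
})

test_that("unidirectional best hits keep one subject per reference query", {
  h <- rbind(mk_hits("og1", "x1", 90), mk_hits("og1", "x2", 110),
             mk_hits("og2", "x1", 80))
  b <- best_hits_unidirectional(h)
  expect_equal(b$subject[b$query == "og1"], "x2")
  expect_equal(nrow(b), 2L)
})

test_that("pair enrichment reproduces the chi-squared oracle on a known table", {
  fx <- make_pair_fixture(n_ab = 20, n_a = 30, n_b = 50, N = 300)
  st <- pair_enrichment(fx$pairs, fx$maps)
  row <- st[st$chrom_a == "spA:A" & st$chrom_b == "spB:B", ]
  oracle <- chisq.test(matrix(c(20, 10, 30, 240), 2, byrow = TRUE),
                       correct = FALSE)
  expect_equal(row$chi2, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(row$p, oracle$p.value, tolerance = 1e-12)
  expect_true(row$enriched)
  expect_true(all(st$q >= st$p))
  expect_true(all(st$chi2 >= 0))
  expect_true(all(st$n_ab <= pmin(st$n_a, st$n_b)))
})

test_that("a pair at exactly its expected count is not enriched", {
  ## n_ab = n_a*n_b/N exactly: 10 = 20*100/200
  fx <- make_pair_fixture(n_ab = 10, n_a = 20, n_b = 100, N = 200)
  st <- pair_enrichment(fx$pairs, fx$maps)
  row <- st[st$chrom_a == "spA:A" & st$chrom_b == "spB:B", ]
  expect_false(row$enriched)
  expect_equal(row$n_ab, row$expected)
})

test_that("BH correction matches the brute-force oracle and m=1 is identity", {
  fx <- make_pair_fixture(n_ab = 15, n_a = 40, n_b = 30, N = 120)
  st <- pair_enrichment(fx$pairs, fx$maps)
  expect_equal(st$q, bh_oracle(st$p), tolerance = 1e-12)
  ## single tested pair: q == p
  fx1 <- make_pair_fixture(n_ab = 5, n_a = 5, n_b = 5, N = 5)
  st1 <- pair_enrichment(fx1$pairs, fx1$maps)
  expect_equal(nrow(st1), 1L)
  expect_equal(st1$q, st1$p)
  expect_error(pair_enrichment(data.frame(gene_a = "zz", gene_b = "yy"),
                               fx$maps), "absent")
})

test_that("chi-squared decisions agree with Fisher on small random tables", {
  set.seed(2024)
  agree <- 0L; total <- 0L
  for (i in 1:150) {
    N <- sample(10:50, 1)
    n_a <- sample(1:(N - 1), 1)
    n_b <- sample(1:(N - 1), 1)
    n_ab <- sample(max(0, n_a + n_b - N):min(n_a, n_b), 1)
    if (n_ab < 1) next
    fx <- make_pair_fixture(n_ab, n_a, n_b, N)
    st <- pair_enrichment(fx$pairs, fx$maps)
    row <- st[st$chrom_a == "spA:A" & st$chrom_b == "spB:B", ]
    m <- matrix(c(n_ab, n_a - n_ab, n_b - n_ab, N - n_a - n_b + n_ab), 2,
                byrow = TRUE)
    fis <- fisher.test(m)$p.value < 0.05
    total <- total + 1L
    if ((row$p < 0.05) == fis) agree <- agree + 1L
  }
  expect_gte(agree / total, 0.95)
})

test_that("the homology graph has one edge per enriched pair", {
  fx <- make_pair_fixture(n_ab = 20, n_a = 30, n_b = 50, N = 300)
  st <- pair_enrichment(fx$pairs, fx$maps)
  g <- homologous_chromosome_graph(st)
  expect_equal(igraph::ecount(g), sum(st$enriched))
  st0 <- st; st0$q <- 1
  expect_equal(igraph::ecount(homologous_chromosome_graph(st0)), 0L)
  expect_true(igraph::vcount(g) >= 4L)
})

test_that("grouping returns components, split by outgroup linkage", {
  ## two disjoint components -> 2 ACs
  el <- data.frame(chrom_a = c("s1:c1", "s1:c3"), chrom_b = c("s2:d1", "s2:d3"))
  st <- data.frame(species_a = "s1", species_b = "s2",
                   chrom_a = el$chrom_a, chrom_b = el$chrom_b,
                   n_ab = 10, n_a = 10, n_b = 10, N = 40, expected = 2.5,
                   chi2 = 30, method = "chisq", p = 1e-8, q = 1e-8,
                   enriched = TRUE)
  g <- homologous_chromosome_graph(st)
  acs <- group_ancestral_chromosomes(g)
  expect_equal(length(unique(acs$membership$ac)), 2L)

  ## one chained component mixing two linkage groups is split in two
  st2 <- rbind(st, within(st[1, ], { chrom_a <- "s1:c1"; chrom_b <- "s2:d3" })[
    , names(st)])
  g2 <- homologous_chromosome_graph(st2)
  linkage <- c("s1:c1" = "L1", "s2:d1" = "L1", "s1:c3" = "L2", "s2:d3" = "L2")
  acs2 <- group_ancestral_chromosomes(g2, outgroup_linkage = linkage)
  expect_equal(length(unique(acs2$membership$ac)), 2L)
  expect_length(acs2$splits, 1L)
  m <- acs2$membership
  expect_equal(m$ac[m$node == "s1:c1"], m$ac[m$node == "s2:d1"])
  expect_false(m$ac[m$node == "s1:c1"] == m$ac[m$node == "s2:d3"])
})

test_that("zero-attrition simulations recover the exact AC structure", {
  sc <- evolution_scenario(5, 40,
    events = list(list(type = "wgd", multiplicity = 2),
                  list(type = "speciate", names = c("sp1", "sp2"))),
    outgroup = list(name = "og"), seed = 31)
  sim <- run_scenario(sc)
  rec <- reconstruct_ac(sim$genomes, sim$outgroup, offtarget_rate = 0,
                        seed = 32)
  m <- rec$acs$membership
  expect_equal(length(unique(m$ac)), 5L)
  ## each recovered group holds exactly the 4 descendants of one true AC
  truth_ac <- sub("\\..*$", "", m$chromosome)
  expect_true(all(tapply(truth_ac, m$ac, function(x) length(unique(x))) == 1L))
  expect_equal(unname(table(m$ac)), rep(4L, 5L), ignore_attr = TRUE)
})

test_that("outgroup gene anchoring applies both rules and their conflicts", {
  ## hand-built ac_set: AC1 = {i:c1}, AC2 = {i:c2}; linkage L1 -> AC1
  acs <- structure(list(
    membership = data.frame(node = c("i:c1", "i:c2"), species = "i",
                            chromosome = c("c1", "c2"),
                            ac = c("AC01", "AC02"), stringsAsFactors = FALSE),
    linkage = c(AC01 = "L1", AC02 = "L2"), anchored = NULL, splits = list()),
    class = "ac_set")
  og_genes <- data.frame(
    gene_id = c("og1", "og2", "og3"), family_id = c("f1", "f2", "f3"),
    chromosome = c("L2", "L3", "L1"), index = 0:2, stringsAsFactors = FALSE)
  og_chrom <- data.frame(chromosome = c("L1", "L2", "L3"), copy_path = "",
                         stringsAsFactors = FALSE)
  og_chrom$acs <- as.list(og_chrom$chromosome)
  og <- paleokaryo:::new_genome_map("og", og_genes, og_chrom)
  ing_genes <- data.frame(
    gene_id = sprintf("i%02d", 1:10), family_id = sprintf("f%02d", 1:10),
    chromosome = c(rep("c1", 5), rep("c2", 5)), index = 0L,
    stringsAsFactors = FALSE)
  ing_chrom <- data.frame(chromosome = c("c1", "c2"), copy_path = "",
                          stringsAsFactors = FALSE)
  ing_chrom$acs <- list("AC01", "AC02")
  ing <- paleokaryo:::recompute_indices(
    paleokaryo:::new_genome_map("i", ing_genes, ing_chrom))

  hits <- rbind(
    mk_hits(rep("og1", 5), c("i06", "i07", "i08", "i09", "i10"), 100),  # 5 to AC2
    mk_hits(rep("og2", 4), c("i06", "i07", "i08", "i09"), 100),         # 4 to AC2
    ## og3: linkage ties it to AC1 (1 hit there) but 5 homologues sit on AC2
    mk_hits(rep("og3", 6), c("i01", "i06", "i07", "i08", "i09", "i10"), 100))
  res <- anchor_outgroup_genes(acs, og, list(ing), hits, min_multi = 5)
  an <- res$anchored
  expect_equal(an$ac[an$gene_id == "og1"], "AC02")       # rule 2 fires
  expect_false("og2" %in% an$gene_id)                    # 4 < min_multi, rule 1 unmet
  expect_false("og3" %in% an$gene_id)                    # rule conflict
  un <- attr(res, "unanchored")
  expect_equal(un$rule[un$gene_id == "og3"], "conflict")
  ## anchored lists are disjoint across ACs by construction
  expect_equal(anyDuplicated(an$gene_id), 0L)
})

test_that("reconstruction at realistic attrition recovers count and anchors truly", {
  sc <- evolution_scenario(6, 100,
    events = list(list(type = "wgd", multiplicity = 2),
                  list(type = "wgd", multiplicity = 2),
                  list(type = "speciate", names = c("sp1", "sp2"),
                       loss_rate = 0.3, transloc_rate = 0.02)),
    outgroup = list(name = "og", loss_rate = 0.2), seed = 55)
  sim <- run_scenario(sc)
  rec <- reconstruct_ac(sim$genomes, sim$outgroup, seed = 56)
  expect_equal(length(unique(rec$acs$membership$ac)), 6L)
  an <- rec$acs$anchored
  expect_gt(nrow(an), 200L)
  ## true AC of an outgroup gene is its family prefix; recovered groups map
  ## to true ACs through their member chromosomes
  m <- rec$acs$membership
  group_truth <- tapply(sub("\\..*$", "", m$chromosome), m$ac,
                        function(x) names(sort(-table(x)))[1])
  acc <- mean(group_truth[an$ac] == sub("_.*$", "", an$family_id))
  expect_gte(acc, 0.95)
})
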