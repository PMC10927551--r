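test_that("ancestral genome construction obeys its contract", {
  g <- make_ancestral_genome(1, 3)
  expect_equal(nrow(g$chrom), 1L)
  expect_equal(nrow(g$genes), 3L)
  expect_equal(length(unique(g$genes$family_id)), 3L)
  expect_identical(g$genes$family_id, g$genes$gene_id)

  g2 <- make_ancestral_genome(17, 300, seed = 42)
  expect_equal(nrow(g2$chrom), 17L)
  expect_equal(nrow(g2$genes), 17L * 300L)
  expect_silent(validate_genome_map(g2))

  expect_error(make_ancestral_genome(2, 0), "genes_per_chr")
  expect_error(make_ancestral_genome(0, 5), "n_chr")
})

test_that("WGD multiplies chromosome and family copy numbers", {
  g <- make_ancestral_genome(2, 10)
  for (m in c(2L, 3L)) {
    w <- apply_wgd(g, m)
    expect_equal(nrow(w$chrom), 2L * m)
    expect_true(all(family_sizes(w) == m))
    expect_silent(validate_genome_map(w))
    expect_equal(sort(unique(w$chrom$copy_path)), letters[seq_len(m)])
  }
  expect_error(apply_wgd(g, 4), "multiplicity")
  empty <- g; empty$genes <- g$genes[0, ]
  expect_error(apply_wgd(empty, 2), "empty")
})

test_that("allopolyploid mode applies an asymmetric extra loss", {
  g <- make_ancestral_genome(4, 200)
  w <- apply_wgd(g, 2, mode = "allo", seed = 7, allo_loss = 0.15)
  lens <- chrom_lengths(w)
  a <- sum(lens[grepl("\\.a$", names(lens))])
  b <- sum(lens[grepl("\\.b$", names(lens))])
  expect_equal(a, 800L)               # favoured subgenome untouched
  expect_lt(b, 800L)                  # the other lost ~15%
  expect_gt(b, 800L * 0.7)
})

test_that("fusion concatenates content and descent; fission reverses it", {
  g <- make_ancestral_genome(3, 10)
  g <- apply_fission(g, "AC02", 5)    # make lengths 10, 5+5, 10
  f <- apply_fusion(g, "AC01", "AC02.p")
  expect_equal(sum(chrom_lengths(f) == 15L), 1L)
  expect_equal(nrow(f$chrom), nrow(g$chrom) - 1L)
  ## gene content conserved as a multiset
  expect_setequal(f$genes$gene_id, g$genes$gene_id)
  fused <- f$chrom[grepl("\\+", f$chrom$chromosome), ]
  expect_setequal(fused$acs[[1]], c("AC01", "AC02"))
  ## fusion order: AC01 genes first
  cg <- chrom_genes(f, fused$chromosome)
  expect_true(all(grepl("^AC01", cg$gene_id[1:10])))
  expect_error(apply_fusion(g, "AC01", "AC01"), "itself")
  expect_error(apply_fusion(g, "AC01", "nope"), "unknown")
})

test_that("fission splits at the breakpoint preserving order", {
  g <- make_ancestral_genome(1, 100)
  s <- apply_fission(g, "AC01", 50)
  expect_equal(unname(chrom_lengths(s)), c(50L, 50L))
  s2 <- apply_fission(g, "AC01", 1)
  expect_equal(unname(chrom_lengths(s2)), c(1L, 99L))
  expect_identical(chrom_genes(s2, "AC01.q")$gene_id, g$genes$gene_id[-1])
  expect_error(apply_fission(g, "AC01", 0), "breakpoint")
  expect_error(apply_fission(g, "AC01", 100), "breakpoint")
})

test_that("attrition identity, degenerate and binomial-bound behaviour", {
  g <- make_ancestral_genome(5, 20)
  expect_identical(apply_attrition(g, 0, 0, 0, seed = 1)$genes, g$genes)
  dead <- apply_attrition(g, 1, 0, 0, seed = 1)
  expect_equal(nrow(dead$genes), 0L)
  expect_equal(nrow(dead$chrom), 5L)           # empty chromosomes retained
  expect_true(all(chrom_lengths(dead) == 0L))

  big <- make_ancestral_genome(10, 1000)       # 10,000 genes
  kept <- nrow(apply_attrition(big, 0.3, seed = 99)$genes)
  ## 99.9% binomial interval around Binomial(10000, 0.7)
  bounds <- qbinom(c(5e-4, 1 - 5e-4), 10000, 0.7)
  expect_gte(kept, bounds[1]); expect_lte(kept, bounds[2])

  expect_error(apply_attrition(g, 1.2), "loss_rate")
})

test_that("translocation and duplication conserve or extend family content", {
  g <- make_ancestral_genome(4, 100)
  tr <- apply_attrition(g, 0, 0.2, 0, seed = 3)
  expect_setequal(tr$genes$gene_id, g$genes$gene_id)   # moves, never deletes
  expect_silent(validate_genome_map(tr))
  du <- apply_attrition(g, 0, 0, 0.2, seed = 4)
  expect_gt(nrow(du$genes), nrow(g$genes))
  expect_true(all(du$genes$family_id %in% g$genes$family_id))
  expect_silent(validate_genome_map(du))
})

test_that("speciation produces independent descendants with known orthology", {
  g <- apply_wgd(make_ancestral_genome(2, 30), 2)
  sp <- speciate(g, c("sp1", "sp2"), seed = 5)
  expect_equal(sp$sp1$species, "sp1")
  ## zero attrition: same family layout, orthology = identical chromosomes
  expect_identical(sp$sp1$genes$family_id, sp$sp2$genes$family_id)
  ort <- true_ortholog_pairs(sp)
  expect_setequal(ort$chromosome, chrom_names(g))
  ## gene ids remain globally unique across descendants
  expect_equal(anyDuplicated(c(sp$sp1$genes$gene_id, sp$sp2$genes$gene_id)), 0L)
  lossy <- speciate(g, c("a", "b"), loss_rate = 0.3, seed = 6)
  expect_false(identical(chrom_lengths(lossy$a), chrom_lengths(lossy$b)))
  expect_error(speciate(g, "only_one"), "at least 2")
})

test_that("artificial midpoint split partitions a chromosome", {
  g <- make_ancestral_genome(1, 100)
  s <- artificial_split(g, "AC01")
  expect_equal(c(nrow(s$left), nrow(s$right)), c(50L, 50L))
  g7 <- make_ancestral_genome(1, 7)
  s7 <- artificial_split(g7, "AC01")
  expect_equal(c(nrow(s7$left), nrow(s7$right)), c(3L, 4L))
  expect_length(intersect(s7$left$gene_id, s7$right$gene_id), 0L)
  expect_setequal(c(s7$left$gene_id, s7$right$gene_id), g7$genes$gene_id)
  one <- make_ancestral_genome(1, 1)
  expect_error(artificial_split(one, "AC01"), "fewer than 2")
})

test_that("true ohnolog pairs follow the recorded copy paths", {
  g <- apply_wgd(make_ancestral_genome(2, 5), 2)
  oh <- true_ohnolog_pairs(g)
  expect_equal(nrow(oh), 2L)                   # one pair per AC
  expect_true(all(oh$ac %in% c("AC01", "AC02")))
})

test_that("hit tables are reciprocal, family-faithful and binomially spurious", {
  g <- make_ancestral_genome(1, 1)
  sp <- speciate(g, c("x", "y"), seed = 1)
  h <- emit_hit_table(sp, score_noise_sd = 0, seed = 2)
  expect_equal(nrow(h), 2L)                    # one pair, both directions
  expect_equal(h$bitscore[1], h$bitscore[2])
  expect_setequal(h$qseqid, h$sseqid)

  g2 <- make_ancestral_genome(2, 50)
  sp2 <- speciate(g2, c("x", "y"), seed = 3)
  clean <- emit_hit_table(sp2, offtarget_rate = 0, seed = 4)
  fam <- function(ids, maps) {
    all_genes <- rbind(maps$x$genes, maps$y$genes)
    all_genes$family_id[match(ids, all_genes$gene_id)]
  }
  expect_identical(fam(clean$qseqid, sp2), fam(clean$sseqid, sp2))

  noisy <- emit_hit_table(sp2, offtarget_rate = 0.05, seed = 5)
  n_true <- nrow(clean)
  n_spur <- nrow(noisy) - n_true
  bounds <- qbinom(c(5e-4, 1 - 5e-4), n_true / 2, 0.05)
  expect_gte(n_spur, bounds[1]); expect_lte(n_spur, bounds[2])
  ## e-value is a monotone map of score
  expect_identical(order(noisy$evalue), order(-noisy$bitscore))
  expect_error(emit_hit_table(sp2, score_noise_sd = -1), "sd")
  expect_error(emit_hit_table(sp2["x"]), "2 genomes")
})

test_that("identical scenario and seed reproduce byte-identical results", {
  sc <- evolution_scenario(3, 40,
    events = list(list(type = "wgd", multiplicity = 3),
                  list(type = "fusion", n = 1),
                  list(type = "speciate", names = c("s1", "s2"),
                       loss_rate = 0.2, ssd_rate = 0.02)),
    outgroup = list(name = "og", loss_rate = 0.1), seed = 77)
  a <- run_scenario(sc)
  b <- run_scenario(sc)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$outgroup, b$outgroup)
  expect_identical(a$truth, b$truth)
  c <- run_scenario(evolution_scenario(3, 40, events = sc$events,
                                       outgroup = sc$outgroup, seed = 78))
  expect_false(identical(a$genomes, c$genomes))
})

test_that("post-1R fusion null matches exhaustive enumeration", {
  expect_equal(simulate_post1R_fusion_null(5, 0, reps = 10), 0)
  frac <- simulate_post1R_fusion_null(2, 2, reps = 4000, seed = 13)
  exact <- fusion_null_enumeration_2x2()
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(frac - exact), 3 * se)
  for (nf in c(2, 3)) {
    f <- simulate_post1R_fusion_null(4, nf, reps = 200, seed = nf)
    expect_gte(f, 0); expect_lte(f, 1)
  }
  expect_error(simulate_post1R_fusion_null(3, 4, reps = 10), "exceed")
  expect_error(simulate_post1R_fusion_null(3, 2, reps = 0), "reps")
})

test_that("scenario YAML round-trips through read_scenario", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "n_ancestral_chromosomes: 4",
    "genes_per_chromosome: 25",
    "loss_rate: 0.2",
    "seed: 5",
    "events:",
    "  - type: wgd",
    "    multiplicity: 3",
    "  - type: speciate",
    "    names: [ham, spam]"), path)
  sc <- read_scenario(path)
  expect_s3_class(sc, "evolution_scenario")
  sim <- run_scenario(sc)
  expect_named(sim$genomes, c("ham", "spam"))
  expect_equal(nrow(sim$genomes$ham$chrom), 12L)
  writeLines("bogus_key: 1", path)
  expect_error(read_scenario(path), "unknown scenario keys")
})
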