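prof <- function(v, ac = "AC1", chr = NA_character_) {
  ## build a retention_profile with a prescribed binary vector
  fams <- sprintf("f%02d", seq_along(v))
  retention_profile(fams, fams[v == 1], ac_id = ac, chromosome = chr)
}

test_that("retention profiles are binary content lookups", {
  fams <- c("g1", "g2", "g3", "g4")
  p <- retention_profile(fams, c("g1", "g3"))
  expect_equal(p$vector, c(1L, 0L, 1L, 0L))
  expect_equal(p$n_retained, 2L)
  expect_equal(retention_profile(fams, character())$vector, rep(0L, 4))
  ## multiplicity ignored: two homologues of g1 still give 1
  expect_equal(retention_profile(fams, c("g1", "g1"))$vector[1], 1L)
  ## invariant to query gene order
  expect_identical(retention_profile(fams, c("g3", "g1"))$vector, p$vector)
  expect_error(retention_profile(character(), "g1"), "empty")
})

test_that("overlapping ratio matches its definition and edge cases", {
  expect_equal(overlapping_ratio(prof(c(1, 1, 0)), prof(c(1, 1, 0))), 1)
  expect_equal(overlapping_ratio(prof(c(1, 1, 0)), prof(c(0, 0, 1))), 0)
  a <- prof(c(1, 1, 1, 0, 0)); b <- prof(c(1, 0, 1, 1, 1))
  expect_equal(overlapping_ratio(a, b), 2 / 3)
  expect_equal(overlapping_ratio(a, b), overlapping_ratio(b, a))
  expect_error(overlapping_ratio(a, prof(c(1, 0, 0), ac = "AC2")), "different ACs")
  expect_error(overlapping_ratio(a, prof(c(0, 0, 0, 0, 0))), "zero")
})

test_that("OR matches the set-intersection oracle and is size-insensitive", {
  set.seed(11)
  fams <- sprintf("f%03d", 1:80)
  for (i in 1:50) {
    fa <- sample(fams, sample(5:60, 1))
    fb <- sample(fams, sample(5:60, 1))
    a <- retention_profile(fams, fa); b <- retention_profile(fams, fb)
    expect_equal(overlapping_ratio(a, b), or_set_oracle(fams, fa, fb))
  }
  ## inflating the larger chromosome with non-AC genes changes nothing
  fa <- sample(fams, 30); fb <- sample(fams, 50)
  base <- overlapping_ratio(retention_profile(fams, fa),
                            retention_profile(fams, fb))
  inflated <- overlapping_ratio(retention_profile(fams, fa),
                                retention_profile(fams, c(fb, sprintf("junk%d", 1:500))))
  expect_equal(inflated, base)
})

test_that("OR matrices filter, symmetrize and flag degenerate input", {
  fams <- sprintf("f%02d", 1:40)
  set.seed(3)
  mk <- function(n, chr) retention_profile(fams, sample(fams, n),
                                           chromosome = chr)
  ps <- list(mk(25, "c1"), mk(30, "c2"), mk(19, "c3"))
  m <- or_matrix(ps, min_retained = 20)
  expect_equal(dim(m$values), c(2L, 2L))          # the 19-retained one is out
  expect_equal(m$excluded$label, "c3")
  expect_identical(m$values, t(m$values))
  expect_equal(unname(diag(m$values)), c(1, 1))
  expect_equal(m$values["c1", "c2"],
               overlapping_ratio(ps[[1]], ps[[2]]))
  single <- or_matrix(ps[1], min_retained = 20)
  expect_true(single$empty)
  expect_error(or_matrix(list(prof(c(1, 1)), prof(c(1, 1), ac = "AC2"))),
               "several ACs")
})

test_that("ohnolog calling uses a strict threshold and both set views", {
  v <- matrix(c(1, .10, .15, .10, 1, .3, .15, .3, 1), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  m <- structure(list(ac_id = "AC1", labels = c("x", "y", "z"),
                      n_retained = c(x = 30, y = 30, z = 30), values = v,
                      excluded = data.frame(), empty = FALSE),
                 class = "or_matrix")
  cl <- call_ohnologues(m, or_min = 0.15)
  ## 0.10 and exactly-0.15 draw no edge; only y-z at 0.3 does
  expect_equal(nrow(cl$edges), 1L)
  expect_setequal(unlist(cl$edges[1, 1:2]), c("y", "z"))

  v2 <- matrix(0.3, 3, 3, dimnames = dimnames(v)); diag(v2) <- 1
  m2 <- m; m2$values <- v2
  cl2 <- call_ohnologues(m2)
  expect_equal(lengths(cl2$components), 3L)
  expect_equal(lengths(cl2$cliques)[1], 3L)       # component and clique agree
  expect_length(cl2$discrepancies, 0L)
})

test_that("per-AC multiplicity counts the largest mutually-ohnologous set", {
  ## simulated 1R + triplication with 20% loss: truth is 6 copies per AC
  anc <- make_ancestral_genome(3, 300)
  fams <- lapply(split(anc$genes$family_id, anc$genes$chromosome), unname)
  g <- apply_attrition(apply_wgd(apply_wgd(anc, 2), 3), loss_rate = 0.2,
                       seed = 17)
  ors <- or_analysis(list(g), fams)
  expect_true(all(ors$multiplicity == 6L))
  ## a lone qualifying descendant counts 1
  m1 <- or_matrix(list(prof(rep(1, 25), chr = "a"),
                       prof(c(rep(1, 21), rep(0, 4)), chr = "b")),
                  min_retained = 20)
  v <- m1$values; v["a", "b"] <- v["b", "a"] <- 0.05
  m1$values <- v
  expect_equal(unname(multiplicity_per_ac(list(A = call_ohnologues(m1)))), 1L)
})

test_that("Ward clustering reproduces the Lance-Williams oracle exactly", {
  set.seed(21)
  for (i in 1:5) {
    s <- matrix(runif(36, 0, 1), 6)
    s <- (s + t(s)) / 2; diag(s) <- 1
    dimnames(s) <- list(letters[1:6], letters[1:6])
    hc <- ward_cluster(s)
    expect_equal(sort(hc$height), sort(ward_lw_oracle(1 - s)),
                 tolerance = 1e-12)
  }
  ## two items merge at their distance; tight pairs merge first
  two <- matrix(c(1, .4, .4, 1), 2, dimnames = list(c("p", "q"), c("p", "q")))
  expect_equal(ward_cluster(two)$height, 0.6)
  ## two tight pairs (within-pair 1-OR = 0.1, between 0.9) merge first
  nm <- c("a1", "a2", "b1", "b2")
  sim <- matrix(0.1, 4, 4, dimnames = list(nm, nm))
  sim[c("a1", "a2"), c("a1", "a2")] <- 0.9
  sim[c("b1", "b2"), c("b1", "b2")] <- 0.9
  diag(sim) <- 1
  hc4 <- ward_cluster(sim)
  expect_equal(sort(hc4$height)[1:2], c(0.1, 0.1))
  first <- sort(nm[abs(hc4$merge[1, ])])
  expect_true(identical(first, c("a1", "a2")) ||
                identical(first, c("b1", "b2")))
  expect_equal(sort(hc4$height), sort(ward_lw_oracle(1 - sim)))
  expect_error(ward_cluster(matrix(1, 1, 1)), "at least 2")
})

test_that("orthologous chromosomes form 2-leaf clades when divergence precedes the split", {
  anc <- make_ancestral_genome(2, 120)
  fams <- lapply(split(anc$genes$family_id, anc$genes$chromosome), unname)
  g <- apply_attrition(apply_wgd(anc, 2), loss_rate = 0.3, seed = 23)
  sp <- speciate(g, c("sp1", "sp2"), seed = 24)  # zero post-split attrition
  ors <- or_analysis(sp, fams)
  for (ac in names(fams)) {
    hc <- ward_cluster(ors$matrices[[ac]])
    singles <- hc$merge[hc$merge[, 1] < 0 & hc$merge[, 2] < 0, , drop = FALSE]
    sisters <- apply(singles, 1, function(r) sort(hc$labels[-r]))
    for (ch in paste0(ac, c(".a", ".b"))) {
      want <- sort(paste(c("sp1", "sp2"), ch, sep = ":"))
      expect_true(any(apply(sisters, 2, identical, want)))
    }
  }
})

test_that("ortholog assignment distinguishes 1:1, ambiguous and unassigned", {
  cr <- matrix(c(0.84, 0.10, 0.08, 0.80), 2, byrow = TRUE,
               dimnames = list(c("h1", "h2"), c("l1", "l2")))
  res <- assign_orthologs(cr)
  expect_equal(res$class[res$chromosome == "h1"], "1:1")
  expect_equal(res$partners[res$chromosome == "h1"], "l1")
  ## two near-tied partners above threshold -> ambiguous 1:2
  cr2 <- matrix(c(0.60, 0.58, 0.05, 0.10, 0.12, 0.62), 2, byrow = TRUE,
                dimnames = list(c("h1", "h2"), c("l1", "l2", "l3")))
  res2 <- assign_orthologs(cr2)
  expect_equal(res2$class[res2$chromosome == "h1"], "1:2")
  expect_equal(res2$partners[res2$chromosome == "h1"], "l1,l2")
  ## everything below threshold is unassigned
  res3 <- assign_orthologs(matrix(0.05, 2, 2,
    dimnames = list(c("a", "b"), c("c", "d"))))
  expect_true(all(res3$class == "unassigned"))
})

test_that("retention asymmetry ratios and the rank-sum null behave", {
  pr <- data.frame(n_a = c(25, 50), n_b = c(25, 114))
  ra <- retention_asymmetry(pr)
  expect_equal(ra$pairs$ratio, c(1, 2.28))
  same <- data.frame(n_a = rep(c(30, 40, 55), 2), n_b = rep(c(60, 44, 60), 2),
                     group = rep(c("g1", "g2"), each = 3))
  rs <- retention_asymmetry(same)
  expect_gt(rs$test$p.value, 0.9)
  zero <- data.frame(n_a = c(10, 0), n_b = c(10, 5))
  rz <- retention_asymmetry(zero)
  expect_equal(nrow(rz$excluded), 1L)
})

test_that("fusion detection counts contributing ACs above the fragment floor", {
  comp <- data.frame(species = "s", chromosome = c("c1", "c2", "c2", "c3", "c3"),
                     ac = c("AC1", "AC1", "AC2", "AC1", "AC2"),
                     n_genes = c(100, 40, 35, 50, 5))
  f <- detect_fusions(comp, min_frag = 10)
  pc <- f$per_chromosome
  expect_equal(pc$fusions[pc$chromosome == "c1"], 0L)
  expect_equal(pc$fusions[pc$chromosome == "c2"], 1L)
  expect_equal(pc$fusions[pc$chromosome == "c3"], 0L)  # AC2 fragment below floor
  expect_equal(unname(f$per_genome["s"]), 1L)
  ## truth round-trip: fuse 3 AC descendants with zero attrition -> 2 fusions
  g <- make_ancestral_genome(4, 60)
  g <- apply_fusion(apply_fusion(g, "AC01", "AC02"), "AC01+AC02", "AC03")
  fams <- lapply(split(make_ancestral_genome(4, 60)$genes$family_id,
                       make_ancestral_genome(4, 60)$genes$chromosome), unname)
  cc <- ac_composition(g, fams)
  f2 <- detect_fusions(cc)
  expect_equal(unname(f2$per_genome["ancestor"]), 2L)
})

test_that("expected OR between ohnologues degrades with loss rate", {
  anc <- make_ancestral_genome(1, 100)
  w <- apply_wgd(anc, 2)
  fams <- unname(split(anc$genes$family_id, anc$genes$chromosome)$AC01)
  mean_or <- sapply(c(0.1, 0.3, 0.5), function(loss) {
    ors <- vapply(1:200, function(r) {
      a <- apply_attrition(w, loss_rate = loss, seed = 1000 * loss + r)
      fb <- split(a$genes$family_id, a$genes$chromosome)
      pa <- retention_profile(fams, fb[["AC01.a"]])
      pb <- retention_profile(fams, fb[["AC01.b"]])
      if (min(pa$n_retained, pb$n_retained) == 0) return(NA_real_)
      overlapping_ratio(pa, pb)
    }, 0)
    mean(ors, na.rm = TRUE)
  })
  expect_true(all(diff(mean_or) < 0))
})

test_that("interspecific orthologous OR exceeds intraspecific ohnologous OR", {
  ## rediploidization-era divergence before the split, milder loss after
  for (rep in 1:5) {
    anc <- make_ancestral_genome(4, 150)
    fams <- lapply(split(anc$genes$family_id, anc$genes$chromosome), unname)
    g <- apply_attrition(apply_wgd(anc, 2), loss_rate = 0.25,
                         seed = 100 + rep)
    sp <- speciate(g, c("sp1", "sp2"), loss_rate = 0.15, seed = 200 + rep)
    fb1 <- split(sp$sp1$genes$family_id, sp$sp1$genes$chromosome)
    fb2 <- split(sp$sp2$genes$family_id, sp$sp2$genes$chromosome)
    orth <- ohn <- numeric()
    for (ac in names(fams)) for (cp in c(".a", ".b")) {
      p1 <- retention_profile(fams[[ac]], fb1[[paste0(ac, cp)]], ac)
      p2 <- retention_profile(fams[[ac]], fb2[[paste0(ac, cp)]], ac)
      orth <- c(orth, overlapping_ratio(p1, p2))
    }
    for (ac in names(fams)) for (fb in list(fb1, fb2)) {
      pa <- retention_profile(fams[[ac]], fb[[paste0(ac, ".a")]], ac)
      pb <- retention_profile(fams[[ac]], fb[[paste0(ac, ".b")]], ac)
      ohn <- c(ohn, overlapping_ratio(pa, pb))
    }
    expect_gt(median(orth), median(ohn))
  }
})

test_that("artificial-split OR never exceeds ohnologous OR in one simulation", {
  for (rep in 1:5) {
    anc <- make_ancestral_genome(5, 200)
    fams <- lapply(split(anc$genes$family_id, anc$genes$chromosome), unname)
    g <- apply_attrition(apply_wgd(anc, 2), loss_rate = 0.2,
                         transloc_rate = 0.02, ssd_rate = 0.05,
                         seed = 300 + rep)
    fb <- split(g$genes$family_id, g$genes$chromosome)
    split_or <- ohn_or <- numeric()
    for (ac in names(fams)) {
      for (cp in c(".a", ".b")) {
        s <- artificial_split(g, paste0(ac, cp))
        pa <- retention_profile(fams[[ac]], s$left$family_id, ac)
        pb <- retention_profile(fams[[ac]], s$right$family_id, ac)
        split_or <- c(split_or, overlapping_ratio(pa, pb))
      }
      pa <- retention_profile(fams[[ac]], fb[[paste0(ac, ".a")]], ac)
      pb <- retention_profile(fams[[ac]], fb[[paste0(ac, ".b")]], ac)
      ohn_or <- c(ohn_or, overlapping_ratio(pa, pb))
    }
    expect_lt(max(split_or), min(ohn_or))
  }
})
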