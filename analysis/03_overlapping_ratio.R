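#!/usr/bin/env Rscript

## The overlapping-ratio analyses: ohnolog calling against the fission
## control, per-AC multiplicity under 1R+CR, cross-species ortholog
## assignment, Ward clustering of retention profiles, and retention
## asymmetry between an auto- and an allopolyploid duplication.

suppressMessages(library(paleokaryo))
dir.create("results", showWarnings = FALSE)
thr <- analysis_thresholds()

## --- cyclostome-style history: 1R then triplication ----------------------
anc <- make_ancestral_genome(17, 300)
fams <- lapply(split(anc$genes$family_id, anc$genes$chromosome), unname)
g <- apply_attrition(apply_wgd(anc, 2), loss_rate = 0.15, seed = 1)
g <- apply_wgd(g, 3)
## rediploidization-era loss after the triplication, before the species
## split, so the six copies diverge and orthologs become resolvable
g <- apply_attrition(g, loss_rate = 0.15, seed = 11)
sp <- speciate(g, c("hagfish", "lamprey"), loss_rate = 0.2,
               transloc_rate = 0.01, ssd_rate = 0.02, seed = 2)
ors <- or_analysis(sp, fams, thr)

mult <- data.frame(ac = rownames(ors$multiplicity), ors$multiplicity,
                   check.names = FALSE)
data.table::fwrite(mult, "results/multiplicity_per_ac.tsv", sep = "\t")
cat(sprintf("per-AC multiplicity (truth 6): hagfish %d-%d, lamprey %d-%d\n",
            min(mult$hagfish), max(mult$hagfish),
            min(mult$lamprey), max(mult$lamprey)))

ohn_or <- unlist(lapply(ors$calls, function(x)
  lapply(x, function(cl) cl$edges$or)))
cat(sprintf("ohnologous OR: median %.2f (IQR %.2f-%.2f, n = %d)\n",
            median(ohn_or), quantile(ohn_or, .25), quantile(ohn_or, .75),
            length(ohn_or)))

## --- fission control: artificial midpoint splits -------------------------
split_or <- unlist(lapply(names(fams), function(ac) {
  sapply(grep(paste0("^", ac), chrom_names(sp$hagfish), value = TRUE),
         function(ch) {
    s <- artificial_split(sp$hagfish, ch)
    pa <- retention_profile(fams[[ac]], s$left$family_id, ac)
    pb <- retention_profile(fams[[ac]], s$right$family_id, ac)
    if (min(pa$n_retained, pb$n_retained) < thr$min_retained) return(NA_real_)
    overlapping_ratio(pa, pb)
  })
}))
split_or <- split_or[!is.na(split_or)]
cat(sprintf("fission-control OR: max %.3f over %d split pairs (ceiling 0.15)\n",
            max(split_or), length(split_or)))

## --- cross-species orthologs and clustering ------------------------------
classes <- table(unlist(lapply(ors$orthologs, function(o) o$class)))
orth <- do.call(rbind, lapply(names(ors$orthologs), function(ac)
  cbind(ac = ac, ors$orthologs[[ac]])))
data.table::fwrite(orth, "results/ortholog_assignment.tsv", sep = "\t")
cat("ortholog classes: ",
    paste(sprintf("%s = %d", names(classes), classes), collapse = ", "), "\n")
orth11 <- orth$best_or[orth$class == "1:1"]
cat(sprintf("1:1 orthologous OR: median %.2f (n = %d)\n",
            median(orth11), length(orth11)))

nwk <- vapply(names(ors$matrices), function(ac) {
  m <- ors$matrices[[ac]]
  if (m$empty || length(m$labels) < 2) return(NA_character_)
  dendrogram_newick(ward_cluster(m))
}, "")
writeLines(nwk[!is.na(nwk)], "results/retention_dendrograms.nwk")

## --- retention asymmetry: autopolyploid 1R vs allopolyploid 2R ------------
asym_pairs <- do.call(rbind, lapply(c(auto = "auto", allo = "allo"),
  function(mode) {
  a2 <- apply_wgd(make_ancestral_genome(17, 300), 2, mode = mode, seed = 5)
  a2 <- apply_attrition(a2, loss_rate = 0.3, seed = 6)
  fb <- split(a2$genes$family_id, a2$genes$chromosome)
  do.call(rbind, lapply(names(fams), function(ac)
    data.frame(group = mode,
               n_a = sum(fams[[ac]] %in% fb[[paste0(ac, ".a")]]),
               n_b = sum(fams[[ac]] %in% fb[[paste0(ac, ".b")]]))))
}))
asym <- retention_asymmetry(asym_pairs)
data.table::fwrite(asym$pairs, "results/retention_asymmetry.tsv", sep = "\t")
cat(sprintf(
  "retention asymmetry ratio: auto median %.2f vs allo %.2f (rank-sum p = %.2g)\n",
  asym$medians[["auto"]], asym$medians[["allo"]], asym$test$p.value))
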