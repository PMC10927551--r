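#!/usr/bin/env Rscript

## Simulate the two karyotype histories the study compares:
##   gnathostome-style: 1R -> 8 interim fusions -> 2R -> two species
##   cyclostome-style:  1R -> triplication (CR)  -> two species
## and write the gene maps plus the ground-truth descent tables.

suppressMessages(library(paleokaryo))
dir.create("results", showWarnings = FALSE)

gnatho <- evolution_scenario(17, 300,
  events = list(list(type = "wgd", multiplicity = 2),
                list(type = "fusion", n = 8),
                list(type = "wgd", multiplicity = 2),
                list(type = "speciate", names = c("chicken", "gar"),
                     loss_rate = 0.3)),
  outgroup = list(name = "seacucumber", loss_rate = 0.2,
                  transloc_rate = 0.01),
  seed = 20240101)
sim_g <- run_scenario(gnatho)

cyclo <- evolution_scenario(17, 300,
  events = list(list(type = "wgd", multiplicity = 2),
                list(type = "attrition", loss_rate = 0.15),
                list(type = "wgd", multiplicity = 3),
                list(type = "speciate", names = c("hagfish", "lamprey"),
                     loss_rate = 0.2, transloc_rate = 0.01,
                     ssd_rate = 0.02)),
  outgroup = list(name = "amphioxus", loss_rate = 0.2),
  seed = 20240102)
sim_c <- run_scenario(cyclo)

for (sim in list(sim_g, sim_c)) {
  for (g in c(sim$genomes, list(sim$outgroup)))
    write_gene_map(g, file.path("results",
                                sprintf("genes_%s.tsv", g$species)))
}
data.table::fwrite(rbind(cbind(history = "gnathostome", sim_g$truth),
                         cbind(history = "cyclostome", sim_c$truth)),
                   "results/truth_chromosomes.tsv", sep = "\t")

cat(sprintf(
  "gnathostome history: %d chromosomes/genome, %d genes in chicken\n",
  nrow(sim_g$genomes$chicken$chrom), nrow(sim_g$genomes$chicken$genes)))
cat(sprintf(
  "cyclostome history:  %d chromosomes/genome, %d genes in hagfish\n",
  nrow(sim_c$genomes$hagfish$chrom), nrow(sim_c$genomes$hagfish$genes)))
cat("wrote gene maps and truth tables under results/\n")
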