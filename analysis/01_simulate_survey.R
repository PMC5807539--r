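#!/usr/bin/env Rscript

## Stage 1 -- generate the synthetic barcode survey every later stage runs on.
##
## The generator emulates the statistical structure of an mtCO1 survey of
## the Bemisia tabaci cryptic species complex: a labelled reference panel
## of known putative species, query barcodes within the intra-species
## divergence band of their species, and "novel" species that have members
## but no reference, sitting beyond the inter-species band from every
## reference. Sequences are 867 nt (the survey fragment length); within-
## species divergence is capped at 2% and between-species divergence floors
## at 6%, comfortably either side of the 3.5% delimitation threshold.

library(whiteflydelim)

out_dir <- "results/synthetic_survey"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20130801L   # survey collection era; fixed for reproducibility

plan <- data.frame(
  species     = c("SSA1", "SSA2", "MED", "MEAM1", "IO", "NOVEL_A", "NOVEL_B"),
  n_members   = c(8, 4, 6, 3, 3, 5, 3),
  max_within  = 0.02,
  min_between = 0.06,
  novel       = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
)

sim <- make_panel_and_queries(plan, seq_length = 867, seed = seed)

write_fasta(sim$panel[, c("id", "description", "residues", "length")],
            file.path(out_dir, "panel.fasta"))
readr::write_tsv(sim$panel[, c("id", "species", "clade", "is_tabaci")],
                 file.path(out_dir, "panel_metadata.tsv"))
write_fasta(sim$queries, file.path(out_dir, "queries.fasta"))
readr::write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
writeLines(sprintf("seed\t%d", seed), file.path(out_dir, "SEED.tsv"))

message(sprintf(
  "simulated survey: %d references (%d species), %d queries (%d planted novel), seed %d, %d generation attempt(s)",
  nrow(sim$panel), length(unique(sim$panel$species)), nrow(sim$queries),
  sum(sim$truth$novel), seed, sim$attempts))
message("wrote panel.fasta / panel_metadata.tsv / queries.fasta / truth.tsv to ",
        out_dir)
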