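#!/usr/bin/env Rscript
# Stage 1: simulate the size-fractionation experiment behind the marker
# library. A synthetic proteome is digested in silico (tryptic + PK
# semi-tryptic peptides) and measured across 4 ultrafiltration fractions x
# 4 replicates of LiP and tryptic-control samples, with two-fold
# accessibility changes planted in 60 known protein regions.

suppressMessages(library(flipms))
dir.create("results", showWarnings = FALSE)
seed <- 42

proteome <- make_proteome(100, c(200, 400), seed = seed)
write_proteome_fasta(proteome, "results/proteome_synthetic.fasta")

peptides <- digest_in_silico(proteome, pk_sites_per_protein = 3,
                             seed = seed + 1)
write.table(peptides, "results/peptides.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

parents <- peptides[peptides$tryptic_type == "fully_tryptic", ]
set.seed(seed + 2)
chosen <- parents[sample(nrow(parents), 60), ]
planted <- data.frame(protein_id = chosen$protein_id, start = chosen$start,
                      end = chosen$end, log2fc = 1, fraction = "100K",
                      stringsAsFactors = FALSE)
write.table(planted, "results/planted_markers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- flip_truth(planted_markers = planted, n_replicates = 4,
                    cv_peptide = 0.1, cv_protein = 0.1, seed = seed + 3)
sim <- simulate_flip_experiment(truth, proteome, peptides)
write_intensity_table(sim$lip, "results/lip_intensities.tsv")
write_intensity_table(sim$tryptic_control, "results/tc_intensities.tsv")
write.table(sim$peptide_truth, "results/peptide_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("proteome: %d proteins, %d peptides (%d fully tryptic)\n",
            nrow(proteome), nrow(peptides), nrow(parents)))
cat(sprintf("planted %d marker regions (log2FC = 1, 100K fraction)\n",
            nrow(planted)))
cat(sprintf("LiP records: %d; tryptic-control records: %d\n",
            nrow(sim$lip), nrow(sim$tryptic_control)))
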