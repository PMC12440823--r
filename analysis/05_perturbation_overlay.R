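#!/usr/bin/env Rscript
# Stage 5: overlay the marker library onto a perturbation experiment.
# A control-vs-stress LiP-MS experiment is simulated on the same proteome;
# accessibility changes are planted in a subset of the library's marker
# regions plus some library-free regions (structural changes that are not
# interaction markers). Significant peptides overlapping a marker by at
# least half their length become marker hits.

suppressMessages(library(flipms))
seed <- 42

proteome <- read_proteome_fasta("results/proteome_synthetic.fasta")
peptides <- read.delim("results/peptides.tsv", stringsAsFactors = FALSE)
library_tab <- read.delim("results/flip_library.tsv",
                          stringsAsFactors = FALSE)

set.seed(seed + 10)
in_lib <- library_tab[sample(nrow(library_tab), 25), ]
parents <- peptides[peptides$tryptic_type == "fully_tryptic", ]
lib_key <- paste(library_tab$protein_id, library_tab$start, library_tab$end)
free <- parents[!paste(parents$protein_id, parents$start,
                       parents$end) %in% lib_key, ]
off_lib <- free[sample(nrow(free), 15), ]
planted <- rbind(
  data.frame(protein_id = in_lib$protein_id, start = in_lib$start,
             end = in_lib$end, log2fc = 1, fraction = "HU",
             stringsAsFactors = FALSE),
  data.frame(protein_id = off_lib$protein_id, start = off_lib$start,
             end = off_lib$end, log2fc = 1, fraction = "HU",
             stringsAsFactors = FALSE))

truth <- flip_truth(planted_markers = planted,
                    fractions = c("ctrl", "HU"), n_replicates = 4,
                    seed = seed + 11)
sim <- simulate_flip_experiment(truth, proteome, peptides)
filt <- detection_filter(rbind(sim$lip, sim$tryptic_control))
norm <- median_normalize(filt, scope = "global")
lip <- norm[norm$sample_type == "lip", ]
tc <- norm[norm$sample_type == "tryptic_control", ]
anova <- propagated_anova(correct_by_protein(lip, tc), lip, tc,
                          variant = "textbook")

hits <- call_marker_hits(anova, peptides, library_tab,
                         min_overlap = 0.5, q_threshold = 0.05)
write.table(hits, "results/marker_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# protein-level abundance calls from the tryptic control
prot_anova <- propagated_anova(
  data.frame(peptide_id = tc$analyte_id, protein_id = tc$analyte_id,
             group = tc$group, replicate = tc$replicate,
             ratio = tc$intensity, stringsAsFactors = FALSE),
  tc, transform(tc, intensity = 1), variant = "textbook")
changed <- protein_abundance_changes(prot_anova, lfc_threshold = 0.5,
                                     q_threshold = 0.05)

n_sig <- sum(anova$q < 0.05, na.rm = TRUE)
cat(sprintf("perturbation: %d significant peptides, %d marker hits on %d proteins\n",
            n_sig, nrow(hits), length(unique(hits$protein_id))))
cat(sprintf("%d high-confidence hits; %d proteins change abundance\n",
            sum(hits$confidence == "high"), length(changed)))
writeLines(unique(hits$protein_id), "results/hit_proteins.txt")
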