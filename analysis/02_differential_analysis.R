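#!/usr/bin/env Rscript
# Stage 2: peptide-level differential analysis between fractions. Applies
# the triplicate-in-two-groups detection filter, fraction-wise median
# normalization, protein-abundance correction (with library-mode ratio
# renormalization), the error-propagated one-way ANOVA (calibrated textbook
# variant; the as-printed variant is written alongside for comparison),
# pairwise Tukey tests, and grouping into unique fully-tryptic regions.

suppressMessages(library(flipms))

lip <- read_intensity_table("results/lip_intensities.tsv")
tc <- read_intensity_table("results/tc_intensities.tsv")
peptides <- read.delim("results/peptides.tsv", stringsAsFactors = FALSE)

filt <- detection_filter(rbind(lip, tc), min_reps = 3, min_groups = 2)
cat(sprintf("detection filter: %d of %d analytes retained\n",
            attr(filt, "filter_counts")["retained"],
            attr(filt, "filter_counts")["analytes"]))

norm <- median_normalize(filt, scope = "per_group")
lip_n <- norm[norm$sample_type == "lip", ]
tc_n <- norm[norm$sample_type == "tryptic_control", ]
ratios <- correct_by_protein(lip_n, tc_n, renormalize_ratios = TRUE)

anova <- propagated_anova(ratios, lip_n, tc_n, variant = "textbook")
anova_printed <- propagated_anova(ratios, lip_n, tc_n,
                                  variant = "as_printed")
anova$f_as_printed <- anova_printed$f[match(anova$peptide_id,
                                            anova_printed$peptide_id)]
write.table(anova, "results/anova_peptides.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

tukey <- pairwise_tukey(ratios, lip_n, tc_n, variant = "textbook",
                        anova = anova)
write.table(tukey, "results/tukey_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

regions <- group_to_parent(anova, peptides)
write.table(regions, "results/regions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- read.delim("results/peptide_truth.tsv", stringsAsFactors = FALSE)
m <- merge(anova, truth, by = "peptide_id")
cat(sprintf("tested %d peptides; %d significant (q < 0.05)\n",
            sum(!is.na(anova$p)), sum(anova$q < 0.05, na.rm = TRUE)))
cat(sprintf("planted-marker recall %.3f, precision %.3f\n",
            mean(m$q[m$is_marker] < 0.05, na.rm = TRUE),
            sum(m$is_marker & m$q < 0.05, na.rm = TRUE) /
              sum(m$q < 0.05, na.rm = TRUE)))
cat(sprintf("%d unique regions from %d grouped peptides\n",
            nrow(regions), sum(regions$n_peptides)))
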