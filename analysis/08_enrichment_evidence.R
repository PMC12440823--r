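#!/usr/bin/env Rscript
# Stage 8: evidence analyses on the marker library. Domain-term enrichment
# of library peptides against all detected peptides (one-sided Fisher, BH),
# disorder overlap of significant vs non-significant peptides, and overlap
# of markers with (synthetic) interaction-disrupting mutation sites against
# a length-weighted resampling null.

suppressMessages(library(flipms))
seed <- 42

peptides <- read.delim("results/peptides.tsv", stringsAsFactors = FALSE)
anova <- read.delim("results/anova_peptides.tsv", stringsAsFactors = FALSE)
library_tab <- read.delim("results/flip_library.tsv",
                          stringsAsFactors = FALSE)
planted <- read.delim("results/planted_markers.tsv",
                      stringsAsFactors = FALSE)
proteome <- read_proteome_fasta("results/proteome_synthetic.fasta")

# domain enrichment: the stage-3 domain table covers half the planted
# regions, so the library should be enriched for it
set.seed(45)
dom_idx <- sample(nrow(planted), nrow(planted) %/% 2)
domains <- data.frame(protein_id = planted$protein_id[dom_idx],
                      start = pmax(1, planted$start[dom_idx] - 5),
                      end = planted$end[dom_idx] + 5,
                      go_term = "protein binding", stringsAsFactors = FALSE)
lib_peps <- peptides[peptides$peptide_id %in%
                       unlist(strsplit(library_tab$peptide_ids, ";")), ]
dom_terms <- transform(domains, term = go_term)
enr <- domain_fisher(lib_peps, peptides, dom_terms)
write.table(enr, "results/domain_enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("domain enrichment: '%s' OR %.1f, p = %.2e (q = %.2e)\n",
            enr$term[1], enr$odds_ratio[1], enr$p[1], enr$q[1]))

# disorder: annotate disorder away from planted regions, so significant
# peptides should be depleted, not enriched
set.seed(46)
dis <- data.frame(protein_id = proteome$protein_id,
                  start = 1, end = 30, stringsAsFactors = FALSE)
peps_sig <- merge(peptides, anova[, c("peptide_id", "q")], by = "peptide_id")
peps_sig$significant <- !is.na(peps_sig$q) & peps_sig$q < 0.05
dd <- disorder_analysis(peps_sig, dis)
cat(sprintf("disordered: %.1f%% of significant vs %.1f%% of others (p = %.2f)\n",
            dd$pct_disordered["significant"],
            dd$pct_disordered["nonsignificant"], dd$p))

# mutation overlap: sites placed preferentially inside marker regions
set.seed(47)
n_sites <- 40
inside <- planted[sample(nrow(planted), 30, replace = TRUE), ]
sites <- rbind(
  data.frame(protein_id = inside$protein_id,
             position = inside$start +
               sapply(inside$end - inside$start, function(w) sample(0:w, 1))),
  data.frame(protein_id = sample(proteome$protein_id, n_sites - 30, TRUE),
             position = sample(50, n_sites - 30, TRUE)))
obs <- mutation_overlap(library_tab, sites, window_aa = 0)
nul <- mutation_null(library_tab,
                     data.frame(protein_id = proteome$protein_id,
                                length = nchar(proteome$sequence)),
                     n_sites = n_sites, n_draws = 10, observed = obs)
obs10 <- mutation_overlap(library_tab, sites, window_aa = 10)
cat(sprintf("mutation overlap: %.1f%% observed (%.1f%% with 10-aa window) vs %.1f%% null mean; empirical p = %.2f, normal-approx p = %.2e\n",
            100 * obs, 100 * obs10, 100 * nul$mean_null, nul$p_empirical,
            nul$p_normal))
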