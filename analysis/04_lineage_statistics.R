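#!/usr/bin/env Rscript
# Lineage-resolved p21 inheritance and sibling statistics.
#
# Anchors every lineage to its first mitosis and computes, for the
# glucose-depletion cohort: the Pearson correlation between the mother's 5-h
# pre-mitosis p21 window mean and her quiescent daughters' 5-h post-mitosis
# window means (G1 group); sibling fate concordance per stage group; the
# pooled sibling discrepancy D and its complement 1 - D for G1-group
# concordant pairs; and the percentage of proliferating daughters versus
# the mother's time to mitosis in 1.3-h bins. A dedicated G1-only cohort
# supplies enough mother-daughter pairs for stable correlations.

suppressMessages({
  library(cyclefate)
  library(data.table)
})

coh <- read_cohort("results/cohorts/glucose_depletion")
fates <- cohort_fates(coh)
lp <- lineage_params()

## mother time-to-mitosis vs daughter proliferation -----------------------------
mo <- coh$truth[generation == 0L & !is.na(division_h)]
fate_of <- setNames(fates$binary, fates$cell_id)
kid_map <- split(coh$lineage$cell_id, coh$lineage$parent_id)
dp <- lapply(mo$cell_id, function(id) {
  f <- fate_of[kid_map[[id]]]
  f <- f[f %in% c("quiescent", "proliferative")]
  f == "proliferative"
})
pv <- proliferation_vs_time(mo$division_h, dp, lp$bin_width)
fwrite(pv$table, "results/proliferation_vs_time.csv")
cat(sprintf("daughter proliferation vs mother time-to-mitosis: r = %.3f (p = %.2g) over %d bins\n",
            pv$r, pv$p_value, nrow(pv$table[n_mothers >= 2])))

## sibling concordance ----------------------------------------------------------
ld <- lineage_p21_data(coh, fates, lp)
conc <- concordance_table(ld$pairs$fate1, ld$pairs$fate2, ld$pairs$group)
fwrite(conc, "results/sibling_concordance.csv")
cat("\nsibling fate concordance by mother stage:\n")
print(conc)

## inheritance statistics on a G1-group lineage cohort --------------------------
g1coh <- simulate_cohort(sim_config("glucose_depletion", n_mothers = 600,
                                    seed = 20260923,
                                    stage_probs = c(G1 = 1, S = 0)))
g1fates <- cohort_fates(g1coh)
g1ld <- lineage_p21_data(g1coh, g1fates, lp)
p <- g1ld$pairs

md <- rbind(p[fate1 == "quiescent", .(pre = mother_pre, post = post1)],
            p[fate2 == "quiescent", .(pre = mother_pre, post = post2)])
md <- md[is.finite(pre) & is.finite(post)]
cor_md <- mother_daughter_correlation(md$pre, md$post)
cat(sprintf("\nmother G2/M vs daughter G0/G1 p21 window means (G1 group): r = %.3f, p = %.2g, n = %d\n",
            cor_md$r, cor_md$p_value, cor_md$n))

cp <- p[concordant == TRUE & fate1 == "quiescent"]
sers <- g1ld$window_series
pl <- lapply(seq_len(nrow(cp)), function(i)
  list(x = sers[[cp$sib1[i]]], y = sers[[cp$sib2[i]]]))
keep <- vapply(pl, function(q) !is.null(q$x) && !is.null(q$y) &&
                 length(q$x) >= 2 && length(q$x) == length(q$y), logical(1))
sib <- sibling_group_discrepancy(pl[keep])
cat(sprintf("G1 concordant sibling pairs: pooled D = %.3f, 1 - D = %.3f over %d pairs\n",
            sib$D_pooled, sib$R2_pooled, sib$n_pairs))
fwrite(data.table(statistic = c("mother_daughter_r", "mother_daughter_p",
                                "mother_daughter_n", "sibling_D_pooled",
                                "sibling_one_minus_D", "sibling_n_pairs",
                                "prolif_vs_time_r"),
                  value = c(cor_md$r, cor_md$p_value, cor_md$n,
                            sib$D_pooled, sib$R2_pooled, sib$n_pairs,
                            pv$r)),
       "results/lineage_statistics.csv")
fwrite(sib$per_pair, "results/sibling_pair_discrepancy.csv")
cat("wrote results/lineage_statistics.csv\n")
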