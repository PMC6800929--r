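#!/usr/bin/env Rscript
# Step 1: simulate the study-sized phantom cohort.
#
# Writes 50 benign + 50 malignant phantom volumes (lossless archive format)
# with vessel ground-truth masks and a manifest to results/cohort/.  The
# benign class emulates radiologically stable solid nodules (broad,
# flat-topped HU histograms); the malignant class emulates histologically
# confirmed cancers (peaked histograms concentrated around 0-100 HU, heavier
# upper tails).

library(noduletex)

master_seed <- 20191007L
out <- file.path("results", "cohort")

manifest <- simulate_cohort(n_benign = 50, n_malignant = 50,
                            master_seed = master_seed, out_dir = out)
m <- read.csv(file.path(out, "manifest.csv"))

cat(sprintf("simulated %d phantoms into %s (master seed %d)\n",
            nrow(m), out, master_seed))
cat(sprintf("radius range %.1f-%.1f mm; %d with vessel ground truth\n",
            min(m$radius_mm), max(m$radius_mm),
            sum(file.exists(paste0(m$exclusion, ".json")))))
print(aggregate(cbind(skw_target, kur_target) ~ label, m, mean))
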