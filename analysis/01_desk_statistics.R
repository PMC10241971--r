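#!/usr/bin/env Rscript
# Desk-scale reproduction of the study's interval estimates: everything here
# is computed from the published 2x2 counts and planning assumptions alone,
# with no record linkage.  Writes results/desk_statistics.json.

suppressPackageStartupMessages(library(teledermacc))
dir.create("results", showWarnings = FALSE)

cm <- confusion_matrix(tp = 19, fp = 351, fn = 2, tn = 4376)
acc <- accuracy_measures(cm)
mgmt <- management_accuracy(c(rep("CORRECT", 21), "INCORRECT"))
yield <- test_yield(n_total = 5389, n_invalid = 172,
                    n_invalid_inconclusive = 91, n_analyzed = 4748)
bud <- buderer_sample_size(se = 0.83, sp = 0.92, prevalence = 0.0185,
                           width = 0.10, z = 1.96)

cat("Management accuracy:"); print(mgmt, digits = 1)
print(acc)
cat(sprintf("Test yield: %.1f%%\n", 100 * yield))
cat(sprintf("Buderer minimum sample size: %d (driven by %s; n_se %d, n_sp %d)\n",
            bud$n_required, bud$driver, bud$n_se, bud$n_sp))

as_pct <- function(p, d = 2) list(estimate = round(100 * p$estimate, d),
                                  conf.low = round(100 * p$conf.low, d),
                                  conf.high = round(100 * p$conf.high, d),
                                  x = p$x, n = p$n)
jsonlite::write_json(list(
  management_accuracy = as_pct(mgmt, 1),
  sensitivity = as_pct(acc$sensitivity),
  specificity = as_pct(acc$specificity),
  ppv = as_pct(acc$ppv), npv = as_pct(acc$npv),
  prevalence = as_pct(acc$prevalence),
  test_yield_pct = round(100 * yield, 1),
  buderer = bud), "results/desk_statistics.json",
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/desk_statistics.json\n")
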