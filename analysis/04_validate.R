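#!/usr/bin/env Rscript

# Step 4: internal (hold-out) validation.
#
# Predicts the share of respondents choosing each alternative of the two
# fixed hold-out tasks from the posterior-weighted individual utilities
# (simulated with product-type Gumbel error of scale 1, the error the
# choice model itself assumes), compares with the shares actually chosen
# in the held-out responses, and reports per-task and overall MAE.

suppressPackageStartupMessages(library(dcemix))
seed <- 1L

attrs <- read_attributes("results/attributes.json")
dataset <- read_choices("results/choices.csv", attrs)
parts <- split_holdout(dataset)
fit <- read_solution("results/solution_2class.json")

W <- individual_partworths(fit)
des <- dataset$design
hold <- des[des$is_holdout, ]
hold <- hold[hold$version == min(hold$version), ]

pred <- predict_holdout_shares(
  W, hold, attrs,
  rfc_config(attribute_error_scale = 0, product_error_scale = 1,
             iterations = 200000L, seed = seed))
obs <- observed_choice_shares(parts$holdout)
mae <- mean_absolute_error(pred, obs)

tab <- merge(pred[pred$group == "total",
                  c("position", "alternative", "share", "se")],
             obs, by = c("position", "alternative"),
             suffixes = c("_pred", "_obs"))
utils::write.csv(tab, "results/holdout_shares.csv", row.names = FALSE)
utils::write.csv(mae$per_task, "results/holdout_mae.csv", row.names = FALSE)
print(round(tab, 1))
cat(sprintf("hold-out MAE per task: %s; overall %.2f%%\n",
            paste(round(mae$per_task$mae, 2), collapse = ", "),
            mae$overall))
cat("wrote results/holdout_shares.csv, holdout_mae.csv\n")
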