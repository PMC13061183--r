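#' @importFrom data.table data.table as.data.table fread fwrite setkeyv
#'   setcolorder setorderv setnames rbindlist copy :=
#' @importFrom stats lm glm binomial coef confint quantile rnorm rbinom runif
#'   rnbinom sd median var aggregate chisq.test t.test aov shapiro.test
#'   kruskal.test wilcox.test model.matrix as.formula pt qt setNames terms
#'   plogis AIC qnorm vcov pnorm complete.cases
#' @importFrom utils head
NULL

.datatable.aware <- TRUE

# silence R CMD check notes for data.table NSE symbols
utils::globalVariables(c(
  ".", ".N", ".SD", "first", "second", "rank", "severity", "frequency",
  "concept", "systemic", "matched", "raw_name", "prescription_id",
  "patient_id", "age", "sex", "specialty", "drug_count", "age_group",
  "n_interactions", "profile", "polypharmacy", "retained", "pct",
  "ddi_count", "any_contra", "total_count", "drug_name", "pair_id", "node"
))
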