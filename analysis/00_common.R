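# Shared settings for the analysis scripts. Source()d by each step.
library(lifespanomics)

SEED <- 1L
RESULTS <- "results/analysis"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

res_path <- function(...) file.path(RESULTS, ...)

load_stage <- function(file) {
  path <- res_path(file)
  if (!file.exists(path))
    stop("missing ", path, " - run the earlier analysis scripts first")
  path
}
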