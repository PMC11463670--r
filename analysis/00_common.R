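# Shared plumbing for the numbered analysis scripts: each script advances the
# workflow by one stage, checkpointing the in-memory state under results/.
suppressMessages({library(Matrix); library(multiomePGC)})

RESULTS <- "results"
STATE <- file.path(RESULTS, "state.rds")
SEED <- 1L

load_state <- function() if (file.exists(STATE)) readRDS(STATE) else NULL

advance <- function(stage) {
  res <- run_pipeline(RESULTS, seed = SEED, stages = stage, state = load_state())
  saveRDS(res, STATE)
  res
}
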