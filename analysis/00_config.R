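# Shared settings for the numbered analysis scripts. Run the scripts in
# order from the repository root:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_qc_score.R
#   ...
# Intermediate tables are handed between scripts under results/analysis/.

library(cognet)

ana <- list(
  dir = "results/analysis",
  seed = 2024L,
  n_t1 = 2709L,    # wave-1 sample size of the motivating design
  n_t2 = 760L,     # respondents also observed six months later
  gamma = 0.5,
  path_size = 100,
  boot_B = 1000,
  cs_B = 250,
  n_perm = 1000,
  folds = 10,
  cutoffs = c(PHQ = 10, GAD = 10)   # conventional screening cutoffs
)
dir.create(ana$dir, showWarnings = FALSE, recursive = TRUE)

ana_path <- function(...) file.path(ana$dir, ...)
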