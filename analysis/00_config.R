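# Shared configuration for the numbered analysis scripts. Each script is run
# from the repository root, e.g.:  Rscript analysis/01_simulate.R
library(smtz)

config <- pipeline_config(seed = 1L)
data_dir <- "results/study"
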