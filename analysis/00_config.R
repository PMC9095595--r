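# Shared settings for the numbered analysis scripts. Each script can be run
# on its own (later stages read the files earlier stages wrote) or in order:
#   for f in analysis/0*.R; do Rscript "$f"; done
# All randomness flows from SEED; outputs land under results/analysis/.

suppressMessages(library(elevphylo))

SEED <- as.integer(Sys.getenv("ELEVPHYLO_SEED", "42"))
N_TREES <- 25    # phylogenetic-uncertainty sample (study used 1000)
N_NULL <- 199    # independent-swap null matrices (study used 1000)
N_ITER <- 1000   # successful swaps per null matrix
N_PERM <- 49     # GDM permutations per tree (study used 1000)

OUT <- "results/analysis"
DATA <- file.path(OUT, "data")
dir.create(DATA, showWarnings = FALSE, recursive = TRUE)

wcsv <- function(df, name) {
  path <- file.path(OUT, name)
  utils::write.csv(df, path, row.names = FALSE)
  message("  wrote ", path)
}
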