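# Loader for the archived field dataset (community matrix, 1000 simulated
# species-level trees, MCC tree). The archive is not redistributable with the
# package; place its extracted files under data-raw/zenodo/ at the repository
# root to enable the real-data reproduction tests.
archive_dir <- function() {
  testthat::test_path("..", "..", "data-raw", "zenodo")
}

load_archive <- function() {
  dir <- archive_dir()
  if (!dir.exists(dir)) {
    stop("archived dataset not found under data-raw/zenodo/ ",
         "(community matrix CSV + 1000-tree newick + MCC newick required)",
         call. = FALSE)
  }
  csvs <- list.files(dir, pattern = "\\.csv$", full.names = TRUE,
                     recursive = TRUE)
  nwks <- list.files(dir, pattern = "\\.(nwk|tre|trees|newick|txt)$",
                     full.names = TRUE, recursive = TRUE)
  find_comm <- function() {
    for (f in csvs) {
      df <- try(utils::read.csv(f, check.names = FALSE, row.names = 1),
                silent = TRUE)
      if (inherits(df, "try-error")) next
      m <- suppressWarnings(as.matrix(df))
      if (is.numeric(m) && all(m %in% c(0, 1)) && min(dim(m)) >= 2) {
        # orient as sites x species (few sites, many species)
        if (nrow(m) > ncol(m)) m <- t(m)
        return(m)
      }
    }
    stop("no binary community matrix CSV found in the archive", call. = FALSE)
  }
  multi <- NULL; mcc <- NULL
  for (f in nwks) {
    tr <- try(ape::read.tree(f), silent = TRUE)
    if (inherits(tr, "try-error") || is.null(tr)) next
    if (inherits(tr, "multiPhylo") && length(tr) >= 100) multi <- tr
    if (inherits(tr, "phylo")) mcc <- tr
  }
  if (is.null(multi)) stop("no multi-tree newick found in the archive",
                           call. = FALSE)
  list(community = find_comm(), trees = multi, mcc = mcc)
}
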