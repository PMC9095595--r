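#' Construct a community incidence matrix
#'
#' Sites x species presence/absence matrix ordered by elevation (low to high).
#' All-zero species columns are dropped with a warning; entries must be 0/1;
#' elevations must be strictly increasing after ordering.
#'
#' @param incidence Numeric/integer matrix, sites in rows, species in columns,
#'   with row and column names.
#' @param elevation Numeric vector of site elevations (m), one per row.
#' @return A `community_matrix`: list with `incidence`, `sites`, `species`,
#'   `elevation`.
#' @export
community_matrix <- function(incidence, elevation) {
  incidence <- as.matrix(incidence)
  stop_if(is.null(rownames(incidence)) || is.null(colnames(incidence)),
          "incidence matrix needs site rownames and species colnames")
  stop_if(!is_binary(incidence), "incidence entries must be 0 or 1")
  stop_if(length(elevation) != nrow(incidence),
          "one elevation per site is required")
  ord <- order(elevation)
  incidence <- incidence[ord, , drop = FALSE]
  elevation <- elevation[ord]
  stop_if(any(diff(elevation) <= 0),
          "site elevations must be strictly increasing (duplicated elevation?)")
  empty <- colSums(incidence) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " species with no occurrences: ",
            paste(colnames(incidence)[empty], collapse = ", "))
    incidence <- incidence[, !empty, drop = FALSE]
  }
  storage.mode(incidence) <- "integer"
  structure(list(incidence = incidence,
                 sites = rownames(incidence),
                 species = colnames(incidence),
                 elevation = as.numeric(elevation)),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d sites x %d species (elevation %g-%g m)\n",
              length(x$sites), length(x$species),
              min(x$elevation), max(x$elevation)))
  invisible(x)
}

#' Read / write a community matrix CSV
#'
#' Format: first column `site`, optional column `elevation`, then one 0/1
#' column per species.
#'
#' @param path CSV path.
#' @param elevation Elevations to use if the CSV has no `elevation` column.
#' @return A `community_matrix`.
#' @export
read_community_matrix <- function(path, elevation = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if(!"site" %in% names(df), "community CSV must have a 'site' column")
  if ("elevation" %in% names(df)) {
    elevation <- df$elevation
    df$elevation <- NULL
  }
  stop_if(is.null(elevation), "no elevation column and none supplied")
  m <- as.matrix(df[setdiff(names(df), "site")])
  rownames(m) <- df$site
  community_matrix(m, elevation)
}

#' @rdname read_community_matrix
#' @param comm A `community_matrix`.
#' @export
write_community_matrix <- function(comm, path) {
  df <- data.frame(site = comm$sites, elevation = comm$elevation,
                   comm$incidence, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
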