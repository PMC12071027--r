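# Plain-text serialization: results tables as CSV, bag sets as one matrix
# CSV per bag plus a manifest.

#' Read / write a factorial results table
#'
#' Comma-separated, dot decimal, header row
#' `Wd,Ly,Dp,Nt,Nb,replicate,F1,AUC,T`.
#'
#' @param table results `data.frame`.
#' @param file CSV path.
#' @return `writeResultsTable` returns `file` invisibly;
#'   `readResultsTable` the table.
#' @export
writeResultsTable <- function(table, file) {
  utils::write.csv(table, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(file) {
  utils::read.csv(file, check.names = FALSE)
}

#' Serialize a bag set to a directory
#'
#' One `<bag_id>.csv` feature matrix per bag plus `manifest.csv` with
#' columns `bag_id, label, n_patches`.
#'
#' @param bagset a [FeatureBagSet-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBagSet <- function(bagset, dir) {
  stopifnot(is(bagset, "FeatureBagSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(bagset@bags)) {
    utils::write.table(bagset@bags[[i]],
                       file.path(dir, paste0(bagset@bagIds[i], ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  manifest <- data.frame(bag_id = bagset@bagIds,
                         label = as.character(bagset@labels),
                         n_patches = vapply(bagset@bags, nrow, integer(1)))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeBagSet
#' @return `readBagSet` returns the reconstructed [FeatureBagSet-class].
#' @export
readBagSet <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  bagList <- lapply(manifest$bag_id, function(id) {
    as.matrix(utils::read.table(file.path(dir, paste0(id, ".csv")), sep = ","))
  })
  bagList <- lapply(bagList, unname)
  FeatureBagSet(bagList, manifest$label, manifest$bag_id)
}
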