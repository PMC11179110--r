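#' Read and write score tables
#'
#' Score tables are CSVs with a header row, a `subject` id column, a `group`
#' column coded 0 = control / 1 = patient, and numeric test/covariate columns.
#'
#' @param path CSV file path.
#' @return `read_score_table` returns a `data.frame`.
#' @export
read_score_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("subject", "group") %in% names(tab)))
    stop("score table must have 'subject' and 'group' columns")
  if (!all(tab$group %in% c(0L, 1L)))
    stop("group must be coded 0 (control) / 1 (patient)")
  tab
}

#' @rdname read_score_table
#' @param table Score table `data.frame`.
#' @export
write_score_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read and write parcellation maps
#'
#' Parcellations are tab-separated files with two columns,
#' `node_index<TAB>module_label`, node indices 0-based.
#'
#' @param path TSV file path.
#' @return `read_parcellation` returns a character vector of module labels
#'   ordered by node.
#' @export
read_parcellation <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("node_index", "module_label"),
                           stringsAsFactors = FALSE)
  n <- nrow(tab)
  if (!setequal(tab$node_index, 0:(n - 1)))
    stop("parcellation must assign every node index 0..N-1 exactly once")
  tab$module_label[order(tab$node_index)]
}

#' @rdname read_parcellation
#' @param modules Character vector of module labels, one per node.
#' @export
write_parcellation <- function(modules, path) {
  utils::write.table(
    data.frame(node_index = seq_along(modules) - 1L, module_label = modules),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write connectome sets
#'
#' A connectome set is a directory of dense whitespace-delimited N x N matrix
#' text files plus a manifest CSV with columns `subject`, `group`, `path`
#' (relative to the manifest's directory).
#'
#' @param manifest Path to the manifest CSV.
#' @return `read_connectome_set` returns a `connectome_cohort`-style list with
#'   `z`, `subject`, `group`.
#' @export
read_connectome_set <- function(manifest) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("subject", "group", "path") %in% names(man)))
    stop("manifest must have columns subject, group, path")
  base <- dirname(manifest)
  zs <- lapply(man$path, function(p) {
    as.matrix(utils::read.table(file.path(base, p), header = FALSE))
  })
  zs <- lapply(zs, function(m) {
    dimnames(m) <- NULL
    m
  })
  structure(list(z = zs, subject = man$subject, group = as.integer(man$group)),
            class = "connectome_cohort")
}

#' @rdname read_connectome_set
#' @param cohort A `connectome_cohort` (e.g. from [simulate_connectomes()]).
#' @param dir Output directory (created if needed).
#' @export
write_connectome_set <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("%s.txt", cohort$subject)
  for (i in seq_along(cohort$z)) {
    utils::write.table(format(cohort$z[[i]], digits = 10, trim = TRUE),
                       file.path(dir, paths[i]),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  man <- data.frame(subject = cohort$subject, group = cohort$group,
                    path = paths)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
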