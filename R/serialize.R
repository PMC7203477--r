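# On-disk form for evaluation artifacts (dictionaries and test pair sets),
# using the same feather + CSV + JSON idiom as the epoch container, so a
# fold's exact evaluation inputs can be archived and re-scored later.

write_signal_array <- function(arr, path) {
  d <- dim(arr)
  mat <- matrix(aperm(arr, c(2L, 1L, 3L)), d[1] * d[2], d[3])
  tab <- as_tibble(mat, .name_repair = ~ sprintf("t%04d", seq_len(d[3])))
  arrow::write_feather(tab, path)
  d
}

read_signal_array <- function(path, d) {
  mat <- as.matrix(arrow::read_feather(path))
  aperm(array(mat, dim = c(d[2], d[1], d[3])), c(2L, 1L, 3L))
}

pack_sources <- function(sources) {
  vapply(sources, paste, character(1), collapse = ";")
}

unpack_sources <- function(x) strsplit(x, ";", fixed = TRUE)

#' Save / load a dictionary
#'
#' Writes the entry signals (feather), the per-entry provenance table
#' (CSV; source sets packed as `;`-separated keys) and the dictionary
#' attributes (JSON) into a directory; the round trip is lossless.
#'
#' @param dict A [build_dictionary()] result.
#' @param path Directory to create/overwrite.
#' @return `path` invisibly; `load_dictionary()` returns the
#'   `ptc_dictionary`.
#' @export
save_dictionary <- function(dict, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- write_signal_array(dict$entries, file.path(path, "entries.feather"))
  meta <- dict$meta
  meta$sources <- pack_sources(meta$sources)
  readr::write_csv(meta, file.path(path, "entries.csv"))
  jsonlite::write_json(
    list(format = "ptcnet-dictionary-1", dims = d,
         n_per_class = dict$n_per_class, entry_kind = dict$entry_kind,
         k = dict$k, labels = dict$labels),
    file.path(path, "attrs.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  at <- jsonlite::read_json(file.path(path, "attrs.json"),
                            simplifyVector = TRUE)
  if (!identical(at$format, "ptcnet-dictionary-1")) {
    stop_format("not a dictionary container")
  }
  meta <- readr::read_csv(file.path(path, "entries.csv"),
                          show_col_types = FALSE, progress = FALSE)
  meta$sources <- unpack_sources(meta$sources)
  structure(list(entries = read_signal_array(file.path(path, "entries.feather"),
                                             at$dims),
                 meta = as_tibble(meta),
                 n_per_class = as.integer(at$n_per_class),
                 entry_kind = at$entry_kind, k = as.integer(at$k),
                 labels = at$labels),
            class = "ptc_dictionary")
}

#' Save / load an evaluation pair set
#'
#' Persists the compact form of a [build_test_pairs()] result — query and
#' entry signal arrays, both provenance tables, and the labeled pair index —
#' so a held-out subject's exact evaluation set can be re-scored against any
#' comparator later.
#'
#' @param ps A `ptc_pair_set`.
#' @param path Directory to create/overwrite.
#' @return `path` invisibly; `load_pair_set()` returns the `ptc_pair_set`.
#' @export
save_pair_set <- function(ps, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dq <- write_signal_array(ps$queries, file.path(path, "queries.feather"))
  de <- write_signal_array(ps$entries, file.path(path, "entries.feather"))
  qm <- ps$query_meta
  qm$sources <- pack_sources(qm$sources)
  readr::write_csv(qm, file.path(path, "queries.csv"))
  em <- ps$entry_meta
  em$sources <- pack_sources(em$sources)
  readr::write_csv(em, file.path(path, "entries.csv"))
  readr::write_csv(ps$index, file.path(path, "index.csv"))
  jsonlite::write_json(
    list(format = "ptcnet-pairset-1", scheme = ps$scheme,
         query_dims = dq, entry_dims = de),
    file.path(path, "attrs.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname save_pair_set
#' @export
load_pair_set <- function(path) {
  at <- jsonlite::read_json(file.path(path, "attrs.json"),
                            simplifyVector = TRUE)
  if (!identical(at$format, "ptcnet-pairset-1")) {
    stop_format("not a pair-set container")
  }
  qm <- readr::read_csv(file.path(path, "queries.csv"),
                        show_col_types = FALSE, progress = FALSE)
  qm$sources <- unpack_sources(qm$sources)
  em <- readr::read_csv(file.path(path, "entries.csv"),
                        show_col_types = FALSE, progress = FALSE)
  em$sources <- unpack_sources(em$sources)
  structure(list(queries = read_signal_array(file.path(path, "queries.feather"),
                                             at$query_dims),
                 query_meta = as_tibble(qm),
                 entries = read_signal_array(file.path(path, "entries.feather"),
                                             at$entry_dims),
                 entry_meta = as_tibble(em),
                 index = as_tibble(readr::read_csv(file.path(path, "index.csv"),
                                                   show_col_types = FALSE,
                                                   progress = FALSE)),
                 scheme = at$scheme),
            class = "ptc_pair_set")
}
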