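#' Read an ego network from JSON
#'
#' The on-disk dialect is a JSON object
#' `{"alters": [{"id": 0, "culture": "A", "domain": "friend"}, ...],
#'   "ties": [[0, 1], [2, 5], ...]}`
#' with 0-based contiguous ids and unordered ties. `domain` may be omitted
#' (treated as `"unspecified"`). All [ego_network()] invariants are enforced
#' on read: bad culture labels, self-ties, duplicate ties, or a tie count
#' above `n(n-1)/2` raise a validation error naming the offending field.
#'
#' @param path file path.
#' @return an [ego_network()].
#' @seealso [write_network()]
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) {
      stop(sprintf("cannot parse %s as network JSON: %s",
                   path, conditionMessage(e)), call. = FALSE)
    }
  )
  if (is.null(obj$alters)) {
    stop(sprintf("%s: missing 'alters' field", path), call. = FALSE)
  }
  alters <- as.data.frame(obj$alters)
  if (is.null(alters$id) || is.null(alters$culture)) {
    stop(sprintf("%s: alters need 'id' and 'culture' fields", path),
         call. = FALSE)
  }
  ord <- order(alters$id)
  alters <- alters[ord, , drop = FALSE]
  if (!identical(as.integer(alters$id), seq_len(nrow(alters)) - 1L)) {
    stop(sprintf("%s: alter ids must be 0..n-1 without gaps or duplicates",
                 path), call. = FALSE)
  }
  domains <- if (is.null(alters$domain)) NULL else as.character(alters$domain)
  ties <- obj$ties
  if (!is.null(ties) && length(ties) > 0L) {
    if (!is.matrix(ties)) ties <- do.call(rbind, ties)
  } else {
    ties <- NULL
  }
  ego_network(as.character(alters$culture), ties = ties, domains = domains)
}

#' Write an ego network to JSON
#'
#' Serializes in the dialect documented at [read_network()], with ties stored
#' smaller-id-first in lexicographic order so output is reproducible and
#' `read_network(write_network(net, path))` is a structural identity.
#'
#' @param network an [ego_network()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "ego_network"))
  alters <- data.frame(
    id = seq_len(network$n_alters) - 1L,
    culture = network$cultures,
    domain = network$domains,
    stringsAsFactors = FALSE
  )
  ties <- unname(lapply(seq_len(nrow(network$ties)),
                        function(i) as.integer(network$ties[i, ])))
  obj <- list(alters = alters, ties = ties)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export an ego network as edge-list CSVs
#'
#' Writes a two-column `source,target` edge list plus a sidecar
#' `id,culture,domain` table of alter attributes, for consumption by generic
#' network tools.
#'
#' @param network an [ego_network()].
#' @param edges_path path for the edge list CSV.
#' @param alters_path path for the alter-attribute CSV.
#' @return invisibly, a list with both paths.
#' @export
write_edge_list <- function(network, edges_path, alters_path) {
  stopifnot(inherits(network, "ego_network"))
  edges <- as.data.frame(network$ties)
  names(edges) <- c("source", "target")
  write.csv(edges, edges_path, row.names = FALSE, quote = FALSE)
  alters <- data.frame(
    id = seq_len(network$n_alters) - 1L,
    culture = network$cultures,
    domain = network$domains
  )
  write.csv(alters, alters_path, row.names = FALSE, quote = FALSE)
  invisible(list(edges = edges_path, alters = alters_path))
}
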