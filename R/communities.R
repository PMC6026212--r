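#' Read a community file (one community per line)
#'
#' Parses the SNAP-style community format: one community per line, node IDs
#' separated by whitespace. Line order defines the community IDs `0 .. k-1`.
#' Empty lines are skipped.
#'
#' @param path Path to the community file.
#' @param net A `crank_network` the node IDs must belong to.
#' @param strict If `TRUE` (default), a node ID absent from `net` is an
#'   error; if `FALSE`, unknown nodes are dropped with a warning.
#' @return A tibble with columns `community` (character) and `node`
#'   (character), one row per membership.
#' @export
read_communities <- function(path, net, strict = TRUE) {
  stopifnot(is_crank_network(net))
  if (!file.exists(path)) {
    abort(sprintf("community file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(trimws(lines), "\\s+")
  fields <- fields[lengths(fields) > 0 & vapply(fields, function(f) any(nzchar(f)), logical(1))]
  if (!length(fields)) {
    return(tibble(community = character(0), node = character(0)))
  }
  comms <- tibble(
    community = rep(as.character(seq_along(fields) - 1L), lengths(fields)),
    node = unlist(fields)
  )
  unknown <- !(comms$node %in% net$nodes)
  if (any(unknown)) {
    if (strict) {
      abort(sprintf(
        "community file references node(s) not in the network: %s",
        paste(utils::head(unique(comms$node[unknown]), 5), collapse = ", ")
      ))
    }
    warn(sprintf("dropping %d membership(s) of unknown nodes", sum(unknown)))
    comms <- comms[!unknown, ]
  }
  validate_communities(comms, net)
}

validate_communities <- function(comms, net = NULL) {
  comms <- as_tibble(as.data.frame(comms))
  if (!all(c("community", "node") %in% names(comms))) {
    if (ncol(comms) >= 2) names(comms)[1:2] <- c("community", "node")
    else abort("communities must have columns `community` and `node`.")
  }
  comms$community <- as.character(comms$community)
  comms$node <- as.character(comms$node)
  comms <- dplyr::distinct(comms, .data$community, .data$node)
  if (!is.null(net)) {
    missing <- setdiff(comms$node, net$nodes)
    if (length(missing)) {
      abort(sprintf(
        "community node(s) not in network: %s",
        paste(utils::head(missing, 5), collapse = ", ")
      ))
    }
  }
  comms
}

#' Write communities in the one-community-per-line format
#'
#' @param comms A tibble with columns `community` and `node`.
#' @param path Output path.
#' @export
write_communities <- function(comms, path) {
  comms <- validate_communities(comms)
  ids <- community_ids(comms)
  lines <- vapply(ids, function(cid) {
    paste(comms$node[comms$community == cid], collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# write a data frame as TSV with optional "# " header lines, without the
# write.table connection warnings
write_tsv_file <- function(df, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(header_lines, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# community IDs in deterministic order: numeric when all numeric, else radix
community_ids <- function(comms) {
  ids <- unique(comms$community)
  sort_ids(ids)
}

sort_ids <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) ids[order(num)] else ids[order(ids, method = "radix")]
}

# list of integer node-index vectors, named by community ID
community_index_list <- function(comms, net) {
  ids <- community_ids(comms)
  out <- lapply(ids, function(cid) {
    node_index(net, comms$node[comms$community == cid], context = "community node")
  })
  names(out) <- ids
  out
}
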