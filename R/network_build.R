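# Building one binary directed clinical-contact network per network id from
# ordinal tie records, under the main dichotomization rule and the two
# sensitivity variants (often-only threshold; full matrix including
# non-participating services).

#' Construct a directed network object
#'
#' Low-level constructor used by \code{\link{build_network}} and by the
#' test-suite: wraps a binary adjacency matrix and a node table into a
#' \code{carenets_network}.
#'
#' @param adjacency Square 0/1 matrix, no self-loops; dimnames are service
#'   ids (added if absent).
#' @param service_type Character vector of node types (recycled if length 1).
#' @param network_id Network identifier.
#' @param participated Logical vector of participation flags.
#' @param build_rule List describing how the network was built.
#' @return An object of class \code{carenets_network}: a list with elements
#'   \code{network_id}, \code{nodes} (data frame), \code{adjacency} and
#'   \code{build_rule}.
#' @export
new_network <- function(adjacency, service_type = "other",
                        network_id = "net", participated = TRUE,
                        build_rule = list()) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  stopifnot(ncol(adjacency) == n)
  mode(adjacency) <- "integer"
  if (any(adjacency != 0L & adjacency != 1L))
    stop("adjacency must be binary", call. = FALSE)
  diag(adjacency) <- 0L
  if (is.null(rownames(adjacency)))
    dimnames(adjacency) <- list(paste0("s", seq_len(n)),
                                paste0("s", seq_len(n)))
  service_type <- rep_len(as.character(service_type), n)
  check_enum(service_type, SERVICE_TYPES, "service_type")
  nodes <- data.frame(service_id = rownames(adjacency),
                      network_id = network_id,
                      service_type = service_type,
                      participated = rep_len(participated, n))
  structure(list(network_id = network_id, nodes = nodes,
                 adjacency = adjacency, build_rule = build_rule),
            class = "carenets_network")
}

#' @export
print.carenets_network <- function(x, ...) {
  s <- summarize_build(x)
  cat(sprintf("<carenets_network %s: %d services (%d participating), %d directed ties>\n",
              x$network_id, s$n_nodes, s$n_participants, s$n_edges))
  if (length(x$build_rule) > 0L)
    cat("  rule:", paste(names(x$build_rule),
                         vapply(x$build_rule, function(v)
                           paste(as.character(v), collapse = "+"), ""),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Build a binary directed clinical-contact network
#'
#' Dichotomizes the ordinal tie survey of one network into a binary directed
#' adjacency. An edge i -> j is present iff at least one clinical relation
#' reaches the threshold: a referral_sent reported by i about j; a
#' referral_received reported by j about i (reversed, since it mirrors a
#' referral from i); or an info_exchange reported by either endpoint,
#' directed reporter -> alter. Organizational ties are never used. The
#' relation kinds are merged by logical OR after thresholding.
#'
#' @param roster Roster rows of one network (see \code{\link{read_roster}}).
#' @param ties Validated tie records of the same network
#'   (\code{\link{read_ties}}).
#' @param threshold \code{"sometimes_or_often"} (main rule: sometimes and
#'   often count as a tie) or \code{"often_only"} (sensitivity variant).
#' @param scope \code{"participants_only"} (main rule: non-responding
#'   services and all their reported ties are dropped) or
#'   \code{"full_matrix"} (sensitivity variant: non-participants are kept as
#'   nodes, with edges incident to them coming only from participants'
#'   reports).
#' @param relations Relation kinds to merge; defaults to the three clinical
#'   kinds. Pass a single kind to build per-relation networks.
#' @param symmetrize_info If \code{TRUE}, an info_exchange report also adds
#'   the reverse edge alter -> reporter. Default \code{FALSE}: the survey is
#'   one-mode, each service rates its own contacts.
#' @return A \code{\link{new_network}} object.
#' @export
#' @examples
#' roster <- data.frame(service_id = c("a", "b"), network_id = "n1",
#'   service_type = "other", participated = TRUE)
#' ties <- data.frame(network_id = "n1", reporter_id = "a", alter_id = "b",
#'   relation_kind = "referral_sent", frequency = "sometimes")
#' build_network(roster, validate_ties(ties, roster))$adjacency
build_network <- function(roster, ties,
                          threshold = c("sometimes_or_often", "often_only"),
                          scope = c("participants_only", "full_matrix"),
                          relations = CLINICAL_KINDS,
                          symmetrize_info = FALSE) {
  threshold <- match.arg(threshold)
  scope <- match.arg(scope)
  roster <- validate_roster(roster)
  if (nrow(roster) == 0L) stop("empty roster", call. = FALSE)
  nid <- unique(roster$network_id)
  if (length(nid) != 1L)
    stop("roster must contain exactly one network_id", call. = FALSE)
  if (nrow(ties) > 0L && any(ties$network_id != nid))
    stop("ties and roster network_id mismatch", call. = FALSE)
  bad_kind <- setdiff(relations, RELATION_KINDS)
  if (length(bad_kind) > 0L)
    stop("unknown relation kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)

  if (scope == "participants_only") roster <- roster[roster$participated, ]
  if (nrow(roster) == 0L)
    stop("no participating services under participants_only scope",
         call. = FALSE)
  ids <- roster$service_id
  n <- length(ids)
  A <- matrix(0L, n, n, dimnames = list(ids, ids))

  min_code <- if (threshold == "sometimes_or_often") 1L else 2L
  keep <- ties$freq_code >= min_code & ties$relation_kind %in% relations &
    ties$reporter_id %in% ids & ties$alter_id %in% ids
  t2 <- ties[keep, , drop = FALSE]
  if (nrow(t2) > 0L) {
    from <- ifelse(t2$relation_kind == "referral_received",
                   t2$alter_id, t2$reporter_id)
    to <- ifelse(t2$relation_kind == "referral_received",
                 t2$reporter_id, t2$alter_id)
    if (symmetrize_info) {
      sym <- t2$relation_kind == "info_exchange"
      from <- c(from, t2$alter_id[sym])
      to <- c(to, t2$reporter_id[sym])
    }
    A[cbind(match(from, ids), match(to, ids))] <- 1L
  }
  diag(A) <- 0L
  new_network(A, roster$service_type, nid, roster$participated,
              build_rule = list(threshold = threshold, scope = scope,
                                relations_used = relations,
                                symmetrize_info = symmetrize_info))
}

#' Summarize a built network
#'
#' @param network A \code{carenets_network}.
#' @return A list with \code{network_id}, \code{n_nodes}, \code{n_edges},
#'   \code{n_participants} and the build rule.
#' @export
summarize_build <- function(network) {
  stopifnot(inherits(network, "carenets_network"))
  list(network_id = network$network_id,
       n_nodes = nrow(network$adjacency),
       n_edges = sum(network$adjacency),
       n_participants = sum(network$nodes$participated),
       build_rule = network$build_rule)
}

#' Export a network to GraphML
#'
#' Writes the directed network with node attributes \code{service_type} and
#' \code{participated}, readable by standard network software.
#'
#' @param network A \code{carenets_network}.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_graphml <- function(network, path) {
  g <- as_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "carenets_network"))
  g <- igraph::graph_from_adjacency_matrix(network$adjacency, mode = "directed")
  igraph::V(g)$service_type <- network$nodes$service_type
  igraph::V(g)$participated <- network$nodes$participated
  g
}
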