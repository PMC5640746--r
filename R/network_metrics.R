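# Network-level exposure metrics: composition and index of dissimilarity
# (differentiation), density / Freeman in-degree centralization / clustering
# (integration), reciprocity, and Coleman homophily indices per service type
# (weak ties / heterophily). All metrics are computed directly on the binary
# adjacency matrix; internal values are fractions, percent scaling is left
# to the rendering layer.

adjacency_of <- function(network) {
  if (inherits(network, "carenets_network")) network$adjacency
  else {
    A <- as.matrix(network)
    diag(A) <- 0L
    A
  }
}

#' Density of a directed network
#'
#' Ratio between the number of directed ties present and the number of
#' possible ties, \eqn{m / (n (n - 1))}.
#'
#' @param network A \code{\link{new_network}} object or adjacency matrix.
#' @return A fraction in \[0, 1\].
#' @export
net_density <- function(network) {
  A <- adjacency_of(network)
  n <- nrow(A)
  if (n < 2L) stop("density undefined for n < 2", call. = FALSE)
  sum(A) / (n * (n - 1))
}

#' Freeman degree centralization
#'
#' How unequal the services are in their number of ties:
#' \eqn{\sum_i (d_{max} - d_i)} divided by its maximum over directed
#' networks of the same size, \eqn{(n - 1)^2}. Equals 0 when every service
#' has the same degree and 1 for an inward star where a single hub is the
#' only service tied to all others. In-degree (ties received) is the
#' default, matching referral networks where being nominated is the
#' centrality signal; out- and total-degree variants are available.
#'
#' @inheritParams net_density
#' @param mode Degree direction: \code{"in"} (default), \code{"out"} or
#'   \code{"total"}.
#' @return A fraction in \[0, 1\].
#' @export
degree_centralization <- function(network, mode = c("in", "out", "total")) {
  mode <- match.arg(mode)
  A <- adjacency_of(network)
  n <- nrow(A)
  if (n < 3L) stop("centralization undefined for n < 3", call. = FALSE)
  d <- switch(mode,
              "in" = colSums(A),
              "out" = rowSums(A),
              "total" = colSums(A) + rowSums(A))
  denom <- switch(mode,
                  "in" = (n - 1)^2,
                  "out" = (n - 1)^2,
                  "total" = 2 * (n - 1)^2)
  sum(max(d) - d) / denom
}

#' Mean normalized in-degree
#'
#' Mean over services of in-degree divided by \eqn{n - 1} (the maximum
#' possible). For a binary directed network this equals the density; it is
#' reported separately because the descriptive tables of referral-network
#' studies list it as its own row.
#'
#' @inheritParams net_density
#' @return A fraction in \[0, 1\].
#' @export
mean_in_degree_normalized <- function(network) {
  A <- adjacency_of(network)
  n <- nrow(A)
  if (n < 2L) stop("undefined for n < 2", call. = FALSE)
  mean(colSums(A) / (n - 1))
}

#' Network-level clustering coefficient
#'
#' The density of connections around each service, averaged over services:
#' the local clustering coefficient is computed on the undirected projection
#' (i and j are neighbours iff i -> j or j -> i) as the fraction of a
#' node's neighbour pairs that are themselves connected. Nodes with fewer
#' than two neighbours contribute 0. Returns 1 on a complete network and 0
#' on a star.
#'
#' @inheritParams net_density
#' @return A fraction in \[0, 1\].
#' @export
clustering_coef <- function(network) {
  A <- adjacency_of(network)
  n <- nrow(A)
  if (n < 3L) stop("clustering undefined for n < 3", call. = FALSE)
  U <- (A + t(A)) > 0
  local <- vapply(seq_len(n), function(i) {
    nb <- which(U[i, ])
    k <- length(nb)
    if (k < 2L) return(0)
    sum(U[nb, nb]) / (k * (k - 1))
  }, numeric(1))
  mean(local)
}

#' Reciprocity of a directed network
#'
#' Proportion of directed ties whose reverse tie also exists.
#'
#' @inheritParams net_density
#' @return A fraction in \[0, 1\].
#' @export
reciprocity <- function(network) {
  A <- adjacency_of(network)
  m <- sum(A)
  if (m == 0) stop("reciprocity undefined with zero ties", call. = FALSE)
  sum(A * t(A)) / m
}

#' Service-type composition of a network
#'
#' Fraction of services of each of the nine types; sums to 1.
#'
#' @param network A \code{\link{new_network}} object, or a character vector
#'   of service types.
#' @return A named numeric vector over the nine service types.
#' @export
composition <- function(network) {
  types <- if (inherits(network, "carenets_network"))
    network$nodes$service_type else as.character(network)
  if (length(types) == 0L) stop("empty network", call. = FALSE)
  check_enum(types, SERVICE_TYPES, "service_type")
  tab <- table(factor(types, levels = SERVICE_TYPES))
  p <- as.numeric(tab) / length(types)
  names(p) <- SERVICE_TYPES
  p
}

#' Index of dissimilarity
#'
#' Departure of a network's service-type composition from a reference
#' composition: half the L1 distance,
#' \eqn{\frac{1}{2} \sum_t |p_t - r_t|}. 0 means the network matches the
#' reference distribution; 0.5 means a 50-percentage-point excess of some
#' types relative to the reference. The reference defaults (in
#' \code{\link{metrics_table}}) to the unweighted mean composition across
#' all networks in the study set.
#'
#' @param composition,reference Two distributions over the same types
#'   (each summing to 1 within 1e-6).
#' @return A fraction in \[0, 1\].
#' @export
#' @examples
#' dissimilarity_index(c(1, 0), c(0.5, 0.5))  # 0.5
dissimilarity_index <- function(composition, reference) {
  if (length(composition) != length(reference))
    stop("compositions must cover the same types", call. = FALSE)
  if (abs(sum(composition) - 1) > 1e-6 || abs(sum(reference) - 1) > 1e-6)
    stop("compositions must each sum to 1", call. = FALSE)
  sum(abs(composition - reference)) / 2
}

#' Coleman homophily index for a service type
#'
#' Group-level homophily of out-ties: with \eqn{w} the proportion of
#' out-ties from members of the type that land on same-type alters and
#' \eqn{e = (n_g - 1) / (n - 1)} the random-mixing expectation, the index is
#' \eqn{(w - e) / (1 - e)} when \eqn{w \ge e} and \eqn{(w - e) / e}
#' otherwise. It is +1 when all out-referrals stay within the type (perfect
#' homophily), -1 when none do (perfect heterophily) and 0 under random
#' mixing. Undefined (NA) when the type has no out-ties or comprises the
#' whole network.
#'
#' @inheritParams net_density
#' @param types One or more of the nine service types, treated as a single
#'   merged group (e.g. social services together with rehabilitation teams).
#' @return A value in \[-1, 1\], or \code{NA_real_} when undefined.
#' @export
coleman_index <- function(network, types) {
  stopifnot(inherits(network, "carenets_network"))
  check_enum(types, SERVICE_TYPES, "service_type")
  A <- network$adjacency
  n <- nrow(A)
  if (n < 2L) stop("Coleman index undefined for n < 2", call. = FALSE)
  member <- network$nodes$service_type %in% types
  n_g <- sum(member)
  if (n_g == 0L) return(NA_real_)
  if (n_g == n) return(NA_real_)  # e = 1: expectation degenerate
  out_edges <- A[member, , drop = FALSE]
  m <- sum(out_edges)
  if (m == 0) return(NA_real_)   # no out-ties: missing, not zero
  w <- sum(out_edges[, member, drop = FALSE]) / m
  e <- (n_g - 1) / (n - 1)
  if (w >= e) (w - e) / (1 - e) else (w - e) / e
}

# Default Coleman groups reported in the descriptive table: primary care,
# crisis/outreach teams, social services merged with rehabilitation teams,
# psychiatric wards.
default_coleman_groups <- function() {
  list(primary_care = "primary_care",
       crisis_outreach = "crisis_outreach",
       social_rehab = c("social_services", "rehabilitation"),
       psychiatric_ward = "psychiatric_ward")
}

#' One row of network metrics
#'
#' Computes the full exposure row for one network: size, composition,
#' dissimilarity against a reference, normalized mean in-degree, in-degree
#' centralization, density, clustering, reciprocity and Coleman indices for
#' the configured groups.
#'
#' @param network A \code{\link{new_network}} object.
#' @param reference Reference composition for the dissimilarity index.
#' @param coleman_groups Named list of type groups; defaults to primary
#'   care, crisis/outreach, social/rehabilitation and psychiatric wards.
#' @return A one-row data frame.
#' @export
network_metrics <- function(network, reference,
                            coleman_groups = default_coleman_groups()) {
  comp <- composition(network)
  n <- nrow(network$adjacency)
  row <- data.frame(network_id = network$network_id, n_services = n)
  for (t in SERVICE_TYPES) row[[paste0("comp_", t)]] <- comp[[t]]
  row$dissimilarity <- dissimilarity_index(comp, reference)
  row$mean_in_degree_norm <-
    if (n >= 2) mean_in_degree_normalized(network) else NA_real_
  row$centralization <-
    if (n >= 3) degree_centralization(network) else NA_real_
  row$density <- if (n >= 2) net_density(network) else NA_real_
  row$clustering <- if (n >= 3) clustering_coef(network) else NA_real_
  row$reciprocity <-
    if (sum(network$adjacency) > 0) reciprocity(network) else NA_real_
  for (g in names(coleman_groups))
    row[[paste0("coleman_", g)]] <- coleman_index(network, coleman_groups[[g]])
  row
}

#' Metrics table for a set of networks
#'
#' One metrics row per network (see \code{\link{network_metrics}}) plus the
#' mean/std/min/max summary per metric, mirroring the descriptive-statistics
#' layout of network studies. The dissimilarity reference is the unweighted
#' mean composition across the supplied networks (each network counts once)
#' unless given.
#'
#' @param networks List of \code{\link{new_network}} objects.
#' @param reference Optional reference composition.
#' @param coleman_groups See \code{\link{network_metrics}}.
#' @return A list of class \code{carenets_metrics}: \code{metrics} (data
#'   frame, one row per network), \code{summary} (mean/std/min/max per
#'   metric, NA values dropped) and \code{reference}.
#' @export
metrics_table <- function(networks, reference = NULL,
                          coleman_groups = default_coleman_groups()) {
  if (length(networks) == 0L) stop("need at least one network", call. = FALSE)
  comps <- vapply(networks, composition, numeric(length(SERVICE_TYPES)))
  if (is.null(reference)) reference <- rowMeans(comps)
  rows <- lapply(networks, network_metrics, reference = reference,
                 coleman_groups = coleman_groups)
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  num <- setdiff(names(metrics), "network_id")
  summ <- do.call(rbind, lapply(num, function(cl) {
    v <- metrics[[cl]]
    v <- v[!is.na(v)]
    data.frame(metric = cl,
               mean = if (length(v)) mean(v) else NA_real_,
               std = if (length(v) > 1) stats::sd(v) else 0,
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_)
  }))
  structure(list(metrics = metrics, summary = summ, reference = reference),
            class = "carenets_metrics")
}

#' @export
print.carenets_metrics <- function(x, digits = 3, ...) {
  cat("<carenets_metrics:", nrow(x$metrics), "networks>\n")
  print(cbind(metric = x$summary$metric,
              round(x$summary[, c("mean", "std", "min", "max")], digits)),
        row.names = FALSE)
  invisible(x)
}

#' Pearson correlations among network metrics
#'
#' Pairwise Pearson correlations (with two-sided p-values) between selected
#' network-level metrics across networks, as used to examine how structural
#' features interrelate. Metrics constant across networks are reported as
#' missing with a warning.
#'
#' @param metrics The \code{metrics} data frame of a
#'   \code{\link{metrics_table}} (or the table itself).
#' @param select Character vector of metric columns; defaults to all numeric
#'   metric columns except the per-type compositions.
#' @return An object of class \code{carenets_corr} with matrices \code{r}
#'   and \code{p} and the number of networks \code{n}. Its print method
#'   star-codes significance at 5\%, 1\% and 0.1\%.
#' @export
correlation_matrix <- function(metrics, select = NULL) {
  if (inherits(metrics, "carenets_metrics")) metrics <- metrics$metrics
  if (is.null(select))
    select <- setdiff(names(metrics)[vapply(metrics, is.numeric, TRUE)],
                      grep("^comp_", names(metrics), value = TRUE))
  if (nrow(metrics) < 3L)
    stop("need at least 3 networks for correlations", call. = FALSE)
  k <- length(select)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(select, select))
  diag(r) <- 1
  diag(p) <- 0
  const <- vapply(select, function(cl) {
    v <- metrics[[cl]]
    stats::var(v, na.rm = TRUE) %in% c(0, NA) || all(is.na(v))
  }, TRUE)
  if (any(const))
    warning("constant metric(s) reported as missing: ",
            paste(select[const], collapse = ", "), call. = FALSE)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (const[i] || const[j]) next
    ok <- stats::complete.cases(metrics[, select[c(i, j)]])
    if (sum(ok) < 3L) next
    ct <- stats::cor.test(metrics[[select[i]]][ok], metrics[[select[j]]][ok])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(r = r, p = p, n = nrow(metrics)),
            class = "carenets_corr")
}

#' @export
print.carenets_corr <- function(x, digits = 2, ...) {
  stars <- ifelse(is.na(x$p), "", ifelse(x$p < 0.001, "***",
            ifelse(x$p < 0.01, "**", ifelse(x$p < 0.05, "*", ""))))
  out <- matrix(paste0(format(round(x$r, digits)), stars),
                nrow(x$r), dimnames = dimnames(x$r))
  out[is.na(x$r)] <- "."
  cat("<carenets_corr over", x$n,
      "networks; significant at *5%, **1%, ***0.1%>\n")
  print(out, quote = FALSE)
  invisible(x)
}
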