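# Thresholded undirected brain networks on channel labels, and the
# degree-based localization readouts: core nodes, degree dynamics, main
# path, and the consensus focus across feature networks.

#' Build a brain network by thresholding a synchronization matrix
#'
#' An edge joins channels i and j iff their synchronization weight strictly
#' exceeds the threshold: the mean of the off-diagonal entries
#' (`rule = "mean"`, the default) or a supplied `value` (`rule = "fixed"`).
#' For mutual-information input the weight is the MI itself. For a T-index
#' matrix the default (`direction = "anomaly"`) links channels whose
#' feature dynamics DIVERGE (`|T|` above threshold): during a seizure the
#' focus channel's nonlinear features break away from the background, so
#' the maximum-degree node of this network is the channel whose dynamics
#' deviate from most others - the localization readout. The alternative
#' `direction = "similarity"` thresholds `-|T|` instead, linking channels
#' with concordant feature dynamics.
#'
#' @param mat An [mi_matrix()], a [t_index_matrix()], or a plain symmetric
#'   numeric matrix (taken as synchronization weights as-is).
#' @param rule `"mean"` or `"fixed"`.
#' @param value Threshold for `rule = "fixed"` (on the weight scale, i.e.
#'   negative-|T| scale for T-index input).
#' @param ... Passed to methods.
#' @return Object of class `brain_network`: list with `graph` (igraph),
#'   `labels`, `threshold`, `source`, `window`, `stage`.
#' @export
threshold_network <- function(mat, rule = c("mean", "fixed"), value = NULL,
                              ...) {
  UseMethod("threshold_network")
}

#' @rdname threshold_network
#' @param source Label recorded as the network's synchronization source.
#' @param window,stage Bookkeeping tags.
#' @export
threshold_network.matrix <- function(mat, rule = c("mean", "fixed"),
                                     value = NULL, source = "MI",
                                     window = NA, stage = NA_character_,
                                     ...) {
  rule <- match.arg(rule)
  if (nrow(mat) < 2 || nrow(mat) != ncol(mat))
    stop("need a square matrix with at least 2 channels")
  labels <- rownames(mat) %||% sprintf("chan%02d", seq_len(nrow(mat)))
  off <- offdiag(mat)
  if (all(is.na(off))) stop("all off-diagonal entries are missing")
  thr <- if (rule == "mean") mean(off, na.rm = TRUE) else {
    if (is.null(value)) stop("`value` is required for rule = 'fixed'")
    value
  }
  adj <- !is.na(mat) & mat > thr
  diag(adj) <- FALSE
  adj <- adj & t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- labels
  structure(list(graph = g, labels = labels, threshold = thr,
                 source = source, window = window, stage = stage),
            class = "brain_network")
}

#' @rdname threshold_network
#' @export
threshold_network.mi_matrix <- function(mat, rule = c("mean", "fixed"),
                                        value = NULL, window = NULL,
                                        stage = NA_character_, ...) {
  threshold_network.matrix(mat$values, rule = rule, value = value,
                           source = "MI", window = window %||% mat$window,
                           stage = stage)
}

#' @rdname threshold_network
#' @param direction For T-index input: `"anomaly"` (default) or
#'   `"similarity"`, see Details.
#' @export
threshold_network.t_index_matrix <- function(mat, rule = c("mean", "fixed"),
                                             value = NULL,
                                             direction = c("anomaly",
                                                           "similarity"),
                                             ...) {
  direction <- match.arg(direction)
  w <- if (direction == "anomaly") mat$values else -mat$values
  threshold_network.matrix(w, rule = rule, value = value,
                           source = mat$feature, window = NA,
                           stage = mat$stage)
}

#' @export
print.brain_network <- function(x, ...) {
  cat(sprintf("<brain_network> %s (%s): %d nodes, %d edges, threshold %.4g\n",
              x$source, format(x$stage), length(x$labels),
              igraph::ecount(x$graph), x$threshold))
  invisible(x)
}

#' Strongest channel pairs of a synchronization matrix
#'
#' The `k` unordered channel pairs with the largest synchronization values,
#' in descending order; ties are broken lexicographically by label pair.
#'
#' @param mat An [mi_matrix()], [t_index_matrix()] (ranked by `-|T|`), or a
#'   symmetric numeric matrix.
#' @param k Number of pairs (default 20); all pairs if fewer exist.
#' @return Data frame with `from`, `to`, `value`, sorted.
#' @export
top_k_edges <- function(mat, k = 20) {
  if (k < 1) stop("`k` must be >= 1")
  if (inherits(mat, "mi_matrix")) m <- mat$values
  else if (inherits(mat, "t_index_matrix")) m <- -mat$values
  else m <- as.matrix(mat)
  labels <- rownames(m) %||% sprintf("chan%02d", seq_len(nrow(m)))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  l1 <- labels[ut[, 1]]; l2 <- labels[ut[, 2]]
  df <- data.frame(from = pmin(l1, l2), to = pmax(l1, l2), value = m[ut])
  df <- df[!is.na(df$value), , drop = FALSE]
  ord <- order(-df$value, df$from, df$to)
  rownames(df) <- NULL
  head(df[ord, , drop = FALSE], k)
}

#' Core nodes of a brain network
#'
#' All nodes attaining the maximum degree (ties give several), sorted by
#' label. An edgeless network yields an empty result flagged with attribute
#' `empty = TRUE`.
#'
#' @param net A [threshold_network()] result.
#' @return Character vector of core-node labels.
#' @export
core_nodes <- function(net) {
  stopifnot(inherits(net, "brain_network"))
  if (igraph::ecount(net$graph) == 0)
    return(structure(character(0), empty = TRUE))
  deg <- igraph::degree(net$graph)
  sort(names(deg)[deg == max(deg)])
}

#' Degree dynamics across a window sequence
#'
#' Per-window degree vectors and mean degree, stage-tagged, for a sequence
#' of networks on a common node set.
#'
#' @param nets List of [threshold_network()] results with identical node
#'   sets.
#' @return List of class `degree_timeseries`: `degrees` (windows x channels
#'   matrix), `mean_degree`, `stage`, `labels`.
#' @export
degree_dynamics <- function(nets) {
  if (!length(nets)) stop("empty network sequence")
  labels <- nets[[1]]$labels
  for (n in nets)
    if (!identical(sort(n$labels), sort(labels)))
      stop("networks have differing node sets")
  deg <- t(vapply(nets, function(n)
    igraph::degree(n$graph)[labels], numeric(length(labels))))
  colnames(deg) <- labels
  structure(list(degrees = deg, mean_degree = rowMeans(deg),
                 stage = vapply(nets, function(n) n$stage %||% NA_character_,
                                ""),
                 labels = labels),
            class = "degree_timeseries")
}

#' Main propagation path of core nodes
#'
#' Concatenates per-window core-node sets in time order, collapses
#' consecutive duplicate sets, and renders the path in the
#' `"A-(B\\C)-D"` notation (multi-node sets parenthesized, members
#' separated by backslashes). Windows with empty core sets are skipped.
#'
#' @param nets List of [threshold_network()] results in temporal order.
#' @return List of class `main_path`: `sets` (list of core-node sets) and
#'   `rendered` (the path string).
#' @export
main_path <- function(nets) {
  if (length(nets) < 1) stop("need at least 1 window")
  sets <- lapply(nets, core_nodes)
  sets <- Filter(length, sets)
  if (!length(sets)) stop("all networks are edgeless")
  keep <- c(TRUE, vapply(seq_along(sets)[-1], function(i)
    !identical(sets[[i]], sets[[i - 1]]), TRUE))
  sets <- sets[keep]
  rendered <- paste(vapply(sets, function(s)
    if (length(s) == 1) s else paste0("(", paste(s, collapse = "\\"), ")"),
    ""), collapse = "-")
  structure(list(sets = sets, rendered = rendered), class = "main_path")
}

#' @export
print.main_path <- function(x, ...) {
  cat("<main_path>", x$rendered, "\n")
  invisible(x)
}

#' Consensus foci across feature networks
#'
#' Counts how often each channel appears among the core nodes of the
#' supplied feature networks and returns the `top` most frequent channels;
#' ties are broken by summed degree across the networks, then by label.
#'
#' @param nets_by_feature Named list mapping feature name to a list of
#'   [threshold_network()] results (e.g. the ictal-stage network of each
#'   nonlinear feature).
#' @param top How many channels to return (default 2).
#' @return Character vector of the top channels; attribute `ranking` holds
#'   the full count/degree table.
#' @export
consensus_foci <- function(nets_by_feature, top = 2) {
  nets <- unlist(nets_by_feature, recursive = FALSE)
  if (!length(nets)) stop("no networks supplied")
  labels <- nets[[1]]$labels
  count <- setNames(numeric(length(labels)), labels)
  degsum <- setNames(numeric(length(labels)), labels)
  any_core <- FALSE
  for (n in nets) {
    cn <- core_nodes(n)
    if (length(cn)) { any_core <- TRUE; count[cn] <- count[cn] + 1 }
    degsum[labels] <- degsum[labels] + igraph::degree(n$graph)[labels]
  }
  if (!any_core) stop("no core nodes in any network")
  ord <- order(-count, -degsum, names(count))
  ranking <- data.frame(channel = names(count)[ord], core_count = count[ord],
                        degree_sum = degsum[ord], row.names = NULL)
  structure(head(ranking$channel, top), ranking = ranking)
}

#' Write a brain network as GraphML
#'
#' @param net A [threshold_network()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "brain_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
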