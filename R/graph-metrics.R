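# Weighted network indices on PLV adjacency matrices. Edge weights are the
# connection strengths in [0, 1]; shortest-path computations map weight w to
# length 1/w (configurable to -log w).

.check_weights <- function(w, require_unit = TRUE) {
  w <- unclass(as.matrix(w))
  if (nrow(w) != ncol(w)) stop("adjacency must be square", call. = FALSE)
  if (any(!is.finite(w))) stop("weights must be finite", call. = FALSE)
  if (max(abs(w - t(w))) > 1e-10) stop("adjacency must be symmetric", call. = FALSE)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (require_unit && any(w > 1 + 1e-12))
    stop("weights must lie in [0, 1]", call. = FALSE)
  diag(w) <- 0
  w
}

.length_graph <- function(w, length_map = c("inverse", "neglog")) {
  length_map <- match.arg(length_map)
  lw <- w
  pos <- w > 0
  lw[pos] <- if (length_map == "inverse") 1 / w[pos] else -log(w[pos])
  lw[!pos] <- 0
  igraph::graph_from_adjacency_matrix(lw, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

.shortest_distances <- function(w, length_map = "inverse") {
  g <- .length_graph(w, length_map)
  igraph::distances(g, algorithm = "dijkstra")
}

#' Nodal strength
#'
#' `s_i = sum_j w_ij`, the summed connection weight at each node.
#'
#' @param w symmetric weight matrix (e.g. a `plv_matrix`).
#' @return Numeric vector of length `nrow(w)`.
#' @export
nodal_strength <- function(w) {
  w <- .check_weights(w, require_unit = FALSE)
  rowSums(w)
}

#' Weighted nodal clustering coefficient (Onnela form)
#'
#' `C_i = [sum_{j != h} (w_ij w_ih w_jh)^{1/3}] / (k_i (k_i - 1))` with
#' `k_i` the number of nonzero-weight neighbors; `C_i = 0` when `k_i < 2`.
#' Weights must already lie in `[0, 1]` (PLV weights are used directly,
#' without max-weight renormalization, so a uniform complete graph of
#' weight c has `C_i = c`).
#'
#' @param w symmetric weight matrix with entries in `[0, 1]`.
#' @return Numeric vector of per-node clustering coefficients.
#' @export
nodal_clustering <- function(w) {
  w <- .check_weights(w)
  w3 <- w^(1 / 3)
  num <- diag(w3 %*% w3 %*% w3)
  k <- rowSums(w > 0)
  out <- numeric(nrow(w))
  ok <- k >= 2
  out[ok] <- num[ok] / (k[ok] * (k[ok] - 1))
  out
}

#' Characteristic path length
#'
#' Mean weighted shortest-path distance over all ordered node pairs, with
#' edge length `1/w` (or `-log w`). Errors on disconnected graphs, naming
#' the components.
#'
#' @param w symmetric weight matrix.
#' @param length_map `"inverse"` (default) or `"neglog"` weight-to-length
#'   map.
#' @return Scalar characteristic path length.
#' @export
characteristic_path_length <- function(w, length_map = "inverse") {
  w <- .check_weights(w, require_unit = FALSE)
  d <- .shortest_distances(w, length_map)
  off <- d[row(d) != col(d)]
  if (any(!is.finite(off))) {
    comp <- igraph::components(.length_graph(w))
    stop(sprintf(
      "graph is disconnected (%d components; sizes %s); path length undefined",
      comp$no, paste(comp$csize, collapse = ", ")), call. = FALSE)
  }
  mean(off)
}

#' Global efficiency
#'
#' Mean over node pairs of inverse shortest-path distance; disconnected
#' pairs contribute 0.
#'
#' @inheritParams characteristic_path_length
#' @return Scalar efficiency; for weights in `[0, 1]` and the inverse
#'   length map this lies in `[0, 1]`.
#' @export
global_efficiency <- function(w, length_map = "inverse") {
  w <- .check_weights(w, require_unit = FALSE)
  if (nrow(w) < 2L) return(0)
  d <- .shortest_distances(w, length_map)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  mean(inv[row(d) != col(d)])
}

#' All four global network indices
#'
#' Global strength is reported as the mean of nodal strengths (so on a
#' complete unit-weight graph of n nodes it equals n - 1), clustering as the
#' mean nodal clustering coefficient, plus characteristic path length and
#' global efficiency.
#'
#' @param w symmetric weight matrix with entries in `[0, 1]`.
#' @param band,subject optional provenance tags.
#' @inheritParams characteristic_path_length
#'
#' @return One-row data frame: `subject`, `band`, `strength`, `clustering`,
#'   `path_length`, `efficiency`.
#' @export
global_metrics <- function(w, band = NA_character_, subject = NA_character_,
                           length_map = "inverse") {
  if (is.na(band) && !is.null(attr(w, "band"))) band <- attr(w, "band")
  data.frame(
    subject = subject, band = band,
    strength = mean(nodal_strength(w)),
    clustering = mean(nodal_clustering(w)),
    path_length = characteristic_path_length(w, length_map),
    efficiency = global_efficiency(w, length_map)
  )
}

#' Cohort-level metric tables from connectivity output
#'
#' @param conn result of [cohort_connectivity()].
#' @param nodal if `TRUE`, also return the per-node strength/clustering
#'   table.
#'
#' @return A list with `global` (long data frame: subject, band, the four
#'   indices) and, when requested, `nodal` (subject, band, node, strength,
#'   clustering).
#' @export
cohort_metrics <- function(conn, nodal = FALSE) {
  subj <- character(0); band <- character(0)
  S <- C <- L <- E <- numeric(0)
  nlist <- list()
  for (s in names(conn$matrices)) {
    for (b in names(conn$matrices[[s]])) {
      w <- conn$matrices[[s]][[b]]
      s_i <- nodal_strength(w)
      c_i <- nodal_clustering(w)
      subj <- c(subj, s); band <- c(band, b)
      S <- c(S, mean(s_i)); C <- c(C, mean(c_i))
      L <- c(L, characteristic_path_length(w))
      E <- c(E, global_efficiency(w))
      if (nodal)
        nlist[[length(nlist) + 1L]] <-
          list(s = s, b = b, s_i = s_i, c_i = c_i)
    }
  }
  nodal_df <- NULL
  if (nodal && length(nlist)) {
    nn <- length(nlist[[1L]]$s_i)
    nodal_df <- data.frame(
      subject = rep(vapply(nlist, `[[`, "", "s"), each = nn),
      band = rep(vapply(nlist, `[[`, "", "b"), each = nn),
      node = rep(seq_len(nn), length(nlist)),
      strength = unlist(lapply(nlist, `[[`, "s_i"), use.names = FALSE),
      clustering = unlist(lapply(nlist, `[[`, "c_i"), use.names = FALSE))
  }
  list(global = data.frame(subject = subj, band = band, strength = S,
                           clustering = C, path_length = L, efficiency = E),
       nodal = nodal_df)
}
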