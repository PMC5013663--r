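#' Shared-parasitism dependence matrix
#'
#' Computes, for every ordered host pair, the proportion of the parasitoids
#' attacking the focal host that were reared from the source host (the
#' Muller dependence index). With habitat-indexed hosts this is the
#' cross-habitat extension: the focal host `i` in habitat `A` and the source
#' host `j` in habitat `B` are separate web nodes, and the parasitoid pool
#' denominator runs over all hosts of the habitats in `pool_scope`.
#'
#' For focal host `i` and source host `j`,
#' `d[i, j] = sum_k (a[i, k] / sum_l a[i, l]) * (a[j, k] / sum_m a[m, k])`
#' where `a` are attack counts, `l` runs over parasitoid species and `m`
#' over the hosts of the pooled habitats. Parasitoid species with zero total
#' recruitment inside the pool contribute nothing (the 0/0 term is skipped).
#' Rows of hosts without any recorded attack are all-zero and flagged via
#' the `parasitized` field rather than `NaN`.
#'
#' When `pool_scope` covers every habitat in the web, each parasitized
#' host's row sums to exactly 1. When the pool is restricted to one habitat
#' (the `q = 1` variant used for within- vs cross-habitat contrasts), rows
#' may sum to less than 1 because parasitoids recruited only from the other
#' habitat drop out of the pool.
#'
#' @param web A `quantweb`.
#' @param pool_scope Character vector of habitats whose hosts form the
#'   parasitoid pool (columns of the result). Defaults to every habitat in
#'   the web. Ignored (single implicit pool) for non-indexed webs.
#' @return A `dependence_matrix` object: `values` (focal hosts x source
#'   hosts), `hosts` (row registry), `sources` (column registry),
#'   `pool_scope`, `basis`, `parasitized` (row flags).
#' @export
dependence_matrix <- function(web, pool_scope = NULL) {
  stopifnot(inherits(web, "quantweb"))
  if (web$habitat_indexed) {
    habitats <- sort(unique(web$hosts$habitat))
    if (is.null(pool_scope)) pool_scope <- habitats
    if (!all(pool_scope %in% habitats)) {
      stop_edgeweb("pool_scope habitat(s) absent from the web: ",
                   paste(setdiff(pool_scope, habitats), collapse = ", "))
    }
    pool <- web$hosts$habitat %in% pool_scope
  } else {
    pool_scope <- NA_character_
    pool <- rep(TRUE, nrow(web$counts))
  }
  W <- web$counts
  storage.mode(W) <- "double"
  Wp <- W[pool, , drop = FALSE]
  row_tot <- rowSums(W)
  col_tot <- colSums(Wp)
  row_frac <- W / ifelse(row_tot > 0, row_tot, 1)
  col_frac <- sweep(Wp, 2, ifelse(col_tot > 0, col_tot, 1), "/")
  values <- row_frac %*% t(col_frac)
  structure(list(values = values,
                 hosts = web$hosts,
                 sources = web$hosts[pool, , drop = FALSE],
                 pool_scope = pool_scope,
                 basis = web$basis,
                 parasitized = row_tot > 0),
            class = "dependence_matrix")
}

#' @export
print.dependence_matrix <- function(x, ...) {
  cat(sprintf(
    "<dependence_matrix> %d focal x %d source hosts (pool: %s; basis: %s)\n",
    nrow(x$values), ncol(x$values),
    paste(x$pool_scope, collapse = ","), x$basis))
  cat(sprintf("  parasitized focal hosts: %d\n", sum(x$parasitized)))
  invisible(x)
}

#' Check that the habitat-indexed index reduces to the plain Muller index
#'
#' For a web whose hosts all sit in one habitat, the habitat-indexed
#' dependence with the pool restricted to that habitat must coincide with
#' the plain (non-indexed) Muller index: the habitat bookkeeping is then
#' vacuous. Returns the maximum absolute difference between the two
#' computations (algebraically zero).
#'
#' @param web A single-habitat `quantweb`.
#' @return Maximum absolute elementwise difference.
#' @export
single_habitat_reduction_check <- function(web) {
  stopifnot(inherits(web, "quantweb"))
  habitats <- unique(web$hosts$habitat)
  if (web$habitat_indexed && length(habitats) > 1) {
    stop_edgeweb("reduction check requires a one-habitat web")
  }
  d2 <- dependence_matrix(web, pool_scope = if (web$habitat_indexed)
    habitats else NULL)
  plain <- quantweb(web$counts,
                    data.frame(taxon = web$hosts$taxon,
                               habitat = NA_character_),
                    web$parasitoids, habitat_indexed = FALSE,
                    basis = web$basis)
  d1 <- dependence_matrix(plain)
  max(abs(d2$values - d1$values))
}

#' Parasitoid overlap graph
#'
#' Builds the host-level projection of the web: one node per parasitized
#' host, an edge wherever two hosts share at least one parasitoid species.
#' Node attributes: `recruited` (parasitoid individuals reared from that
#' host, i.e. its row total) and `self_loop` (the conspecific dependence,
#' the summed `d` of the host on its own taxon in either habitat). Edge
#' weight is the symmetrized dependence `(d[i,j] + d[j,i]) / 2` - a
#' visualization-oriented choice - and edges are classified `within-P`,
#' `within-N` or `cross-habitat`.
#'
#' @param dep A `dependence_matrix` computed from `web` with the full pool.
#' @param web The `quantweb` the dependence was computed from.
#' @return An `igraph` graph.
#' @export
overlap_graph <- function(dep, web) {
  stopifnot(inherits(dep, "dependence_matrix"), inherits(web, "quantweb"))
  if (!identical(dep$hosts$key, web$hosts$key) ||
      !identical(dep$sources$key, web$hosts$key)) {
    stop_edgeweb("dependence matrix and web registries do not match ",
                 "(overlap graph needs the full-pool dependence)")
  }
  keep <- which(rowSums(web$counts) > 0)
  if (length(keep) == 0) {
    stop_edgeweb("no parasitized hosts; overlap graph is empty")
  }
  A <- web$counts[keep, , drop = FALSE] > 0
  share <- A %*% t(A)
  hosts <- web$hosts[keep, , drop = FALSE]
  # conspecific dependence: same taxon, either habitat
  self_loop <- vapply(seq_along(keep), function(r) {
    i <- keep[r]
    js <- which(dep$sources$taxon == dep$hosts$taxon[i])
    sum(dep$values[i, js])
  }, 0)
  g <- igraph::make_empty_graph(n = length(keep), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = hosts$key)
  g <- igraph::set_vertex_attr(g, "taxon", value = hosts$taxon)
  g <- igraph::set_vertex_attr(g, "habitat", value = hosts$habitat)
  g <- igraph::set_vertex_attr(g, "recruited",
                               value = unname(rowSums(web$counts)[keep]))
  g <- igraph::set_vertex_attr(g, "self_loop", value = self_loop)
  pairs <- which(upper.tri(share) & share > 0, arr.ind = TRUE)
  if (nrow(pairs)) {
    w <- (dep$values[cbind(keep[pairs[, 1]], keep[pairs[, 2]])] +
            dep$values[cbind(keep[pairs[, 2]], keep[pairs[, 1]])]) / 2
    hab_a <- hosts$habitat[pairs[, 1]]
    hab_b <- hosts$habitat[pairs[, 2]]
    cls <- ifelse(is.na(hab_a) | is.na(hab_b), "within",
                  ifelse(hab_a != hab_b, "cross-habitat",
                         paste0("within-", hab_a)))
    g <- igraph::add_edges(g, rbind(pairs[, 1], pairs[, 2]))
    g <- igraph::set_edge_attr(g, "weight", value = w)
    g <- igraph::set_edge_attr(g, "class", value = cls)
  }
  g
}

#' Export an overlap graph to GraphML
#'
#' @param graph An `igraph` graph from [overlap_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_graph <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
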