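# Directed subgraphs of the Goldner-Harary graph used by the GHPat extractor.
#
# The Goldner-Harary graph is the smallest non-Hamiltonian maximal planar
# graph: 11 nodes, 27 undirected edges.  GHPat derives from it seven directed
# subgraphs, each with exactly 8 directed edges over 6, 7 or 9 of the 11
# nodes.  Edge q of the selected subgraph contributes bit q (LSB-first) of an
# 8-bit code for every 11-sample signal block.

# 7 x 8 source / target node-index tables, one row per subgraph, one column
# per directed edge (edge order defines bit order).
.gh_src <- rbind(
  c(1, 1, 1, 1, 1, 1, 1, 1),
  c(11, 11, 11, 11, 11, 11, 11, 11),
  c(3, 3, 4, 5, 6, 6, 7, 8),
  c(1, 1, 4, 7, 6, 6, 5, 8),
  c(2, 2, 2, 1, 11, 10, 10, 10),
  c(6, 6, 6, 6, 6, 6, 6, 6),
  c(1, 2, 11, 10, 1, 3, 11, 9)
)
.gh_tgt <- rbind(
  c(2, 3, 4, 6, 7, 9, 10, 11),
  c(2, 3, 5, 6, 8, 9, 10, 1),
  c(4, 5, 6, 6, 7, 8, 9, 9),
  c(4, 7, 6, 6, 5, 8, 11, 11),
  c(1, 3, 11, 6, 6, 9, 1, 11),
  c(1, 3, 11, 9, 4, 7, 8, 5),
  c(2, 11, 10, 1, 3, 11, 9, 1)
)

# node sets actually touched by each subgraph's edges
.gh_nodes <- lapply(1:7, function(h) sort(unique(c(.gh_src[h, ], .gh_tgt[h, ]))))

# 7 x 11 averaging-weight matrices: row h gives the weights such that
# W %*% block yields the seven local means.  "nodeset" averages over the node
# set a subgraph really uses; "literal" reproduces the printed mean formulas
# verbatim (where the third mean duplicates the first and the seventh uses
# subgraph 6's node set).
.gh_weights <- local({
  W <- matrix(0, 7, 11)
  for (h in 1:7) W[h, .gh_nodes[[h]]] <- 1 / length(.gh_nodes[[h]])
  lit_sets <- list(
    c(1, 2, 3, 4, 6, 7, 9, 10, 11),
    c(1, 2, 3, 5, 6, 8, 9, 10, 11),
    c(1, 2, 3, 4, 6, 7, 9, 10, 11),
    c(3, 4, 5, 6, 7, 8, 9),
    c(1, 4, 5, 6, 7, 8, 11),
    c(1, 2, 3, 6, 9, 10, 11),
    c(1, 3, 4, 5, 6, 7, 8, 9, 11)
  )
  L <- matrix(0, 7, 11)
  for (h in 1:7) L[h, lit_sets[[h]]] <- 1 / length(lit_sets[[h]])
  list(nodeset = W, literal = L)
})

#' Directed Goldner-Harary subgraph tables
#'
#' Returns the seven ordered directed-edge tables over the 11 Goldner-Harary
#' nodes that drive GHPat textural coding.  Each subgraph has exactly 8
#' directed edges; edge `q` produces bit `q` (least-significant first) of the
#' 8-bit block code.
#'
#' @return A list of 7 subgraph specifications.  Each element has
#'   `id` (1-7), `edges` (an 8 x 2 integer matrix of `source`/`target` node
#'   indices in 1..11, in bit order), `nodes` (the sorted node set used), and
#'   `node_count` (6, 7 or 9).
#' @seealso [encode_block()], [ghpat_transform()], [gh_subgraphs_json()]
#' @examples
#' sg <- gh_subgraphs()
#' sapply(sg, `[[`, "node_count")
#' @export
gh_subgraphs <- function() {
  lapply(1:7, function(h) {
    edges <- cbind(source = .gh_src[h, ], target = .gh_tgt[h, ])
    list(
      id = h,
      edges = edges,
      nodes = .gh_nodes[[h]],
      node_count = length(.gh_nodes[[h]])
    )
  })
}

#' Export the subgraph tables as JSON
#'
#' Serializes the output of [gh_subgraphs()] for external audit.
#'
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return Invisibly the JSON string (also written to `path` when given).
#' @export
gh_subgraphs_json <- function(path = NULL) {
  js <- jsonlite::toJSON(
    lapply(gh_subgraphs(), function(s) {
      list(
        id = s$id,
        edges = lapply(seq_len(nrow(s$edges)), function(q) {
          list(source = s$edges[q, 1], target = s$edges[q, 2])
        }),
        nodes = s$nodes,
        node_count = s$node_count
      )
    }),
    auto_unbox = TRUE, pretty = TRUE
  )
  if (!is.null(path)) writeLines(js, path)
  invisible(as.character(js))
}
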