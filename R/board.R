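# Nodes are integers 1..n, colours integers 1..m. Edges are stored as a
# 2-column matrix with u < v in each row; mesh and small-world ("extra")
# edges are kept separate so the bare periodic lattice can be recovered.

torus_mesh_edges <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 3 || cols < 3) {
    stop("torus mesh needs rows >= 3 and cols >= 3 for a simple degree-4 lattice")
  }
  id <- function(r, c) (r - 1L) * cols + c
  e <- matrix(0L, nrow = 2L * rows * cols, ncol = 2L)
  k <- 0L
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      right <- id(r, if (c == cols) 1L else c + 1L)
      down  <- id(if (r == rows) 1L else r + 1L, c)
      e[k <- k + 1L, ] <- sort(c(id(r, c), right))
      e[k <- k + 1L, ] <- sort(c(id(r, c), down))
    }
  }
  unique(e)
}

adjacency_list <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      u <- edges[k, 1]; v <- edges[k, 2]
      adj[[u]] <- c(adj[[u]], v)
      adj[[v]] <- c(adj[[v]], u)
    }
  }
  lapply(adj, sort)
}

#' Generate the game network: periodic mesh plus random small-world links
#'
#' Builds a \code{rows x cols} torus (every node has exactly four lattice
#' neighbours) and adds \code{n_extra_links} distinct random long-range
#' edges, rejecting any candidate that would push an endpoint's total degree
#' above \code{max_degree}.
#'
#' @param rows,cols torus dimensions; \code{rows * cols} players.
#' @param n_extra_links number of small-world links to add (default 10).
#' @param max_degree degree cap including mesh edges (default 5).
#' @param seed optional integer seed for reproducible link placement.
#' @param max_tries rejection-sampling budget before giving up.
#' @return an object of class \code{swap_board} (uncoloured; see
#'   \code{\link{assign_colours}}).
#' @examples
#' b <- generate_board(5, 6, n_extra_links = 10, seed = 1)
#' table(node_degrees(b))
#' @export
generate_board <- function(rows, cols, n_extra_links = 10, max_degree = 5,
                           seed = NULL, max_tries = 1000 * max(1, n_extra_links)) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  n <- rows * cols
  if (n < 4) stop("need at least 4 nodes")
  if (max_degree < 4) stop("max_degree must be >= 4 to accommodate the mesh")
  if (!is.null(seed)) set.seed(seed)
  mesh <- torus_mesh_edges(rows, cols)
  deg <- integer(n)
  deg[] <- tabulate(c(mesh), nbins = n)
  have <- new.env(hash = TRUE)
  ekey <- function(u, v) paste0(u, "-", v)
  for (k in seq_len(nrow(mesh))) assign(ekey(mesh[k, 1], mesh[k, 2]), TRUE, envir = have)
  extra <- matrix(0L, nrow = 0, ncol = 2)
  tries <- 0L
  while (nrow(extra) < n_extra_links) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", n_extra_links, " extra links under degree cap ",
           max_degree, " within the retry budget")
    }
    uv <- sort(sample.int(n, 2L))
    if (exists(ekey(uv[1], uv[2]), envir = have, inherits = FALSE)) next
    if (deg[uv[1]] >= max_degree || deg[uv[2]] >= max_degree) next
    assign(ekey(uv[1], uv[2]), TRUE, envir = have)
    deg[uv] <- deg[uv] + 1L
    extra <- rbind(extra, uv)
  }
  dimnames(extra) <- NULL
  structure(list(
    rows = rows, cols = cols, n = n,
    mesh_edges = mesh, extra_edges = extra,
    adj = adjacency_list(n, rbind(mesh, extra)),
    colour = rep(NA_integer_, n), m = NA_integer_, l = NA_integer_,
    max_degree = max_degree
  ), class = "swap_board")
}

#' @export
print.swap_board <- function(x, ...) {
  cat("swap_board:", x$rows, "x", x$cols, "torus,",
      nrow(x$extra_edges), "small-world links\n")
  if (!anyNA(x$colour)) {
    cat("colours:", x$m, "groups of", x$l, "| largest clusters:",
        paste(vapply(seq_len(x$m), function(g) largest_cluster(x, g), 1L),
              collapse = " "), "\n")
  } else {
    cat("colours: unassigned\n")
  }
  invisible(x)
}

#' Node degrees of a board
#' @param board a \code{swap_board}.
#' @return integer vector of total degrees (mesh + extra links).
#' @export
node_degrees <- function(board) {
  tabulate(c(board$mesh_edges, board$extra_edges), nbins = board$n)
}

all_edges <- function(board) rbind(board$mesh_edges, board$extra_edges)

#' Assign colours (group memberships) to a board
#'
#' Two modes: \code{"proper"} gives a proper colouring of the bare mesh
#' (no two lattice-adjacent nodes share a colour, so every start cluster on
#' the mesh has size 1), and \code{"random_constrained"} shuffles colours
#' uniformly and resamples until a validator accepts the configuration.
#' The default validator reproduces the experimental start condition: no
#' group may hold more than 6 points under the point scheme.
#'
#' @param board a \code{swap_board}.
#' @param m number of colour groups; \code{n} must be divisible by \code{m}.
#' @param mode \code{"proper"} or \code{"random_constrained"}.
#' @param validator optional predicate \code{function(board) TRUE/FALSE}
#'   applied in \code{random_constrained} mode.
#' @param seed optional integer seed.
#' @param max_tries resampling budget for the constrained mode.
#' @return the board with colours assigned and \code{m}, \code{l} set.
#' @export
assign_colours <- function(board, m,
                           mode = c("random_constrained", "proper"),
                           validator = NULL, seed = NULL, max_tries = 1000) {
  mode <- match.arg(mode)
  if (board$n %% m != 0) stop("n = ", board$n, " is not divisible by m = ", m)
  l <- board$n %/% m
  if (!is.null(seed)) set.seed(seed)
  board$m <- as.integer(m)
  board$l <- as.integer(l)
  if (mode == "proper") {
    if (board$cols %% m != 0 || board$rows %% m == 1) {
      stop("no diagonal proper ", m, "-colouring for this torus: need cols divisible by m and rows %% m != 1")
    }
    rc <- arrayInd(seq_len(board$n), c(board$cols, board$rows))
    # node id = (r-1)*cols + c  => col index is the fast dimension
    colr <- ((rc[, 2] - 1L) + (rc[, 1] - 1L)) %% m + 1L
    board$colour <- as.integer(colr)
    me <- board$mesh_edges
    if (any(board$colour[me[, 1]] == board$colour[me[, 2]])) {
      stop("internal error: diagonal colouring is not proper on this torus")
    }
    return(board)
  }
  if (is.null(validator)) {
    validator <- function(b) {
      all(vapply(seq_len(b$m), function(g) group_points(b, g), 0) <= 6)
    }
  }
  base <- rep(seq_len(m), each = l)
  for (k in seq_len(max_tries)) {
    board$colour <- sample(base)
    if (isTRUE(validator(board))) return(board)
  }
  stop("no colour assignment satisfied the validator within ", max_tries, " tries")
}

# Weighted quick-union with path halving over same-colour edges.
cluster_membership <- function(board) {
  if (anyNA(board$colour)) stop("board has no colour assignment")
  n <- board$n
  parent <- seq_len(n)
  size <- rep(1L, n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  e <- all_edges(board)
  storage.mode(e) <- "integer"
  same <- board$colour[e[, 1]] == board$colour[e[, 2]]
  e <- e[same, , drop = FALSE]
  for (k in seq_len(nrow(e))) {
    ru <- find(e[k, 1]); rv <- find(e[k, 2])
    if (ru != rv) {
      if (size[ru] < size[rv]) { tmp <- ru; ru <- rv; rv <- tmp }
      parent[rv] <- ru
      size[ru] <- size[ru] + size[rv]
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  list(comp = root, size = size[root])
}

#' Cluster size of the monochromatic component containing a node
#'
#' The cluster of a node is the connected component of same-coloured nodes
#' (over mesh and small-world edges) containing it.
#'
#' @param board a coloured \code{swap_board}.
#' @param node node id in 1..n.
#' @return integer in \code{[1, l]}.
#' @export
cluster_size <- function(board, node) {
  if (length(node) != 1 || is.na(node) || node < 1 || node > board$n) {
    stop("unknown node: ", node)
  }
  cluster_membership(board)$size[node]
}

#' Per-node cluster sizes
#' @param board a coloured \code{swap_board}.
#' @return integer vector, one cluster size per node.
#' @export
all_cluster_sizes <- function(board) cluster_membership(board)$size

#' Largest monochromatic cluster of a colour
#' @param board a coloured \code{swap_board}.
#' @param colour colour index in 1..m.
#' @return integer, the maximum cluster size over nodes of that colour.
#' @export
largest_cluster <- function(board, colour) {
  if (colour < 1 || colour > board$m || is.na(board$m)) stop("invalid colour: ", colour)
  sizes <- all_cluster_sizes(board)
  max(sizes[board$colour == colour])
}

#' Largest cluster per colour
#' @param board a coloured \code{swap_board}.
#' @return integer vector of length m.
#' @export
largest_clusters <- function(board) {
  sizes <- all_cluster_sizes(board)
  vapply(seq_len(board$m), function(g) max(sizes[board$colour == g]), 1L)
}

#' Masked local view of a node
#'
#' What a player can see: their own cluster size, the colour and cluster
#' size of each directly linked neighbour, the current points of their own
#' group, and the global largest cluster per colour. Nothing about
#' non-adjacent nodes is included.
#'
#' @param state a \code{game_state} (see \code{\link{new_game}}).
#' @param node focal node id.
#' @return a list with elements \code{focal}, \code{colour}, \code{s_i},
#'   \code{neighbours} (data.frame: node, colour, s), \code{group_points},
#'   \code{global_largest}.
#' @export
local_view <- function(state, node) {
  board <- state$board
  if (node < 1 || node > board$n) stop("unknown node: ", node)
  sizes <- state$cluster_sizes
  nb <- board$adj[[node]]
  list(
    focal = node,
    colour = board$colour[node],
    s_i = sizes[node],
    neighbours = data.frame(node = nb, colour = board$colour[nb], s = sizes[nb]),
    group_points = state$points[board$colour[node]],
    global_largest = state$global_largest
  )
}

#' Boustrophedon (snake) path over the torus grid
#'
#' Row-major with every second row reversed, so consecutive path nodes are
#' always mesh-adjacent; colour blocks laid along it are connected.
#' @param rows,cols grid dimensions.
#' @return integer vector of node ids in path order.
#' @export
snake_path <- function(rows, cols) {
  out <- integer(0)
  for (r in seq_len(rows)) {
    ids <- ((r - 1L) * cols + 1L):(r * cols)
    if (r %% 2 == 0) ids <- rev(ids)
    out <- c(out, ids)
  }
  out
}

#' Colour a board in contiguous blocks along the snake path
#'
#' @param board a \code{swap_board}.
#' @param blocks list of \code{c(colour, length)} pairs covering all n
#'   nodes in path order.
#' @return the coloured board.
#' @export
snake_colour_blocks <- function(board, blocks) {
  path <- snake_path(board$rows, board$cols)
  col <- integer(board$n)
  pos <- 1L
  for (bl in blocks) {
    col[path[pos:(pos + bl[2] - 1L)]] <- bl[1]
    pos <- pos + bl[2]
  }
  if (pos != board$n + 1L) stop("blocks must cover all ", board$n, " nodes")
  board$colour <- as.integer(col)
  board$m <- length(unique(col))
  board$l <- board$n %/% board$m
  board
}

#' Construct a board whose largest clusters match a target
#'
#' Splits each colour into a block of the target size plus remainder
#' blocks, lays the blocks along the snake path, and searches block orders
#' until the realised largest clusters equal the target (merges through
#' off-path adjacencies rule some orders out). Deterministic for a given
#' target.
#'
#' @param largest integer vector, target largest cluster per colour.
#' @param rows,cols grid dimensions (no small-world links are added).
#' @param l group size.
#' @param max_tries search budget over block orders.
#' @return a coloured \code{swap_board} with
#'   \code{largest_clusters(board) == largest}.
#' @export
board_with_largest <- function(largest, rows = 5, cols = 6, l = 10,
                               max_tries = 20000) {
  m <- length(largest)
  if (any(largest < 1 | largest > l)) stop("targets must lie in 1..l")
  board <- generate_board(rows, cols, n_extra_links = 0)
  blocks <- list()
  for (g in seq_len(m)) {
    blocks[[length(blocks) + 1L]] <- c(g, largest[g])
    rem <- l - largest[g]
    while (rem > 0) {
      piece <- min(rem, largest[g])
      # avoid a remainder block tying the target unless unavoidable
      if (piece == largest[g] && rem > 1) piece <- piece - 1L
      blocks[[length(blocks) + 1L]] <- c(g, piece)
      rem <- rem - piece
    }
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(20251L)
  n_block_tries <- min(max_tries, 2000L)
  for (k in seq_len(n_block_tries)) {
    ord <- if (k == 1) seq_along(blocks) else sample(seq_along(blocks))
    cand <- snake_colour_blocks(board, blocks[ord])
    cand$m <- as.integer(m); cand$l <- as.integer(l)
    if (identical(as.integer(largest_clusters(cand)), as.integer(largest))) {
      return(cand)
    }
  }
  # fallback: hill-climb from random colourings, swapping colour pairs to
  # shrink the distance to the target largest-cluster profile
  board$m <- as.integer(m); board$l <- as.integer(l)
  dist <- function(b) sum(abs(largest_clusters(b) - largest))
  for (restart in 1:50) {
    board$colour <- sample(rep(seq_len(m), each = l))
    d <- dist(board)
    for (it in seq_len(2000)) {
      if (d == 0) return(board)
      i <- sample.int(board$n, 1L)
      j <- sample(which(board$colour != board$colour[i]), 1L)
      cand <- board
      cand$colour[c(i, j)] <- board$colour[c(j, i)]
      d2 <- dist(cand)
      if (d2 <= d) { board <- cand; d <- d2 }
    }
    if (d == 0) return(board)
  }
  stop("no colouring realised largest clusters (",
       paste(largest, collapse = ", "), ") within the search budget")
}

#' Write a board as plain text (edge list) plus a JSON colour map
#'
#' The edge list has one \code{"u v"} pair per line, 0-based, mesh edges
#' first; the companion JSON stores dimensions, the mesh/extra split and the
#' colour assignment.
#'
#' @param board a \code{swap_board}.
#' @param edge_file,meta_file output paths.
#' @export
write_board <- function(board, edge_file, meta_file) {
  e <- all_edges(board) - 1L
  writeLines(paste(e[, 1], e[, 2]), edge_file)
  meta <- list(
    rows = board$rows, cols = board$cols, n = board$n,
    n_mesh_edges = nrow(board$mesh_edges),
    max_degree = board$max_degree,
    m = board$m, l = board$l,
    colour = if (anyNA(board$colour)) NULL else board$colour - 1L
  )
  jsonlite::write_json(meta, meta_file, auto_unbox = TRUE, null = "null")
}

#' Read a board written by \code{\link{write_board}}
#' @param edge_file,meta_file paths written by \code{write_board}.
#' @return a \code{swap_board}.
#' @export
read_board <- function(edge_file, meta_file) {
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  lines <- strsplit(readLines(edge_file), " ", fixed = TRUE)
  e <- do.call(rbind, lapply(lines, function(x) as.integer(x) + 1L))
  mesh <- e[seq_len(meta$n_mesh_edges), , drop = FALSE]
  extra <- e[-seq_len(meta$n_mesh_edges), , drop = FALSE]
  colour <- if (is.null(meta$colour)) rep(NA_integer_, meta$n) else as.integer(meta$colour) + 1L
  structure(list(
    rows = meta$rows, cols = meta$cols, n = meta$n,
    mesh_edges = mesh, extra_edges = extra,
    adj = adjacency_list(meta$n, e),
    colour = colour,
    m = if (is.null(meta$m)) NA_integer_ else as.integer(meta$m),
    l = if (is.null(meta$l)) NA_integer_ else as.integer(meta$l),
    max_degree = meta$max_degree
  ), class = "swap_board")
}

#' Export a board as GraphML for external visualisation
#' @param board a \code{swap_board}.
#' @param file output path.
#' @export
write_board_graphml <- function(board, file) {
  cols <- c("red", "green", "blue", "orange", "purple", "cyan")
  nodes <- vapply(seq_len(board$n), function(i) {
    col <- if (is.na(board$colour[i])) "grey" else cols[(board$colour[i] - 1) %% length(cols) + 1]
    sprintf('  <node id="n%d"><data key="colour">%s</data></node>', i - 1L, col)
  }, "")
  e <- all_edges(board) - 1L
  edges <- sprintf('  <edge source="n%d" target="n%d"/>', e[, 1], e[, 2])
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '<key id="colour" for="node" attr.name="colour" attr.type="string"/>',
    '<graph edgedefault="undirected">',
    nodes, edges,
    "</graph>", "</graphml>"
  ), file)
}
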