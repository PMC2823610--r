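# Median-joining haplotype networks for mtDNA control-region (HVRI)
# alignments, hypermutable-site masking by parsimony post-processing, and
# haplogroup assignment of query sequences.
#
# Gaps ('-') and ambiguous bases ('N') are treated as missing: the
# corresponding position is skipped pairwise in all distances.

MISSING_STATES <- c("-", "N", "?")

#' Construct a haplotype alignment
#'
#' @param sequences named character vector of equal-length aligned sequences
#'   over A, C, G, T, '-' and N, or a character matrix (rows = sequences).
#' @param mask optional logical vector per column; `TRUE` = column is used.
#' @return object of class `hap_alignment` with fields `mat` (character
#'   matrix), `ids`, and `mask`.
#' @export
hap_alignment <- function(sequences, mask = NULL) {
  if (is.matrix(sequences)) {
    mat <- toupper(sequences)
  } else {
    if (length(unique(nchar(sequences))) > 1L)
      stop("sequences must all have equal length")
    mat <- do.call(rbind, strsplit(toupper(as.character(sequences)), ""))
    rownames(mat) <- names(sequences)
  }
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("seq", seq_len(nrow(mat)))
  if (is.null(mask)) mask <- rep(TRUE, ncol(mat))
  stopifnot(length(mask) == ncol(mat))
  structure(list(mat = mat, ids = rownames(mat), mask = as.logical(mask)),
            class = "hap_alignment")
}

#' Read an aligned FASTA of HVRI sequences
#' @param file FASTA path.
#' @export
read_hvri_fasta <- function(file) {
  m <- ape::read.dna(file, format = "fasta", as.character = TRUE,
                     as.matrix = TRUE)
  hap_alignment(toupper(m))
}

# Hamming distance between two state vectors over used columns, skipping
# positions where either state is missing.
hap_dist <- function(x, y, mask) {
  use <- mask & !(x %in% MISSING_STATES) & !(y %in% MISSING_STATES) &
    !is.na(x) & !is.na(y)
  sum(x[use] != y[use])
}

node_key <- function(seq, mask) {
  s <- seq[mask]
  s[s %in% MISSING_STATES] <- "."
  s[is.na(s)] <- "."
  paste(s, collapse = "")
}

#' Collapse an alignment into distinct haplotype nodes
#'
#' Sequences identical over the unmasked columns share a node; node
#' multiplicity is its member count.
#'
#' @param aln a [hap_alignment()].
#' @return list of nodes, each `list(seq, members, multiplicity, is_median)`,
#'   with the alignment mask attached as attribute `mask`.
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "hap_alignment"))
  if (nrow(aln$mat) == 0L) stop("empty alignment")
  if (!any(aln$mask)) stop("all columns are masked out")
  keys <- apply(aln$mat, 1L, node_key, mask = aln$mask)
  groups <- split(seq_along(keys), factor(keys, levels = unique(keys)))
  nodes <- lapply(groups, function(ix)
    list(seq = aln$mat[ix[1L], ], members = aln$ids[ix],
         multiplicity = length(ix), is_median = FALSE))
  names(nodes) <- NULL
  attr(nodes, "mask") <- aln$mask
  nodes
}

node_dist_matrix <- function(nodes, mask) {
  n <- length(nodes)
  D <- matrix(0L, n, n)
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- hap_dist(nodes[[i]]$seq, nodes[[j]]$seq, mask)
  D
}

# Prim's MST, deterministic tie-break by lowest vertex index.
# Returns edge matrix (2 columns) and total cost.
mst_edges <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(list(edges = matrix(integer(), 0L, 2L), cost = 0L))
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- D[1L, ]; parent <- rep(1L, n)
  edges <- matrix(0L, n - 1L, 2L); cost <- 0L
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    in_tree[v] <- TRUE
    edges[k, ] <- c(parent[v], v)
    cost <- cost + D[parent[v], v]
    upd <- !in_tree & D[v, ] < best
    best[upd] <- D[v, upd]; parent[upd] <- v
  }
  list(edges = edges, cost = cost)
}

# Minimax (bottleneck) path distances through the MST.
minimax_from_mst <- function(D, edges) {
  n <- nrow(D)
  M <- matrix(0, n, n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1L]; b <- edges[k, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  for (s in seq_len(n)) {
    seen <- rep(FALSE, n); seen[s] <- TRUE
    queue <- s
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in adj[[u]]) if (!seen[v]) {
        seen[v] <- TRUE
        M[s, v] <- max(M[s, u], D[u, v])
        queue <- c(queue, v)
      }
    }
  }
  M
}

msn_adjacency <- function(D, epsilon) {
  mst <- mst_edges(D)
  M <- minimax_from_mst(D, mst$edges)
  A <- D <= (M + epsilon)
  diag(A) <- FALSE
  A
}

median_vector <- function(a, b, c) {
  pick <- function(x, y, z) {
    v <- c(x, y, z)
    known <- !(v %in% MISSING_STATES) & !is.na(v)
    v <- v[known]
    if (!length(v)) return(NA_character_)
    tab <- table(v)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else v[1L]   # 3-way tie: deterministic pick
  }
  mapply(pick, a, b, c, USE.NAMES = FALSE)
}

#' Build a median-joining haplotype network
#'
#' Iterates the median-joining construction: build the epsilon-relaxed
#' minimum spanning network over the current node set; for connected triples
#' compute position-wise majority (median/Steiner) vectors; greedily add the
#' median vector that most reduces the total connection cost (minimum
#' spanning tree length); prune median nodes whose removal does not increase
#' the cost; repeat to a fixed point.  With `epsilon = 0` and no admissible
#' medians the result is the minimum spanning network.
#'
#' @param nodes node list from [collapse_haplotypes()] (mask attached), or a
#'   `hap_alignment`.
#' @param epsilon non-negative integer relaxation parameter (0 = strict).
#' @return object of class `hap_network`: `nodes`, `edges` data.frame
#'   (`from`, `to`, `weight`, `from_median`, `to_median`), `epsilon`, `mask`,
#'   `cost` (total MST length).
#' @export
build_mj_network <- function(nodes, epsilon = 0L) {
  if (inherits(nodes, "hap_alignment")) nodes <- collapse_haplotypes(nodes)
  stopifnot(epsilon >= 0L, length(nodes) >= 1L)
  mask <- attr(nodes, "mask")
  if (is.null(mask)) mask <- rep(TRUE, length(nodes[[1L]]$seq))

  keys <- vapply(nodes, function(nd) node_key(nd$seq, mask), "")
  repeat {
    changed <- FALSE
    D <- node_dist_matrix(nodes, mask)
    cost <- mst_edges(D)$cost
    A <- msn_adjacency(D, epsilon)
    n <- length(nodes)
    # candidate medians from triples with >= 2 linked pairs
    cand <- list(); cand_keys <- character()
    if (n >= 3L) {
      for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
        if (A[i, j] + A[i, k] + A[j, k] < 2L) next
        mv <- median_vector(nodes[[i]]$seq, nodes[[j]]$seq, nodes[[k]]$seq)
        key <- node_key(mv, mask)
        if (key %in% keys || key %in% cand_keys) next
        cand[[length(cand) + 1L]] <- mv
        cand_keys <- c(cand_keys, key)
      }
    }
    if (length(cand)) {
      # cost of MST with each candidate appended
      new_costs <- vapply(cand, function(mv) {
        dv <- vapply(nodes, function(nd) hap_dist(nd$seq, mv, mask), 0)
        D2 <- rbind(cbind(D, dv), c(dv, 0))
        mst_edges(D2)$cost
      }, 0)
      b <- which.min(new_costs)
      if (new_costs[b] < cost) {
        nodes[[length(nodes) + 1L]] <- list(seq = cand[[b]], members = character(),
                                            multiplicity = 0L, is_median = TRUE)
        keys <- c(keys, cand_keys[b])
        changed <- TRUE
      }
    }
    if (!changed) {
      # prune median nodes whose removal leaves the cost unchanged
      repeat {
        med <- which(vapply(nodes, `[[`, TRUE, "is_median"))
        if (!length(med)) break
        D <- node_dist_matrix(nodes, mask)
        cost <- mst_edges(D)$cost
        pruned <- FALSE
        for (m in med) {
          keep <- setdiff(seq_along(nodes), m)
          if (mst_edges(D[keep, keep, drop = FALSE])$cost <= cost) {
            nodes <- nodes[keep]; keys <- keys[keep]
            pruned <- TRUE
            break
          }
        }
        if (!pruned) break
      }
      break
    }
  }

  D <- node_dist_matrix(nodes, mask)
  A <- msn_adjacency(D, epsilon)
  idx <- which(upper.tri(A) & A, arr.ind = TRUE)
  is_med <- vapply(nodes, `[[`, TRUE, "is_median")
  edges <- data.frame(
    from = idx[, 1L], to = idx[, 2L],
    weight = D[idx],
    from_median = is_med[idx[, 1L]], to_median = is_med[idx[, 2L]])
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, epsilon = as.integer(epsilon),
                 mask = mask, cost = mst_edges(D)$cost),
            class = "hap_network")
}

#' @export
print.hap_network <- function(x, ...) {
  cat(sprintf(paste0("hap_network: %d nodes (%d observed, %d median), ",
                     "%d edges, MST cost %d, epsilon %d\n"),
              length(x$nodes), sum(!vapply(x$nodes, `[[`, TRUE, "is_median")),
              sum(vapply(x$nodes, `[[`, TRUE, "is_median")),
              nrow(x$edges), x$cost, x$epsilon))
  invisible(x)
}

#' Total connection cost (MST length) of a network's node set
#' @param network a `hap_network`.
#' @export
network_cost <- function(network) network$cost

# Per-column minimum number of state changes the network topology implies:
# the smallest number of change-edges a spanning tree of the network graph
# needs for that column, i.e. (number of connected components linked only by
# same-state edges) - 1.  Edges touching a missing state are free (the
# unknown state can be imputed).
column_change_counts <- function(network) {
  nodes <- network$nodes
  n <- length(nodes)
  m <- length(nodes[[1L]]$seq)
  ed <- network$edges
  changes <- integer(m)
  for (j in seq_len(m)) {
    if (!network$mask[j]) next
    st <- vapply(nodes, function(nd) nd$seq[j], "")
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (k in seq_len(nrow(ed))) {
      a <- ed$from[k]; b <- ed$to[k]
      free <- st[a] %in% MISSING_STATES || st[b] %in% MISSING_STATES ||
        is.na(st[a]) || is.na(st[b]) || st[a] == st[b]
      if (free) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
    comps <- length(unique(vapply(seq_len(n), find, 0L)))
    changes[j] <- comps - 1L
  }
  changes
}

#' Identify and mask hypermutable alignment columns
#'
#' Parsimony post-processing: on the maximum-parsimony (Steiner) tree inside
#' the current network, count the state changes each column implies; columns
#' changing more than `threshold` times are masked.  The caller should
#' rebuild the network once on the new mask (see
#' [build_haplotype_network()]).
#'
#' @param aln the source [hap_alignment()].
#' @param network a first-pass `hap_network` built from `aln`.
#' @param threshold maximum tolerated number of changes per column
#'   (default 3).
#' @return updated logical mask (existing masked columns stay masked).
#' @export
mask_hypermutable_sites <- function(aln, network, threshold = 3L) {
  changes <- column_change_counts(network)
  mask <- network$mask & (changes <= threshold)
  if (!any(mask))
    stop("threshold ", threshold, " would mask every column")
  mask
}

#' One-shot network construction with hypermutable-site masking
#'
#' Builds a first-pass median-joining network, masks columns whose implied
#' change count exceeds `threshold`, and rebuilds once on the reduced mask.
#'
#' @inheritParams mask_hypermutable_sites
#' @inheritParams build_mj_network
#' @param aln a [hap_alignment()].
#' @return list `network` (final `hap_network`) and `mask`.
#' @export
build_haplotype_network <- function(aln, epsilon = 0L, threshold = 3L) {
  net1 <- build_mj_network(collapse_haplotypes(aln), epsilon)
  mask <- mask_hypermutable_sites(aln, net1, threshold)
  aln2 <- hap_alignment(aln$mat, mask)
  list(network = build_mj_network(collapse_haplotypes(aln2), epsilon),
       mask = mask)
}

#' Assign a haplogroup label to a query sequence
#'
#' Nearest-reference rule: the query receives the label of the reference
#' haplotype minimising the Hamming distance over unmasked sites.  A tie
#' across different labels yields `"unknown"` with a warning.
#'
#' @param query a single aligned sequence (string or character vector).
#' @param references named list, label -> character vector of reference
#'   sequences (same alignment length).
#' @param mask optional logical column mask (default: all columns used).
#' @return a haplogroup label, or `"unknown"` on ambiguity.
#' @export
assign_haplogroup <- function(query, references, mask = NULL) {
  q <- if (length(query) == 1L) strsplit(toupper(query), "")[[1L]] else toupper(query)
  if (!length(references)) stop("references must be non-empty")
  if (is.null(mask)) mask <- rep(TRUE, length(q))
  best_per_label <- vapply(references, function(refs) {
    min(vapply(refs, function(r) {
      rv <- if (length(r) == 1L) strsplit(toupper(r), "")[[1L]] else toupper(r)
      if (length(rv) != length(q))
        stop("reference length ", length(rv), " != query length ", length(q))
      hap_dist(q, rv, mask)
    }, 0))
  }, 0)
  winners <- names(best_per_label)[best_per_label == min(best_per_label)]
  if (length(winners) > 1L) {
    warning("ambiguous haplogroup assignment (tie between ",
            paste(winners, collapse = ", "), "); returning 'unknown'")
    return("unknown")
  }
  winners
}

#' Write a network edge list as a tab-separated file
#' @param network a `hap_network`.
#' @param file path or connection.
#' @export
write_network_edges <- function(network, file) {
  lab <- node_labels(network)
  df <- network$edges
  out <- data.frame(node_a = lab[df$from], node_b = lab[df$to],
                    weight = df$weight,
                    a_is_median = df$from_median, b_is_median = df$to_median)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

node_labels <- function(network) {
  vapply(seq_along(network$nodes), function(i) {
    nd <- network$nodes[[i]]
    if (nd$is_median) sprintf("mv%d", i) else nd$members[1L]
  }, "")
}

#' Write a network in Graphviz DOT format
#' @param network a `hap_network`.
#' @param file path or connection.
#' @export
write_network_dot <- function(network, file) {
  lab <- node_labels(network)
  lines <- c("graph haplotypes {",
             sprintf("  \"%s\" [shape=%s];", lab,
                     ifelse(vapply(network$nodes, `[[`, TRUE, "is_median"),
                            "point", "circle")),
             sprintf("  \"%s\" -- \"%s\" [label=%d];",
                     lab[network$edges$from], lab[network$edges$to],
                     network$edges$weight),
             "}")
  writeLines(lines, file)
  invisible(lines)
}
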