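# Subcomponent search: count appearances of a small element-labelled query
# graph in the shell-restricted bond graph of a target particle.
#
# Matching is subgraph monomorphism by default (every query edge must map to
# a target edge; extra target edges among matched atoms are allowed); the
# induced = TRUE flag forbids those extra edges. Embeddings that cover the
# same set of target atoms (query automorphisms) are collapsed to a single
# counted appearance. All matched atoms must lie in the shell.

#' Search for a local structure in a particle's shell
#'
#' Builds the bond graph of `target`, restricts it to shell-shell edges for
#' the given `thickness`, and enumerates element-label-preserving embeddings
#' of `query` into it by backtracking. To search the whole particle, pass a
#' thickness of at least half its size.
#'
#' Matching is purely topological: the query's geometry only enters through
#' bond inference (when the query is given as a structure rather than a
#' [pattern_graph()]).
#'
#' @param target a [nano_structure()].
#' @param query a [pattern_graph()] or a [nano_structure()] (bonds inferred
#'   with the same `tolerance`).
#' @param thickness shell thickness, Angstrom.
#' @param tolerance bond-inference tolerance factor.
#' @param induced if `TRUE`, require induced subgraph isomorphism (no extra
#'   target edges among matched atoms).
#' @return object of class `match_result`: `count` (number of distinct
#'   matched atom sets), `embeddings` (list of integer maps, query node ->
#'   target atom index; one representative per atom set), `shell`.
#' @export
find_subcomponents <- function(target, query, thickness, tolerance = 1.15,
                               induced = FALSE) {
  stopifnot(inherits(target, "nano_structure"))
  if (inherits(query, "nano_structure")) {
    query <- structure_to_pattern(query, tolerance)
  }
  stopifnot(inherits(query, "pattern_graph"))
  if (!all(is_known_element(query$nodes))) {
    stop("query contains unknown element label(s)", call. = FALSE)
  }

  shell <- assign_shell(target, thickness)
  bg <- shell_subgraph(infer_bonds(target, tolerance), shell, target$elements)

  nq <- length(query$nodes)
  nt <- bg$n_atoms
  # adjacency as a set-per-atom representation
  adj <- vector("list", nt)
  if (nrow(bg$edges) > 0) {
    for (k in seq_len(nrow(bg$edges))) {
      i <- bg$edges[k, 1]; j <- bg$edges[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  q_adj <- vector("list", nq)
  if (nrow(query$edges) > 0) {
    for (k in seq_len(nrow(query$edges))) {
      i <- query$edges[k, 1]; j <- query$edges[k, 2]
      q_adj[[i]] <- c(q_adj[[i]], j)
      q_adj[[j]] <- c(q_adj[[j]], i)
    }
  }
  q_deg <- lengths(q_adj)

  # candidate targets per query node: shell atoms of the right element with
  # enough shell-subgraph degree
  shell_atoms <- which(shell$is_shell)
  cand <- lapply(seq_len(nq), function(u) {
    shell_atoms[target$elements[shell_atoms] == query$nodes[u] &
                  bg$degree[shell_atoms] >= q_deg[u]]
  })
  if (any(lengths(cand) == 0)) {
    return(new_match_result(list(), shell, query))
  }

  # visit order: rarest candidate set first, then prefer nodes adjacent to
  # already-placed ones so edge constraints prune early
  order <- integer(nq)
  placed <- logical(nq)
  order[1] <- which.min(lengths(cand))
  placed[order[1]] <- TRUE
  for (s in seq_len(nq - 1L)) {
    frontier <- which(!placed & vapply(q_adj, function(nb) any(placed[nb]), logical(1)))
    pick <- if (length(frontier) > 0) frontier[which.min(lengths(cand)[frontier])]
            else which(!placed)[which.min(lengths(cand)[which(!placed)])]
    order[s + 1L] <- pick
    placed[pick] <- TRUE
  }

  found <- new.env(parent = emptyenv())  # atom-set key -> representative map
  assignment <- integer(nq)
  used <- logical(nt)

  recurse <- function(depth) {
    if (depth > nq) {
      if (induced) {
        # every target edge among matched atoms must be a query edge
        matched <- assignment
        q_edge_key <- character(0)
        if (nrow(query$edges) > 0) {
          q_edge_key <- paste(pmin(matched[query$edges[, 1]], matched[query$edges[, 2]]),
                              pmax(matched[query$edges[, 1]], matched[query$edges[, 2]]))
        }
        for (u in seq_len(nq)) {
          extra <- intersect(adj[[matched[u]]], matched)
          for (v in extra) {
            key <- paste(min(matched[u], v), max(matched[u], v))
            if (!key %in% q_edge_key) return(invisible(NULL))
          }
        }
      }
      key <- paste(sort(assignment), collapse = ",")
      if (is.null(found[[key]])) found[[key]] <- assignment
      return(invisible(NULL))
    }
    u <- order[depth]
    need <- q_adj[[u]]
    for (a in cand[[u]]) {
      if (used[a]) next
      ok <- TRUE
      for (v in need) {
        if (assignment[v] != 0L && !(assignment[v] %in% adj[[a]])) { ok <- FALSE; break }
      }
      if (!ok) next
      assignment[u] <<- a
      used[a] <<- TRUE
      recurse(depth + 1L)
      used[a] <<- FALSE
      assignment[u] <<- 0L
    }
    invisible(NULL)
  }
  recurse(1L)

  embeddings <- as.list(found)
  names(embeddings) <- NULL
  new_match_result(embeddings, shell, query)
}

new_match_result <- function(embeddings, shell, query) {
  structure(
    list(count = length(embeddings), embeddings = embeddings,
         shell = shell, query = query),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: %d appearance(s) of a %d-node query in the shell>\n",
              x$count, length(x$query$nodes)))
  invisible(x)
}

#' Write matched atoms as XYZ
#'
#' Emits one XYZ model per matched appearance into a single multi-model file
#' (models concatenated; each carries its own count/comment header), so the
#' hits can be visualised with standard tooling.
#'
#' @param result a `match_result` from [find_subcomponents()].
#' @param target the searched [nano_structure()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matches_xyz <- function(result, target, path) {
  stopifnot(inherits(result, "match_result"), inherits(target, "nano_structure"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(result$embeddings)) {
    atoms <- result$embeddings[[k]]
    writeLines(as.character(length(atoms)), con)
    writeLines(sprintf("match %d of %d", k, result$count), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", target$elements[atoms],
                       target$coords[atoms, 1], target$coords[atoms, 2],
                       target$coords[atoms, 3]), con)
  }
  if (length(result$embeddings) == 0) {
    writeLines(c("0", "no matches"), con)
  }
  invisible(path)
}
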