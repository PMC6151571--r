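# Gene Ontology DAG: OBO 1.2 parsing, validation, ancestor/descendant closures.

GO_NAMESPACES <- c("biological_process", "cellular_component", "molecular_function")

#' Parse an OBO 1.2 ontology into a GO DAG
#'
#' Reads `[Term]` stanzas from an OBO 1.2 flat file and builds a directed
#' acyclic graph of GO terms. Both `is_a` and `relationship: part_of` links
#' are treated identically as parent edges; all other relationship types are
#' ignored. Obsolete terms are dropped, as are parent links that point outside
#' the retained term set or across namespaces. Each of the three namespaces
#' (biological_process, cellular_component, molecular_function) present in the
#' file must contain exactly one parentless term, its root.
#'
#' @param x OBO text (a character blob or vector of lines) or a file path.
#' @return An object of class `go_dag`: a list with elements
#'   `ids` (character vector of term ids), `name`, `namespace` (named by id),
#'   `parents` and `children` (named lists of character vectors), and
#'   `roots` (named by namespace).
#' @examples
#' obo <- paste(
#'   "format-version: 1.2", "",
#'   "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process", "",
#'   "[Term]", "id: GO:0000002", "name: child", "namespace: biological_process",
#'   "is_a: GO:0000001 ! root", sep = "\n")
#' dag <- parse_obo(obo)
#' dag$roots
#' @export
parse_obo <- function(x) {
  lines <- read_lines_flex(x)
  n <- length(lines)
  terms <- list()
  cur <- NULL
  cur_line <- NA_integer_
  in_term <- FALSE

  flush_term <- function(cur, cur_line) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$id) || is.null(cur$namespace)) {
      stop2("malformed [Term] stanza starting at line ", cur_line,
            ": missing id or namespace")
    }
    cur
  }

  for (i in seq_len(n)) {
    line <- sub("\\s+$", "", lines[[i]])
    if (line == "") next
    if (grepl("^\\[", line)) {
      t <- flush_term(cur, cur_line)
      if (!is.null(t)) terms[[length(terms) + 1L]] <- t
      cur <- NULL
      if (line == "[Term]") {
        in_term <- TRUE
        cur <- list(parents = character(0), relations = character(0),
                    obsolete = FALSE)
        cur_line <- i
      } else {
        in_term <- FALSE
      }
      next
    }
    if (!in_term) next
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1L]]
    if (length(m) == 0L) stop2("malformed line ", i, " in OBO input: ", line)
    key <- m[[2L]]
    val <- m[[3L]]
    if (key == "id") {
      if (!grepl(GO_ID_RE, val)) stop2("malformed GO id at line ", i, ": ", val)
      cur$id <- val
    } else if (key == "name") {
      cur$name <- val
    } else if (key == "namespace") {
      if (!val %in% GO_NAMESPACES) stop2("unknown namespace at line ", i, ": ", val)
      cur$namespace <- val
    } else if (key == "is_a") {
      pid <- sub("\\s*!.*$", "", val)
      if (!grepl(GO_ID_RE, pid)) stop2("malformed is_a target at line ", i, ": ", val)
      cur$parents <- c(cur$parents, pid)
      cur$relations <- c(cur$relations, "is_a")
    } else if (key == "relationship") {
      parts <- strsplit(sub("\\s*!.*$", "", val), "\\s+")[[1L]]
      if (length(parts) == 2L && parts[[1L]] == "part_of") {
        if (!grepl(GO_ID_RE, parts[[2L]])) {
          stop2("malformed relationship target at line ", i, ": ", val)
        }
        cur$parents <- c(cur$parents, parts[[2L]])
        cur$relations <- c(cur$relations, "part_of")
      }
      # other relationship types (regulates, ...) carry no parent semantics here
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(tolower(val), "true")
    }
  }
  t <- flush_term(cur, cur_line)
  if (!is.null(t)) terms[[length(terms) + 1L]] <- t

  terms <- Filter(function(t) !t$obsolete, terms)
  if (length(terms) == 0L) stop2("no non-obsolete [Term] stanzas found")
  ids <- vapply(terms, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop2("duplicate term id: ", ids[duplicated(ids)][[1L]])
  }
  name <- setNames(vapply(terms, function(t) t$name %||% "", character(1)), ids)
  namespace <- setNames(vapply(terms, `[[`, character(1), "namespace"), ids)

  parents <- setNames(vector("list", length(ids)), ids)
  relations <- setNames(vector("list", length(ids)), ids)
  for (t in terms) {
    keep <- t$parents %in% ids & namespace[t$parents] == t$namespace
    keep[is.na(keep)] <- FALSE
    p <- t$parents[keep]
    r <- t$relations[keep]
    dup <- duplicated(p)
    parents[[t$id]] <- p[!dup]
    relations[[t$id]] <- r[!dup]
  }

  new_go_dag(ids, name, namespace, parents, relations)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Assemble + validate a go_dag from its parts.
new_go_dag <- function(ids, name, namespace, parents, relations = NULL) {
  children <- setNames(replicate(length(ids), character(0), simplify = FALSE), ids)
  for (id in ids) {
    for (p in parents[[id]]) {
      children[[p]] <- c(children[[p]], id)
    }
  }
  # acyclicity via igraph on the parent-edge graph
  edges <- unlist(lapply(ids, function(id) {
    ps <- parents[[id]]
    if (length(ps) == 0L) return(character(0))
    rbind(rep(id, length(ps)), ps)
  }))
  if (length(edges) > 0L) {
    g <- igraph::make_graph(edges, directed = TRUE)
    if (!igraph::is_dag(g)) {
      comp <- igraph::components(igraph::make_graph(edges, directed = TRUE), "strong")
      cyc <- names(comp$membership)[comp$membership == which(comp$csize > 1)[1L]]
      stop2("ontology contains a cycle involving ", cyc[[1L]])
    }
  }
  roots <- character(0)
  for (ns in GO_NAMESPACES) {
    in_ns <- ids[namespace[ids] == ns]
    if (length(in_ns) == 0L) next
    parentless <- in_ns[vapply(parents[in_ns], length, integer(1)) == 0L]
    if (length(parentless) != 1L) {
      stop2("namespace ", ns, " has ", length(parentless),
            " parentless terms (expected exactly 1 root)")
    }
    roots[[ns]] <- parentless
  }
  structure(
    list(ids = ids, name = name, namespace = namespace,
         parents = parents, relations = relations,
         children = lapply(children, function(x) sort(unique(x))),
         roots = roots),
    class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat("go_dag with", length(x$ids), "terms in",
      length(x$roots), "namespace(s)\n")
  for (ns in names(x$roots)) {
    cat("  ", ns, ": ", sum(x$namespace == ns), " terms, root ",
        x$roots[[ns]], "\n", sep = "")
  }
  invisible(x)
}

#' Number of terms in a GO DAG
#' @param dag A `go_dag`.
#' @return Integer count of terms.
#' @export
n_terms <- function(dag) length(dag$ids)

assert_in_dag <- function(dag, go_ids) {
  missing <- setdiff(go_ids, dag$ids)
  if (length(missing) > 0L) {
    stop2("unknown GO id(s): ", paste(head(missing, 5L), collapse = ", "))
  }
  invisible(go_ids)
}

#' Ancestor closure of a GO term
#'
#' Returns the reflexive-transitive closure over parent edges (`is_a` and
#' `part_of` alike): the term itself plus every term on any path up to its
#' namespace root, root included. This is the "propagation to the root" used
#' throughout evaluation.
#'
#' @param dag A `go_dag`.
#' @param go_id A single term id present in `dag`.
#' @return Character vector of term ids (sorted).
#' @export
go_ancestors <- function(dag, go_id) {
  assert_in_dag(dag, go_id)
  closure_over(dag$parents, go_id, reflexive = TRUE)
}

#' Descendant set of a GO term
#'
#' All terms below `go_id` in the DAG (transitive closure over child edges),
#' excluding the term itself.
#'
#' @inheritParams go_ancestors
#' @return Character vector of term ids (sorted), empty for a leaf.
#' @export
go_descendants <- function(dag, go_id) {
  assert_in_dag(dag, go_id)
  closure_over(dag$children, go_id, reflexive = FALSE)
}

closure_over <- function(adj, start, reflexive) {
  seen <- new.env(parent = emptyenv())
  queue <- start
  while (length(queue) > 0L) {
    id <- queue[[length(queue)]]
    queue <- queue[-length(queue)]
    if (exists(id, envir = seen, inherits = FALSE)) next
    assign(id, TRUE, envir = seen)
    nxt <- adj[[id]]
    if (length(nxt) > 0L) queue <- c(queue, nxt)
  }
  out <- ls(seen)
  if (!reflexive) out <- setdiff(out, start)
  sort(out)
}

# Edge distance from each descendant of `go_id` down the DAG (BFS).
descendant_distances <- function(dag, go_id) {
  dist <- c(setNames(0L, go_id))
  frontier <- go_id
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    nxt <- unique(unlist(dag$children[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, names(dist))
    if (length(nxt) == 0L) break
    dist[nxt] <- d
    frontier <- nxt
  }
  dist[-1L]
}
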